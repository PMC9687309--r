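#' Material parameter set
#'
#' Bundles the constants of the two density--modulus laws used throughout the
#' package: the SIMP power law for micro-level (design) elements and the
#' piecewise BMD--modulus regression for continuum-level (non-design)
#' elements.
#'
#' @param E0 Reference elastic modulus in Pa. Default 15 GPa, the modulus of
#'   fully mineralized cortical/trabecular tissue.
#' @param gamma SIMP penalization exponent (dimensionless, >= 1). Default 3.
#' @param nu Poisson ratio, in (0, 0.5). Default 0.3 for all elements.
#' @param rho_min Lower relative-density bound (bone marrow). Default 0.01.
#' @param rho_max Upper relative-density bound (solid bone). Default 1.
#'
#' @return An object of class \code{material_params}.
#' @export
#' @examples
#' p <- material_params()
#' simp_modulus(0.5, p) / 1e9   # 1.875 GPa
material_params <- function(E0 = 15e9, gamma = 3, nu = 0.3,
                            rho_min = 0.01, rho_max = 1) {
  stopifnot(is.numeric(E0), length(E0) == 1L, E0 > 0)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 1)
  stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0, nu < 0.5)
  stopifnot(is.numeric(rho_min), is.numeric(rho_max),
            rho_min > 0, rho_min < rho_max, rho_max <= 1)
  structure(list(E0 = E0, gamma = gamma, nu = nu,
                 rho_min = rho_min, rho_max = rho_max),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Material parameters:\n")
  cat(sprintf("  E0      : %.4g GPa\n", x$E0 / 1e9))
  cat(sprintf("  gamma   : %g (SIMP exponent)\n", x$gamma))
  cat(sprintf("  nu      : %g\n", x$nu))
  cat(sprintf("  density : [%g, %g]\n", x$rho_min, x$rho_max))
  invisible(x)
}

#' SIMP density--modulus law (micro level)
#'
#' Power-law interpolation \eqn{E(\rho) = \rho^\gamma E_0} used for the
#' design elements of the region of interest. Penalization (\eqn{\gamma > 1})
#' makes intermediate densities structurally inefficient, driving the
#' optimizer toward near-solid/near-void trabecular patterns.
#'
#' @param rho Relative density, scalar or array, within
#'   \code{[params$rho_min, params$rho_max]}.
#' @param params A \code{\link{material_params}} object.
#' @return Elastic modulus in Pa, same shape as \code{rho}.
#' @export
simp_modulus <- function(rho, params = material_params()) {
  check_density(rho, lower = params$rho_min, upper = params$rho_max)
  rho^params$gamma * params$E0
}

#' Continuum BMD--modulus law (macro level)
#'
#' Piecewise power-law relationship between relative density and elastic
#' modulus used for the non-design (continuum) elements:
#' \deqn{E = 0.3044\,(2\rho)^{1.49} E_0 \quad (\rho \le 0.84)}
#' \deqn{E = 0.1908\,(2\rho)^{2.39} E_0 \quad (\rho > 0.84)}
#' The factor 2 maps relative density onto the apparent-density scale of the
#' underlying regression; with it, the two branches agree at the 0.84 break
#' point and \eqn{E(1) = E_0} to within 0.1\%.
#'
#' @inheritParams simp_modulus
#' @return Elastic modulus in Pa, same shape as \code{rho}.
#' @export
continuum_modulus <- function(rho, params = material_params()) {
  check_density(rho, lower = NA, upper = 1)
  if (any(rho <= 0, na.rm = TRUE))
    stop("continuum_modulus() requires rho > 0", call. = FALSE)
  lo <- 0.3044 * (2 * rho)^1.49
  hi <- 0.1908 * (2 * rho)^2.39
  ifelse_keep_shape(rho <= 0.84, lo, hi) * params$E0
}

# shape-preserving ifelse (base ifelse drops dim attributes)
ifelse_keep_shape <- function(test, yes, no) {
  out <- no
  out[test] <- yes[test]
  out
}

check_density <- function(rho, lower, upper) {
  if (!is.numeric(rho))
    stop("density must be numeric", call. = FALSE)
  if (any(!is.finite(rho)))
    stop("density contains non-finite values", call. = FALSE)
  if (any(rho < 0) || any(rho > 1))
    stop("density outside [0, 1]", call. = FALSE)
  if (!is.na(lower) && (any(rho < lower - 1e-12) || any(rho > upper + 1e-12)))
    stop(sprintf("density outside [%g, %g]", lower, upper), call. = FALSE)
  invisible(TRUE)
}
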