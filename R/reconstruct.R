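#' Optimizer control parameters
#'
#' @param epsilon Bound on the density-deviation constraint
#'   \eqn{g(\rho) = \frac1N \sum_i (\rho_i - \rho_{0,i})^2 \le \epsilon}.
#'   Default 0.01.
#' @param filter_radius Density-filter radius in HR-element widths
#'   (default 2.5, giving strut widths of a few elements — the
#'   trabecular scale at the target resolution; 0 disables filtering).
#' @param move_limit MMA move limit as a fraction of the density range.
#' @param max_iters Iteration cap (default 700).
#' @param change_tol Convergence threshold on the maximum absolute design
#'   change per iteration (default 0.01).
#' @param solver \code{"auto"}, \code{"full"} (solve the whole refined
#'   global model each iteration) or \code{"condensed"} (exact one-time
#'   static condensation of the non-design exterior; identical results).
#' @param condense_threshold Exterior-DOF count above which \code{"auto"}
#'   switches to the condensed solver.
#' @param verbose Print a per-iteration log line.
#' @return A list of class \code{recon_control}.
#' @export
recon_control <- function(epsilon = 0.01, filter_radius = 2.5,
                          move_limit = 0.2, max_iters = 700,
                          change_tol = 0.01,
                          solver = c("auto", "full", "condensed"),
                          condense_threshold = 20000, verbose = FALSE) {
  stopifnot(epsilon > 0, filter_radius >= 0, move_limit > 0, max_iters >= 1,
            change_tol >= 0)
  structure(list(epsilon = epsilon, filter_radius = filter_radius,
                 move_limit = move_limit, max_iters = max_iters,
                 change_tol = change_tol, solver = match.arg(solver),
                 condense_threshold = condense_threshold,
                 verbose = isTRUE(verbose)),
            class = "recon_control")
}

#' Density-deviation constraint value
#'
#' Mean squared deviation between the current and input density fields:
#' \eqn{g(\rho) = \frac1N \sum_i (\rho_i - \rho_{0,i})^2}. Keeping it below
#' a small \eqn{\epsilon} preserves the patient-specific continuum density
#' information while the compliance objective redistributes material.
#'
#' @param rho,rho0 Density vectors/matrices of identical length.
#' @return Scalar g (dimensionless).
#' @export
constraint_value <- function(rho, rho0) {
  if (length(rho) != length(rho0))
    stop("rho and rho0 differ in length", call. = FALSE)
  mean((as.numeric(rho) - as.numeric(rho0))^2)
}

#' Weighted multi-load compliance objective
#'
#' \eqn{f(\rho) = \sum_j c_j \frac12 u_j^T K u_j}, computed by one linear
#' solve per load case on the given model.
#'
#' @param model A constrained \code{fe_model} (its moduli encode the
#'   current densities).
#' @param loads Load vector or matrix (one column per case).
#' @param weights Case weights summing to 1 (default: single case weight 1).
#' @return Compliance in J (for unit thickness).
#' @export
compliance_objective <- function(model, loads, weights = NULL) {
  F <- as.matrix(loads)
  if (is.null(weights)) weights <- rep(1 / ncol(F), ncol(F))
  stopifnot(length(weights) == ncol(F))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("case weights must sum to 1", call. = FALSE)
  U <- as.matrix(fe_solve(model, F))
  sum(weights * 0.5 * colSums(F * U))
}

#' Compliance and constraint sensitivities
#'
#' Self-adjoint SIMP compliance sensitivity for the design elements:
#' \eqn{\partial f/\partial\rho_i = -\sum_j c_j\,\gamma\rho_i^{\gamma-1}E_0
#' \,(\frac12 u_{e,j}^T k_0 u_{e,j})}, which is nonpositive everywhere, and
#' the constraint gradient \eqn{\partial g/\partial \rho_i =
#' 2(\rho_i - \rho_{0,i})/N}.
#'
#' @param rho Design densities (vector, design-element order).
#' @param model The \code{fe_model} the displacements were computed on.
#' @param design_ids Element ids of the design variables.
#' @param U Displacement matrix (one column per case).
#' @param weights Case weights.
#' @param params \code{\link{material_params}}.
#' @param rho0 Input densities (for the constraint gradient).
#' @return List with \code{dF} and \code{dG}.
#' @export
compliance_sensitivities <- function(rho, model, design_ids, U, weights,
                                     params = material_params(),
                                     rho0 = rho) {
  U <- as.matrix(U)
  q <- matrix(0, length(design_ids), ncol(U))
  ke <- unit_ke(model$nu)
  for (j in seq_len(ncol(U))) {
    ue <- matrix(U[model$edof[design_ids, , drop = FALSE], j],
                 length(design_ids), 8)
    q[, j] <- 0.5 * rowSums((ue %*% ke) * ue)
  }
  dF <- -params$gamma * rho^(params$gamma - 1) * params$E0 *
    as.numeric(q %*% weights)
  dG <- 2 * (rho - rho0) / length(rho)
  list(dF = dF, dG = dG)
}

#' Cone-weighted density filter
#'
#' Linear filtering of a design-density field with cone weights
#' \eqn{w = \max(0, r - d)} over the neighborhood of each element, rows
#' normalized (partition of unity: constants are unchanged). Radius 0
#' returns the input. Suppresses checkerboard patterns and sets the minimum
#' feature scale of the reconstructed trabeculae.
#'
#' @param field Numeric matrix (design grid).
#' @param radius Filter radius in element widths.
#' @return Filtered matrix of the same shape.
#' @export
density_filter <- function(field, radius) {
  stopifnot(is.matrix(field), radius >= 0)
  if (radius == 0) return(field)
  w <- filter_offsets(radius)
  num <- shift_accumulate(field, w)
  den <- shift_accumulate(matrix(1, nrow(field), ncol(field)), w)
  num / den
}

# adjoint of density_filter (H^T y for the row-normalized H)
density_filter_t <- function(y, radius) {
  if (radius == 0) return(y)
  w <- filter_offsets(radius)
  den <- shift_accumulate(matrix(1, nrow(y), ncol(y)), w)
  shift_accumulate(y / den, w)
}

filter_offsets <- function(radius) {
  r <- ceiling(radius - 1e-9) - 1L
  r <- max(r, 0L)
  g <- expand.grid(di = -r:r, dj = -r:r)
  d <- sqrt(g$di^2 + g$dj^2)
  keep <- d < radius
  list(di = g$di[keep], dj = g$dj[keep], w = radius - d[keep])
}

shift_accumulate <- function(m, off) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  for (k in seq_along(off$w)) {
    di <- off$di[k]; dj <- off$dj[k]
    ri <- max(1, 1 + di):min(ny, ny + di)
    ci <- max(1, 1 + dj):min(nx, nx + dj)
    out[ri, ci] <- out[ri, ci] + off$w[k] * m[ri - di, ci - dj, drop = FALSE]
  }
  out
}

#' Reconstruct trabecular microstructure in a region of interest
#'
#' Compliance-minimizing topology optimization of the HR density field in
#' the ROI under the density-deviation constraint, by either of two routes:
#' \describe{
#'   \item{\code{mode = "global"} (conventional)}{the whole LR image is
#'     refined n x n; ROI sub-elements follow the SIMP law as design
#'     variables, all others the continuum BMD law, and the full refined
#'     global model is solved under the global loads at every design
#'     update.}
#'   \item{\code{mode = "localized"}}{physiological local loads for the ROI
#'     are first estimated on the LR model by static condensation
#'     (\code{\link{estimate_local_loads}}), then only the refined
#'     localized model is optimized under those fixed boundary loads, with
#'     three pinned corner DOFs removing the rigid-body modes of the
#'     self-equilibrated load set.}
#' }
#' Both modes iterate: FE solve per load case, filtered compliance
#' sensitivities, MMA design update, until the maximum density change drops
#' below \code{control$change_tol} or \code{control$max_iters} is reached.
#' The design is initialized at the refined input densities (a feasible
#' start) and the objective is normalized by its initial value.
#'
#' @param x A \code{\link{femur_phantom}} (image + landmarks) or a
#'   \code{\link{density_image}} (then \code{loads} is required).
#' @param roi A \code{\link{roi_spec}}.
#' @param mode \code{"localized"} or \code{"global"}.
#' @param n Refinement factor (default 12: 600 to 50 um).
#' @param load_cases List of \code{\link{load_case}} objects (phantom
#'   input only).
#' @param material \code{\link{material_params}}.
#' @param control \code{\link{recon_control}}.
#' @param loads Optional: function(model) returning a load matrix (one
#'   column per case) for the given model; overrides \code{load_cases}.
#' @param weights Case weights (required with \code{loads}).
#' @return An object of class \code{bone_recon}.
#' @export
reconstruct <- function(x, roi, mode = c("localized", "global"), n = 12,
                        load_cases = default_load_cases(),
                        material = material_params(),
                        control = recon_control(),
                        loads = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "femur_phantom")) {
    image <- x$image
    landmarks <- x$landmarks
    if (is.null(loads)) {
      loads <- function(model)
        vapply(load_cases, distribute_load, numeric(model$ndof),
               landmarks = landmarks, model = model)
      weights <- vapply(load_cases, function(lc) lc$weight, numeric(1))
    }
  } else if (inherits(x, "density_image")) {
    image <- x
    if (is.null(loads))
      stop("supply a loads function when x is a density_image",
           call. = FALSE)
  } else stop("x must be a femur_phantom or density_image", call. = FALSE)
  if (is.null(weights)) stop("weights required", call. = FALSE)
  weights <- weights / sum(weights)
  validate_roi(image, roi)

  if (mode == "global") {
    br <- build_refined_model(image, roi, n, material)
    F <- as.matrix(loads(br$model))
    design_ids <- as.vector(br$design_eid)
    ev <- make_case_evaluator(br$model, design_ids, F,
                              solver = control$solver,
                              condense_threshold = control$condense_threshold,
                              roi = roi, n = n)
    rho0 <- br$rho0
    lr_win <- extract_roi(image, roi)
    rho0_lr <- matrix(pmax(lr_win$values, material$rho_min),
                      roi$rows, roi$cols)
    extras <- list(hr_image = br$hr_image)
  } else {
    lr_model <- build_lr_continuum_model(image, material)
    F_lr <- as.matrix(loads(lr_model))
    lls <- estimate_local_loads(lr_model, F_lr, roi, image)
    hr_img <- refine_image(extract_roi(image, roi), n)
    hr_model <- build_fe_model(hr_img, moduli = 1, nu = material$nu)
    hr_model$fixed_dofs <- pin_corner_dofs(hr_model)
    F <- lift_local_loads(lls, n, hr_model)
    design_ids <- seq_len(hr_model$nel)
    ev <- make_case_evaluator(hr_model, design_ids, F, solver = "full")
    rho0 <- matrix(pmax(hr_img$values, material$rho_min),
                   nrow(hr_img$values), ncol(hr_img$values))
    rho0_lr <- matrix(pmax(extract_roi(image, roi)$values,
                           material$rho_min), roi$rows, roi$cols)
    extras <- list(local_loads = lls, hr_image = hr_img)
  }

  res <- optimize_density(ev, rho0, rho0_lr, n, weights, material, control)
  out <- c(res,
           list(mode = mode, roi = roi, n = n,
                pixel_size_um = image$pixel_size_um / n,
                weights = weights, material = material, control = control),
           extras)
  class(out) <- "bone_recon"
  out
}

#' Build the LR continuum global model
#'
#' One element per active LR pixel, continuum BMD moduli (densities floored
#' at the design lower bound), distal bottom edge fully fixed.
#'
#' @param image LR \code{\link{density_image}}.
#' @param material \code{\link{material_params}}.
#' @return A constrained \code{fe_model}.
#' @export
build_lr_continuum_model <- function(image, material = material_params()) {
  m <- build_fe_model(image, moduli = 1, nu = material$nu)
  rho <- pmax(image$values[cbind(m$elem_rc[, 1], m$elem_rc[, 2])],
              material$rho_min)
  m$moduli <- continuum_modulus(rho, material)
  m$fixed_dofs <- edge_fixed_dofs(m, "bottom")
  m
}

# minimal rigid-body restraint for the self-equilibrated localized model:
# both DOFs of the lower-left corner node plus uy of the lower-right corner
pin_corner_dofs <- function(model) {
  a <- model$nid[1, 1]
  b <- model$nid[1, ncol(model$nid)]
  stopifnot(!is.na(a), !is.na(b))
  sort(c(2L * a - 1L, 2L * a, 2L * b))
}

# The optimization loop shared by both modes. eval_cases(E) must return
# list(compliance = per-case 1/2 f'u, q = ndesign x J matrix of
# unit-modulus element strain energies 1/2 u' k0 u).
#
# The density-deviation constraint acts on the continuum-level density: the
# mean of the HR design field over each parent LR pixel is held within the
# epsilon budget of that pixel's input density, which preserves the
# patient-specific BMD map while letting the penalized (SIMP) objective
# segregate material into discrete trabeculae inside each pixel.
optimize_density <- function(ev, rho0, rho0_lr, n_block, weights, material,
                             control) {
  rho0v <- as.numeric(rho0)
  nr <- nrow(rho0); nc <- ncol(rho0)
  bid <- matrix(0L, nr, nc)   # LR-block id of each HR design element
  bid[] <- (rep(ceiling(seq_len(nc) / n_block), each = nr) - 1L) *
    (nr / n_block) + rep(ceiling(seq_len(nr) / n_block), nc)
  rho0_lrv <- as.numeric(rho0_lr)
  N_lr <- length(rho0_lrv)
  stopifnot(N_lr * n_block^2 == length(rho0v), max(bid) == N_lr)
  bidv <- as.integer(bid)
  x <- pmin(pmax(rho0v, material$rho_min), material$rho_max)
  state <- NULL
  f_hist <- g_hist <- ch_hist <- numeric(0)
  f0 <- NULL
  converged <- FALSE
  restored <- 0L
  rad <- control$filter_radius
  # Continuation schedules, deterministic in the iteration count and hence
  # identical across modes:
  #  - SIMP penalty gamma ramps 1 -> gamma over the first ramp_iters
  #    iterations. At gamma = 1 the micro law has continuum-comparable
  #    stiffness, so the localized (force-driven) and global
  #    (displacement-embedded) models start from matched stress states;
  #    struts then segregate progressively as the penalty grows.
  #  - The move limit halves periodically after the ramp, damping
  #    bound-to-bound cycling so the design-change criterion can engage.
  #  - A smoothed Heaviside projection of the filtered field sharpens the
  #    strut interfaces (projection steepness beta doubling on a fixed
  #    schedule), so converged designs are near 0/1 rather than ringed by
  #    wide gray transition zones.
  ramp_iters <- min(60L, max(10L, control$max_iters %/% 4))
  gamma_at <- function(it)
    1 + (material$gamma - 1) * min(1, (it - 1) / ramp_iters)
  beta_at <- function(it) min(16, 2^(max(it - ramp_iters, 0) / 30))
  settle_it <- ramp_iters + 120L   # beta reaches its maximum here
  move_at <- function(it)
    control$move_limit * 0.5^(max(it - settle_it, 0) %/% 24L)
  eta <- 0.5
  project <- function(v, beta) {
    den <- tanh(beta * eta) + tanh(beta * (1 - eta))
    H <- (tanh(beta * eta) + tanh(beta * (v - eta))) / den
    list(rho = material$rho_min + (1 - material$rho_min) * H,
         drho = (1 - material$rho_min) * beta / cosh(beta * (v - eta))^2 /
           den)
  }
  block_g <- function(rho_phys) {
    m <- as.numeric(rowsum(rho_phys, bidv)) / n_block^2
    list(g = constraint_value(m, rho0_lrv), dev = m - rho0_lrv)
  }
  for (it in seq_len(control$max_iters)) {
    gam <- gamma_at(it)
    v <- as.numeric(density_filter(matrix(x, nr, nc), rad))
    pr <- project(v, beta_at(it))
    rho_phys <- pr$rho
    E <- rho_phys^gam * material$E0
    sol <- ev(E)
    f <- sum(weights * sol$compliance)
    bg <- block_g(rho_phys)
    g <- bg$g - control$epsilon
    dF_phys <- -gam * rho_phys^(gam - 1) *
      material$E0 * as.numeric(sol$q %*% weights)
    # scale the objective so its gradient is O(1) for the MMA subproblem.
    # The scale is taken from the ROI interior (one LR block in from the
    # cut boundary) where the global and localized stress fields coincide,
    # so both modes step through the same trajectory; scaling leaves the
    # KKT point unchanged.
    if (is.null(f0)) {
      ri <- matrix(FALSE, nr, nc)
      ri[(n_block + 1):(nr - n_block), (n_block + 1):(nc - n_block)] <- TRUE
      f0 <- max(mean(abs(dF_phys[as.vector(ri)])), 1e-300)
    }
    dF_phys <- dF_phys / f0
    dG_phys <- 2 * bg$dev[bidv] / (N_lr * n_block^2)
    dF <- as.numeric(density_filter_t(matrix(dF_phys * pr$drho, nr, nc), rad))
    dG <- as.numeric(density_filter_t(matrix(dG_phys * pr$drho, nr, nc), rad))
    upd <- mma_update(x, dF, dG, g, state,
                      xmin = material$rho_min, xmax = material$rho_max,
                      move = max(move_at(it), control$change_tol / 4))
    state <- upd$state
    if (isTRUE(state$restored)) restored <- restored + 1L
    change <- max(abs(upd$x - x))
    x <- upd$x
    f_hist <- c(f_hist, f)
    g_hist <- c(g_hist, g + control$epsilon)
    ch_hist <- c(ch_hist, change)
    if (control$verbose)
      message(sprintf("it %4d  f %.6g  g %.3g  max|drho| %.4f",
                      it, f, g + control$epsilon, change))
    # the design-change criterion applies once the continuation schedules
    # have settled; earlier iterates are still being reshaped by them
    if (it >= settle_it && change < control$change_tol) {
      converged <- TRUE
      break
    }
  }
  v <- density_filter(matrix(x, nr, nc), rad)
  rho_phys <- matrix(project(as.numeric(v), beta_at(length(f_hist)))$rho,
                     nr, nc)
  list(rho = rho_phys, rho0 = rho0, rho0_lr = rho0_lr,
       f_history = f_hist, g_history = g_hist,
       change_history = ch_hist,
       g_final = block_g(as.numeric(rho_phys))$g,
       iterations = length(f_hist), converged = converged,
       settle_iteration = min(settle_it, length(f_hist)),
       restored_steps = restored)
}

#' @export
print.bone_recon <- function(x, ...) {
  cat(sprintf("bone_recon (%s mode): %d x %d elements at %g um\n",
              x$mode, nrow(x$rho), ncol(x$rho), x$pixel_size_um))
  s <- if (is.null(x$settle_iteration)) 1L else x$settle_iteration
  cat(sprintf(
    "  %d iterations, %sconverged; compliance %.5g -> %.5g (final-penalty phase)\n",
    x$iterations, if (x$converged) "" else "NOT ",
    x$f_history[s], x$f_history[x$iterations]))
  cat(sprintf("  constraint g = %.4g (epsilon %.3g)\n",
              x$g_final, x$control$epsilon))
  invisible(x)
}

#' @export
summary.bone_recon <- function(object, threshold = 0.5, ...) {
  rep <- morphometry(object, threshold = threshold)
  out <- list(recon = object, morphometry = rep)
  class(out) <- "summary.bone_recon"
  out
}

#' @export
print.summary.bone_recon <- function(x, ...) {
  print(x$recon)
  cat("\nMorphometry of the reconstructed field:\n")
  print(x$morphometry)
  invisible(x)
}

#' @export
plot.bone_recon <- function(x, what = c("density", "history"), ...) {
  what <- match.arg(what)
  if (what == "density") {
    img <- density_image(x$rho, pixel_size_um = x$pixel_size_um)
    plot(img, main = sprintf("%s reconstruction", x$mode), ...)
  } else {
    graphics::par(mfrow = c(1, 2))
    graphics::plot(x$f_history, type = "l", xlab = "iteration",
                   ylab = "compliance (J)", main = "objective")
    graphics::plot(x$g_history, type = "l", xlab = "iteration",
                   ylab = "g", main = "constraint")
    graphics::abline(h = x$control$epsilon, lty = 2)
    graphics::par(mfrow = c(1, 1))
  }
  invisible(x)
}

# ---- case evaluators ------------------------------------------------------

make_case_evaluator <- function(model, design_ids, F, solver = "auto",
                                condense_threshold = 20000,
                                roi = NULL, n = NULL) {
  F <- as.matrix(F)
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  n_ext <- length(free) - length(unique(as.vector(
    model$edof[design_ids, , drop = FALSE])))
  if (solver == "auto")
    solver <- if (!is.null(roi) && n_ext > condense_threshold)
      "condensed" else "full"
  if (solver == "condensed" && is.null(roi))
    stop("condensed solver needs the ROI geometry", call. = FALSE)
  if (solver == "condensed")
    condensed_evaluator(model, design_ids, F, roi, n)
  else
    full_evaluator(model, design_ids, F)
}

full_evaluator <- function(model, design_ids, F) {
  map <- stiffness_map(model)
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  Ff <- F[free, , drop = FALSE]
  moduli <- model$moduli
  ke <- unit_ke(model$nu)
  edof_d <- model$edof[design_ids, , drop = FALSE]
  chol_cache <- new.env(parent = emptyenv())
  function(E_design) {
    moduli[design_ids] <- E_design
    K <- stiffness_from_map(map, moduli)
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    if (is.null(chol_cache$ch)) chol_cache$ch <- Matrix::Cholesky(Kff)
    else chol_cache$ch <- Matrix::update(chol_cache$ch, Kff)
    Uf <- as.matrix(Matrix::solve(chol_cache$ch, Ff))
    U <- matrix(0, model$ndof, ncol(F))
    U[free, ] <- Uf
    q <- matrix(0, length(design_ids), ncol(F))
    for (j in seq_len(ncol(F))) {
      ue <- matrix(U[edof_d, j], length(design_ids), 8)
      q[, j] <- 0.5 * rowSums((ue %*% ke) * ue)
    }
    list(compliance = 0.5 * colSums(F * U), q = q, U = U)
  }
}

# Exact static condensation of the fixed-modulus exterior onto the ROI cut
# boundary, done once; each design update then solves only an ROI-sized
# system. Algebraically identical to the full solve (linear elasticity).
condensed_evaluator <- function(model, design_ids, F, roi, n) {
  gr <- roi$row0 * n + seq_len(roi$rows * n + 1)
  gc <- roi$col0 * n + seq_len(roi$cols * n + 1)
  nid_win <- model$nid[gr, gc, drop = FALSE]
  stopifnot(!any(is.na(nid_win)))
  Rnodes <- as.vector(nid_win)
  Rdofs <- node_dofs(Rnodes)
  if (any(model$fixed_dofs %in% Rdofs))
    stop("ROI touches the fixed boundary; use the full solver",
         call. = FALSE)
  on_perim <- matrix(FALSE, nrow(nid_win), ncol(nid_win))
  on_perim[c(1, nrow(on_perim)), ] <- TRUE
  on_perim[, c(1, ncol(on_perim))] <- TRUE
  Cdofs <- node_dofs(nid_win[on_perim])

  pos <- integer(model$ndof)
  pos[Rdofs] <- seq_along(Rdofs)
  nR <- length(Rdofs)
  c_loc <- pos[Cdofs]

  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  Ldofs <- setdiff(free, Rdofs)

  # exterior-element stiffness (these moduli never change)
  ext_ids <- setdiff(seq_len(model$nel), design_ids)
  ext_model <- list(edof = model$edof[ext_ids, , drop = FALSE],
                    nel = length(ext_ids), nu = model$nu,
                    ndof = model$ndof)
  K_ext <- stiffness_from_map(stiffness_map(ext_model),
                              model$moduli[ext_ids])
  K_LL <- Matrix::forceSymmetric(K_ext[Ldofs, Ldofs, drop = FALSE])
  K_LC <- K_ext[Ldofs, Cdofs, drop = FALSE]
  ch_LL <- Matrix::Cholesky(K_LL)
  ncolC <- length(Cdofs)
  S <- as.matrix(K_ext[Cdofs, Cdofs, drop = FALSE])
  chunk <- 96L
  for (s0 in seq(1L, ncolC, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, ncolC)
    X <- as.matrix(Matrix::solve(ch_LL, as.matrix(K_LC[, idx, drop = FALSE])))
    S[, idx] <- S[, idx] - as.matrix(Matrix::crossprod(K_LC, X))
  }
  S <- (S + t(S)) / 2
  Ssp <- Matrix::sparseMatrix(i = rep(c_loc, times = ncolC),
                              j = rep(c_loc, each = ncolC),
                              x = as.vector(S), dims = c(nR, nR))

  f_L <- F[Ldofs, , drop = FALSE]
  uL0 <- as.matrix(Matrix::solve(ch_LL, f_L))
  const_term <- colSums(f_L * uL0)
  f_red <- F[Rdofs, , drop = FALSE]
  f_red[c_loc, ] <- f_red[c_loc, ] - as.matrix(Matrix::crossprod(K_LC, uL0))

  # ROI elements on window-local DOF numbering
  roi_model <- list(edof = matrix(pos[model$edof[design_ids, ]],
                                  length(design_ids), 8),
                    nel = length(design_ids), nu = model$nu, ndof = nR)
  map_roi <- stiffness_map(roi_model)
  ke <- unit_ke(model$nu)
  chol_cache <- new.env(parent = emptyenv())
  # L-side displacement reconstruction pieces kept for full-field queries
  function(E_design) {
    K_red <- stiffness_from_map(map_roi, E_design) + Ssp
    K_red <- Matrix::forceSymmetric(K_red)
    if (is.null(chol_cache$ch)) chol_cache$ch <- Matrix::Cholesky(K_red)
    else chol_cache$ch <- Matrix::update(chol_cache$ch, K_red)
    U_R <- as.matrix(Matrix::solve(chol_cache$ch, f_red))
    q <- matrix(0, length(E_design), ncol(F))
    for (j in seq_len(ncol(F))) {
      ue <- matrix(U_R[roi_model$edof, j], length(E_design), 8)
      q[, j] <- 0.5 * rowSums((ue %*% ke) * ue)
    }
    list(compliance = 0.5 * (colSums(f_red * U_R) + const_term), q = q,
         U_R = U_R)
  }
}
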