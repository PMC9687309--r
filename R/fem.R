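#' Element stiffness matrix for a square bilinear quadrilateral
#'
#' Plane stress, unit thickness, 2x2 Gauss quadrature. For a square element
#' the result is independent of the edge length, so \code{size_um} only
#' documents the physical scale. Node order: lower-left, lower-right,
#' upper-right, upper-left; DOFs (ux, uy) per node.
#'
#' @param modulus Elastic modulus in Pa (> 0).
#' @param nu Poisson ratio.
#' @param size_um Element edge length in micrometres (unused by the value,
#'   kept for interface symmetry).
#' @return Symmetric 8x8 matrix with three rigid-body null modes.
#' @export
element_stiffness <- function(modulus, nu = 0.3, size_um = 50) {
  stopifnot(modulus > 0)
  modulus * unit_ke(nu)
}

# unit-modulus element stiffness, cached per nu
unit_ke <- local({
  cache <- new.env(parent = emptyenv())
  function(nu) {
    key <- sprintf("%.12g", nu)
    if (!is.null(cache[[key]])) return(cache[[key]])
    D <- matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3) / (1 - nu^2)
    xi_n <- c(-1, 1, 1, -1)
    eta_n <- c(-1, -1, 1, 1)
    gp <- 1 / sqrt(3)
    ke <- matrix(0, 8, 8)
    for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) {
      dN_dxi <- 0.25 * xi_n * (1 + gy * eta_n)
      dN_deta <- 0.25 * eta_n * (1 + gx * xi_n)
      # square element: jacobian = (h/2) I; h cancels against det(J)
      B <- matrix(0, 3, 8)
      B[1, seq(1, 8, 2)] <- dN_dxi
      B[2, seq(2, 8, 2)] <- dN_deta
      B[3, seq(1, 8, 2)] <- dN_deta
      B[3, seq(2, 8, 2)] <- dN_dxi
      ke <- ke + t(B) %*% D %*% B
    }
    ke <- (ke + t(ke)) / 2
    cache[[key]] <- ke
    ke
  }
})

#' Build a structured-grid plane-stress FE model over an image mask
#'
#' Each active pixel of the image becomes one square bilinear element; only
#' nodes touched by active elements receive degrees of freedom. Element ids
#' run column-major over active pixels, node ids column-major over used grid
#' vertices; node k owns DOFs (2k-1, 2k) = (ux, uy).
#'
#' @param image A \code{\link{density_image}} (the mask defines the domain).
#' @param moduli Per-active-element modulus vector (Pa), or a single value.
#' @param nu Poisson ratio.
#' @param fixed_dofs Integer vector of constrained DOF ids (may be set
#'   later; required before any solve).
#' @return An object of class \code{fe_model}.
#' @export
build_fe_model <- function(image, moduli, nu = 0.3, fixed_dofs = integer()) {
  stopifnot(inherits(image, "density_image"))
  mask <- image$mask
  ny <- nrow(mask); nx <- ncol(mask)
  nel <- sum(mask)
  if (nel == 0L) stop("mask has no active pixels", call. = FALSE)
  if (length(moduli) == 1L) moduli <- rep(moduli, nel)
  stopifnot(length(moduli) == nel, all(moduli > 0))

  eid <- matrix(NA_integer_, ny, nx)
  eid[mask] <- seq_len(nel)
  ec <- which(mask, arr.ind = TRUE)          # row, col per element (col-major)
  o <- order(ec[, 2], ec[, 1])               # enforce column-major id order
  ec <- ec[o, , drop = FALSE]
  eid[mask] <- NA_integer_
  eid[cbind(ec[, 1], ec[, 2])] <- seq_len(nel)

  # used node grid vertices
  node_used <- matrix(FALSE, ny + 1, nx + 1)
  node_used[cbind(ec[, 1],     ec[, 2])]     <- TRUE
  node_used[cbind(ec[, 1],     ec[, 2] + 1)] <- TRUE
  node_used[cbind(ec[, 1] + 1, ec[, 2] + 1)] <- TRUE
  node_used[cbind(ec[, 1] + 1, ec[, 2])]     <- TRUE
  nnode <- sum(node_used)
  nid <- matrix(NA_integer_, ny + 1, nx + 1)
  nid[node_used] <- seq_len(nnode)

  n1 <- nid[cbind(ec[, 1],     ec[, 2])]
  n2 <- nid[cbind(ec[, 1],     ec[, 2] + 1)]
  n3 <- nid[cbind(ec[, 1] + 1, ec[, 2] + 1)]
  n4 <- nid[cbind(ec[, 1] + 1, ec[, 2])]
  edof <- cbind(2L * n1 - 1L, 2L * n1, 2L * n2 - 1L, 2L * n2,
                2L * n3 - 1L, 2L * n3, 2L * n4 - 1L, 2L * n4)

  nrc <- which(node_used, arr.ind = TRUE)
  nrc <- nrc[order(nid[node_used]), , drop = FALSE]
  h_mm <- image$pixel_size_um / 1000
  node_xy <- cbind(image$origin_mm[1] + (nrc[, 2] - 1) * h_mm,
                   image$origin_mm[2] + (nrc[, 1] - 1) * h_mm)

  structure(list(mask = mask, eid = eid, elem_rc = ec, edof = edof,
                 nid = nid, node_rc = nrc, node_xy = node_xy,
                 nel = nel, nnode = nnode, ndof = 2L * nnode,
                 moduli = as.numeric(moduli), nu = nu,
                 element_size_um = image$pixel_size_um,
                 origin_mm = image$origin_mm,
                 fixed_dofs = as.integer(fixed_dofs)),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("fe_model: %d elements, %d nodes (%d DOFs), %g um elements\n",
              x$nel, x$nnode, x$ndof, x$element_size_um))
  cat(sprintf("  fixed DOFs: %d; modulus range [%.3g, %.3g] Pa\n",
              length(x$fixed_dofs), min(x$moduli), max(x$moduli)))
  invisible(x)
}

#' Fix both DOFs of all nodes on one straight edge of the model
#'
#' For the femur phantom, \code{edge = "bottom"} clamps the distal cut of the
#' shaft (the standard proximal-femur boundary condition).
#'
#' @param model An \code{fe_model}.
#' @param edge One of \code{"bottom"}, \code{"top"}, \code{"left"},
#'   \code{"right"}.
#' @return Integer vector of DOF ids.
#' @export
edge_fixed_dofs <- function(model, edge = "bottom") {
  rc <- model$node_rc
  sel <- switch(match.arg(edge, c("bottom", "top", "left", "right")),
                bottom = rc[, 1] == min(rc[, 1]),
                top    = rc[, 1] == max(rc[, 1]),
                left   = rc[, 2] == min(rc[, 2]),
                right  = rc[, 2] == max(rc[, 2]))
  nodes <- which(sel)
  sort(c(2L * nodes - 1L, 2L * nodes))
}

#' Assemble the global sparse stiffness matrix
#'
#' @param model An \code{fe_model}.
#' @return A symmetric sparse \code{dgCMatrix} of size \code{ndof x ndof}.
#' @export
assemble_stiffness <- function(model) {
  map <- stiffness_map(model)
  stiffness_from_map(map, model$moduli)
}

# One-time sparsity bookkeeping so the optimizer can refresh K@x with a
# single sparse mat-vec when only element moduli change.
stiffness_map <- function(model) {
  ke <- unit_ke(model$nu)
  nel <- model$nel
  a <- rep(1:8, times = 8)
  b <- rep(1:8, each = 8)
  Iv <- as.vector(model$edof[, a])
  Jv <- as.vector(model$edof[, b])
  kev <- as.vector(ke)                      # ke[a[k], b[k]] for k = 1..64
  Ev <- rep(seq_len(nel), times = 64)
  Vv <- rep(kev, each = nel)
  ord <- order(Jv, Iv)
  Is <- Iv[ord]; Js <- Jv[ord]
  n <- length(Is)
  newg <- c(TRUE, Is[-1] != Is[-n] | Js[-1] != Js[-n])
  grp <- cumsum(newg)
  nnzk <- grp[n]
  Tmap <- Matrix::sparseMatrix(i = grp, j = Ev[ord], x = Vv[ord],
                               dims = c(nnzk, nel))
  skel <- Matrix::sparseMatrix(i = Is[newg], j = Js[newg],
                               x = rep(0, nnzk),
                               dims = c(model$ndof, model$ndof))
  list(skel = skel, Tmap = Tmap)
}

stiffness_from_map <- function(map, moduli) {
  K <- map$skel
  K@x <- as.numeric(map$Tmap %*% moduli)
  K
}

#' Solve the constrained linear elastic system
#'
#' Displacements are zero at \code{model$fixed_dofs}; the reduced system is
#' solved by sparse Cholesky factorization up to 5e5 free DOFs and by
#' Jacobi-preconditioned conjugate gradients above (relative tolerance 1e-8).
#'
#' @param model An \code{fe_model} with nonempty \code{fixed_dofs}.
#' @param load Numeric load vector of length \code{ndof} (N), or a matrix
#'   with one column per load case.
#' @param method \code{"auto"}, \code{"direct"} or \code{"pcg"}.
#' @param tol Relative residual tolerance for the iterative solver.
#' @return Displacement vector (or matrix) of length \code{ndof}, zero at
#'   fixed DOFs.
#' @export
fe_solve <- function(model, load, method = c("auto", "direct", "pcg"),
                     tol = 1e-8) {
  method <- match.arg(method)
  if (length(model$fixed_dofs) == 0L)
    stop("model has no fixed DOFs; constrain it before solving", call. = FALSE)
  f <- as.matrix(load)
  stopifnot(nrow(f) == model$ndof, all(is.finite(f)))
  K <- assemble_stiffness(model)
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free, , drop = FALSE]
  if (method == "auto")
    method <- if (length(free) <= 5e5) "direct" else "pcg"
  uf <- if (method == "direct") {
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                   error = function(e) NULL)
    if (is.null(ch)) singularity_report(model)
    as.matrix(Matrix::solve(ch, ff))
  } else {
    apply(ff, 2, function(b) pcg_solve(Kff, b, tol = tol))
  }
  u <- matrix(0, model$ndof, ncol(f))
  u[free, ] <- uf
  # residual check on free DOFs; a large residual from a "successful"
  # factorization is the numerical signature of a floating component
  r <- Kff %*% uf - ff
  rel <- sqrt(colSums(as.matrix(r)^2)) / pmax(sqrt(colSums(ff^2)), 1e-300)
  if (any(colSums(ff^2) > 0 & rel > 1e-6)) singularity_report(model)
  if (ncol(u) == 1L) drop(u) else u
}

pcg_solve <- function(A, b, tol = 1e-8, maxit = NULL) {
  n <- length(b)
  if (is.null(maxit)) maxit <- max(1000L, 10L * n)
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bn) return(x)
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("PCG failed to converge", call. = FALSE)
}

singularity_report <- function(model) {
  lab <- EBImage::bwlabel(model$mask * 1)
  ncomp <- max(lab)
  fixed_nodes <- unique((model$fixed_dofs + 1L) %/% 2L)
  anchored <- logical(ncomp)
  for (k in seq_len(ncomp)) {
    els <- model$eid[lab == k]
    nds <- unique(as.vector((model$edof[els, , drop = FALSE] + 1L) %/% 2L))
    anchored[k] <- any(nds %in% fixed_nodes)
  }
  stop(sprintf(paste0("stiffness matrix is singular: %d connected ",
                      "component(s), %d without any constraint (%s)"),
               ncomp, sum(!anchored),
               paste(which(!anchored), collapse = ", ")), call. = FALSE)
}

#' Displacement-driven solve with reaction recovery
#'
#' Prescribes displacements on a set of DOFs (in addition to the model's
#' zero-fixed DOFs), solves for the remaining DOFs, and returns the reaction
#' forces \eqn{(Ku - f)} at the prescribed DOFs. This is the operational form
#' of static condensation: the reactions are exactly the forces the removed
#' surroundings exert through the cut boundary.
#'
#' @param model An \code{fe_model}.
#' @param prescribed Named numeric vector: names are DOF ids, values the
#'   prescribed displacements.
#' @param load Optional applied load vector (length \code{ndof}).
#' @return List with \code{u} (full displacement vector) and
#'   \code{reactions} (full-length vector, nonzero only at prescribed and
#'   fixed DOFs).
#' @export
fe_reactions <- function(model, prescribed, load = NULL) {
  pd <- as.integer(names(prescribed))
  if (length(pd) == 0L) stop("no prescribed DOFs", call. = FALSE)
  if (any(is.na(pd)) || any(pd < 1L) || any(pd > model$ndof))
    stop("prescribed DOF ids outside model", call. = FALSE)
  if (anyDuplicated(pd)) stop("duplicate prescribed DOFs", call. = FALSE)
  f <- if (is.null(load)) numeric(model$ndof) else as.numeric(load)
  stopifnot(length(f) == model$ndof)
  K <- assemble_stiffness(model)
  held <- union(pd, model$fixed_dofs)
  free <- setdiff(seq_len(model$ndof), held)
  u <- numeric(model$ndof)
  u[pd] <- as.numeric(prescribed)
  if (length(free)) {
    rhs <- f[free] - as.numeric(K[free, held, drop = FALSE] %*% u[held])
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    ch <- tryCatch(Matrix::Cholesky(Kff), error = function(e) NULL)
    if (is.null(ch)) singularity_report(model)
    u[free] <- as.numeric(Matrix::solve(ch, rhs))
  }
  r <- numeric(model$ndof)
  r[held] <- as.numeric(K[held, , drop = FALSE] %*% u) - f[held]
  list(u = u, reactions = r)
}

#' Per-element and total strain energy
#'
#' @param model An \code{fe_model}.
#' @param u Displacement vector of length \code{ndof}.
#' @return List with \code{per_element} (J, length \code{nel}) and
#'   \code{total} (equal to \eqn{\frac12 u^T K u}).
#' @export
strain_energy <- function(model, u) {
  stopifnot(length(u) == model$ndof)
  e <- element_energies(model, u, model$moduli)
  list(per_element = e, total = sum(e))
}

# 0.5 * E_i * u_e' ke0 u_e, vectorized over elements
element_energies <- function(model, u, moduli) {
  ke <- unit_ke(model$nu)
  ue <- matrix(u[model$edof], model$nel, 8)
  0.5 * moduli * rowSums((ue %*% ke) * ue)
}
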