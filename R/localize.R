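#' Extract a region of interest from a density image
#'
#' Crops the image to the ROI window; densities are bit-identical to the
#' global values and the origin is shifted so physical coordinates are
#' preserved. Extraction works anywhere within the mask, including across
#' the cortical shell.
#'
#' @param image A \code{\link{density_image}}.
#' @param roi A \code{\link{roi_spec}} fully inside the mask.
#' @return The cropped \code{\link{density_image}}.
#' @export
extract_roi <- function(image, roi) {
  validate_roi(image, roi)
  rs <- roi$row0 + seq_len(roi$rows)
  cs <- roi$col0 + seq_len(roi$cols)
  h <- image$pixel_size_um / 1000
  density_image(image$values[rs, cs, drop = FALSE],
                image$mask[rs, cs, drop = FALSE],
                pixel_size_um = image$pixel_size_um,
                origin_mm = image$origin_mm + c(roi$col0 * h, roi$row0 * h))
}

# node-grid bookkeeping for the ROI cut boundary: global and local node ids
# of the single layer of nodes on the ROI perimeter (and of the full window)
roi_boundary_map <- function(global_model, roi) {
  rows <- roi$rows; cols <- roi$cols
  gr <- roi$row0 + seq_len(rows + 1)       # node-grid rows of the window
  gc <- roi$col0 + seq_len(cols + 1)
  nid_win <- global_model$nid[gr, gc, drop = FALSE]
  if (any(is.na(nid_win)))
    stop("ROI window touches nodes outside the model", call. = FALSE)
  on_perim <- matrix(FALSE, rows + 1, cols + 1)
  on_perim[c(1, rows + 1), ] <- TRUE
  on_perim[, c(1, cols + 1)] <- TRUE
  # local node ids follow column-major order over the window node grid,
  # matching build_fe_model() on the cropped image
  local_nid <- matrix(seq_len((rows + 1) * (cols + 1)), rows + 1, cols + 1)
  list(global_nodes = nid_win[on_perim],
       local_nodes = local_nid[on_perim],
       nid_win = nid_win, local_nid = local_nid)
}

node_dofs <- function(nodes) {
  as.vector(rbind(2L * nodes - 1L, 2L * nodes))
}

#' Cut-boundary displacements of an ROI under a global load
#'
#' Solves the global model and returns the displacements of the single
#' layer of nodes on the ROI perimeter, keyed by the DOF ids of the
#' localized (cropped) model so they can be prescribed on it directly.
#'
#' @param global_model Global LR \code{fe_model} (constrained).
#' @param load Global load vector (length \code{global_model$ndof}) or a
#'   precomputed displacement via \code{u}.
#' @param roi A \code{\link{roi_spec}}.
#' @param u Optional: reuse an existing global displacement solution.
#' @return Named numeric vector: names are localized-model DOF ids, values
#'   displacements.
#' @export
cut_boundary_displacements <- function(global_model, load, roi, u = NULL) {
  if (is.null(u)) u <- fe_solve(global_model, load)
  bm <- roi_boundary_map(global_model, roi)
  gd <- node_dofs(bm$global_nodes)
  ld <- node_dofs(bm$local_nodes)
  stats::setNames(u[gd], ld)
}

#' Estimate physiological local loads for an ROI by static condensation
#'
#' For each load case the global LR model is solved under its global loads,
#' the cut-boundary displacements of the ROI are read off, and prescribing
#' them on the localized LR model (identical densities and moduli in the
#' window) yields the cut-boundary reactions: exactly the forces the
#' discarded surroundings exert on the ROI. These reactions are the local
#' loads; by static condensation their resultant force and moment vanish
#' per case.
#'
#' @param global_model Global LR \code{fe_model} (constrained, continuum
#'   moduli).
#' @param loads Matrix of global load vectors (one column per case) or a
#'   single vector.
#' @param roi A \code{\link{roi_spec}}.
#' @param image The LR \code{\link{density_image}} the global model was
#'   built on (for the localized crop).
#' @return An object of class \code{local_load_set}: list with
#'   \code{forces} (localized-model force vectors, one column per case),
#'   \code{boundary_dofs} (localized cut-boundary DOF ids), \code{model}
#'   (the localized LR \code{fe_model}), \code{roi}.
#' @export
estimate_local_loads <- function(global_model, loads, roi, image) {
  F <- as.matrix(loads)
  stopifnot(nrow(F) == global_model$ndof)
  local_img <- extract_roi(image, roi)
  local_model <- build_fe_model(local_img, moduli = 1, nu = global_model$nu)
  # moduli copied from the global model so the window stiffness is identical
  gids <- global_model$eid[cbind(roi$row0 + local_model$elem_rc[, 1],
                                 roi$col0 + local_model$elem_rc[, 2])]
  local_model$moduli <- global_model$moduli[gids]

  U <- fe_solve(global_model, F)
  U <- as.matrix(U)
  bm <- roi_boundary_map(global_model, roi)
  ld <- node_dofs(bm$local_nodes)
  gd <- node_dofs(bm$global_nodes)
  forces <- matrix(0, local_model$ndof, ncol(F))
  for (j in seq_len(ncol(F))) {
    Dc <- stats::setNames(U[gd, j], ld)
    res <- fe_reactions(local_model, Dc)
    forces[, j] <- res$reactions
  }
  out <- structure(list(forces = forces, boundary_dofs = sort(ld),
                        model = local_model, roi = roi,
                        image = local_img),
                   class = "local_load_set")
  check_self_equilibrium(out)
  out
}

# self-equilibration invariant: per case, resultant force and moment ~ 0
check_self_equilibrium <- function(lls, tol = 1e-6) {
  xy <- lls$model$node_xy
  ctr <- colMeans(xy)
  for (j in seq_len(ncol(lls$forces))) {
    f <- lls$forces[, j]
    fx <- f[seq(1, length(f), 2)]
    fy <- f[seq(2, length(f), 2)]
    scale <- sum(sqrt(fx^2 + fy^2))
    if (scale == 0) next
    res_f <- c(sum(fx), sum(fy))
    res_m <- sum((xy[, 1] - ctr[1]) * fy - (xy[, 2] - ctr[2]) * fx)
    if (max(abs(res_f)) > tol * scale ||
        abs(res_m) > tol * scale * max(1, diff(range(xy))))
      warning(sprintf(paste0("local load case %d is not self-equilibrated ",
                             "(force %.3g, moment %.3g at scale %.3g)"),
                      j, max(abs(res_f)), res_m, scale), call. = FALSE)
  }
  invisible(lls)
}

#' @export
print.local_load_set <- function(x, ...) {
  cat(sprintf("local_load_set: %d case(s) on a %d x %d LR ROI (%d boundary DOFs)\n",
              ncol(x$forces), x$roi$rows, x$roi$cols,
              length(x$boundary_dofs)))
  for (j in seq_len(ncol(x$forces)))
    cat(sprintf("  case %d: |F| sum %.4g N\n", j,
                sum(abs(x$forces[, j]))))
  invisible(x)
}

# lift LR boundary nodal forces onto the refined localized model. Each LR
# nodal force is spread as a linear hat over its tributary stretch of the
# HR cut boundary (the two adjacent LR edge halves), i.e. the consistent
# nodal loads of a piecewise-linear boundary traction at LR granularity.
# Resultants per LR node are preserved exactly, so the lifted set stays
# self-equilibrated, while the point-load singularity of a single-node
# mapping is avoided.
lift_local_loads <- function(lls, n, hr_model) {
  rows <- lls$roi$rows; cols <- lls$roi$cols
  lr_nid <- matrix(seq_len((rows + 1) * (cols + 1)), rows + 1, cols + 1)
  # closed perimeter walk over the HR window node grid (counter-clockwise)
  nyh <- rows * n + 1; nxh <- cols * n + 1
  path_rc <- rbind(
    cbind(1, 1:(nxh - 1)),                  # bottom, left -> right
    cbind(1:(nyh - 1), nxh),                # right, bottom -> top
    cbind(nyh, nxh:2),                      # top, right -> left
    cbind(nyh:2, 1))                        # left, top -> bottom
  L <- nrow(path_rc)
  hr_path <- hr_model$nid[path_rc]
  stopifnot(!any(is.na(hr_path)))
  F <- matrix(0, hr_model$ndof, ncol(lls$forces))
  hat <- 1 - abs(-(n - 1):(n - 1)) / n      # sums to n
  # LR nodes sit every n-th position along the walk
  lr_path_rc <- rbind(
    cbind(1, 1:cols), cbind(1:rows, cols + 1),
    cbind(rows + 1, (cols + 1):2), cbind((rows + 1):2, 1))
  for (s in seq_len(nrow(lr_path_rc))) {
    lr_node <- lr_nid[lr_path_rc[s, 1], lr_path_rc[s, 2]]
    lr_d <- c(2L * lr_node - 1L, 2L * lr_node)
    fv <- lls$forces[lr_d, , drop = FALSE]
    if (all(fv == 0)) next
    p0 <- (s - 1) * n                       # 0-based position on the walk
    pos <- (p0 + (-(n - 1):(n - 1))) %% L + 1
    nodes <- hr_path[pos]
    for (k in seq_along(nodes)) {
      d <- c(2L * nodes[k] - 1L, 2L * nodes[k])
      F[d, ] <- F[d, ] + (hat[k] / n) * fv
    }
  }
  F
}
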