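# Shared fixtures, built in code.

# uniform unit-square plate image (ny x nx LR pixels)
plate_image <- function(ny, nx, rho = 1, pixel_size_um = 600) {
  density_image(matrix(rho, ny, nx), pixel_size_um = pixel_size_um)
}

# smooth heterogeneous plate for condensation / reconstruction toys
wavy_image <- function(ny = 16, nx = 16, lo = 0.2, hi = 0.7,
                       pixel_size_um = 600) {
  v <- lo + (hi - lo) * outer(sin(seq(0.3, pi - 0.3, length.out = ny)),
                              sin(seq(0.3, pi - 0.3, length.out = nx)))
  density_image(v, pixel_size_um = pixel_size_um)
}

# vertical-stripe binary phantom with background margins so no stripe
# touches the image border (border pixels have no outside background in
# the distance transform)
stripe_binary <- function(n = 60, bone_px = 3, gap_px = 9) {
  b <- matrix(FALSE, n, n)
  j <- gap_px
  while (j + bone_px <= n - gap_px) {
    b[, j + seq_len(bone_px)] <- TRUE
    j <- j + bone_px + gap_px
  }
  b
}

# sinusoidal stripe field along a given angle from vertical
stripe_field <- function(angle_deg, n = 96, period = 8) {
  th <- angle_deg * pi / 180
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), n), n, n)
  u <- x * cos(th) - y * sin(th)
  0.5 + 0.45 * sin(2 * pi * u / period)
}

# uniform vertical traction on the top edge of a model, total force F_N
top_edge_load <- function(model, F_N = -100) {
  f <- numeric(model$ndof)
  topn <- which(model$node_rc[, 1] == max(model$node_rc[, 1]))
  f[2 * topn] <- F_N / length(topn)
  f
}

# desk-scale phantom cached across tests
desk_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- femur_phantom(width_mm = 47.1, height_mm = 52.2,
                                    seed = seed)
    cache[[key]]
  }
})

# paired desk-scale reconstructions (expensive; cached and shared between
# the method-agreement and qualitative-regression tests)
desk_pair <- local({
  cache <- new.env(parent = emptyenv())
  function(preset, size_px, seed = 1) {
    key <- sprintf("%s_%d_%d", preset, size_px, seed)
    if (is.null(cache[[key]])) {
      ph <- desk_phantom(seed)
      roi <- roi_preset(ph, preset, size_px)
      ctrl <- recon_control(max_iters = 300, change_tol = 0.01)
      cache[[key]] <- list(
        global = reconstruct(ph, roi, mode = "global", n = 6,
                             control = ctrl),
        localized = reconstruct(ph, roi, mode = "localized", n = 6,
                                control = ctrl))
    }
    cache[[key]]
  }
})
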