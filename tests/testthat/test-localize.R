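test_that("ROI extraction round-trips and shifts the origin", {
  img <- wavy_image(12, 14)
  roi <- roi_spec(3, 4, 5, 6)
  crop <- extract_roi(img, roi)
  expect_identical(dim(crop$values), c(5L, 6L))
  expect_identical(crop$values, img$values[4:8, 5:10])
  expect_equal(crop$origin_mm, c(4 * 0.6, 3 * 0.6))
  # re-embedding returns the original window bit-for-bit
  back <- img$values
  back[4:8, 5:10] <- crop$values
  expect_identical(back, img$values)
})

test_that("extraction works across the cortical shell", {
  ph <- desk_phantom(1)
  # straddle the shell: window near the mask edge that stays inside it
  m <- ph$image$mask
  ok <- NULL
  for (r0 in 5:60) for (c0 in 5:55) {
    win <- m[r0 + 1:6, c0 + 1:6]
    if (all(win) && any(ph$image$values[r0 + 1:6, c0 + 1:6] == 0.95)) {
      ok <- roi_spec(r0, c0, 6, 6); break
    }
  }
  expect_false(is.null(ok))
  crop <- extract_roi(ph$image, ok)
  expect_true(any(crop$values == 0.95))
})

test_that("cut-boundary displacements match the global solution", {
  set.seed(21)
  img <- density_image(matrix(runif(14 * 14, 0.3, 0.9), 14, 14))
  m <- build_lr_continuum_model(img)
  roi <- roi_spec(4, 4, 6, 6)
  f <- top_edge_load(m, -200)
  u <- fe_solve(m, f)
  Dc <- cut_boundary_displacements(m, f, roi)
  expect_length(Dc, 2 * (4 * 6))
  # zero load -> zero Dc
  expect_equal(unname(cut_boundary_displacements(m, numeric(m$ndof), roi)),
               rep(0, length(Dc)))
  # identical whether computed from the load or a reused solution
  expect_identical(Dc, cut_boundary_displacements(m, NULL, roi, u = u))
  # homogeneous plate under uniform stress: Dc follows the linear field
  hom <- plate_image(14, 14, rho = 1, pixel_size_um = 1e6)
  mh <- build_fe_model(hom, moduli = 1e9, nu = 0.3)
  bn <- which(mh$node_rc[, 1] == 1)
  mh$fixed_dofs <- c(2L * bn, 2L * bn[1] - 1L)
  sigma <- 1e5
  fh <- numeric(mh$ndof)
  tn <- which(mh$node_rc[, 1] == 15)
  wts <- rep(1, length(tn)); wts[c(1, length(tn))] <- 0.5
  fh[2 * tn] <- sigma * wts / sum(wts) * 14
  uh <- fe_solve(mh, fh)
  Dch <- cut_boundary_displacements(mh, NULL, roi, u = uh)
  bm <- trabrec:::roi_boundary_map(mh, roi)
  ydof <- trabrec:::node_dofs(bm$local_nodes)
  gnode <- bm$global_nodes
  y_m <- mh$node_xy[gnode, 2] / 1000      # node height in metres
  uy <- Dch[as.character(2L * bm$local_nodes)]
  expect_equal(unname(uy), sigma / 1e9 * y_m, tolerance = 1e-6)
})

test_that("estimated local loads are self-equilibrated and linear", {
  set.seed(31)
  img <- density_image(matrix(runif(16 * 16, 0.25, 0.95), 16, 16))
  m <- build_lr_continuum_model(img)
  roi <- roi_spec(5, 5, 7, 7)
  f <- top_edge_load(m, -350)
  lls <- estimate_local_loads(m, f, roi, img)
  fx <- lls$forces[seq(1, nrow(lls$forces), 2), 1]
  fy <- lls$forces[seq(2, nrow(lls$forces), 2), 1]
  scale <- sum(sqrt(fx^2 + fy^2))
  expect_lt(abs(sum(fx)), 1e-6 * scale)
  expect_lt(abs(sum(fy)), 1e-6 * scale)
  xy <- lls$model$node_xy
  mom <- sum(xy[, 1] * fy - xy[, 2] * fx)
  expect_lt(abs(mom), 1e-6 * scale * diff(range(xy)))
  # linear in the global load magnitude
  lls3 <- estimate_local_loads(m, 3 * f, roi, img)
  expect_equal(lls3$forces, 3 * lls$forces, tolerance = 1e-9)
  # zero load -> zero local loads
  lls0 <- estimate_local_loads(m, numeric(m$ndof), roi, img)
  expect_equal(max(abs(lls0$forces)), 0)
})

test_that("static condensation is exact up to a rigid-body motion", {
  # principal oracle: re-applying the estimated loads to the localized
  # model reproduces the global interior field, for several random
  # heterogeneous fields and ROI positions
  set.seed(41)
  cases <- list(list(dim = c(18, 20), roi = roi_spec(5, 6, 7, 7)),
                list(dim = c(18, 20), roi = roi_spec(2, 10, 6, 8)),
                list(dim = c(15, 15), roi = roi_spec(6, 2, 5, 9)))
  for (cs in cases) {
    img <- density_image(matrix(runif(prod(cs$dim), 0.2, 0.9),
                                cs$dim[1], cs$dim[2]))
    m <- build_lr_continuum_model(img)
    f <- top_edge_load(m, -100)
    rn <- which(m$node_rc[, 2] == max(m$node_rc[, 2]))
    f[2 * rn - 1] <- 30 / length(rn)      # add a shear component
    u <- fe_solve(m, f)
    lls <- estimate_local_loads(m, f, cs$roi, img)
    lm <- lls$model
    lm$fixed_dofs <- trabrec:::pin_corner_dofs(lm)
    ul <- fe_solve(lm, lls$forces[, 1])
    bm <- trabrec:::roi_boundary_map(m, cs$roi)
    gw <- as.vector(bm$nid_win); lw <- as.vector(bm$local_nid)
    ug <- numeric(lm$ndof)
    ug[2 * lw - 1] <- u[2 * gw - 1]
    ug[2 * lw] <- u[2 * gw]
    xy <- lm$node_xy
    A <- rbind(cbind(1, 0, -xy[, 2]), cbind(0, 1, xy[, 1]))
    d <- c(ug[seq(1, lm$ndof, 2)] - ul[seq(1, lm$ndof, 2)],
           ug[seq(2, lm$ndof, 2)] - ul[seq(2, lm$ndof, 2)])
    resid <- d - A %*% qr.solve(A, d)
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum(ug^2)), 1e-6)
  }
})

test_that("operational condensation equals the explicit Schur complement", {
  set.seed(51)
  img <- density_image(matrix(runif(8 * 8, 0.3, 0.9), 8, 8))
  m <- build_lr_continuum_model(img)
  roi <- roi_spec(2, 2, 4, 4)
  f <- top_edge_load(m, -50)
  u <- fe_solve(m, f)
  bm <- trabrec:::roi_boundary_map(m, roi)
  cd_l <- trabrec:::node_dofs(bm$local_nodes)
  Dc <- u[trabrec:::node_dofs(bm$global_nodes)]
  lls <- estimate_local_loads(m, f, roi, img)
  # explicit: F'c = (K'cc - K'cl Kll^-1 K'lc) Dc on the localized model
  K <- as.matrix(assemble_stiffness(lls$model))
  cdofs <- sort(cd_l)
  Dc_s <- Dc[order(cd_l)]
  ldofs <- setdiff(seq_len(nrow(K)), cdofs)
  S <- K[cdofs, cdofs] - K[cdofs, ldofs] %*%
    solve(K[ldofs, ldofs], K[ldofs, cdofs])
  expect_equal(unname(lls$forces[cdofs, 1]), unname(as.numeric(S %*% Dc_s)),
               tolerance = 1e-8)
})
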