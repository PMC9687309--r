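# all boundary DOFs of a rectangular model
boundary_dofs_of <- function(m) {
  rc <- m$node_rc
  sel <- rc[, 1] %in% range(rc[, 1]) | rc[, 2] %in% range(rc[, 2])
  sort(c(2L * which(sel) - 1L, 2L * which(sel)))
}

test_that("element stiffness is symmetric with three rigid-body modes and linear in E", {
  ke <- element_stiffness(2e9, 0.3)
  expect_equal(ke, t(ke))
  # rigid translations and infinitesimal rotation are zero-energy
  tx <- rep(c(1, 0), 4)
  ty <- rep(c(0, 1), 4)
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rot <- as.vector(t(cbind(-xy[, 2], xy[, 1])))
  for (u in list(tx, ty, rot))
    expect_lt(max(abs(ke %*% u)), 1e-6 * max(abs(ke)))
  expect_equal(sum(abs(eigen(ke, symmetric = TRUE)$values) <
                     1e-9 * max(ke)), 3)
  expect_equal(element_stiffness(4e9, 0.3), 2 * ke)
})

test_that("uniaxial patch test recovers closed-form strain and energy", {
  img <- plate_image(1, 1, pixel_size_um = 1e6)  # one 1 m element
  m <- build_fe_model(img, moduli = 2e9, nu = 0.3)
  bn <- which(m$node_rc[, 1] == 1)
  m$fixed_dofs <- c(2L * bn, 2L * bn[1] - 1L)    # roller base + one pin
  sigma <- 1e6                                   # N per unit edge
  f <- numeric(m$ndof)
  tn <- which(m$node_rc[, 1] == 2)
  f[2 * tn] <- sigma / 2
  u <- fe_solve(m, f)
  expect_equal(unname(u[2 * tn]), rep(sigma / 2e9, 2), tolerance = 1e-9)
  se <- strain_energy(m, u)
  expect_equal(se$total, 0.5 * sigma^2 / 2e9, tolerance = 1e-9)
  expect_true(all(se$per_element >= 0))
  # quadratic form: doubling displacement quadruples energy
  expect_equal(strain_energy(m, 2 * u)$total, 4 * se$total)
  # zero load -> zero displacement
  expect_equal(fe_solve(m, numeric(m$ndof)), numeric(m$ndof))
})

test_that("cantilever tip deflection approaches beam theory", {
  img <- plate_image(4, 32, pixel_size_um = 1e6)
  m <- build_fe_model(img, moduli = 1e9, nu = 0.3)
  m$fixed_dofs <- edge_fixed_dofs(m, "left")
  tipn <- which(m$node_rc[, 2] == max(m$node_rc[, 2]))
  P <- 1e4
  f <- numeric(m$ndof)
  f[2 * tipn] <- -P / length(tipn)
  u <- fe_solve(m, f)
  eb <- -P * 32^3 / (3 * 1e9 * 4^3 / 12)
  expect_lt(abs(mean(u[2 * tipn]) - eb) / abs(eb), 0.1)
})

test_that("work balance holds and solvers agree", {
  set.seed(11)
  img <- density_image(matrix(runif(8 * 10, 0.3, 1), 8, 10))
  m <- build_lr_continuum_model(img)
  f <- top_edge_load(m, -500)
  ud <- fe_solve(m, f, method = "direct")
  up <- fe_solve(m, f, method = "pcg", tol = 1e-10)
  expect_lt(sqrt(sum((ud - up)^2)) / sqrt(sum(ud^2)), 1e-6)
  se <- strain_energy(m, ud)
  expect_equal(0.5 * sum(f * ud), se$total, tolerance = 1e-6)
})

test_that("mesh refinement of a continuum problem converges", {
  comp <- vapply(c(1, 2, 4), function(n) {
    hr <- refine_image(wavy_image(6, 6, lo = 0.3, hi = 0.7), n)
    m <- build_lr_continuum_model(hr)
    bn <- which(m$node_rc[, 1] == 1)
    m$fixed_dofs <- c(2L * bn, 2L * bn[1] - 1L)   # roller base
    tn <- which(m$node_rc[, 1] == max(m$node_rc[, 1]))
    w <- rep(1, length(tn)); w[c(1, length(tn))] <- 0.5
    f <- numeric(m$ndof); f[2 * tn] <- -1000 * w / sum(w)
    compliance_objective(m, f, 1)
  }, numeric(1))
  expect_true(all(diff(comp) > 0))   # monotone softening toward the limit
  d12 <- abs(comp[2] - comp[1]) / comp[1]
  d24 <- abs(comp[3] - comp[2]) / comp[2]
  expect_lt(d24, d12)
  expect_lt(d24, 0.02)               # <2 % between n and 2n
})

test_that("reactions recover constraint forces and consistent tractions", {
  img <- plate_image(4, 4, pixel_size_um = 1e6)
  m <- build_fe_model(img, moduli = 1e9, nu = 0.3)
  m$fixed_dofs <- edge_fixed_dofs(m, "bottom")
  f <- top_edge_load(m, -300)
  u <- fe_solve(m, f)
  # round trip: prescribing the solved boundary reproduces the reactions
  bn <- which(m$node_rc[, 1] == 1)
  bd <- sort(c(2L * bn - 1L, 2L * bn))
  m2 <- m; m2$fixed_dofs <- integer()
  res <- fe_reactions(m2, stats::setNames(u[bd], bd), load = f)
  K <- assemble_stiffness(m)
  expect_equal(res$reactions[bd],
               as.numeric((K %*% u)[bd]) - f[bd], tolerance = 1e-8)
  # vertical equilibrium: reactions balance the applied load
  expect_equal(sum(res$reactions[2L * bn]), 300, tolerance = 1e-6)
  # rigid translation of a free homogeneous patch -> zero reactions
  m3 <- m; m3$fixed_dofs <- integer()
  all_b <- boundary_dofs_of(m3)
  rigid <- stats::setNames(rep(c(1e-3, 2e-3),
                               length(all_b) / 2)[seq_along(all_b)], all_b)
  rigid[] <- ifelse(as.integer(names(rigid)) %% 2 == 1, 1e-3, 2e-3)
  r3 <- fe_reactions(m3, rigid)
  expect_lt(max(abs(r3$reactions)), 1e-9 * 1e9 * 1e-3)
  # uniform-strain boundary displacement -> interior follows linear field
  eps <- 1e-4
  lin <- stats::setNames(numeric(length(all_b)), all_b)
  for (d in all_b) {
    node <- (as.integer(d) + 1L) %/% 2L
    lin[as.character(d)] <- if (as.integer(d) %% 2L == 1L)
      0 else eps * m3$node_xy[node, 2]
  }
  r4 <- fe_reactions(m3, lin)
  iy <- 2L * which(m3$node_rc[, 1] == 3 & m3$node_rc[, 2] == 3)
  expect_equal(r4$u[iy], eps * m3$node_xy[iy / 2, 2], tolerance = 1e-6)
})


test_that("unconstrained models raise a component-aware singularity error", {
  img <- plate_image(3, 3)
  m <- build_fe_model(img, moduli = 1e9)
  expect_error(fe_solve(m, numeric(m$ndof)), "fixed DOFs")
  # two disconnected blocks, only one anchored
  mask <- matrix(FALSE, 3, 7)
  mask[, 1:3] <- TRUE
  mask[, 5:7] <- TRUE
  img2 <- density_image(matrix(1, 3, 7), mask)
  m2 <- build_fe_model(img2, moduli = 1e9)
  bn <- which(m2$node_rc[, 1] == 1 & m2$node_rc[, 2] <= 4)
  m2$fixed_dofs <- sort(c(2L * bn - 1L, 2L * bn))
  expect_error(fe_solve(m2, numeric(m2$ndof) + 1), "component")
})

test_that("density image TIFF round trip preserves values and metadata", {
  set.seed(5)
  mask <- matrix(TRUE, 6, 5); mask[1, 1] <- FALSE
  v <- matrix(round(runif(30), 4), 6, 5); v[1, 1] <- 0
  img <- density_image(v, mask, pixel_size_um = 600, origin_mm = c(1, 2))
  path <- tempfile(fileext = ".tiff")
  write_density_image(img, path)
  back <- read_density_image(path)
  expect_equal(back$values[mask], img$values[mask], tolerance = 1e-4)
  expect_identical(back$mask, img$mask)
  expect_equal(back$pixel_size_um, 600)
  expect_equal(back$origin_mm, c(1, 2))
})
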