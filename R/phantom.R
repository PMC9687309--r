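#' Synthetic proximal-femur phantom
#'
#' Generates a masked 2D relative-density image of a proximal femur together
#' with the anatomical landmarks needed to apply physiological loads. The
#' outline is a smooth union of four primitives (head disc, neck corridor,
#' greater-trochanter lobe, shaft corridor); densities comprise a cortical
#' shell, smooth regional cancellous levels, densified bands along the
#' principal compressive (head-to-calcar) and tensile/trochanteric
#' trajectories, and a small seeded Gaussian random field. All geometry
#' scales with the domain, so half-scale "desk" phantoms preserve the
#' anatomy.
#'
#' @param width_mm,height_mm Physical domain size in mm. Defaults 94.2 x
#'   104.4 (the full-scale proximal femur); use 47.1 x 52.2 for the
#'   half-scale desk phantom.
#' @param pixel_size_um Pixel edge length in micrometres (default 600, the
#'   clinical low-resolution scale).
#' @param seed Integer seed; fully determines the output.
#' @param cortical_thickness_mm Cortical shell thickness (default 1.2 mm).
#' @param noise_sd Standard deviation of the smooth (correlated) density
#'   noise field.
#' @param texture_sd Standard deviation of the independent per-pixel
#'   texture (partial-volume variability of unresolved trabeculae).
#'
#' @return An object of class \code{femur_phantom}: list with \code{image}
#'   (a \code{\link{density_image}}), \code{landmarks} (named list of mm
#'   coordinates and radii), and \code{params}.
#' @export
#' @examples
#' ph <- femur_phantom(width_mm = 47.1, height_mm = 52.2, seed = 1)
#' dim(ph$image$values)
femur_phantom <- function(width_mm = 94.2, height_mm = 104.4,
                          pixel_size_um = 600, seed = 1,
                          cortical_thickness_mm = 1.2,
                          noise_sd = 0.04, texture_sd = 0.15) {
  W <- width_mm; H <- height_mm
  h <- pixel_size_um / 1000
  nx <- round(W / h); ny <- round(H / h)
  if (nx < 16 || ny < 16)
    stop("domain too small to contain the femur geometry", call. = FALSE)

  # pixel centers
  px <- (seq_len(nx) - 0.5) * h
  py <- (seq_len(ny) - 0.5) * h
  X <- matrix(px, ny, nx, byrow = TRUE)
  Y <- matrix(py, ny, nx)

  geo <- femur_geometry(W, H)
  sd_head  <- sdf_disc(X, Y, geo$head_center, geo$head_radius)
  sd_troch <- sdf_disc(X, Y, geo$troch_center, geo$troch_radius)
  sd_neck  <- sdf_capsule(X, Y, geo$neck_a, geo$neck_b, geo$neck_radius)
  sd_shaft <- sdf_capsule(X, Y, geo$shaft_a, geo$shaft_b, geo$shaft_radius)
  k <- 0.02 * W
  sdf <- smooth_max(smooth_max(sd_head, sd_neck, k),
                    smooth_max(sd_troch, sd_shaft, k), k)
  mask <- sdf > 0

  # cortical shell: pixels within the shell thickness of the outer boundary
  dpx <- EBImage::distmap(mask * 1)
  shell <- mask & (dpx * h <= cortical_thickness_mm)

  # regional cancellous base levels, blended by distance to each primitive
  sig <- 0.03 * W
  wh <- stats::plogis(sd_head / sig)
  wt <- stats::plogis(sd_troch / sig)
  wn <- stats::plogis(sd_neck / sig)
  ws <- stats::plogis(sd_shaft / sig)
  base <- (0.52 * wh + 0.28 * wt + 0.08 * wn + 0.15 * ws) /
    (wh + wt + wn + ws + 1e-9)

  # trabecular trajectory bands (continuum-level densification)
  band <- function(a, b, halfwidth, boost) {
    d <- pmax(-sdf_capsule(X, Y, a, b, 0), 0)
    boost * exp(-(d / halfwidth)^2)
  }
  bands <- band(geo$head_center, geo$calcar, 0.030 * W, 0.40) +
    band(geo$tens_a, geo$tens_b, 0.025 * W, 0.40) +
    band(geo$sec_a, geo$sec_b, 0.030 * W, 0.30)

  # two-scale BMD variability: a smooth field (regional inhomogeneity) plus
  # independent per-pixel texture emulating partial-volume averaging of
  # unresolved trabeculae within each 600 um pixel
  noise <- with_seed(seed, {
    z <- matrix(stats::rnorm(ny * nx), ny, nx)
    zs <- EBImage::gblur(z, sigma = 1.5)
    zs / stats::sd(zs) * noise_sd +
      matrix(stats::rnorm(ny * nx, sd = texture_sd), ny, nx)
  })

  interior <- pmin(pmax(base + bands + noise, 0.01), 0.9)
  values <- matrix(0, ny, nx)
  values[mask] <- interior[mask]
  values[shell] <- 0.95

  img <- density_image(values, mask, pixel_size_um = pixel_size_um)
  landmarks <- c(geo, list(
    distal_edge = "bottom",
    roi_centers = list(head = geo$head_center,
                       neck = geo$neck_mid,
                       intertrochanter = geo$intertroch_center)))
  structure(list(image = img, landmarks = landmarks,
                 params = list(width_mm = W, height_mm = H,
                               pixel_size_um = pixel_size_um, seed = seed,
                               cortical_thickness_mm = cortical_thickness_mm,
                               noise_sd = noise_sd,
                               texture_sd = texture_sd)),
            class = "femur_phantom")
}

femur_geometry <- function(W, H) {
  list(
    head_center   = c(0.68 * W, 0.80 * H),
    head_radius   = 0.170 * W,
    troch_center  = c(0.28 * W, 0.60 * H),
    troch_radius  = 0.155 * W,
    neck_a        = c(0.40 * W, 0.58 * H),
    neck_b        = c(0.68 * W, 0.80 * H),
    neck_radius   = 0.130 * W,
    neck_mid      = c(0.50 * W, 0.655 * H),
    shaft_a       = c(0.30 * W, -0.10 * H),
    shaft_b       = c(0.30 * W, 0.56 * H),
    shaft_radius  = 0.135 * W,
    calcar        = c(0.52 * W, 0.48 * H),
    tens_a        = c(0.25 * W, 0.50 * H),
    tens_b        = c(0.62 * W, 0.72 * H),
    sec_a         = c(0.40 * W, 0.44 * H),
    sec_b         = c(0.32 * W, 0.68 * H),
    intertroch_center = c(0.32 * W, 0.56 * H))
}

sdf_disc <- function(X, Y, center, r) {
  r - sqrt((X - center[1])^2 + (Y - center[2])^2)
}

sdf_capsule <- function(X, Y, a, b, r) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- pmin(pmax(((X - a[1]) * abx + (Y - a[2]) * aby) / len2, 0), 1)
  r - sqrt((X - a[1] - t * abx)^2 + (Y - a[2] - t * aby)^2)
}

smooth_max <- function(a, b, k) {
  m <- pmax(a, b)
  m + k * log1p(exp(-abs(a - b) / k))
}

# evaluate expr with a temporary RNG state; leaves the caller's RNG untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.femur_phantom <- function(x, ...) {
  cat(sprintf("femur_phantom: %.1f x %.1f mm at %g um/pixel (seed %d)\n",
              x$params$width_mm, x$params$height_mm,
              x$params$pixel_size_um, x$params$seed))
  print(x$image)
  invisible(x)
}

#' @export
plot.femur_phantom <- function(x, ...) {
  plot(x$image, main = "femur phantom", ...)
  lm <- x$landmarks
  graphics::points(lm$head_center[1], lm$head_center[2], pch = 3, col = "red")
  graphics::points(lm$troch_center[1], lm$troch_center[2], pch = 3,
                   col = "blue")
  invisible(x)
}

#' Physiological load cases for the proximal femur
#'
#' The three daily-activity load cases: one-legged stance, abduction and
#' adduction. Each case pairs a hip-contact force on the femoral-head
#' surface with an abductor muscle force on the greater-trochanter surface;
#' angles are measured from the vertical (+y) axis, positive toward +x
#' (medial). The normalized weights reflect daily loading cycles
#' (6000/2000/2000) and sum to 1.
#'
#' @return List of three \code{load_case} objects.
#' @export
default_load_cases <- function() {
  list(
    load_case("one_legged_stance", hip_N = 2317, hip_angle_deg = 24,
              abductor_N = 703, abductor_angle_deg = 28, weight = 0.6),
    load_case("abduction", hip_N = 1158, hip_angle_deg = -15,
              abductor_N = 351, abductor_angle_deg = -8, weight = 0.2),
    load_case("adduction", hip_N = 1548, hip_angle_deg = 56,
              abductor_N = 468, abductor_angle_deg = 35, weight = 0.2))
}

#' Construct a load case
#'
#' @param name Case name.
#' @param hip_N,hip_angle_deg Hip-contact force magnitude (N) and angle from
#'   vertical (degrees), applied toward the femoral-head center.
#' @param abductor_N,abductor_angle_deg Abductor muscle force, applied
#'   toward the greater-trochanter center.
#' @param weight Normalized weight of the case in the compliance objective.
#' @return A \code{load_case} object.
#' @export
load_case <- function(name, hip_N, hip_angle_deg, abductor_N,
                      abductor_angle_deg, weight) {
  stopifnot(hip_N >= 0, abductor_N >= 0, weight >= 0)
  structure(list(name = name,
                 hip = list(magnitude_N = hip_N, angle_deg = hip_angle_deg,
                            surface = "femoral_head"),
                 abductor = list(magnitude_N = abductor_N,
                                 angle_deg = abductor_angle_deg,
                                 surface = "greater_trochanter"),
                 weight = weight),
            class = "load_case")
}

#' Distribute a load case over the phantom surface arcs
#'
#' Each force is spread over a cosine-weighted arc of boundary nodes
#' centered on the point where the load axis enters the surface; all nodal
#' forces are parallel to the load axis and point toward the landmark
#' center, and the weights are normalized so the vector resultant equals the
#' stated magnitude at the stated angle exactly.
#'
#' @param case A \code{\link{load_case}}.
#' @param landmarks Landmark list from \code{\link{femur_phantom}}.
#' @param model An \code{fe_model} built over the phantom mask (any
#'   refinement level).
#' @param arc_half_deg Half-width of the loaded arc in degrees (default 30,
#'   i.e. a 60-degree arc).
#' @return Nodal force vector of length \code{model$ndof} (N).
#' @export
distribute_load <- function(case, landmarks, model, arc_half_deg = 30) {
  stopifnot(inherits(case, "load_case"))
  f <- numeric(model$ndof)
  f <- f + surface_arc_load(model, landmarks$head_center,
                            landmarks$head_radius,
                            case$hip$magnitude_N, case$hip$angle_deg,
                            arc_half_deg, "femoral head")
  f <- f + surface_arc_load(model, landmarks$troch_center,
                            landmarks$troch_radius,
                            case$abductor$magnitude_N,
                            case$abductor$angle_deg,
                            arc_half_deg, "greater trochanter")
  f
}

surface_arc_load <- function(model, center, radius, magnitude, angle_deg,
                             arc_half_deg, what) {
  f <- numeric(model$ndof)
  if (magnitude == 0) return(f)
  bn <- boundary_node_ids(model)
  xy <- model$node_xy[bn, , drop = FALSE]
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  rr <- sqrt(dx^2 + dy^2)
  phi <- atan2(dx, dy) * 180 / pi        # node direction from vertical
  dphi <- ((phi - angle_deg + 180) %% 360) - 180
  sel <- rr >= 0.7 * radius & rr <= 1.3 * radius & abs(dphi) <= arc_half_deg
  if (!any(sel))
    stop(sprintf("no boundary nodes found on the %s arc", what),
         call. = FALSE)
  w <- cos(dphi[sel] / arc_half_deg * pi / 2)
  w <- w / sum(w)
  th <- angle_deg * pi / 180
  dir <- c(-sin(th), -cos(th))           # toward the landmark center
  nodes <- bn[sel]
  f[2 * nodes - 1] <- magnitude * w * dir[1]
  f[2 * nodes]     <- magnitude * w * dir[2]
  f
}

# nodes adjacent to fewer than 4 active elements (mask surface incl. domain
# edge)
boundary_node_ids <- function(model) {
  ny <- nrow(model$mask); nx <- ncol(model$mask)
  cnt <- matrix(0L, ny + 1, nx + 1)
  m <- model$mask
  cnt[1:ny, 1:nx] <- cnt[1:ny, 1:nx] + m                # node = LL of elem
  cnt[1:ny, 2:(nx + 1)] <- cnt[1:ny, 2:(nx + 1)] + m    # node = LR
  cnt[2:(ny + 1), 2:(nx + 1)] <- cnt[2:(ny + 1), 2:(nx + 1)] + m
  cnt[2:(ny + 1), 1:nx] <- cnt[2:(ny + 1), 1:nx] + m
  used <- !is.na(model$nid)
  sort(model$nid[used & cnt < 4L])
}
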