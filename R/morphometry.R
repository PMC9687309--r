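#' Binarize a density field
#'
#' Bone phase is \code{rho >= threshold}. Topology-optimized fields are
#' contrast-enhanced around the input densities, so the midpoint threshold
#' 0.5 is the default.
#'
#' @param rho Numeric matrix of densities.
#' @param threshold Threshold in (0, 1).
#' @return Logical matrix (TRUE = bone).
#' @export
binarize <- function(rho, threshold = 0.5) {
  stopifnot(is.matrix(rho), threshold > 0, threshold < 1)
  rho >= threshold
}

#' Bone volume fraction (BV/TV)
#'
#' @param binary Logical matrix from \code{\link{binarize}}.
#' @return Percentage of bone-phase pixels in the region.
#' @export
bv_tv <- function(binary) {
  stopifnot(is.matrix(binary), is.logical(binary))
  if (length(binary) == 0) stop("empty region", call. = FALSE)
  100 * sum(binary) / length(binary)
}

#' Mean local thickness of a phase (2D)
#'
#' Largest-inscribed-disc thickness: every pixel of the chosen phase is
#' assigned the diameter of the largest disc that contains it and fits
#' inside the phase (the 2D restriction of the standard model-independent
#' local-thickness definition), and the area-weighted mean is returned.
#' Computed from the Euclidean distance map by covering the phase with
#' discs of decreasing radius (morphological dilation per radius level).
#'
#' Applied to the bone phase this is Tb.Th; applied to the background
#' (marrow) phase, Tb.Sp.
#'
#' @param binary Logical matrix; TRUE pixels form the measured phase.
#' @param pixel_size_um Pixel edge length (um).
#' @return Mean thickness in micrometres.
#' @export
local_thickness <- function(binary, pixel_size_um = 50) {
  stopifnot(is.matrix(binary), is.logical(binary))
  if (!any(binary)) {
    warning("phase absent; thickness undefined", call. = FALSE)
    return(NA_real_)
  }
  th <- thickness_map(binary)
  mean(th[binary]) * pixel_size_um
}

# Per-pixel largest-inscribed-disc diameter, in pixels. A pixel whose
# Euclidean distance to the background is d carries a disc of diameter
# 2d - 1; every pixel covered by that disc is at least that thick. Distance
# levels are processed descending on a quarter-pixel grid, with coverage of
# each level computed from the distance map of its center set.
thickness_map <- function(binary) {
  d <- as.matrix(EBImage::distmap(binary * 1))
  dq <- round(d * 4) / 4
  th <- matrix(0, nrow(binary), ncol(binary))
  for (r in sort(unique(dq[dq > 0]), decreasing = TRUE)) {
    centers <- dq >= r
    unset <- th == 0
    if (!any(unset & binary)) break
    if (r > 0.5) {
      # distance from every pixel to the nearest center
      dc <- as.matrix(EBImage::distmap((!centers) * 1))
      covered <- centers | (dc <= r - 0.5)
    } else covered <- centers
    sel <- covered & unset & binary
    th[sel] <- 2 * r - 1
  }
  th[!binary] <- 0
  th
}

#' Trabecular number from the plate model
#'
#' \eqn{Tb.N = (BV/TV)/Tb.Th} with BV/TV as a fraction and Tb.Th in mm:
#' the number of plate-like trabeculae crossed per millimetre.
#'
#' @param bv_tv BV/TV in percent.
#' @param tb_th Tb.Th in micrometres (> 0).
#' @return Tb.N in 1/mm.
#' @export
tb_n <- function(bv_tv, tb_th) {
  if (any(tb_th <= 0)) stop("tb_th must be positive", call. = FALSE)
  (bv_tv / 100) / (tb_th / 1000)
}

#' Primary trabecular alignment angle
#'
#' Orientation of the primary trabecular group, from the distribution of
#' local structure-tensor orientations: intensity gradients by central
#' differences give a per-pixel structure orientation (perpendicular to the
#' gradient) weighted by the squared gradient magnitude; the weighted
#' orientation distribution is accumulated on the doubled-angle circle, and
#' the angle reported is the energy-weighted circular mean around the
#' distribution's dominant peak. Using the peak rather than the full-tensor
#' average keeps the measurement pinned to the primary group when secondary
#' trabeculae cross it at large angles. Reported in degrees from vertical
#' (+y), positive toward +x, in [-90, 90).
#'
#' @param rho Numeric matrix (density field or binarized image as 0/1).
#' @param min_anisotropy Smallest admissible eigenvalue ratio of the
#'   ROI-averaged structure tensor; fields more isotropic than this return
#'   NA with a warning.
#' @param peak_halfwidth_deg Half-width (degrees) of the orientation window
#'   averaged around the dominant peak.
#' @return Angle in degrees, or NA for isotropic fields.
#' @export
alignment_angle <- function(rho, min_anisotropy = 1.05,
                            peak_halfwidth_deg = 30) {
  if (is.logical(rho)) rho <- rho * 1
  stopifnot(is.matrix(rho))
  ny <- nrow(rho); nx <- ncol(rho)
  if (ny < 3 || nx < 3) stop("field too small", call. = FALSE)
  # Scharr 3x3 derivative (minimal orientation anisotropy)
  i0 <- 2:(ny - 1); j0 <- 2:(nx - 1)
  sch <- function(m) (3 * m[i0 - 1, ] + 10 * m[i0, ] + 3 * m[i0 + 1, ]) / 16
  dx <- (rho[, j0 + 1] - rho[, j0 - 1]) / 2
  dy <- (rho[i0 + 1, ] - rho[i0 - 1, ]) / 2
  gx <- as.vector(sch(dx))
  gy <- as.vector((3 * dy[, j0 - 1] + 10 * dy[, j0] + 3 * dy[, j0 + 1]) / 16)
  w <- gx^2 + gy^2
  # isotropy guard from the averaged tensor
  Jxx <- mean(gx^2); Jyy <- mean(gy^2); Jxy <- mean(gx * gy)
  disc <- sqrt(((Jxx - Jyy) / 2)^2 + Jxy^2)
  l1 <- (Jxx + Jyy) / 2 + disc
  l2 <- (Jxx + Jyy) / 2 - disc
  if (l1 <= 0 || l1 / max(l2, 1e-300) < min_anisotropy) {
    warning("field too isotropic for an alignment angle", call. = FALSE)
    return(NA_real_)
  }
  # structure orientation = gradient + 90 deg, on the doubled-angle circle
  dbl <- (2 * (atan2(gy, gx) + pi / 2)) %% (2 * pi)
  nbin <- 72L
  bin <- pmin(floor(dbl / (2 * pi) * nbin) + 1L, nbin)
  h <- vapply(seq_len(nbin), function(b) sum(w[bin == b]), numeric(1))
  # circular smoothing over +-3 bins
  hs <- vapply(seq_len(nbin), function(b)
    sum(h[((b - 4L + seq_len(7L)) - 1L) %% nbin + 1L]), numeric(1))
  ctr <- (which.max(hs) - 0.5) / nbin * 2 * pi
  sel <- abs(((dbl - ctr + pi) %% (2 * pi)) - pi) <
    2 * peak_halfwidth_deg * pi / 180
  # exact tensor orientation of the selected (primary-group) pixels
  Jxx <- sum(gx[sel]^2); Jyy <- sum(gy[sel]^2); Jxy <- sum(gx[sel] * gy[sel])
  theta_g <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)  # dominant gradient direction
  ang <- -theta_g * 180 / pi                   # structure, from vertical
  ((ang + 90) %% 180) - 90
}

#' Morphometric report for a reconstructed field
#'
#' Computes BV/TV, Tb.Th, Tb.Sp, Tb.N and the alignment angle for a density
#' field or a \code{\link{bone_recon}} result.
#'
#' @param x A \code{bone_recon} or a numeric density matrix.
#' @param pixel_size_um Pixel size (taken from the recon object when given).
#' @param threshold Binarization threshold.
#' @return An object of class \code{morphometry_report}.
#' @export
morphometry <- function(x, pixel_size_um = NULL, threshold = 0.5) {
  if (inherits(x, "bone_recon")) {
    rho <- x$rho
    if (is.null(pixel_size_um)) pixel_size_um <- x$pixel_size_um
    label <- if (!is.null(x$roi$name)) x$roi$name else "roi"
  } else {
    rho <- x
    if (is.null(pixel_size_um))
      stop("pixel_size_um required for a bare matrix", call. = FALSE)
    label <- "roi"
  }
  b <- binarize(rho, threshold)
  bvtv <- bv_tv(b)
  tbth <- local_thickness(b, pixel_size_um)
  tbsp <- local_thickness(!b, pixel_size_um)
  structure(list(label = label,
                 bv_tv = bvtv,
                 tb_th = tbth,
                 tb_sp = tbsp,
                 tb_n = if (is.na(tbth)) NA_real_ else tb_n(bvtv, tbth),
                 alignment_deg = alignment_angle(rho),
                 threshold = threshold,
                 pixel_size_um = pixel_size_um,
                 shape = dim(rho)),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("morphometry (%s, threshold %.2f, %g um/px):\n",
              x$label, x$threshold, x$pixel_size_um))
  cat(sprintf("  BV/TV  %6.2f %%\n", x$bv_tv))
  cat(sprintf("  Tb.Th  %6.2f um\n", x$tb_th))
  cat(sprintf("  Tb.Sp  %6.2f um\n", x$tb_sp))
  cat(sprintf("  Tb.N   %6.3f 1/mm\n", x$tb_n))
  cat(sprintf("  align  %6.2f deg from vertical\n", x$alignment_deg))
  invisible(x)
}

#' Compare two morphometric reports
#'
#' BV/TV difference in percentage points; Tb.Th, Tb.Sp and Tb.N as relative
#' errors in percent of the first report; alignment as the absolute angular
#' difference in degrees (mod 180).
#'
#' @param a,b \code{morphometry_report}s of the same region and threshold.
#' @return Named list of errors.
#' @export
compare_morphometry <- function(a, b) {
  stopifnot(inherits(a, "morphometry_report"),
            inherits(b, "morphometry_report"))
  if (!identical(a$shape, b$shape))
    stop("reports cover different regions", call. = FALSE)
  if (a$threshold != b$threshold)
    stop("reports use different thresholds", call. = FALSE)
  dang <- abs(a$alignment_deg - b$alignment_deg) %% 180
  dang <- min(dang, 180 - dang)
  list(bv_tv_pp = abs(a$bv_tv - b$bv_tv),
       tb_th_pct = 100 * abs(a$tb_th - b$tb_th) / a$tb_th,
       tb_sp_pct = 100 * abs(a$tb_sp - b$tb_sp) / a$tb_sp,
       tb_n_pct = 100 * abs(a$tb_n - b$tb_n) / a$tb_n,
       alignment_deg = dang)
}
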