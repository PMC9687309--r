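#' Masked 2D relative-density image
#'
#' The common container for every density field in the package: the
#' low-resolution input, refined fields, and reconstructed output. Values are
#' stored as a matrix with row 1 at the \emph{bottom} of the physical domain
#' (y increases with row index, x with column index), so pixel (1,1) sits at
#' the lower-left corner.
#'
#' @param values Numeric matrix of relative densities in [0, 1].
#' @param mask Logical matrix of the same shape; TRUE marks active
#'   (bone-domain) pixels. Defaults to all-TRUE.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param origin_mm Physical coordinate (x, y) of the lower-left corner, mm.
#'
#' @return An object of class \code{density_image} with fields
#'   \code{values}, \code{mask}, \code{pixel_size_um}, \code{origin_mm}.
#' @export
density_image <- function(values, mask = NULL, pixel_size_um = 600,
                          origin_mm = c(0, 0)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(is.matrix(mask), is.logical(mask),
            identical(dim(mask), dim(values)))
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0)
  stopifnot(length(origin_mm) == 2L)
  v <- values[mask]
  if (length(v) && (any(v < 0) || any(v > 1)))
    stop("active-pixel densities must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, mask = mask,
                 pixel_size_um = pixel_size_um,
                 origin_mm = as.numeric(origin_mm)),
            class = "density_image")
}

#' @export
print.density_image <- function(x, ...) {
  cat(sprintf("density_image: %d x %d pixels (%g um/pixel), %d active\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              sum(x$mask)))
  v <- x$values[x$mask]
  if (length(v))
    cat(sprintf("  density range [%.3f, %.3f], mean %.3f\n",
                min(v), max(v), mean(v)))
  cat(sprintf("  origin (%.2f, %.2f) mm\n", x$origin_mm[1], x$origin_mm[2]))
  invisible(x)
}

#' @export
plot.density_image <- function(x, main = "density", ...) {
  v <- x$values
  v[!x$mask] <- NA
  h <- x$pixel_size_um / 1000
  xs <- x$origin_mm[1] + (seq_len(ncol(v)) - 0.5) * h
  ys <- x$origin_mm[2] + (seq_len(nrow(v)) - 0.5) * h
  graphics::image(xs, ys, t(v), asp = 1, col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x (mm)", ylab = "y (mm)", main = main,
                  zlim = c(0, 1), useRaster = TRUE, ...)
  invisible(x)
}

#' Write a density image to 16-bit TIFF with a JSON sidecar
#'
#' Densities are scaled to the 16-bit range (value/65535); masked-out pixels
#' are written as 0 and recorded via the sidecar's mask encoding. The sidecar
#' \code{<path>.json} stores pixel size, origin and mask.
#'
#' @param image A \code{\link{density_image}}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_density_image <- function(image, path) {
  stopifnot(inherits(image, "density_image"))
  v <- image$values
  v[!image$mask] <- 0
  # tiff expects row 1 at the top; flip so files view naturally
  m <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = image$pixel_size_um,
               origin_mm = image$origin_mm,
               mask_encoding = "rle_rowmajor_bottomup",
               mask_rle = rle_encode(as.vector(image$mask)),
               shape = dim(image$values))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a density image written by \code{write_density_image}
#'
#' @param path TIFF path with accompanying \code{<path>.json} sidecar.
#' @return A \code{\link{density_image}}.
#' @export
read_density_image <- function(path) {
  m <- tiff::readTIFF(path)
  v <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mask <- matrix(rle_decode(meta$mask_rle, prod(meta$shape)),
                   meta$shape[1], meta$shape[2])
    density_image(round(v * 65535) / 65535, mask,
                  pixel_size_um = meta$pixel_size_um,
                  origin_mm = meta$origin_mm)
  } else {
    density_image(round(v * 65535) / 65535)
  }
}

rle_encode <- function(x) {
  r <- rle(x)
  list(lengths = r$lengths, values = r$values)
}

rle_decode <- function(enc, n) {
  out <- inverse.rle(structure(list(lengths = as.integer(enc$lengths),
                                    values = as.logical(enc$values)),
                               class = "rle"))
  stopifnot(length(out) == n)
  out
}
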