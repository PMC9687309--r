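#' Run configuration for the reconstruction pipeline
#'
#' Bundles phantom, ROI, material and optimizer settings into one
#' serializable object. Defaults reproduce the reference configuration:
#' 600 um input, 50 um target (n = 12), epsilon 0.01, gamma 3, E0 15 GPa,
#' nu 0.3, case weights 0.6/0.2/0.2. The desk-scale preset switches to the
#' half-size phantom with n = 6 for routine runs.
#'
#' @param phantom Named list of \code{\link{femur_phantom}} arguments.
#' @param rois List of ROI requests, each \code{list(preset =, size_px =)}
#'   or an explicit \code{\link{roi_spec}}.
#' @param n Refinement factor.
#' @param modes Character vector from \code{c("global", "localized")}.
#' @param material \code{\link{material_params}}.
#' @param control \code{\link{recon_control}}.
#' @param seed Master seed (propagated to the phantom unless it sets its
#'   own).
#' @param desk_scale If TRUE, use the half-scale phantom (47.1 x 52.2 mm)
#'   and n = 6 unless overridden.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(phantom = list(), rois = list(list(preset = "head", size_px = 16),
                                                     list(preset = "neck", size_px = 8),
                                                     list(preset = "intertrochanter", size_px = 16)),
                       n = NULL, modes = c("global", "localized"),
                       material = material_params(),
                       control = recon_control(), seed = 1,
                       desk_scale = FALSE) {
  stopifnot(all(modes %in% c("global", "localized")))
  ph_defaults <- if (desk_scale)
    list(width_mm = 47.1, height_mm = 52.2, pixel_size_um = 600)
  else list(width_mm = 94.2, height_mm = 104.4, pixel_size_um = 600)
  phantom <- utils::modifyList(ph_defaults, phantom)
  if (is.null(phantom$seed)) phantom$seed <- seed
  if (is.null(n)) n <- if (desk_scale) 6 else 12
  structure(list(phantom = phantom, rois = rois, n = n, modes = modes,
                 material = material, control = control, seed = seed,
                 desk_scale = desk_scale),
            class = "run_config")
}

#' Write/read a run configuration as JSON
#'
#' @param config A \code{\link{run_config}}.
#' @param path JSON file path.
#' @return \code{path} / the restored \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$material <- unclass(x$material)
  x$control <- unclass(x$control)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(seq_len(if (is.data.frame(x$rois)) nrow(x$rois)
                         else length(x$rois)),
                 function(i) if (is.data.frame(x$rois)) as.list(x$rois[i, ])
                 else x$rois[[i]])
  run_config(phantom = as.list(x$phantom), rois = rois, n = x$n,
             modes = x$modes,
             material = do.call(material_params, as.list(x$material)),
             control = do.call(recon_control, as.list(x$control)),
             seed = x$seed, desk_scale = isTRUE(x$desk_scale))
}

#' Run the full validation pipeline
#'
#' phantom -> loads -> reconstruction (per ROI, per mode) -> morphometry ->
#' mode comparison. When both modes are requested the comparison table
#' mirrors the conventional/localized error layout (BV/TV in percentage
#' points, Tb indices as relative errors, alignment in degrees).
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Optional output directory; when given, density TIFFs,
#'   per-iteration history CSVs, morphometry and comparison CSVs are
#'   written there.
#' @return List with \code{phantom}, \code{runs} (per ROI and mode),
#'   \code{reports}, and \code{comparison} (data frame, when both modes
#'   ran), invisibly when writing files.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ph <- do.call(femur_phantom, config$phantom)
  runs <- list()
  reports <- list()
  comp_rows <- list()
  for (r in config$rois) {
    roi <- if (inherits(r, "roi_spec")) r
    else roi_preset(ph, r$preset, r$size_px)
    key <- if (!is.null(roi$name)) sprintf("%s_%d", roi$name, roi$rows)
    else sprintf("roi_%d_%d", roi$row0, roi$col0)
    for (mode in config$modes) {
      res <- tryCatch(
        reconstruct(ph, roi, mode = mode, n = config$n,
                    material = config$material, control = config$control),
        error = function(e)
          stop(sprintf("[%s/%s] %s", key, mode, conditionMessage(e)),
               call. = FALSE))
      runs[[key]][[mode]] <- res
      reports[[key]][[mode]] <- morphometry(res)
    }
    if (all(c("global", "localized") %in% config$modes)) {
      err <- compare_morphometry(reports[[key]]$global,
                                 reports[[key]]$localized)
      comp_rows[[key]] <- data.frame(
        roi = key,
        bvtv_conv = reports[[key]]$global$bv_tv,
        bvtv_loc = reports[[key]]$localized$bv_tv,
        bvtv_err_pp = err$bv_tv_pp,
        tbth_err_pct = err$tb_th_pct,
        tbsp_err_pct = err$tb_sp_pct,
        tbn_err_pct = err$tb_n_pct,
        align_err_deg = err$alignment_deg,
        iters_conv = runs[[key]]$global$iterations,
        iters_loc = runs[[key]]$localized$iterations)
    }
  }
  comparison <- if (length(comp_rows))
    do.call(rbind, c(comp_rows, list(make.row.names = FALSE))) else NULL
  out <- list(phantom = ph, runs = runs, reports = reports,
              comparison = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_density_image(ph$image, file.path(out_dir, "phantom.tiff"))
    for (key in names(runs)) for (mode in names(runs[[key]])) {
      res <- runs[[key]][[mode]]
      stem <- file.path(out_dir, sprintf("%s_%s", key, mode))
      write_density_image(
        density_image(res$rho, pixel_size_um = res$pixel_size_um),
        paste0(stem, ".tiff"))
      utils::write.csv(data.frame(iteration = seq_along(res$f_history),
                                  compliance = res$f_history,
                                  g = res$g_history,
                                  max_change = res$change_history),
                       paste0(stem, "_history.csv"), row.names = FALSE)
      rep <- reports[[key]][[mode]]
      utils::write.csv(data.frame(index = c("BV/TV (%)", "Tb.Th (um)",
                                            "Tb.Sp (um)", "Tb.N (1/mm)",
                                            "alignment (deg)"),
                                  value = c(rep$bv_tv, rep$tb_th, rep$tb_sp,
                                            rep$tb_n, rep$alignment_deg)),
                       paste0(stem, "_morphometry.csv"), row.names = FALSE)
    }
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(out_dir, "errors.csv"),
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Deterministic toy fixtures for development and regression testing
#'
#' Small, seed-determined objects exercising every stage of the pipeline
#' at negligible cost: a heterogeneous toy plate image, a binary stripe
#' phantom with known morphometry, and a ready-to-run toy reconstruction
#' case (plate, centered ROI, top load).
#'
#' @param seed Integer seed.
#' @return Named list with \code{plate} (a \code{\link{density_image}}),
#'   \code{stripes} (logical matrix, 3 px struts / 9 px gaps),
#'   \code{topopt} (list with \code{image}, \code{roi}, \code{loads}
#'   function and \code{n}).
#' @export
make_fixtures <- function(seed = 1) {
  vals <- with_seed(seed, matrix(stats::runif(16 * 16, 0.25, 0.85), 16, 16))
  plate <- density_image(vals, pixel_size_um = 600)
  stripes <- matrix(FALSE, 60, 60)
  j <- 9
  while (j + 3 <= 51) {
    stripes[, j + 1:3] <- TRUE
    j <- j + 12
  }
  topopt <- list(
    image = plate,
    roi = roi_spec(5, 5, 6, 6),
    loads = function(model) {
      f <- numeric(model$ndof)
      tn <- which(model$node_rc[, 1] == max(model$node_rc[, 1]))
      f[2 * tn] <- -150 / length(tn)
      f
    },
    n = 3)
  list(plate = plate, stripes = stripes, topopt = topopt)
}
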