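#' Analysis configuration
#'
#' Collects every tunable parameter of the mask-and-index pipeline with
#' the method's standard defaults: 6 px dilation radius, 9 px boxcar
#' window, temporal-filter cutoff 0.0026 Hz (periods shorter than about
#' 6.4 min rejected).  All supplied values are validated together and
#' every violation is reported in one error message.
#'
#' @param dilation_radius Disk radius for mask dilation, pixels.
#' @param boxcar_w Odd boxcar window width, pixels.
#' @param sobel_threshold_scale Sobel threshold multiplier
#'   (see [binarize_edges()]).
#' @param tfilter Logical; apply the temporal-frequency filter between
#'   preprocessing and index computation.
#' @param threshold_hz Temporal-filter cutoff, Hz.
#' @param dt Frame interval of the input movie, seconds.
#' @param max_shift Alignment search radius, pixels (0 = no alignment).
#' @param pixel_size Optional pixel edge, micrometres (metadata).
#' @param save_intermediates Logical; write mask and filtered-mask TIFFs
#'   next to the results.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(dilation_radius = 6, boxcar_w = 9,
                            sobel_threshold_scale = 2, tfilter = FALSE,
                            threshold_hz = 0.0026, dt = 300, max_shift = 0,
                            pixel_size = NULL, save_intermediates = FALSE) {
  cfg <- list(dilation_radius = dilation_radius, boxcar_w = boxcar_w,
              sobel_threshold_scale = sobel_threshold_scale,
              tfilter = isTRUE(tfilter), threshold_hz = threshold_hz,
              dt = dt, max_shift = max_shift, pixel_size = pixel_size,
              save_intermediates = isTRUE(save_intermediates))
  errs <- character(0)
  if (dilation_radius < 0 || dilation_radius != round(dilation_radius)) {
    errs <- c(errs, "`dilation_radius` must be a non-negative integer")
  }
  if (boxcar_w < 1 || boxcar_w != round(boxcar_w) || boxcar_w %% 2 == 0) {
    errs <- c(errs, "`boxcar_w` must be an odd integer >= 1")
  }
  if (sobel_threshold_scale < 0) {
    errs <- c(errs, "`sobel_threshold_scale` must be non-negative")
  }
  if (threshold_hz <= 0) errs <- c(errs, "`threshold_hz` must be positive")
  if (is.null(dt) || !is.numeric(dt) || dt <= 0) {
    errs <- c(errs, "`dt` (frame interval, seconds) must be positive")
  }
  if (max_shift < 0 || max_shift != round(max_shift)) {
    errs <- c(errs, "`max_shift` must be a non-negative integer")
  }
  if (length(errs) > 0L) {
    stop(paste(c("invalid analysis configuration:", errs), collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' Run the full motility pipeline on one or more movies
#'
#' For every input TIFF: read the frame series, preprocess it into
#' binary masks (optional alignment, Sobel binarization, dilation),
#' optionally remove high-frequency pixels with the temporal filter,
#' compute both motility indices, and write a per-movie CSV.  A JSON run
#' record (config echo, package version, input checksums, per-stage
#' timings, warnings) is written once per call.  Output is deterministic
#' for fixed inputs and configuration.
#'
#' @param inputs Character vector of multi-page TIFF paths (one movie
#'   each).
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `results` (named list of
#'   `motility_result`s), `csv_paths` and `record`.
#' @export
run_pipeline <- function(inputs, config = analysis_config(), out_dir = ".") {
  stopifnot(inherits(config, "analysis_config"))
  if (length(inputs) == 0L) stop("no input files given", call. = FALSE)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  warnings_seen <- character(0)
  results <- list()
  csv_paths <- character(0)
  timings <- list()
  for (path in inputs) {
    stem <- tools::file_path_sans_ext(basename(path))
    t0 <- proc.time()[["elapsed"]]
    series <- read_frame_series(path, config$dt, config$pixel_size)
    masks <- preprocess_series(series,
                               dilation_radius = config$dilation_radius,
                               threshold_scale = config$sobel_threshold_scale,
                               max_shift = config$max_shift)
    if (config$save_intermediates) {
      write_binary_series(masks, file.path(out_dir, paste0(stem, "_masks.tif")))
    }
    if (config$tfilter) {
      fm <- withCallingHandlers(
        classify_pixels(masks, config$threshold_hz),
        warning = function(w) {
          warnings_seen <<- c(warnings_seen, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      masks <- apply_filter(masks, fm)
      if (config$save_intermediates) {
        write_binary_series(masks,
                            file.path(out_dir, paste0(stem, "_filtered.tif")))
      }
    }
    res <- motility_index(masks, w = config$boxcar_w)
    csv <- file.path(out_dir, paste0(stem, "_motility.csv"))
    write_motility_csv(res, csv, config = .config_echo(config))
    results[[stem]] <- res
    csv_paths <- c(csv_paths, csv)
    timings[[stem]] <- proc.time()[["elapsed"]] - t0
  }

  record <- list(
    package = "motilindex",
    version = as.character(utils::packageVersion("motilindex")),
    config = .config_echo(config),
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    timings_s = timings,
    warnings = warnings_seen
  )
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, csv_paths = csv_paths, record = record))
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg[!vapply(cfg, is.null, logical(1))]
}
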