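#' Read a multi-page TIFF as a frame series
#'
#' One grayscale page per time point; 8/16-bit integer pages are
#' normalized to \[0, 1\] floats on read.  RGB/multi-channel TIFFs are
#' rejected: the analysis is defined for a single fluorescence channel.
#'
#' @param path Path to a multi-page TIFF.
#' @param frame_interval Seconds between pages (> 0); acquisition
#'   metadata is supplied by the caller, not parsed from TIFF tags.
#' @param pixel_size Optional pixel edge in micrometres.
#' @return A [frame_series()].
#' @export
read_frame_series <- function(path, frame_interval, pixel_size = NULL) {
  if (!file.exists(path)) stop("input TIFF not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) {
        p <- p[, , 1]
      } else {
        stop("multi-channel TIFF: a single grayscale channel is required",
             call. = FALSE)
      }
    }
    p
  })
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
    stop("TIFF pages have inconsistent dimensions: ", path, call. = FALSE)
  }
  frame_series(pages, frame_interval, pixel_size)
}

#' Read one multi-page TIFF per time point as a z-stack series
#'
#' Each file contributes one Z x rows x cols stack (its pages are the
#' optical sections).
#'
#' @param paths Character vector of TIFF paths, in time order.
#' @param frame_interval Seconds between consecutive stacks.
#' @param pixel_size Optional pixel edge in micrometres.
#' @return A [zstack_series()].
#' @export
read_zstack_series <- function(paths, frame_interval, pixel_size = NULL) {
  stacks <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("input TIFF not found: ", p, call. = FALSE)
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(x) length(dim(x)) != 2L, logical(1)))) {
      stop("multi-channel TIFF: a single grayscale channel is required",
           call. = FALSE)
    }
    arr <- array(NA_real_, c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    arr
  })
  zstack_series(stacks, frame_interval, pixel_size)
}

#' Write a frame series as a multi-page TIFF
#'
#' Intensities are clipped to \[0, 1\] and written at the requested bit
#' depth (one page per frame).
#'
#' @param series A [frame_series()].
#' @param path Output path.
#' @param bits_per_sample 8, 16 or 32.
#' @return `path`, invisibly.
#' @export
write_frame_series <- function(series, path, bits_per_sample = 8) {
  stopifnot(inherits(series, "frame_series"))
  frames <- lapply(series$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Write a binary mask series as an 8-bit multi-page TIFF (0/255)
#'
#' @param series A [binary_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_series <- function(series, path) {
  stopifnot(inherits(series, "binary_series"))
  tiff::writeTIFF(lapply(series$masks, function(m) (m != 0) * 1),
                  path, bits.per.sample = 8)
  invisible(path)
}

#' Write a motility result as CSV
#'
#' One row per interval with columns `t`, `R`, `A_t`, `A_t1`, `M1`,
#' `M2`, `N`, followed by a summary row (`t = "mean"`) carrying the mean
#' area and the mean indices.  Analysis parameters are echoed as `#`
#' comment lines before the header.
#'
#' @param result A `motility_result` from [motility_index()].
#' @param path Output CSV path.
#' @param config Optional named list echoed into the comment header.
#' @return `path`, invisibly.
#' @seealso [read_motility_csv()]
#' @export
write_motility_csv <- function(result, path, config = NULL) {
  stopifnot(inherits(result, "motility_result"))
  iv <- result$intervals
  for (col in c("R", "A_t", "A_t1", "M1", "M2", "N")) {
    if (is.null(iv[[col]])) iv[[col]] <- NA
  }
  iv <- iv[, c("t", "R", "A_t", "A_t1", "M1", "M2", "N")]
  iv$t <- as.character(iv$t)
  summary_row <- tibble::tibble(
    t = "mean", R = NA_real_, A_t = result$area_mean, A_t1 = NA_real_,
    M1 = result$m1_mean, M2 = result$m2_mean, N = NA_real_
  )
  tab <- rbind(iv, summary_row)
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(list(package = paste0("motilindex ",
                                  utils::packageVersion("motilindex")),
                 boxcar_w = result$w,
                 frame_interval_s = result$frame_interval),
            config)
  for (k in names(meta)) {
    if (!is.null(meta[[k]])) {
      writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
                 con)
    }
  }
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motility CSV written by [write_motility_csv()]
#'
#' @param path CSV path.
#' @return List with `intervals` (tibble of numeric interval rows),
#'   `area_mean`, `m1_mean`, `m2_mean` and `meta` (the parsed comment
#'   header as a named character vector).
#' @export
read_motility_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- stats::setNames(
    sub("^# [^:]+: ", "", meta_lines),
    sub("^# ([^:]+):.*$", "\\1", meta_lines)
  )
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  sm <- tab[tab$t == "mean", , drop = FALSE]
  iv <- tab[tab$t != "mean", , drop = FALSE]
  iv$t <- as.integer(iv$t)
  list(
    intervals = tibble::as_tibble(iv),
    area_mean = sm$A_t[1], m1_mean = sm$M1[1], m2_mean = sm$M2[1],
    meta = meta
  )
}

#' Write a synthetic movie with its ground-truth sidecar
#'
#' The rendered frames go to a multi-page TIFF and the ground truth
#' (config echo, tip-length trajectories, per-interval changed-pixel
#' counts, mean tip speed) to a JSON sidecar next to it.
#'
#' @param movie Result of [generate_movie()].
#' @param path Output TIFF path; the sidecar is `<path>.truth.json`.
#' @param bits_per_sample Bit depth for the TIFF.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits_per_sample = 8) {
  write_frame_series(movie$series, path, bits_per_sample)
  cfg <- movie$config
  cfg$noise <- unclass(cfg$noise)
  truth <- list(
    config = unclass(cfg),
    tip_speed_mean = movie$truth$tip_speed_mean,
    tip_speeds = movie$truth$tip_speeds,
    lengths = movie$truth$lengths,
    changed_pixels_per_interval =
      vapply(movie$truth$changed, sum, numeric(1))
  )
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
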