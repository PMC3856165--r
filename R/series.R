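#' Time-lapse frame series
#'
#' A `frame_series` holds an ordered sequence of single-channel 2D
#' intensity frames together with its time base.  It is the common
#' container for raw fluorescence movies before binarization.
#'
#' @param frames List of numeric matrices, one per time point.  All
#'   matrices must share the same dimensions and contain finite,
#'   non-negative intensities.
#' @param frame_interval Seconds between consecutive frames (> 0).
#' @param pixel_size Optional pixel edge length in micrometres
#'   (metadata only; no computation depends on it).
#'
#' @return An object of class `frame_series`: a list with elements
#'   `frames`, `frame_interval` and `pixel_size`.
#' @seealso [binary_series()], [zstack_series()], [read_frame_series()]
#' @export
#' @examples
#' fs <- frame_series(list(matrix(0, 8, 8), matrix(1, 8, 8)),
#'                    frame_interval = 300)
#' n_frames(fs)
frame_series <- function(frames, frame_interval, pixel_size = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("`frames` must be a list of at least two matrices", call. = FALSE)
  }
  frames <- lapply(frames, .as_intensity_matrix)
  .check_same_dim(frames)
  .check_interval(frame_interval)
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size),
    class = "frame_series"
  )
}

#' Time series of z-stacks
#'
#' Container for one 3D image stack per time point, prior to
#' maximum-intensity projection.  Stacks are stored as Z x nrow x ncol
#' arrays.
#'
#' @param stacks List of numeric 3D arrays (Z x nrow x ncol), one per
#'   time point; all must share dimensions and Z >= 1.
#' @param frame_interval Seconds between consecutive stacks (> 0).
#' @param pixel_size Optional pixel edge length in micrometres.
#'
#' @return An object of class `zstack_series`.
#' @seealso [max_intensity_project()]
#' @export
zstack_series <- function(stacks, frame_interval, pixel_size = NULL) {
  if (!is.list(stacks) || length(stacks) < 1L) {
    stop("`stacks` must be a non-empty list of 3D arrays", call. = FALSE)
  }
  ok <- vapply(stacks, function(s) is.array(s) && length(dim(s)) == 3L,
               logical(1))
  if (!all(ok)) stop("each stack must be a 3D array (Z x rows x cols)",
                     call. = FALSE)
  dims <- vapply(stacks, dim, integer(3))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1])) {
    stop("all stacks must share identical dimensions", call. = FALSE)
  }
  .check_interval(frame_interval)
  structure(
    list(stacks = stacks, frame_interval = frame_interval,
         pixel_size = pixel_size),
    class = "zstack_series"
  )
}

#' Binary mask series
#'
#' Preprocessed time series of strictly binary (0/1) masks, the input
#' to all motility-index computations.  Element `masks[[t]][x, y]` is
#' the binary intensity of pixel (x, y) at time point t.
#'
#' @param masks List of matrices with values in {0, 1}, identical
#'   dimensions, length >= 2.
#' @param frame_interval Seconds between consecutive masks (> 0).
#'
#' @return An object of class `binary_series`.
#' @seealso [preprocess_series()], [motility_index()]
#' @export
binary_series <- function(masks, frame_interval) {
  if (!is.list(masks) || length(masks) < 2L) {
    stop("`masks` must be a list of at least two matrices", call. = FALSE)
  }
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stop("each mask must be a matrix", call. = FALSE)
    if (is.logical(m)) {
      storage.mode(m) <- "integer"
    } else if (!all(m == 0L | m == 1L)) {
      stop("mask values must be strictly 0 or 1", call. = FALSE)
    }
    storage.mode(m) <- "integer"
    m
  })
  .check_same_dim(masks)
  .check_interval(frame_interval)
  structure(list(masks = masks, frame_interval = frame_interval),
            class = "binary_series")
}

#' Number of time points in a series
#' @param x A `frame_series`, `zstack_series` or `binary_series`.
#' @return Integer count of time points.
#' @export
n_frames <- function(x) {
  UseMethod("n_frames")
}

#' @export
n_frames.frame_series <- function(x) length(x$frames)

#' @export
n_frames.zstack_series <- function(x) length(x$stacks)

#' @export
n_frames.binary_series <- function(x) length(x$masks)

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_series> %d frames of %d x %d px, dt = %g s\n",
              length(x$frames), d[1], d[2], x$frame_interval))
  invisible(x)
}

#' @export
print.zstack_series <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat(sprintf("<zstack_series> %d stacks of %d x %d x %d (Z x rows x cols), dt = %g s\n",
              length(x$stacks), d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' @export
print.binary_series <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<binary_series> %d masks of %d x %d px, dt = %g s\n",
              length(x$masks), d[1], d[2], x$frame_interval))
  invisible(x)
}

# ---- internal validators -------------------------------------------------

.as_intensity_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("each frame must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("frame intensities must be finite", call. = FALSE)
  if (any(m < 0)) stop("frame intensities must be non-negative", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

.check_same_dim <- function(mats) {
  d1 <- dim(mats[[1]])
  same <- vapply(mats, function(m) identical(dim(m), d1), logical(1))
  if (!all(same)) stop("all frames must share identical dimensions",
                       call. = FALSE)
  invisible(TRUE)
}

.check_interval <- function(frame_interval) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a single positive number (seconds)",
         call. = FALSE)
  }
  invisible(TRUE)
}
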