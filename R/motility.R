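#' Pixel-redistribution (difference) image
#'
#' Absolute difference of two consecutive binary masks.  A value of 1
#' marks a pixel that was either added or lost between the two time
#' points; the operation is symmetric in its arguments.
#'
#' @param mask_t,mask_t1 Binary matrices (values in {0, 1}) of equal
#'   dimensions: the masks at time points t and t + 1.
#' @return Integer matrix with values in {0, 1}.
#' @export
difference_image <- function(mask_t, mask_t1) {
  stopifnot(is.matrix(mask_t), is.matrix(mask_t1))
  if (!identical(dim(mask_t), dim(mask_t1))) {
    stop("masks must have identical dimensions", call. = FALSE)
  }
  out <- abs((mask_t1 != 0) - (mask_t != 0))
  storage.mode(out) <- "integer"
  out
}

#' Cell area of a binary mask
#'
#' Number of 1-pixels, i.e. the sum of the binary intensity over the
#' image.
#'
#' @param mask Binary matrix.
#' @return Integer pixel count.
#' @export
cell_area <- function(mask) {
  stopifnot(is.matrix(mask))
  as.integer(sum(mask != 0))
}

#' Boxcar (moving-average) smoothing of a difference image
#'
#' Replaces every pixel of the redistribution image by the mean of the
#' w x w window centred on it, with a fixed 1/w^2 normalization and zero
#' padding outside the image (border windows are not renormalized).
#' Computed exactly via a summed-area table.
#'
#' @param delta Binary difference image (matrix in {0, 1}).
#' @param w Odd window width in pixels (>= 1).
#' @return Numeric matrix with values in \[0, 1\].
#' @export
boxcar_average <- function(delta, w) {
  .check_boxcar_w(w)
  stopifnot(is.matrix(delta))
  h <- (w - 1L) %/% 2L
  nr <- nrow(delta); nc <- ncol(delta)
  # zero-padded summed-area table: z[i + 1, j + 1] = sum(delta[1:i, 1:j])
  z <- matrix(0, nr + 1L, nc + 1L)
  z[-1L, -1L] <- apply(apply(delta, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- pmax(seq_len(nr) - h, 1L); i2 <- pmin(seq_len(nr) + h, nr)
  j1 <- pmax(seq_len(nc) - h, 1L); j2 <- pmin(seq_len(nc) + h, nc)
  win <- z[i2 + 1L, j2 + 1L, drop = FALSE] - z[i1, j2 + 1L, drop = FALSE] -
    z[i2 + 1L, j1, drop = FALSE] + z[i1, j1, drop = FALSE]
  win / (as.numeric(w)^2)
}

#' Boxcar-weighted redistribution image
#'
#' Element-wise product of the boxcar-averaged image and the binary
#' difference image.  The product suppresses isolated single-pixel
#' changes (typically artifact) and up-weights clustered changes that
#' reflect coordinated structural remodeling.
#'
#' @param boxcar Numeric matrix from [boxcar_average()].
#' @param delta Binary difference image of the same dimensions.
#' @return Numeric matrix, zero wherever `delta` is zero.
#' @export
weighted_redistribution <- function(boxcar, delta) {
  stopifnot(is.matrix(boxcar), is.matrix(delta))
  if (!identical(dim(boxcar), dim(delta))) {
    stop("`boxcar` and `delta` must have identical dimensions", call. = FALSE)
  }
  boxcar * (delta != 0)
}

#' Area-normalized motility index (Method 1)
#'
#' For every interval t the redistributed-pixel count
#' `R(t) = sum(|delta(t)|)` is divided by the mean cell area over all
#' time points of the series.  Area normalization makes indices from
#' cells of different sizes comparable, at the cost of coupling the
#' index to the projected cell area (see [motility_m2()] for the
#' size-independent alternative).
#'
#' @param series A [binary_series()].
#' @return A `motility_result` (see [motility_index()]) whose interval
#'   table carries columns `t`, `R`, `A_t`, `A_t1`, `M1`.
#' @export
motility_m1 <- function(series) {
  motility_index(series, method = "m1")
}

#' Boxcar-weighted motility index (Method 2)
#'
#' For every interval t, the difference image is boxcar-averaged
#' ([boxcar_average()]) and multiplied back onto the difference image
#' ([weighted_redistribution()]); the index is the mean of the weighted
#' image over its N nonzero pixels.  An interval with no redistribution
#' (N = 0) has index 0.  The index lies in \[0, 1\], grows with the
#' spatial clustering of changes, and does not depend on the total cell
#' area.
#'
#' Since every changed pixel contributes at least 1/w^2 to its own
#' window, the nonzero pixels of the weighted image coincide exactly
#' with the changed pixels, so N may equivalently be read as the count
#' of nonzero difference pixels.
#'
#' @param series A [binary_series()].
#' @param w Odd boxcar window width (default 9).
#' @return A `motility_result` (see [motility_index()]) whose interval
#'   table carries columns `t`, `R`, `M2`, `N`.
#' @export
motility_m2 <- function(series, w = 9) {
  motility_index(series, w = w, method = "m2")
}

#' Motility indices of a binary mask series
#'
#' Computes, per consecutive-frame interval, the redistributed-pixel
#' count R(t), the frame areas, the area-normalized index M1(t) and the
#' boxcar-weighted index M2(t), plus their means over all intervals.
#'
#' @param series A [binary_series()].
#' @param w Odd boxcar window width for M2 (default 9).
#' @param method `"both"` (default), `"m1"` or `"m2"`.
#' @return An object of class `motility_result`: list with
#'   * `intervals`: tibble, one row per interval (`t` pairs frames `t`
#'     and `t + 1`) with columns among `R`, `A_t`, `A_t1`, `M1`, `M2`,
#'     `N`;
#'   * `area_mean`: mean cell area over all frames (M1 only);
#'   * `m1_mean`, `m2_mean`: means over intervals;
#'   * `w`, `frame_interval`, `method`.
#' @export
#' @examples
#' a <- matrix(0L, 20, 20); a[6:15, 6:15] <- 1L
#' b <- matrix(0L, 20, 20); b[6:15, 7:16] <- 1L
#' res <- motility_index(binary_series(list(a, b), 300))
#' res$m1_mean  # 0.2: 20 redistributed pixels / mean area 100
motility_index <- function(series, w = 9, method = c("both", "m1", "m2")) {
  stopifnot(inherits(series, "binary_series"))
  method <- match.arg(method)
  tt <- n_frames(series)
  areas <- vapply(series$masks, cell_area, integer(1))
  area_mean <- mean(areas)
  do_m1 <- method %in% c("both", "m1")
  do_m2 <- method %in% c("both", "m2")
  if (do_m1 && area_mean == 0) {
    stop("mean cell area is zero (all frames empty); M1 is undefined",
         call. = FALSE)
  }
  if (do_m2) .check_boxcar_w(w)

  rows <- lapply(seq_len(tt - 1L), function(t) {
    delta <- difference_image(series$masks[[t]], series$masks[[t + 1L]])
    r <- sum(delta)
    row <- list(t = t, R = as.integer(r),
                A_t = areas[t], A_t1 = areas[t + 1L])
    if (do_m1) row$M1 <- r / area_mean
    if (do_m2) {
      theta <- weighted_redistribution(boxcar_average(delta, w), delta)
      n <- sum(theta > 0)
      row$M2 <- if (n > 0) sum(theta) / n else 0
      row$N <- as.integer(n)
    }
    tibble::as_tibble(row)
  })
  intervals <- dplyr::bind_rows(rows)

  structure(
    list(
      intervals = intervals,
      area_mean = area_mean,
      m1_mean = if (do_m1) mean(intervals$M1) else NA_real_,
      m2_mean = if (do_m2) mean(intervals$M2) else NA_real_,
      w = if (do_m2) as.integer(w) else NA_integer_,
      frame_interval = series$frame_interval,
      method = method
    ),
    class = "motility_result"
  )
}

#' @export
print.motility_result <- function(x, ...) {
  cat(sprintf("<motility_result> %d intervals, dt = %g s\n",
              nrow(x$intervals), x$frame_interval))
  if (!is.na(x$m1_mean)) {
    cat(sprintf("  mean M1 = %.6g  (mean area %.1f px)\n",
                x$m1_mean, x$area_mean))
  }
  if (!is.na(x$m2_mean)) {
    cat(sprintf("  mean M2 = %.6g  (boxcar w = %d)\n", x$m2_mean, x$w))
  }
  invisible(x)
}

#' Sweep the boxcar window width
#'
#' Recomputes the mean boxcar-weighted index of a series for each window
#' width in `w_values`, holding preprocessing fixed.  Absolute index
#' values shrink as the window grows; the sweep is meant for choosing
#' the width that best separates experimental groups for a given
#' structure size.
#'
#' @param series A [binary_series()].
#' @param w_values Vector of odd window widths (default `seq(3, 21, 2)`).
#' @return A tibble of class `boxcar_sweep` with columns `w` and
#'   `m2_mean`.
#' @export
boxcar_sweep <- function(series, w_values = seq(3L, 21L, 2L)) {
  for (w in w_values) .check_boxcar_w(w)
  out <- tibble::tibble(
    w = as.integer(w_values),
    m2_mean = vapply(w_values,
                     function(w) motility_index(series, w, "m2")$m2_mean,
                     numeric(1))
  )
  class(out) <- c("boxcar_sweep", class(out))
  out
}

#' Normalize index values to a control group mean
#'
#' Divides each value by the mean of the control values, the convention
#' used to express per-cell indices relative to a pre-treatment or
#' untreated baseline.
#'
#' @param values Numeric vector to normalize.
#' @param control_values Numeric vector whose mean is the denominator;
#'   must be non-empty with a strictly positive mean.
#' @return Numeric vector of normalized values.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0L || !is.numeric(control_values)) {
    stop("`control_values` must be a non-empty numeric vector", call. = FALSE)
  }
  cm <- mean(control_values)
  if (!is.finite(cm) || cm <= 0) {
    stop("control mean must be strictly positive", call. = FALSE)
  }
  values / cm
}

#' Paired before/after comparison of per-cell indices
#'
#' Two-sided paired t-test of per-cell mean motility indices measured
#' under two conditions (e.g. before and after a drug), with group
#' means and a 95% confidence interval for the mean paired difference.
#' When all paired differences are identical the t statistic is
#' degenerate: it is reported as 0 (no change) or +/-Inf, the p-value as
#' `NA`, and `zero_variance` is flagged.
#'
#' @param before,after Numeric vectors of equal length (>= 2), one entry
#'   per cell.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return One-row tibble with columns `n`, `mean_before`, `mean_after`,
#'   `mean_diff` (before - after), `conf_low`, `conf_high`, `statistic`,
#'   `p_value`, `zero_variance`.
#' @export
paired_comparison <- function(before, after, conf_level = 0.95) {
  if (length(before) != length(after)) {
    stop("`before` and `after` must have equal length", call. = FALSE)
  }
  n <- length(before)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  d <- before - after
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(tibble::tibble(
      n = n, mean_before = mean(before), mean_after = mean(after),
      mean_diff = md, conf_low = md, conf_high = md,
      statistic = if (md == 0) 0 else Inf * sign(md),
      p_value = NA_real_, zero_variance = TRUE
    ))
  }
  tt <- stats::t.test(before, after, paired = TRUE, conf.level = conf_level)
  tibble::tibble(
    n = n, mean_before = mean(before), mean_after = mean(after),
    mean_diff = unname(tt$estimate),
    conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
    statistic = unname(tt$statistic), p_value = tt$p.value,
    zero_variance = FALSE
  )
}

.check_boxcar_w <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w) ||
      (w %% 2) == 0) {
    stop("boxcar width `w` must be a single odd integer >= 1", call. = FALSE)
  }
  invisible(TRUE)
}
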