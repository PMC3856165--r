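#' One-sided power spectrum of a pixel intensity trace
#'
#' Discrete Fourier transform of the mean-subtracted trace, reported at
#' the positive frequencies k / (T * dt) for k = 1 .. floor(T/2) (DC is
#' excluded).  Power is scaled so that its total equals the time-domain
#' sum of squared deviations from the mean (Parseval): frequencies below
#' the Nyquist count twice, the Nyquist bin (even T) once.
#'
#' @param values Numeric trace of length T >= 2 (typically a binary
#'   pixel trace from a [binary_series()]).
#' @param dt Sampling interval in seconds (> 0).
#' @return Tibble with columns `frequency` (Hz) and `power`.
#' @export
pixel_power_spectrum <- function(values, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  tt <- length(values)
  if (tt < 2L) stop("a trace needs at least two samples", call. = FALSE)
  x <- values - mean(values)
  xf <- stats::fft(x)
  k <- seq_len(tt %/% 2L)
  coef <- ifelse(tt %% 2L == 0L & k == tt %/% 2L, 1, 2)
  tibble::tibble(
    frequency = k / (tt * dt),
    power = coef * Mod(xf[k + 1L])^2 / tt
  )
}

#' Dominant temporal frequency of a spectrum
#'
#' Frequency of the maximum-power bin among the nonzero frequencies;
#' ties break toward the lower frequency.  A spectrum with (numerically)
#' zero total power — a static pixel — reports 0 Hz.
#'
#' @param spectrum Tibble from [pixel_power_spectrum()].
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency", "power") %in% names(spectrum)))
  total <- sum(spectrum$power)
  if (total <= 1e-12 * length(spectrum$power)) return(0)
  spectrum$frequency[which.max(spectrum$power)]
}

#' Classify pixels by their dominant temporal frequency
#'
#' Computes, for every pixel of a binary series, the dominant frequency
#' of its mean-subtracted intensity trace and rejects pixels whose
#' dominant frequency strictly exceeds the threshold.  High-frequency
#' flicker is characteristic of imaging artifact, whereas biological
#' remodeling produces slower, step-like traces; static pixels (zero
#' spectral power) are always accepted.
#'
#' @param series A [binary_series()] with at least 4 time points,
#'   acquired at a rapid frame interval (the filter presumes temporal
#'   oversampling of the biology).
#' @param threshold Rejection cutoff in Hz (default 0.0026, i.e. periods
#'   shorter than about 6.4 min are treated as noise).  A threshold at
#'   or above the Nyquist frequency makes the filter vacuous and raises
#'   a warning.
#' @return An object of class `frequency_mask`: list with matrices
#'   `dominant_freq` (Hz; 0 for static pixels) and `accepted` (1 =
#'   kept), plus `threshold`, `nyquist` and `frame_interval`.
#' @export
classify_pixels <- function(series, threshold = 0.0026) {
  stopifnot(inherits(series, "binary_series"))
  tt <- n_frames(series)
  if (tt < 4L) stop("temporal classification needs at least 4 time points",
                    call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive frequency in Hz",
         call. = FALSE)
  }
  dt <- series$frame_interval
  nyq <- 1 / (2 * dt)
  if (threshold >= nyq) {
    warning(sprintf(paste0("threshold %.4g Hz is at or above the Nyquist ",
                           "frequency %.4g Hz; the filter rejects nothing"),
                    threshold, nyq))
  }
  if (tt < 16L) {
    warning("fewer than 16 time points: frequency resolution is coarse")
  }
  nr <- nrow(series$masks[[1]]); nc <- ncol(series$masks[[1]])
  # traces as columns of a T x (nr*nc) matrix
  tr <- vapply(series$masks, as.numeric, numeric(nr * nc))
  tr <- t(tr)
  tr <- sweep(tr, 2L, colMeans(tr))
  xf <- stats::mvfft(tr)
  k <- seq_len(tt %/% 2L)
  coef <- ifelse(tt %% 2L == 0L & k == tt %/% 2L, 1, 2)
  pw <- Mod(xf[k + 1L, , drop = FALSE])^2 * coef / tt
  freqs <- k / (tt * dt)
  peak <- apply(pw, 2L, which.max)
  dom <- freqs[peak]
  static <- colSums(pw) <= 1e-12 * length(k)
  dom[static] <- 0
  dom_m <- matrix(dom, nr, nc)
  structure(
    list(
      dominant_freq = dom_m,
      accepted = (dom_m <= threshold) * 1L,
      threshold = threshold,
      nyquist = nyq,
      frame_interval = dt
    ),
    class = "frequency_mask"
  )
}

#' @export
print.frequency_mask <- function(x, ...) {
  cat(sprintf(paste0("<frequency_mask> %d x %d px, threshold %.4g Hz ",
                     "(Nyquist %.4g Hz)\n  rejected %d / %d pixels\n"),
              nrow(x$accepted), ncol(x$accepted), x$threshold, x$nyquist,
              sum(x$accepted == 0L), length(x$accepted)))
  invisible(x)
}

#' Apply a temporal-frequency filter to a binary series
#'
#' Every rejected pixel's trace is replaced by its temporal majority
#' value, held constant across all frames (ties between 0 and 1 resolve
#' to 0).  This removes the pixel's contribution to every difference
#' image while leaving image geometry intact; accepted pixels are
#' untouched.  The operation is idempotent for a fixed mask.
#'
#' @param series A [binary_series()].
#' @param mask A `frequency_mask` from [classify_pixels()] with matching
#'   dimensions.
#' @return A filtered [binary_series()].
#' @export
apply_filter <- function(series, mask) {
  stopifnot(inherits(series, "binary_series"), inherits(mask, "frequency_mask"))
  if (!identical(dim(series$masks[[1]]), dim(mask$accepted))) {
    stop("series and frequency mask dimensions differ", call. = FALSE)
  }
  rej <- which(mask$accepted == 0L)
  if (length(rej) == 0L) return(series)
  tt <- n_frames(series)
  onsum <- Reduce(`+`, series$masks)
  majority <- (onsum[rej] > tt / 2) * 1L   # tie (exactly T/2) -> 0
  masks <- lapply(series$masks, function(m) {
    m[rej] <- majority
    m
  })
  binary_series(masks, series$frame_interval)
}
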