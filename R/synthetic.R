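#' Imaging-artifact configuration for synthetic movies
#'
#' Parameters of the non-biological artifact sources that the motility
#' method is designed to suppress: stochastic flicker of cell-perimeter
#' pixels, slow lateral specimen drift, photobleaching and detector
#' noise.
#'
#' @param edge_flicker_p Per-frame probability that a perimeter pixel of
#'   the true cell silhouette toggles (on-pixels drop out, adjacent
#'   off-pixels light up).
#' @param drift_px_per_frame Magnitude of the accumulated sub-pixel
#'   translation per frame, in pixels (direction drawn once per movie).
#' @param bleach_rate Fractional fluorescence decay per frame.
#' @param detector_sigma Standard deviation of additive Gaussian
#'   detector noise, on the \[0, 1\] intensity scale.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(edge_flicker_p = 0.05, drift_px_per_frame = 0.05,
                         bleach_rate = 0.01, detector_sigma = 0.02) {
  probs <- c(edge_flicker_p = edge_flicker_p)
  rates <- c(drift_px_per_frame = drift_px_per_frame,
             bleach_rate = bleach_rate, detector_sigma = detector_sigma)
  if (any(probs < 0 | probs > 1)) {
    stop("flicker probability must lie in [0, 1]", call. = FALSE)
  }
  if (any(rates < 0)) stop("noise rates must be non-negative", call. = FALSE)
  structure(as.list(c(probs, rates)), class = "noise_config")
}

#' Synthetic dynamic-cell movie configuration
#'
#' Describes a single simulated cell: a static soma disk bearing
#' `n_filopodia` fine radial processes whose tips perform reflected
#' random walks with direction persistence, so that the cell remodels
#' continuously without net area growth.  Rendering mimics fluorescence
#' imaging: the binary silhouette is blurred with a Gaussian point-spread
#' function, subjected to the artifacts in [noise_config()], and
#' quantized to 8 bits.
#'
#' Default geometry and time base follow a typical two-photon
#' glial-imaging session at this scale: a 96 x 96 px field at 0.155
#' um/px, 20 s frame interval, soma radius 12 px, 20 processes of 2 px
#' width.  `mean_step` is the mean tip displacement per frame in pixels;
#' 0 yields a fixed (motionless) cell.  The default direction-reversal
#' probability 0.05/frame keeps extension/retraction cycles on the
#' several-minute timescale characteristic of glial filopodia.
#'
#' @param canvas Image size, `c(rows, cols)`.
#' @param n_filopodia Number of radial processes.
#' @param filopodium_width Process width in pixels (1-3 is realistic).
#' @param mean_step Mean tip step per frame, pixels (>= 0).
#' @param p_switch Per-frame probability a tip reverses direction.
#' @param soma_radius Soma disk radius, pixels.
#' @param n_frames Number of time points T.
#' @param dt Frame interval, seconds.
#' @param pixel_size Pixel edge, micrometres (metadata).
#' @param noise A [noise_config()].
#' @param seed Integer seed; the movie is fully reproducible from it.
#' @param len_min,len_max Reflection bounds of the tip random walk,
#'   pixels from the soma surface.  `len_max = NULL` uses the largest
#'   length that keeps dilated masks inside the canvas.
#' @param psf_sigma Gaussian point-spread-function sigma, pixels.
#' @return A list of class `synthetic_cell_config`.
#' @export
synthetic_cell_config <- function(canvas = c(96, 96), n_filopodia = 20,
                                  filopodium_width = 2, mean_step = 2,
                                  p_switch = 0.05, soma_radius = 12,
                                  n_frames = 20, dt = 20, pixel_size = 0.155,
                                  noise = noise_config(), seed = 1,
                                  len_min = 3, len_max = NULL,
                                  psf_sigma = 1) {
  if (is.null(len_max)) len_max <- floor(min(canvas) / 2 - soma_radius - 10)
  cfg <- list(canvas = as.integer(canvas), n_filopodia = as.integer(n_filopodia),
              filopodium_width = filopodium_width, mean_step = mean_step,
              p_switch = p_switch, soma_radius = soma_radius,
              n_frames = as.integer(n_frames), dt = dt,
              pixel_size = pixel_size, noise = noise, seed = as.integer(seed),
              len_min = len_min, len_max = len_max, psf_sigma = psf_sigma)
  errs <- character(0)
  if (length(cfg$canvas) != 2L || any(cfg$canvas < 16L)) {
    errs <- c(errs, "`canvas` must be two dimensions of at least 16 px")
  }
  if (cfg$n_filopodia < 1L) errs <- c(errs, "`n_filopodia` must be positive")
  if (cfg$filopodium_width <= 0) {
    errs <- c(errs, "`filopodium_width` must be positive")
  }
  if (cfg$mean_step < 0) errs <- c(errs, "`mean_step` must be >= 0")
  if (cfg$p_switch < 0 || cfg$p_switch > 1) {
    errs <- c(errs, "`p_switch` must lie in [0, 1]")
  }
  if (cfg$soma_radius <= 0) errs <- c(errs, "`soma_radius` must be positive")
  if (cfg$n_frames < 2L) errs <- c(errs, "`n_frames` must be at least 2")
  if (cfg$dt <= 0) errs <- c(errs, "`dt` must be positive")
  if (!inherits(noise, "noise_config")) {
    errs <- c(errs, "`noise` must come from noise_config()")
  }
  if (cfg$len_max <= cfg$len_min) {
    errs <- c(errs, "canvas too small for this soma radius (len_max <= len_min)")
  }
  if (cfg$n_filopodia * (cfg$filopodium_width + 1) >
      2 * pi * cfg$soma_radius) {
    errs <- c(errs, sprintf(
      "%d filopodia of width %g do not fit on a soma perimeter of %.0f px",
      cfg$n_filopodia, cfg$filopodium_width, 2 * pi * cfg$soma_radius))
  }
  if (length(errs) > 0L) {
    stop(paste(c("invalid synthetic configuration:", errs), collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_cell_config")
}

#' Preset synthetic movie configurations
#'
#' `"motile"` is the default dynamic cell; `"fixed"` freezes all tip
#' kinetics (`mean_step = 0`) while keeping the imaging artifacts,
#' emulating a chemically fixed specimen that measures the noise floor.
#'
#' @param preset `"motile"` or `"fixed"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_cell_config()].
#' @return A `synthetic_cell_config`.
#' @export
synthetic_preset <- function(preset = c("motile", "fixed"), seed = 1, ...) {
  preset <- match.arg(preset)
  args <- list(seed = seed, ...)
  if (preset == "fixed") args$mean_step <- 0
  do.call(synthetic_cell_config, args)
}

#' Generate a synthetic dynamic-cell movie with ground truth
#'
#' Renders the configured cell over `n_frames` time points.  Tip lengths
#' follow a reflected random walk: each frame the tip reverses direction
#' with probability `p_switch`, then moves by `|N(mean_step,
#' (mean_step/2)^2)|` pixels, reflecting at `len_min`/`len_max` so the
#' cell area is stationary.  The true (pre-artifact) silhouette is
#' recorded per frame, then perimeter flicker, Gaussian blur,
#' photobleaching, accumulated sub-pixel drift and detector noise are
#' applied and the frame is quantized to 8 bits.
#'
#' @param config A [synthetic_cell_config()].
#' @return List with elements
#'   * `series`: the rendered [frame_series()];
#'   * `truth`: list with `masks` (true binary silhouettes), `changed`
#'     (per-interval symmetric differences of consecutive true masks),
#'     `lengths` (T x n_filopodia matrix), `tip_speeds` (per-filopodium
#'     mean absolute step) and `tip_speed_mean`;
#'   * `config`: the configuration echo.
#' @export
#' @examples
#' mv <- generate_movie(synthetic_cell_config(n_frames = 3, seed = 7))
#' mv$truth$tip_speed_mean
generate_movie <- function(config) {
  stopifnot(inherits(config, "synthetic_cell_config"))
  withr::with_seed(config$seed, .render_movie(config))
}

#' Generate a matched movie pair with scaled motility
#'
#' Produces two movies from the same seed: the reference movie `a`, and
#' movie `b` whose tip steps are scaled by `motility_ratio` (identical
#' process layout, directions and reversal times; `motility_ratio = 0`
#' gives a fixed cell with artifact only).  The pair emulates a
#' before/after treatment design in which a drug slows filopodial
#' kinetics.
#'
#' @param config A [synthetic_cell_config()] for the reference movie.
#' @param motility_ratio Step-scale factor in \[0, 1\] for movie `b`.
#' @param seed Optional seed overriding `config$seed` for both movies.
#' @return List with movies `a` and `b` (each as from
#'   [generate_movie()]) and `motility_ratio`.
#' @export
generate_pair <- function(config, motility_ratio, seed = NULL) {
  stopifnot(inherits(config, "synthetic_cell_config"))
  if (!is.numeric(motility_ratio) || length(motility_ratio) != 1L ||
      motility_ratio < 0 || motility_ratio > 1) {
    stop("`motility_ratio` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cfg_b <- config
  cfg_b$mean_step <- config$mean_step * motility_ratio
  list(a = generate_movie(config), b = generate_movie(cfg_b),
       motility_ratio = motility_ratio)
}

# ---- rendering internals -------------------------------------------------

.render_movie <- function(cfg) {
  nr <- cfg$canvas[1]; nc <- cfg$canvas[2]
  tt <- cfg$n_frames; nf <- cfg$n_filopodia
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  bg <- 0.05; fg <- 0.85

  # kinetic randomness is drawn up front so that scaling mean_step scales
  # the realized steps exactly (matched-pair construction)
  angles <- 2 * pi * (seq_len(nf) - 1) / nf +
    stats::runif(nf, -pi / (2 * nf), pi / (2 * nf))
  span <- cfg$len_max - cfg$len_min
  len <- stats::runif(nf, cfg$len_min + 0.15 * span, cfg$len_max - 0.15 * span)
  dir <- sample(c(-1, 1), nf, replace = TRUE)
  switch_u <- matrix(stats::runif(nf * (tt - 1)), tt - 1, nf)
  step_z <- matrix(stats::rnorm(nf * (tt - 1)), tt - 1, nf)
  drift_angle <- stats::runif(1, 0, 2 * pi)

  lengths <- matrix(NA_real_, tt, nf)
  lengths[1, ] <- len
  for (t in seq_len(tt - 1)) {
    dir <- ifelse(switch_u[t, ] < cfg$p_switch, -dir, dir)
    step <- abs(cfg$mean_step + (cfg$mean_step / 2) * step_z[t, ])
    len <- len + dir * step
    over <- len > cfg$len_max
    len[over] <- 2 * cfg$len_max - len[over]; dir[over] <- -1
    under <- len < cfg$len_min
    len[under] <- 2 * cfg$len_min - len[under]; dir[under] <- 1
    len <- pmin(pmax(len, cfg$len_min), cfg$len_max)
    lengths[t + 1, ] <- len
  }

  true_masks <- vector("list", tt)
  frames <- vector("list", tt)
  for (t in seq_len(tt)) {
    m <- .disk_mask(nr, nc, cy, cx, cfg$soma_radius)
    for (i in seq_len(nf)) {
      m <- .draw_segment(
        m,
        cy + (cfg$soma_radius - 1) * sin(angles[i]),
        cx + (cfg$soma_radius - 1) * cos(angles[i]),
        cy + (cfg$soma_radius + lengths[t, i]) * sin(angles[i]),
        cx + (cfg$soma_radius + lengths[t, i]) * cos(angles[i]),
        cfg$filopodium_width / 2
      )
    }
    true_masks[[t]] <- m * 1L

    noisy <- m
    p <- cfg$noise$edge_flicker_p
    if (p > 0) {
      perim <- which(m & !.erode1(m))
      halo <- which(.dilate1(m) & !m)
      if (length(perim)) noisy[perim[stats::runif(length(perim)) < p]] <- FALSE
      if (length(halo)) noisy[halo[stats::runif(length(halo)) < p]] <- TRUE
    }
    im <- bg + (fg - bg) * (1 - cfg$noise$bleach_rate)^(t - 1) *
      .gauss_blur(noisy * 1, cfg$psf_sigma)
    d <- cfg$noise$drift_px_per_frame * (t - 1)
    if (d > 0) {
      im <- .bilinear_shift(im, d * sin(drift_angle), d * cos(drift_angle),
                            fill = bg)
    }
    if (cfg$noise$detector_sigma > 0) {
      im <- im + stats::rnorm(nr * nc, 0, cfg$noise$detector_sigma)
    }
    frames[[t]] <- round(pmin(pmax(im, 0), 1) * 255) / 255
  }

  changed <- lapply(seq_len(tt - 1), function(t) {
    difference_image(true_masks[[t]], true_masks[[t + 1]])
  })
  tip_speeds <- apply(lengths, 2L, function(l) mean(abs(diff(l))))
  list(
    series = frame_series(frames, cfg$dt, cfg$pixel_size),
    truth = list(masks = true_masks, changed = changed, lengths = lengths,
                 tip_speeds = tip_speeds,
                 tip_speed_mean = mean(tip_speeds)),
    config = cfg
  )
}

.disk_mask <- function(nr, nc, cy, cx, r) {
  dy <- (seq_len(nr) - cy)^2
  dx <- (seq_len(nc) - cx)^2
  outer(dy, dx, `+`) <= r^2
}

# Paint all pixels within `halfw` of the segment (y0,x0)-(y1,x1).
.draw_segment <- function(mask, y0, x0, y1, x1, halfw) {
  nr <- nrow(mask); nc <- ncol(mask)
  r1 <- max(1L, floor(min(y0, y1) - halfw - 1)); r2 <- min(nr, ceiling(max(y0, y1) + halfw + 1))
  c1 <- max(1L, floor(min(x0, x1) - halfw - 1)); c2 <- min(nc, ceiling(max(x0, x1) + halfw + 1))
  if (r1 > r2 || c1 > c2) return(mask)
  ys <- r1:r2; xs <- c1:c2
  vy <- y1 - y0; vx <- x1 - x0
  len2 <- vy^2 + vx^2
  py <- matrix(ys - y0, length(ys), length(xs))
  px <- matrix(rep(xs - x0, each = length(ys)), length(ys), length(xs))
  s <- if (len2 > 0) pmin(pmax((py * vy + px * vx) / len2, 0), 1) else 0
  d2 <- (py - s * vy)^2 + (px - s * vx)^2
  mask[ys, xs] <- mask[ys, xs] | (d2 <= halfw^2)
  mask
}

.erode1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  i <- seq_len(nr) + 1L; j <- seq_len(nc) + 1L
  pad[i, j] & pad[i - 1L, j] & pad[i + 1L, j] & pad[i, j - 1L] & pad[i, j + 1L]
}

.dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  i <- seq_len(nr) + 1L; j <- seq_len(nc) + 1L
  pad[i, j] | pad[i - 1L, j] | pad[i + 1L, j] | pad[i, j - 1L] | pad[i, j + 1L]
}

.gauss_blur <- function(im, sigma) {
  if (sigma <= 0) return(im)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(im); nc <- ncol(im)
  pass <- function(m) {   # along rows, zero padding
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) {
      rs <- max(1, 1 + o):min(nrow(m), nrow(m) + o)
      out[rs, ] <- out[rs, ] + k[o + r + 1] * m[rs - o, ]
    }
    out
  }
  t(pass(t(pass(im))))
}

.bilinear_shift <- function(im, dy, dx, fill = 0) {
  i0 <- floor(dy); fy <- dy - i0
  j0 <- floor(dx); fx <- dx - j0
  s <- function(a, b) shift_frame(im, i0 + a, j0 + b, fill = fill)
  (1 - fy) * (1 - fx) * s(0, 0) + fy * (1 - fx) * s(1, 0) +
    (1 - fy) * fx * s(0, 1) + fy * fx * s(1, 1)
}
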