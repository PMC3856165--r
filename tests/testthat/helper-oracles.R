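# Brute-force reference implementations used as independent oracles.
# They share no code with the package internals: plain double loops and
# direct formula evaluation only.

naive_boxcar <- function(delta, w) {
  h <- (w - 1) / 2
  nr <- nrow(delta); nc <- ncol(delta)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (m in (i - h):(i + h)) {
        for (n in (j - h):(j + h)) {
          if (m >= 1 && m <= nr && n >= 1 && n <= nc) acc <- acc + delta[m, n]
        }
      }
      out[i, j] <- acc / w^2
    }
  }
  out
}

naive_m1 <- function(masks) {
  tt <- length(masks)
  areas <- vapply(masks, sum, numeric(1))
  abar <- mean(areas)
  vapply(seq_len(tt - 1), function(t) {
    sum(abs(masks[[t + 1]] - masks[[t]])) / abar
  }, numeric(1))
}

naive_m2 <- function(masks, w) {
  tt <- length(masks)
  vapply(seq_len(tt - 1), function(t) {
    delta <- abs(masks[[t + 1]] - masks[[t]])
    theta <- naive_boxcar(delta, w) * delta
    n <- sum(theta > 0)
    if (n == 0) 0 else sum(theta) / n
  }, numeric(1))
}

naive_sobel <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  at <- function(i, j) frame[min(max(i, 1), nr), min(max(j, 1), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      gx <- at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1) -
        at(i - 1, j - 1) - 2 * at(i, j - 1) - at(i + 1, j - 1)
      gy <- at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1) -
        at(i - 1, j - 1) - 2 * at(i - 1, j) - at(i - 1, j + 1)
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

naive_dft_power <- function(x, dt) {
  tt <- length(x)
  x <- x - mean(x)
  ks <- seq_len(tt %/% 2)
  power <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(tt - 1)) / tt))
    im <- sum(x * sin(-2 * pi * k * (0:(tt - 1)) / tt))
    c <- if (tt %% 2 == 0 && k == tt %/% 2) 1 else 2
    c * (re^2 + im^2) / tt
  }, numeric(1))
  list(frequency = ks / (tt * dt), power = power)
}

rand_binary_series <- function(nr, nc, tt, p = 0.3, dt = 300) {
  binary_series(
    lapply(seq_len(tt), function(i) {
      matrix(as.integer(runif(nr * nc) < p), nr, nc)
    }),
    frame_interval = dt
  )
}

# canvas with a square blob at the given top-left corner
square_mask <- function(nr, nc, r0, c0, side) {
  m <- matrix(0L, nr, nc)
  m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- 1L
  m
}
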