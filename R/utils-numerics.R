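## Shared numerical primitives: zero-phase Butterworth filtering in the
## frequency domain, analytic signal, colored noise synthesis, Gaussian
## smoothing, and circular statistics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase Butterworth filtering
#'
#' Applies an order-`order` Butterworth filter forwards and backwards
#' (zero phase), realized in the frequency domain through the exact
#' magnitude-squared Butterworth response. The input is reflection-padded
#' to suppress circular edge transients. This is numerically stable for
#' narrow passbands where the transfer-function (b, a) form of a high-order
#' band-pass filter is not.
#'
#' @param x numeric vector, finite.
#' @param rate_hz sampling rate in Hz.
#' @param type one of `"low"`, `"high"`, `"pass"`.
#' @param cutoff_hz scalar cutoff for low/high; length-2 `c(lo, hi)` band
#'   edges in Hz for `"pass"`.
#' @param order filter order (the forward pass; the two-pass magnitude is
#'   the square of the single-pass response, as with `filtfilt`).
#' @return filtered numeric vector, same length as `x`.
#' @export
zero_phase_butter <- function(x, rate_hz, type = c("pass", "low", "high"),
                              cutoff_hz, order = 8) {
  type <- match.arg(type)
  if (!all(is.finite(x))) stop("zero_phase_butter: input contains non-finite samples")
  n <- length(x)
  if (n < 4) return(x * 0)
  npad <- min(n - 1L, as.integer(rate_hz))
  xp <- c(rev(x[2:(npad + 1L)]), x, rev(x[(n - npad):(n - 1L)]))
  m <- length(xp)
  f <- seq(0, rate_hz, length.out = m + 1L)[seq_len(m)]
  f <- ifelse(f > rate_hz / 2, rate_hz - f, f)  # two-sided grid folded
  h2 <- switch(type,
    low = {
      fc <- cutoff_hz[1]
      1 / (1 + (f / fc)^(2 * order))
    },
    high = {
      fc <- cutoff_hz[1]
      r <- ifelse(f == 0, Inf, fc / f)
      1 / (1 + r^(2 * order))
    },
    pass = {
      if (length(cutoff_hz) != 2 || cutoff_hz[1] >= cutoff_hz[2])
        stop("zero_phase_butter: band must be c(lo, hi) with lo < hi")
      if (cutoff_hz[2] >= rate_hz / 2)
        stop("zero_phase_butter: band outside Nyquist")
      f0sq <- cutoff_hz[1] * cutoff_hz[2]
      bw <- cutoff_hz[2] - cutoff_hz[1]
      w <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
      1 / (1 + w^(2 * order))
    })
  ## Two passes (forward + backward) square the magnitude response.
  y <- Re(stats::fft(stats::fft(xp) * h2^2, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' @param x real numeric vector.
#' @return complex vector `x + i * H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' 1/f^chi Gaussian noise by spectral shaping
#'
#' Draws white Gaussian noise and shapes its amplitude spectrum to
#' `1/f^(chi/2)` (power `1/f^chi`), using the current RNG state.
#'
#' @param n number of samples.
#' @param rate_hz sampling rate.
#' @param exponent spectral exponent chi of the power spectrum.
#' @param floor_hz frequencies below this keep the gain at `floor_hz`
#'   (avoids a divergent DC).
#' @return numeric vector with unit standard deviation.
#' @export
powerlaw_noise <- function(n, rate_hz, exponent = 1.5, floor_hz = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, rate_hz, length.out = n + 1L)[seq_len(n)]
  f <- ifelse(f > rate_hz / 2, rate_hz - f, f)
  g <- pmax(f, floor_hz)^(-exponent / 2)
  g[1] <- 0
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Gaussian kernel smoothing
#'
#' FIR Gaussian smoothing with edge renormalization (the kernel mass that
#' falls outside the signal is excluded rather than zero-padded).
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param length_ms kernel support in milliseconds.
#' @param width_ms kernel width in milliseconds, in the figure-legend sense
#'   of a full width; the Gaussian sd is `width_ms / 2`.
#' @export
gauss_smooth <- function(x, rate_hz, length_ms, width_ms) {
  half <- max(1L, round(length_ms / 2 * rate_hz / 1000))
  t <- (-half):half
  k <- exp(-0.5 * (t / (width_ms * rate_hz / 1000 / 2))^2)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, length(x)), rep(0, half)), k, sides = 2)
  as.numeric((num / den)[(half + 1L):(half + length(x))])
}

#' Rayleigh test of circular uniformity
#'
#' @param phases numeric vector of phases in radians.
#' @return list with `n`, `r` (mean resultant length), `z` (Rayleigh
#'   statistic `n r^2`) and the standard large-sample `p` approximation.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0) return(list(n = 0L, r = NA_real_, z = NA_real_, p = NA_real_))
  C <- sum(cos(phases)); S <- sum(sin(phases))
  r <- sqrt(C^2 + S^2) / n
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(n = as.integer(n), r = r, z = z, p = p)
}

#' Circular mean of phases
#' @param phases phases in radians.
#' @export
circular_mean <- function(phases) {
  Arg(sum(exp(1i * phases)))
}

#' Derive a child integer seed from a base seed and a stream tag
#'
#' Deterministic and kept well below the 32-bit integer maximum; used to
#' give every stochastic component of a session its own reproducible
#' stream.
#' @param seed base integer seed; @param tag character stream label.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147480000)
}

## Internal: with_seed - evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}
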