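## Shuffle-corrected joint peri-stimulus cross-correlograms (eq-jpsth) for
## two continuous trial-aligned signals, and the diagonal cross-correlogram
## with its most-negative lag.

#' Shuffle-corrected eq-jpsth of two trial-aligned signals
#'
#' `raw(t1, t2)` is the trial-mean cross product of signal A at `t1` and
#' signal B at `t2`. The trial pairing of B is permuted `n_shuffles` times;
#' the corrected matrix is `(raw - mean(shuffled)) / sqrt(varA(t1) *
#' varB(t2))` with the time-resolved across-trial variances, which bounds
#' it in [-1, 1] (a correlation coefficient). A cell is significant when
#' the raw value lies outside all shuffled values (two-sided, equivalent
#' p of about 0.02 at 100 shuffles).
#'
#' @param A,B trials x bins matrices (same shape, same trial order).
#' @param n_shuffles number of trial-pairing shuffles.
#' @param seed RNG seed.
#' @param bin_centers_ms optional bin times carried through.
#' @return list of class `jpsth`: `corrected`, `sig` (-1/0/+1), `raw`,
#'   `n_trials`, `bin_centers_ms`, `bin_ms`.
#' @export
eq_jpsth <- function(A, B, n_shuffles = 100, seed = 1, bin_centers_ms = NULL) {
  stopifnot(all(dim(A) == dim(B)))
  n <- nrow(A)
  if (n < 20) stop("eq_jpsth: need >= 20 trials for a usable shuffle null")
  raw <- crossprod(A, B) / n
  lo <- matrix(Inf, ncol(A), ncol(B))
  hi <- matrix(-Inf, ncol(A), ncol(B))
  acc <- matrix(0, ncol(A), ncol(B))
  with_seed(derive_seed(seed, "jpsth"), {
    for (s in seq_len(n_shuffles)) {
      Bp <- B[sample.int(n), , drop = FALSE]
      sh <- crossprod(A, Bp) / n
      acc <- acc + sh
      lo <- pmin(lo, sh); hi <- pmax(hi, sh)
    }
  })
  mean_sh <- acc / n_shuffles
  va <- apply(A, 2, stats::var) * (n - 1) / n
  vb <- apply(B, 2, stats::var) * (n - 1) / n
  denom <- sqrt(outer(va, vb))
  denom[denom == 0] <- Inf
  corrected <- (raw - mean_sh) / denom
  sig <- matrix(0L, ncol(A), ncol(B))
  sig[raw > hi] <- 1L   # strictly outside all shuffle values
  sig[raw < lo] <- -1L
  bc <- bin_centers_ms %||% seq_len(ncol(A))
  structure(list(corrected = corrected, sig = sig, raw = raw, n_trials = n,
                 bin_centers_ms = bc, bin_ms = if (length(bc) > 1) diff(bc[1:2]) else NA),
            class = "jpsth")
}

#' Diagonal cross-correlogram of an eq-jpsth
#'
#' Averages the corrected matrix along the main diagonal and
#' `n_para` paradiagonals for each lag, separately for the epochs before
#' and after a split time (e.g. the attended-cue onset). The matrix
#' convention is `corrected[t_A, t_B]`, so a positive lag means signal B
#' (e.g. beta) later than signal A (e.g. hand velocity) — B lagging A.
#'
#' @param jp a `jpsth`.
#' @param split_ms epoch boundary (bin-center time); bins strictly before
#'   it form the `pre` epoch, the rest the `post` epoch. NULL = one epoch.
#' @param max_lag_ms largest |lag| reported.
#' @param n_para paradiagonals averaged on each side of each lag.
#' @return list: per epoch a data frame `lag_ms`, `value`, plus
#'   `most_negative_lag_ms` per epoch.
#' @export
cross_correlogram <- function(jp, split_ms = NULL, max_lag_ms = 500,
                              n_para = 1) {
  bc <- jp$bin_centers_ms
  bin_ms <- jp$bin_ms
  max_lag <- floor(max_lag_ms / bin_ms)
  epochs <- if (is.null(split_ms)) list(all = seq_along(bc))
            else list(pre = which(bc < split_ms), post = which(bc >= split_ms))
  out <- list()
  for (en in names(epochs)) {
    idx <- epochs[[en]]
    if (length(idx) < max_lag + n_para + 2) {
      max_lag_e <- max(1, length(idx) - n_para - 2)
      warning("cross_correlogram: epoch '", en, "' shorter than max lag; truncated")
    } else max_lag_e <- max_lag
    lags <- (-max_lag_e):max_lag_e
    val <- rep(NA_real_, length(lags))
    M <- jp$corrected
    for (li in seq_along(lags)) {
      l <- lags[li]
      acc <- c()
      for (dpar in (-n_para):n_para) {
        i <- idx
        j <- i + l + dpar
        ok <- j >= min(idx) & j <= max(idx)
        if (any(ok)) acc <- c(acc, M[cbind(i[ok], j[ok])])
      }
      val[li] <- mean(acc)
    }
    df <- data.frame(lag_ms = lags * bin_ms, value = val)
    out[[en]] <- df
    out[[paste0("most_negative_lag_ms_", en)]] <- df$lag_ms[which.min(df$value)]
  }
  out
}
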