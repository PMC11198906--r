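## Spectral analysis: Welch-style sliding-window spectrograms, the pre-SC1
## per-trial power estimate, the two-minima straight-line aperiodic (1/f)
## estimator in log-log space, per-trial beta peak frequency, and the beta
## band dominance index.

LOW_BAND <- c(13, 19)
HIGH_BAND <- c(23, 29)

## Hann-tapered, zero-padded power estimate of windowed segments.
## x: matrix windows x samples; nfft: pad length; returns windows x freqs
## power on the grid 0..(rate/2) at rate/nfft resolution.
welch_power <- function(x, rate_hz, nfft) {
  nw <- ncol(x)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  xt <- sweep(x, 2, taper, `*`)
  pad <- matrix(0, nrow(x), nfft - nw)
  X <- stats::mvfft(t(cbind(xt, pad)))
  nf <- nfft %/% 2 + 1
  P <- (Mod(X[seq_len(nf), , drop = FALSE])^2) /
    (sum(taper^2) * rate_hz)
  P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
  t(P)
}

#' Sliding-window spectrogram of trial-cut LFP
#'
#' Welch-type estimate per 300-ms Hann-tapered window (one segment per
#' window), zero-padded to a 1-Hz frequency grid, with 50-ms window shifts.
#' The signal is high-pass filtered at 3 Hz beforehand.
#'
#' @param trial_matrix trials x time matrix at `rate_hz` (e.g. from
#'   [align_and_cut()]); may also carry a `time_ms` attribute.
#' @param rate_hz sampling rate.
#' @param win_ms,step_ms,res_hz window length, shift, frequency resolution.
#' @param max_freq_hz truncate the stored grid (default 100 Hz).
#' @param highpass_hz pre-filter cutoff (4th order, zero phase); 0 disables.
#' @param time_ms optional column times of `trial_matrix` (ms).
#' @return list of class `spectrogram`: `freqs_hz`, `win_centers_ms`,
#'   `power` (trials x windows x freqs), `norm_divisor` (NULL until
#'   [normalize_spectrogram()]).
#' @export
compute_spectrogram <- function(trial_matrix, rate_hz, win_ms = 300,
                                step_ms = 50, res_hz = 1, max_freq_hz = 100,
                                highpass_hz = 3, time_ms = NULL) {
  stopifnot(ncol(trial_matrix) >= win_ms * rate_hz / 1000)
  if (rate_hz < 2 * max_freq_hz) stop("sampling rate below 2x max frequency of interest")
  nw <- round(win_ms * rate_hz / 1000)
  step <- round(step_ms * rate_hz / 1000)
  nfft <- round(rate_hz / res_hz)
  starts <- seq(1, ncol(trial_matrix) - nw + 1, by = step)
  t0 <- if (!is.null(time_ms)) time_ms[1] else 0
  centers <- t0 + (starts - 1 + nw / 2) * 1000 / rate_hz
  nf_keep <- sum(seq(0, rate_hz / 2, by = res_hz) <= max_freq_hz)
  power <- array(NA_real_, c(nrow(trial_matrix), length(starts), nf_keep))
  for (i in seq_len(nrow(trial_matrix))) {
    x <- trial_matrix[i, ]
    if (highpass_hz > 0) x <- zero_phase_butter(x, rate_hz, "high", highpass_hz, order = 4)
    seg <- t(vapply(starts, function(s) x[s:(s + nw - 1)], numeric(nw)))
    P <- welch_power(seg, rate_hz, nfft)
    power[i, , ] <- P[, seq_len(nf_keep)]
  }
  structure(list(freqs_hz = seq(0, by = res_hz, length.out = nf_keep),
                 win_centers_ms = centers, power = power, norm_divisor = NULL),
            class = "spectrogram")
}

#' Normalize a spectrogram by its 10-40 Hz grand mean
#'
#' Divides by the mean power between 10 and 40 Hz across all trials and
#' windows, making spectrograms invariant to per-site gain.
#' @param spec a `spectrogram`.
#' @export
normalize_spectrogram <- function(spec) {
  sel <- spec$freqs_hz >= 10 & spec$freqs_hz <= 40
  div <- mean(spec$power[, , sel])
  if (!is.finite(div) || div <= 0) stop("normalize_spectrogram: zero divisor")
  spec$power <- spec$power / div
  spec$norm_divisor <- div
  spec
}

#' Per-trial pre-SC1 power spectrum
#'
#' Averages five 500-ms Hann windows with 400-ms overlap over a 900-ms
#' epoch, then normalizes by the site's mean 10-40 Hz power across trials.
#'
#' @param trial_matrix trials x time matrix holding (at least) 900 ms of
#'   pre-SC1 signal at `rate_hz`; the trailing 900 ms are used.
#' @param rate_hz sampling rate.
#' @param highpass_hz pre-filter cutoff (default 3 Hz, zero phase).
#' @return list: `freqs_hz` (1-Hz grid to 100 Hz), `power`
#'   (trials x freqs, normalized), `n_windows` (5), `norm_divisor`.
#' @export
pre_sc1_power <- function(trial_matrix, rate_hz, highpass_hz = 3) {
  need <- round(900 * rate_hz / 1000)
  short <- which(apply(trial_matrix, 1, function(r) sum(!is.na(r))) < need)
  if (ncol(trial_matrix) < need)
    stop("pre_sc1_power: epoch shorter than 900 ms for trials: ",
         paste(short, collapse = ", "))
  x <- trial_matrix[, (ncol(trial_matrix) - need + 1):ncol(trial_matrix), drop = FALSE]
  nw <- round(500 * rate_hz / 1000)
  step <- round(100 * rate_hz / 1000)  # 400 ms overlap
  starts <- seq(1, need - nw + 1, by = step)
  stopifnot(length(starts) == 5)
  nfft <- round(rate_hz)  # 1 Hz grid
  nf_keep <- sum(seq(0, rate_hz / 2) <= 100)
  power <- matrix(NA_real_, nrow(x), nf_keep)
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    if (highpass_hz > 0) xi <- zero_phase_butter(xi, rate_hz, "high", highpass_hz, order = 4)
    seg <- t(vapply(starts, function(s) xi[s:(s + nw - 1)], numeric(nw)))
    P <- welch_power(seg, rate_hz, nfft)
    power[i, ] <- colMeans(P[, seq_len(nf_keep), drop = FALSE])
  }
  freqs <- seq(0, by = 1, length.out = nf_keep)
  sel <- freqs >= 10 & freqs <= 40
  div <- mean(power[, sel])
  if (!is.finite(div) || div <= 0) stop("pre_sc1_power: zero normalization divisor")
  list(freqs_hz = freqs, power = power / div, n_windows = length(starts),
       norm_divisor = div)
}

## last strict local minimum of y at frequencies < f_limit; NA when none
last_local_min_before <- function(freqs, y, f_limit) {
  idx <- which(freqs > min(freqs) & freqs < max(freqs) & freqs < f_limit)
  idx <- idx[idx > 1 & idx < length(y)]
  lm <- idx[y[idx] < y[idx - 1] & y[idx] < y[idx + 1]]
  if (!length(lm)) NA_integer_ else max(lm)
}

#' Two-minima aperiodic (1/f) fit
#'
#' Fits the aperiodic component as a straight line in log10(power) vs
#' log10(frequency), drawn through the last local minimum of the
#' site-average log spectrum before 10 Hz and the last local minimum before
#' 50 Hz. When either minimum is absent, the first anchor is set at 10 Hz
#' and the second at the minimum value between 35 and 50 Hz.
#'
#' @param mean_log_power site-average log10 power on a 1-Hz grid.
#' @param freqs_hz the frequency grid (must cover 5-50 Hz).
#' @return list of class `aperiodic_fit`: `f_lo_anchor`, `f_hi_anchor`,
#'   `slope`, `intercept` (log10-log10 line), `fallback` flag.
#' @export
fit_aperiodic <- function(mean_log_power, freqs_hz) {
  stopifnot(length(mean_log_power) == length(freqs_hz))
  if (min(freqs_hz) > 5 || max(freqs_hz) < 50)
    stop("fit_aperiodic: spectrum must cover 5-50 Hz")
  use <- freqs_hz >= 5 & freqs_hz <= 50 & freqs_hz > 0
  f <- freqs_hz[use]; y <- mean_log_power[use]
  i_lo <- last_local_min_before(f, y, 10)
  i_hi <- last_local_min_before(f, y, 50)
  fallback <- is.na(i_lo) || is.na(i_hi) ||
    (!is.na(i_lo) && !is.na(i_hi) && f[i_hi] <= f[i_lo])
  if (!fallback) {
    f1 <- f[i_lo]; y1 <- y[i_lo]; f2 <- f[i_hi]; y2 <- y[i_hi]
  } else {
    f1 <- 10; y1 <- y[which.min(abs(f - 10))]
    hi_rng <- which(f >= 35 & f <= 50)
    i2 <- hi_rng[which.min(y[hi_rng])]
    f2 <- f[i2]; y2 <- y[i2]
  }
  slope <- (y2 - y1) / (log10(f2) - log10(f1))
  intercept <- y1 - slope * log10(f1)
  structure(list(f_lo_anchor = f1, f_hi_anchor = f2, slope = slope,
                 intercept = intercept, fallback = fallback),
            class = "aperiodic_fit")
}

#' Evaluate an aperiodic fit on a frequency grid
#' @param fit an `aperiodic_fit`; @param freqs_hz frequencies (> 0).
#' @return log10 power of the fitted line.
#' @export
aperiodic_line <- function(fit, freqs_hz) {
  fit$intercept + fit$slope * log10(freqs_hz)
}

#' Periodic-only component of per-trial spectra
#'
#' Subtracts the fitted aperiodic line from each single trial's log10
#' spectrum.
#'
#' @param trial_log_power trials x freqs matrix of log10 power.
#' @param fit an `aperiodic_fit` from the same site.
#' @param freqs_hz the shared frequency grid.
#' @return trials x freqs matrix of log-power residuals.
#' @export
periodic_component <- function(trial_log_power, fit, freqs_hz) {
  if (ncol(trial_log_power) != length(freqs_hz))
    stop("periodic_component: frequency grid mismatch")
  line <- aperiodic_line(fit, pmax(freqs_hz, .Machine$double.eps))
  sweep(trial_log_power, 2, line, `-`)
}

#' Per-trial beta peak frequency
#'
#' Frequency with maximal periodic power between 10 and 40 Hz; ties are
#' broken toward the lower frequency.
#'
#' @param periodic trials x freqs periodic matrix.
#' @param freqs_hz grid; @param range search range (Hz).
#' @return data frame with `peak_hz` and a `degenerate` flag per trial
#'   (all-equal spectrum: the range start is returned).
#' @export
peak_frequency <- function(periodic, freqs_hz, range = c(10, 40)) {
  sel <- which(freqs_hz >= range[1] & freqs_hz <= range[2])
  if (!length(sel)) stop("peak_frequency: range outside grid")
  peaks <- numeric(nrow(periodic)); degen <- logical(nrow(periodic))
  for (i in seq_len(nrow(periodic))) {
    y <- periodic[i, sel]
    degen[i] <- diff(range(y)) == 0
    peaks[i] <- freqs_hz[sel[which.max(y)]]  # which.max takes first = lowest
  }
  data.frame(peak_hz = peaks, degenerate = degen)
}

#' Beta band dominance index
#'
#' `(low - high) / (low + high)` on trial-averaged periodic power over
#' 13-19 Hz vs 23-29 Hz; significance by a paired t test on the per-trial
#' band means. Positive indices mean low-band dominance.
#'
#' @param periodic trials x freqs periodic matrix (log-power residuals).
#' @param freqs_hz grid.
#' @param low_band,high_band band edges, inclusive.
#' @param strong_threshold |index| needed for a "strong" label.
#' @return list of class `band_dominance`: `index`, `p_value`, `label`
#'   (low/high), `strong` (|index| > threshold), `degenerate` (both band
#'   means negative: index undefined), per-trial means `low_trials`,
#'   `high_trials`.
#' @export
band_dominance <- function(periodic, freqs_hz, low_band = LOW_BAND,
                           high_band = HIGH_BAND, strong_threshold = 0.25) {
  if (nrow(periodic) < 2) stop("band_dominance: need >= 2 trials")
  sel_l <- freqs_hz >= low_band[1] & freqs_hz <= low_band[2]
  sel_h <- freqs_hz >= high_band[1] & freqs_hz <= high_band[2]
  lt <- rowMeans(periodic[, sel_l, drop = FALSE])
  ht <- rowMeans(periodic[, sel_h, drop = FALSE])
  L <- mean(lt); H <- mean(ht)
  degenerate <- (L < 0 && H < 0)
  index <- if (L + H == 0) 0 else (L - H) / (L + H)
  p <- tryCatch(stats::t.test(lt, ht, paired = TRUE)$p.value,
                error = function(e) NA_real_)
  structure(list(index = index, p_value = p,
                 label = if (index >= 0) "low" else "high",
                 strong = is.finite(index) && abs(index) > strong_threshold,
                 degenerate = degenerate,
                 low_trials = lt, high_trials = ht),
            class = "band_dominance")
}

#' Spearman correlation of dominance index with antero-posterior coordinate
#'
#' @param dominance_df data frame with columns `index` and `ap_coord`
#'   (one row per site; >= 5 sites).
#' @return list with `rho`, `p` (Spearman rank correlation).
#' @export
dominance_ap_correlation <- function(dominance_df) {
  if (nrow(dominance_df) < 5) stop("dominance_ap_correlation: need >= 5 sites")
  if (stats::sd(dominance_df$ap_coord) == 0) stop("constant AP coordinate")
  ct <- suppressWarnings(
    stats::cor.test(dominance_df$index, dominance_df$ap_coord, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Full pre-SC1 spectral characterization of one site
#'
#' Cuts the 900-ms epoch preceding SC1 for the included trials, runs the
#' pre-SC1 power estimate, the two-minima aperiodic fit (on the site-average
#' log spectrum), the periodic residuals, per-trial peak frequencies and the
#' band dominance index.
#'
#' @param store a session store.
#' @param site_id LFP site (channel `lfp_<site_id>`).
#' @param include outcomes to keep (default correct + non-hold).
#' @return list: `freqs_hz`, `power`, `fit`, `periodic`, `peaks`,
#'   `dominance`, `trial_ids`.
#' @export
site_spectral_summary <- function(store, site_id,
                                  include = c("correct", "non_hold")) {
  rec <- store$records[[paste0("lfp_", site_id)]]
  if (is.null(rec)) stop("no LFP record for site ", site_id)
  tr <- store$trials[store$trials$outcome %in% include & !is.na(store$trials$t_sc1_on), ]
  cut <- align_and_cut(rec, tr, "sc1_on", c(-900, 0))
  ps <- pre_sc1_power(cut$values, rec$rate_hz)
  logp <- log10(ps$power)
  fit <- fit_aperiodic(colMeans(logp), ps$freqs_hz)
  periodic <- periodic_component(logp, fit, ps$freqs_hz)
  list(freqs_hz = ps$freqs_hz, power = ps$power, fit = fit,
       periodic = periodic,
       peaks = peak_frequency(periodic, ps$freqs_hz),
       dominance = band_dominance(periodic, ps$freqs_hz),
       trial_ids = cut$trial_ids)
}

#' Dominance table for all sites of a session
#'
#' @param store session store; @param include outcomes to keep.
#' @return data frame: site_id, ap_coord, index, p_value, label, strong.
#' @export
session_dominance_table <- function(store, include = c("correct", "non_hold")) {
  out <- lapply(seq_len(nrow(store$sites)), function(s) {
    sid <- store$sites$site_id[s]
    d <- site_spectral_summary(store, sid, include)$dominance
    data.frame(site_id = sid, ap_coord = store$sites$ap_coord[s],
               index = d$index, p_value = d$p_value, label = d$label,
               strong = d$strong, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
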