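## Band-limited amplitude envelopes: zero-phase Butterworth band-pass,
## Hilbert envelope, session-wide z-normalization, pooling across sites by
## band dominance, plus multi-unit activity (MUA) extraction from wideband
## signals and EMG conditioning.

BAND_EDGES <- list(low = c(12, 20), high = c(21, 31))

#' Band-pass filter an LFP around one beta band
#'
#' Zero-phase 8th-order Butterworth band-pass; the band edges follow the
#' dominant-band convention 16 +/- 4 Hz (low) and 26 +/- 5 Hz (high).
#'
#' @param record a [continuous_record()] or numeric vector.
#' @param band `"low"`, `"high"`, or numeric `c(lo, hi)` Hz.
#' @param rate_hz required when `record` is a bare vector.
#' @return same type as the input, band-limited.
#' @export
bandpass_beta <- function(record, band = c("low", "high"), rate_hz = NULL) {
  edges <- if (is.character(band)) BAND_EDGES[[match.arg(band)]] else band
  if (inherits(record, "continuous_record")) {
    if (record$rate_hz < 4 * edges[2])
      stop("bandpass_beta: sampling rate below 4x band top")
    y <- zero_phase_butter(record$samples, record$rate_hz, "pass", edges, order = 8)
    record$samples <- y
    record
  } else {
    if (is.null(rate_hz)) stop("bandpass_beta: rate_hz required for a bare vector")
    if (rate_hz < 4 * edges[2]) stop("bandpass_beta: sampling rate below 4x band top")
    zero_phase_butter(record, rate_hz, "pass", edges, order = 8)
  }
}

#' Instantaneous amplitude by the Hilbert transform
#' @param x band-limited numeric vector (or `continuous_record`).
#' @return nonnegative amplitude sequence (same type).
#' @export
hilbert_envelope <- function(x) {
  if (inherits(x, "continuous_record")) {
    x$samples <- Mod(analytic_signal(x$samples))
    x
  } else {
    Mod(analytic_signal(x))
  }
}

#' Instantaneous phase by the Hilbert transform
#' @param x band-limited numeric vector.
#' @export
hilbert_phase <- function(x) Arg(analytic_signal(x))

#' Z-normalize an amplitude envelope over the session
#'
#' Subtracts the grand mean and divides by the grand standard deviation.
#' The first and last `edge_ms` are excluded from the statistics (filter
#' edge effects) but still transformed.
#'
#' @param amplitude numeric vector (session-long envelope).
#' @param rate_hz sampling rate; @param edge_ms excluded edges.
#' @return z-scored vector with attributes `grand_mean`, `grand_sd`.
#' @export
znormalize_envelope <- function(amplitude, rate_hz = 1000, edge_ms = 200) {
  n <- length(amplitude)
  k <- min(round(edge_ms * rate_hz / 1000), floor((n - 1) / 2))
  core <- amplitude[(k + 1):(n - k)]
  m <- mean(core); s <- stats::sd(core)
  if (!is.finite(s) || s == 0) stop("znormalize_envelope: constant envelope")
  structure((amplitude - m) / s, grand_mean = m, grand_sd = s)
}

#' Session-long z-scored beta envelope of one site
#'
#' Band-pass -> Hilbert envelope -> session z-normalization.
#' @param store session store; @param site_id site; @param band band name.
#' @return a [continuous_record()] in z units.
#' @export
site_envelope_record <- function(store, site_id, band) {
  rec <- store$records[[paste0("lfp_", site_id)]]
  if (is.null(rec)) stop("no LFP record for site ", site_id)
  env <- hilbert_envelope(bandpass_beta(rec$samples, band, rec$rate_hz))
  z <- znormalize_envelope(env, rec$rate_hz)
  continuous_record(paste0("env_", band, "_", site_id), "lfp", rec$rate_hz,
                    as.numeric(z), t0_ms = rec$t0_ms, units = "z")
}

#' Pool trial-cut envelopes across sites by band dominance
#'
#' Each site contributes its dominant band only; rows from all sites with
#' the same dominance are stacked into one trials x time matrix per band.
#'
#' @param store session store.
#' @param dominance dominance table from [session_dominance_table()].
#' @param align_event,window_ms trial alignment (defaults: selection-cue
#'   onset, -1200..5600 ms).
#' @param include trial outcomes to keep.
#' @param strong_only keep only sites with |index| > 0.25.
#' @return list with one element per band (`low`, `high`), each a list
#'   `values` (pooled trials x time), `site_id`, `trial_id` (per row),
#'   `time_ms`, or `NULL` with an `empty` marker when no site contributes.
#' @export
pool_by_dominance <- function(store, dominance, align_event = "sel_on",
                              window_ms = c(-1200, 5600),
                              include = c("correct", "non_hold"),
                              strong_only = FALSE) {
  if (!all(store$sites$site_id %in% dominance$site_id))
    stop("pool_by_dominance: dominance missing for some sites")
  tr <- store$trials[store$trials$outcome %in% include, ]
  out <- list()
  for (bnd in c("low", "high")) {
    rows <- dominance[dominance$label == bnd, ]
    if (strong_only) rows <- rows[abs(rows$index) > 0.25, ]
    vals <- list(); sid <- character(0); tid <- integer(0); tms <- NULL
    for (s in rows$site_id) {
      envrec <- site_envelope_record(store, s, bnd)
      cut <- align_and_cut(envrec, tr, align_event, window_ms)
      vals[[length(vals) + 1L]] <- cut$values
      sid <- c(sid, rep(s, nrow(cut$values)))
      tid <- c(tid, cut$trial_ids)
      tms <- cut$time_ms
    }
    out[[bnd]] <- if (!length(vals)) {
      list(empty = TRUE, band = bnd)
    } else {
      list(empty = FALSE, band = bnd, values = do.call(rbind, vals),
           site_id = sid, trial_id = tid, time_ms = tms)
    }
  }
  out
}

#' Multi-unit activity envelope from a wideband signal
#'
#' Band-pass 300-6000 Hz, clip at +/- 2 sd, square, low-pass 250 Hz,
#' downsample to 1 kHz, square root, and normalize by the mean over the
#' whole signal.
#'
#' @param record wideband [continuous_record()] (rate >= 12 kHz).
#' @return 1 kHz `continuous_record` with mean 1.
#' @export
extract_mua <- function(record) {
  if (record$rate_hz < 12000) stop("extract_mua: rate too low (< 12 kHz)")
  x <- record$samples
  s <- stats::sd(x)
  if (s == 0) stop("extract_mua: zero-variance input")
  hi <- min(6000, record$rate_hz / 2 * 0.95)
  x <- zero_phase_butter(x, record$rate_hz, "pass", c(300, hi), order = 4)
  x <- pmin(pmax(x, -2 * s), 2 * s)
  x <- x^2
  x <- zero_phase_butter(x, record$rate_hz, "low", 250, order = 4)
  dec <- resample_record(
    continuous_record(record$channel_id, "wideband", record$rate_hz, x,
                      t0_ms = record$t0_ms), 1000, "linear")
  y <- sqrt(pmax(dec$samples, 0))
  y <- y / mean(y)
  continuous_record(paste0("mua_", record$channel_id), "wideband", 1000, y,
                    t0_ms = record$t0_ms, units = "a.u.")
}

#' Condition an EMG signal
#'
#' Rectify, low-pass at 250 Hz, resample to 1 kHz, then Gaussian-smooth
#' (150-ms kernel length, 100-ms width).
#'
#' @param record EMG [continuous_record()].
#' @return smoothed-amplitude `continuous_record` at 1 kHz.
#' @export
condition_emg <- function(record) {
  x <- abs(record$samples)
  if (record$rate_hz > 500)
    x <- zero_phase_butter(x, record$rate_hz, "low", 250, order = 4)
  rec <- continuous_record(record$channel_id, "emg", record$rate_hz, x,
                           t0_ms = record$t0_ms)
  rec1k <- if (record$rate_hz == 1000) rec else resample_record(rec, 1000, "linear")
  rec1k$samples <- gauss_smooth(rec1k$samples, 1000, 150, 100)
  rec1k
}
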