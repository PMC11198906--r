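## Resampling and trial cutting/alignment.

#' Resample a continuous record
#'
#' Linear interpolation for continuous signals; nearest-neighbor for
#' categorical label streams (the output then takes only input values).
#'
#' @param record a [continuous_record()].
#' @param target_hz output rate (> 0).
#' @param method `"linear"` or `"nearest"`.
#' @return resampled `continuous_record` covering the same time span
#'   (within one output sample).
#' @export
resample_record <- function(record, target_hz, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(target_hz > 0)
  x <- record$samples
  if (!all(is.finite(x)) && is.null(record$mask))
    stop("resample_record: non-finite samples without missing-mask")
  n <- length(x)
  t_in <- record_times(record)
  dur <- n / record$rate_hz * 1000
  n_out <- max(1L, round(dur * target_hz / 1000))
  t_out <- record$t0_ms + (seq_len(n_out) - 1) * 1000 / target_hz
  if (identical(target_hz, record$rate_hz)) return(record)
  if (method == "linear") {
    y <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
  } else {
    idx <- pmin(pmax(round((t_out - record$t0_ms) * record$rate_hz / 1000) + 1, 1), n)
    y <- x[idx]
  }
  mask_out <- NULL
  if (!is.null(record$mask)) {
    idx <- pmin(pmax(round((t_out - record$t0_ms) * record$rate_hz / 1000) + 1, 1), n)
    mask_out <- record$mask[idx]
    y[!is.finite(y)] <- 0
  }
  continuous_record(record$channel_id, record$kind, target_hz, y,
                    t0_ms = record$t0_ms, units = record$units, mask = mask_out)
}

## Resolve an event column name: accepts "sel_on" or "t_sel_on".
event_column <- function(trials, align_event) {
  cand <- if (align_event %in% names(trials)) align_event else paste0("t_", align_event)
  if (!cand %in% names(trials))
    stop("align_and_cut: unknown event name '", align_event, "'")
  cand
}

#' Cut a continuous record into an aligned trials x time matrix
#'
#' Row `t` holds samples from `align_event(t) + window_ms[1]` (inclusive) to
#' `align_event(t) + window_ms[2]` (exclusive) at the record's own rate.
#' Trials whose window is not fully covered by the recording (or whose align
#' event is missing) are excluded and reported.
#'
#' @param record a [continuous_record()].
#' @param trials trial table.
#' @param align_event event column, e.g. `"sel_on"` or `"t_go"`.
#' @param window_ms `c(start, stop)` relative to the event, half-open.
#' @return list with `values` (matrix), `mask` (matrix, TRUE = missing),
#'   `trial_ids`, `time_ms` (column times relative to the event) and
#'   `excluded` (trial ids without coverage).
#' @export
align_and_cut <- function(record, trials, align_event, window_ms) {
  col <- event_column(trials, align_event)
  ev <- trials[[col]]
  rate <- record$rate_hz
  n_col <- round((window_ms[2] - window_ms[1]) * rate / 1000)
  if (n_col <= 0) stop("align_and_cut: empty window")
  n <- length(record$samples)
  start_idx <- round((ev + window_ms[1] - record$t0_ms) * rate / 1000) + 1
  ok <- !is.na(ev) & start_idx >= 1 & (start_idx + n_col - 1) <= n
  if (!any(ok)) stop("align_and_cut: zero trials with window coverage")
  keep <- which(ok)
  values <- matrix(NA_real_, length(keep), n_col)
  maskm <- matrix(FALSE, length(keep), n_col)
  for (j in seq_along(keep)) {
    idx <- start_idx[keep[j]] + 0:(n_col - 1)
    values[j, ] <- record$samples[idx]
    if (!is.null(record$mask)) maskm[j, ] <- record$mask[idx]
  }
  list(values = values, mask = maskm,
       trial_ids = trials$trial_id[keep],
       time_ms = window_ms[1] + (0:(n_col - 1)) * 1000 / rate,
       excluded = trials$trial_id[!ok])
}
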