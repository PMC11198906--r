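## Session data model and on-disk store.
##
## A session is a directory bundle:
##   signals/<channel_id>.feather   one column "value" (+ "mask" when present)
##   spikes.csv                     unit_id, site_id, t_ms (long format)
##   trials.csv                     one row per trial (see trial table fields)
##   sites.csv                      site metadata
##   session.json                   per-channel rate/kind/units/t0 + provenance
## All stored times are milliseconds from session start.

CHANNEL_KINDS <- c("lfp", "hand_x", "hand_y", "eye_x", "eye_y", "wideband", "emg")

TRIAL_COLUMNS <- c(
  "trial_id", "condition", "sc1_pos", "sc2_pos", "sc3_pos", "valid_target",
  "outcome", "attended", "ambiguous",
  "t_touch", "t_sel_on", "t_sel_off", "t_sc1_on", "t_sc1_off",
  "t_sc2_on", "t_sc2_off", "t_sc3_on", "t_sc3_off", "t_go", "t_move_on",
  "rt_ms")

#' Continuous signal record
#'
#' @param channel_id unique channel name.
#' @param kind one of `r paste(CHANNEL_KINDS, collapse=", ")`.
#' @param rate_hz sampling rate (> 0).
#' @param samples numeric vector; non-finite values only where `mask` is TRUE.
#' @param t0_ms session time of the first sample.
#' @param units physical units label.
#' @param mask optional logical vector marking missing/invalid samples.
#' @return object of class `continuous_record`.
#' @export
continuous_record <- function(channel_id, kind, rate_hz, samples,
                              t0_ms = 0, units = "a.u.", mask = NULL) {
  stopifnot(rate_hz > 0, kind %in% CHANNEL_KINDS)
  if (!is.null(mask)) stopifnot(length(mask) == length(samples))
  bad <- !is.finite(samples)
  if (any(bad) && (is.null(mask) || !all(mask[bad])))
    stop("continuous_record: non-finite samples without a covering mask")
  structure(list(channel_id = as.character(channel_id), kind = kind,
                 rate_hz = rate_hz, t0_ms = t0_ms, units = units,
                 samples = as.numeric(samples), mask = mask),
            class = "continuous_record")
}

#' @export
print.continuous_record <- function(x, ...) {
  cat(sprintf("<continuous_record %s [%s] %g Hz, %d samples, t0=%g ms>\n",
              x$channel_id, x$kind, x$rate_hz, length(x$samples), x$t0_ms))
  invisible(x)
}

## sample times of a record, ms
record_times <- function(rec) {
  rec$t0_ms + (seq_along(rec$samples) - 1) * 1000 / rec$rate_hz
}

#' Spike train of one unit
#' @param unit_id unit name; @param site_id recording site; both strings.
#' @param spike_times_ms strictly increasing spike times, session ms.
#' @export
spike_train <- function(unit_id, site_id, spike_times_ms) {
  spike_times_ms <- as.numeric(spike_times_ms)
  if (is.unsorted(spike_times_ms, strictly = TRUE))
    stop("spike_train: spike times must be strictly increasing")
  structure(list(unit_id = as.character(unit_id), site_id = as.character(site_id),
                 spike_times_ms = spike_times_ms), class = "spike_train")
}

#' Assemble a session store in memory
#'
#' @param records named list of [continuous_record()]s.
#' @param trials trial table data frame (see package vignette for columns).
#' @param sites site metadata data frame with at least `site_id`, `monkey_id`,
#'   `ap_coord`, `ml_coord`, `electrode_kind`, `n_trials`.
#' @param spikes list of [spike_train()]s (possibly empty).
#' @param meta free-form list (rates, generator provenance, ...).
#' @return object of class `session_store`.
#' @export
session_store <- function(records, trials, sites, spikes = list(), meta = list()) {
  names(records) <- vapply(records, `[[`, "", "channel_id")
  if (length(spikes))  # canonical unit order so write/read round-trips exactly
    spikes <- spikes[order(vapply(spikes, `[[`, "", "unit_id"))]
  st <- structure(list(records = records, trials = trials, sites = sites,
                       spikes = spikes, meta = meta), class = "session_store")
  validate_session(st)
  st
}

#' @export
print.session_store <- function(x, ...) {
  cat(sprintf("<session_store: %d channels, %d trials, %d sites, %d units>\n",
              length(x$records), nrow(x$trials), nrow(x$sites), length(x$spikes)))
  invisible(x)
}

#' Validate a session store
#'
#' Checks channel kinds and rates, the trial table schema (event order,
#' cue/delay durations, reaction-time consistency) and spike-train bounds.
#' @param store a `session_store`.
#' @param tol_ms tolerance on cue/delay durations, in ms (one sample).
#' @return invisibly TRUE, or stops with a schema error.
#' @export
validate_session <- function(store, tol_ms = 1) {
  tr <- store$trials
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols))
    stop("trial table missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(store$sites$site_id))
    stop("site_id not unique")
  ev <- c("t_touch", "t_sel_on", "t_sel_off", "t_sc1_on", "t_sc1_off",
          "t_sc2_on", "t_sc2_off", "t_sc3_on", "t_sc3_off", "t_go", "t_move_on")
  for (i in seq_len(nrow(tr))) {
    times <- as.numeric(tr[i, ev])
    times <- times[!is.na(times)]
    if (is.unsorted(times, strictly = TRUE))
      stop("trial ", tr$trial_id[i], ": event times not strictly increasing")
  }
  full <- !is.na(tr$t_go)
  if (any(full)) {
    cue_ok <- function(on, off) abs((tr[[off]] - tr[[on]])[full] - 300) <= tol_ms
    del_ok <- function(off, nxt) abs((tr[[nxt]] - tr[[off]])[full] - 1000) <= tol_ms
    ok <- cue_ok("t_sel_on", "t_sel_off") & cue_ok("t_sc1_on", "t_sc1_off") &
      cue_ok("t_sc2_on", "t_sc2_off") & cue_ok("t_sc3_on", "t_sc3_off") &
      del_ok("t_sel_off", "t_sc1_on") & del_ok("t_sc1_off", "t_sc2_on") &
      del_ok("t_sc2_off", "t_sc3_on") & del_ok("t_sc3_off", "t_go")
    if (!all(ok)) stop("trial cue/delay durations violate 300/1000 ms task structure")
    has_rt <- full & !is.na(tr$t_move_on) & !is.na(tr$rt_ms)
    if (any(abs((tr$t_move_on - tr$t_go - tr$rt_ms)[has_rt]) > tol_ms))
      stop("rt_ms inconsistent with t_move_on - t_go")
  }
  for (rec in store$records) {
    if (!inherits(rec, "continuous_record")) stop("records must be continuous_record")
  }
  for (sp in store$spikes) {
    if (length(sp$spike_times_ms)) {
      ref <- store$records[[1]]
      tmax <- ref$t0_ms + length(ref$samples) * 1000 / ref$rate_hz
      if (min(sp$spike_times_ms) < ref$t0_ms - 1 || max(sp$spike_times_ms) > tmax + 1)
        stop("spike train ", sp$unit_id, " outside session bounds")
    }
  }
  invisible(TRUE)
}

#' Write a session store to disk
#'
#' @param store a `session_store`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(store, path) {
  dir.create(file.path(path, "signals"), recursive = TRUE, showWarnings = FALSE)
  chmeta <- list()
  for (rec in store$records) {
    df <- data.frame(value = rec$samples)
    if (!is.null(rec$mask)) df$mask <- rec$mask
    arrow::write_feather(df, file.path(path, "signals", paste0(rec$channel_id, ".feather")))
    chmeta[[rec$channel_id]] <- list(kind = rec$kind, rate_hz = rec$rate_hz,
                                     t0_ms = rec$t0_ms, units = rec$units)
  }
  utils::write.csv(store$trials, file.path(path, "trials.csv"), row.names = FALSE)
  utils::write.csv(store$sites, file.path(path, "sites.csv"), row.names = FALSE)
  if (length(store$spikes)) {
    sp <- do.call(rbind, lapply(store$spikes, function(s)
      data.frame(unit_id = s$unit_id, site_id = s$site_id, t_ms = s$spike_times_ms)))
  } else {
    sp <- data.frame(unit_id = character(), site_id = character(), t_ms = numeric())
  }
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  jsonlite::write_json(list(channels = chmeta, meta = store$meta),
                       file.path(path, "session.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session store from disk
#'
#' @param path session directory written by [write_session()].
#' @return a `session_store`; fails with an error naming any missing
#'   mandatory component.
#' @export
read_session <- function(path) {
  for (comp in c("trials.csv", "sites.csv", "spikes.csv", "session.json", "signals")) {
    if (!file.exists(file.path(path, comp)))
      stop("read_session: missing mandatory component '", comp, "'")
  }
  js <- jsonlite::read_json(file.path(path, "session.json"), simplifyVector = TRUE)
  trials <- utils::read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  trials$ambiguous <- as.logical(trials$ambiguous)
  sites <- utils::read.csv(file.path(path, "sites.csv"), stringsAsFactors = FALSE)
  spdf <- utils::read.csv(file.path(path, "spikes.csv"), stringsAsFactors = FALSE)
  spikes <- lapply(split(spdf, spdf$unit_id), function(d)
    spike_train(d$unit_id[1], d$site_id[1], sort(d$t_ms)))
  spikes <- unname(spikes)
  records <- list()
  for (ch in names(js$channels)) {
    f <- file.path(path, "signals", paste0(ch, ".feather"))
    if (!file.exists(f)) stop("read_session: missing signal file for channel '", ch, "'")
    df <- as.data.frame(arrow::read_feather(f))
    cm <- js$channels[[ch]]
    records[[ch]] <- continuous_record(ch, cm$kind, cm$rate_hz, df$value,
                                       t0_ms = cm$t0_ms, units = cm$units,
                                       mask = if ("mask" %in% names(df)) df$mask else NULL)
  }
  session_store(records, trials, sites, spikes, meta = as.list(js$meta))
}
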