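## Generator configuration. Defaults define the emulated study conditions:
## a ~40% abort rate, ~12% distractor errors, lognormal reaction times with a
## time-on-task drift, bursty 16/26 Hz rhythms whose dominance follows the
## antero-posterior site coordinate, negative hand-velocity -> low-beta
## coupling at 125 ms lag, gaze-In -> high-beta coupling at 240 ms lead, and
## an RT modulation of low beta during movement preparation.

#' Default synthetic-session generator parameters
#'
#' @param n_sites number of LFP sites.
#' @param n_trials number of initiated trials (including aborts).
#' @param ... overrides for any top-level group (`task`, `lfp`, `coupling`,
#'   `hand`, `eye`, `spikes`) or scalar; supplied lists are merged field-wise
#'   into the defaults.
#' @return nested parameter list.
#' @export
generator_params <- function(n_sites = 20, n_trials = 100, ...) {
  p <- list(
    n_sites = n_sites,
    n_trials = n_trials,
    task = list(
      hold_ms = 1000, cue_ms = 300, delay_ms = 1000,
      n_conditions = 3, n_positions = 4, block_size = 15,
      p_abort = 0.40, p_distractor_error = 0.12, p_non_hold = 0.05,
      pre_touch_ms = 1500, post_go_ms = 1400, iti_ms = 800),
    lfp = list(
      aperiodic_exponent = 1.5, aperiodic_offset = 1.0,
      low_center = 16, high_center = 26,
      freq_jitter_hz = 0.35,
      burst_sigma = 0.6, burst_tau_ms = 150,
      band_amp = 1.3,
      ## mixture in [0,1]: weight of the low band at a site given its
      ## antero-posterior coordinate (mm; positive = anterior)
      dominance_gradient = function(ap) stats::plogis(-ap / 2.5),
      envelope_template = default_envelope_templates()),
    coupling = list(
      hand_to_lowbeta_gain = -0.25, lag_beta_lags_hand_ms = 125,
      gaze_to_highbeta_gain = 0.5, lead_gaze_ms = 240,
      rt_to_lowbeta_gain = 0.20,
      time_on_task_slope = 0.25),
    hand = list(
      ## micro-movement velocity scales (cm/s); the Y rail has less
      ## friction, so more spontaneous movement along Y
      micro_v_sd_x = 0.35, micro_v_sd_y = 0.50, micro_tau_ms = 150,
      pos_leak_tau_ms = 400,
      post_valid_gain = c(blue = 0.5, green = 0.9, pink = 1.3),
      reach_dur_ms = 300, rate_hz = 250,
      rt_mean_ms = 280, rt_sdlog = 0.12),
    eye = list(
      rate_hz = 240, gain_v_per_cm = 0.25, offset_v = c(0.3, -0.2),
      noise_v = 0.004, sat_bound_v = 4,
      distort_c1 = 0.02, distort_c2 = 0.01,
      fix_jitter_cm = 0.12, fix_tau_ms = 80,
      dwell_mean_ms = 350, dwell_min_ms = 150,
      p_out_base = 0.40, p_out_attend = 0.12,
      blink_p_per_delay = 0.18, blink_plateau_ms = 80,
      work_half_w_cm = 13, work_half_h_cm = 10,
      out_point_cm = c(18, 14)),
    spikes = list(
      n_units_per_site = 2, baseline_rate_hz = 25,
      kappa = 0.8, preferred_phase = pi / 3))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(p[[nm]])) {
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  p
}

#' Default per-band amplitude envelope templates
#'
#' Piecewise-linear target envelopes, expressed as breakpoints anchored to
#' task events (resolved per trial; `valid_on`/`valid_off` follow the
#' *attended* condition). The high band is high throughout with dips around
#' each spatial cue (deepest at the attended one); the low band ramps up to a
#' maximum between the selection cue and the attended spatial cue, then drops
#' and stays low; both collapse after GO. Shapes are configuration, not code.
#'
#' @return list with `low` and `high` breakpoint data frames
#'   (`anchor`, `offset_ms`, `level`).
#' @export
default_envelope_templates <- function() {
  bp <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(anchor = m[, 1], offset_ms = as.numeric(m[, 2]),
               level = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  }
  high <- bp(
    "touch", -400, 0.85,
    "touch", 0, 0.95,
    "sel_on", 0, 1.15,
    "sc1_on", -100, 1.15, "sc1_on", 60, 0.72, "sc1_on", 340, 0.72, "sc1_on", 520, 1.15,
    "sc2_on", -100, 1.15, "sc2_on", 60, 0.72, "sc2_on", 340, 0.72, "sc2_on", 520, 1.15,
    "sc3_on", -100, 1.15, "sc3_on", 60, 0.72, "sc3_on", 340, 0.72, "sc3_on", 520, 1.15,
    "valid_on", 60, 0.45, "valid_on", 340, 0.50,  # deeper dip at the attended cue
    "go", -50, 1.15,
    "go", 150, 0.40, "go", 800, 0.65,
    "end", 0, 0.85)
  low <- bp(
    "touch", -400, 0.65,
    "touch", 0, 0.72,
    "sel_on", -200, 1.10,
    "valid_on", 60, 1.10,
    "valid_on", 500, 0.60,
    "go", -50, 0.60,
    "go", 200, 0.32, "go", 800, 0.50,
    "end", 0, 0.65)
  list(low = low, high = high)
}

## Resolve a breakpoint table against one trial's events; returns a
## data.frame(t_ms, level) in session time, sorted, deduplicated.
resolve_template <- function(tpl, trial, iti_ms) {
  attended <- trial$attended %||% trial$condition
  vidx <- valid_sc_index(attended)
  valid_on <- trial[[c("t_sc1_on", "t_sc2_on", "t_sc3_on")[vidx]]]
  anchor_time <- function(a) switch(a,
    touch = trial$t_touch, sel_on = trial$t_sel_on,
    sc1_on = trial$t_sc1_on, sc2_on = trial$t_sc2_on, sc3_on = trial$t_sc3_on,
    valid_on = valid_on, go = trial$t_go,
    end = (trial$t_go %||% NA) + iti_ms,
    stop("unknown template anchor: ", a))
  t_abs <- vapply(tpl$anchor, anchor_time, 0) + tpl$offset_ms
  keep <- !is.na(t_abs)
  d <- data.frame(t_ms = t_abs[keep], level = tpl$level[keep])
  d <- d[order(d$t_ms), ]
  ## on time collisions the later table row wins, so attended-cue-specific
  ## breakpoints override the generic per-cue ones
  d[!duplicated(d$t_ms, fromLast = TRUE), ]
}

#' Evaluate the planted envelope template for a set of trials
#'
#' Builds the per-ms piecewise-linear template over a whole session;
#' between-trial spans sit at the band's resting level (the template's
#' first level).
#'
#' @param tpl breakpoint table (one band) from the generator params.
#' @param trials trial table with event times.
#' @param n_ms session length in ms (1 kHz grid).
#' @param iti_ms inter-trial interval used to resolve the `end` anchor.
#' @return numeric vector of length `n_ms`.
#' @export
envelope_template_trace <- function(tpl, trials, n_ms, iti_ms = 800) {
  pts_t <- numeric(0); pts_v <- numeric(0)
  rest <- tpl$level[1]
  for (i in seq_len(nrow(trials))) {
    tr <- as.list(trials[i, ])
    if (is.na(tr$t_go)) next  # aborted: stay near rest
    d <- resolve_template(tpl, tr, iti_ms)
    pts_t <- c(pts_t, d$t_ms); pts_v <- c(pts_v, d$level)
  }
  if (!length(pts_t)) return(rep(rest, n_ms))
  o <- order(pts_t)
  stats::approx(pts_t[o], pts_v[o], xout = seq_len(n_ms) - 1,
                rule = 2, ties = "ordered")$y
}
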