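## LFP simulation: 1/f^chi background plus two bursty narrow-band rhythms
## (low ~16 Hz, high ~26 Hz) whose instantaneous amplitude follows the
## task-locked envelope templates, multiplied by behavioral couplings:
##   low band  x (1 + g_hand * z(hand speed at t - 125 ms)),   g_hand < 0
##             x (1 + g_rt * z(RT)) during movement preparation
##   high band x (1 + g_gaze * centered gaze-In at t - 240 ms), g_gaze > 0
##   both      x (1 + slope * (trial position - 0.5))            time-on-task
## The site's low/high mixture is set by the antero-posterior dominance
## gradient. The realized per-band envelopes and carrier phases are returned
## as ground truth.

## lag a series by `lag_ms` (positive = use the past value), edge-padded
lag_series <- function(x, lag_ms) {
  n <- length(x)
  if (lag_ms == 0) return(x)
  if (lag_ms > 0) c(rep(x[1], lag_ms), x[seq_len(n - lag_ms)])
  else c(x[(-lag_ms + 1):n], rep(x[n], -lag_ms))
}

#' Simulate one site's LFP
#'
#' @param params generator parameters.
#' @param trials trial table.
#' @param site one row of the site table (needs `ap_coord`).
#' @param hand_speed_1k planted 1 kHz hand speed (cm/s), session-long.
#' @param gaze_in_1k planted 1 kHz gaze In/Out indicator (0/1).
#' @param seed integer seed.
#' @return list with `record` (1 kHz [continuous_record()]), `env_low`,
#'   `env_high` (realized per-ms band envelopes, mixture-weighted),
#'   `phase_low`, `phase_high` (carrier phases), `mixture` (low-band weight).
#' @export
simulate_lfp <- function(params, trials, site, hand_speed_1k, gaze_in_1k,
                         seed = 1) {
  lf <- params$lfp
  cp <- params$coupling
  n <- session_length_ms(params, trials)
  stopifnot(length(hand_speed_1k) >= n, length(gaze_in_1k) >= n)
  mix <- lf$dominance_gradient(site$ap_coord)
  with_seed(derive_seed(seed, paste0("lfp_", site$site_id)), {
    bg <- lf$aperiodic_offset * powerlaw_noise(n, 1000, lf$aperiodic_exponent)
    ## deterministic templates
    tpl_low <- envelope_template_trace(lf$envelope_template$low, trials, n,
                                       params$task$iti_ms)
    tpl_high <- envelope_template_trace(lf$envelope_template$high, trials, n,
                                        params$task$iti_ms)
    ## behavioral modulators
    hz <- hand_speed_1k[seq_len(n)]
    hz <- (hz - stats::median(hz)) / (stats::mad(hz) + 1e-12)
    hz <- pmin(pmax(hz, -2.5), 2.5)
    mod_hand <- 1 + cp$hand_to_lowbeta_gain * lag_series(hz, cp$lag_beta_lags_hand_ms)
    gz <- gaze_in_1k[seq_len(n)] - mean(gaze_in_1k[seq_len(n)])
    mod_gaze <- 1 + cp$gaze_to_highbeta_gain * lag_series(gz, cp$lead_gaze_ms)
    ## RT and time-on-task per-ms modulators
    mod_rt <- rep(1, n); mod_tot <- rep(1, n)
    rtz <- trials$rt_ms
    rtz <- (rtz - mean(rtz, na.rm = TRUE)) / (stats::sd(rtz, na.rm = TRUE) + 1e-12)
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      ## time-on-task applies across the whole trial span
      t_end <- if (is.na(tr$t_go)) tr$t_touch + 6500 else tr$t_go + 1400
      span <- max(1, round(tr$t_touch - 1000)):min(n, round(t_end))
      mod_tot[span] <- 1 + cp$time_on_task_slope * (tr$trial_frac - 0.5)
      if (!is.na(tr$t_go) && !is.na(rtz[i])) {
        att <- tr$attended %||% tr$condition
        von <- tr[[c("t_sc1_on", "t_sc2_on", "t_sc3_on")[valid_sc_index(att)]]]
        prep <- max(1, round(von)):min(n, round(tr$t_go))
        mod_rt[prep] <- 1 + cp$rt_to_lowbeta_gain * rtz[i]
      }
    }
    ## bursts: lognormal amplitude fluctuations with ~burst_tau_ms timescale
    burst <- function() {
      g <- ar1_process(n, lf$burst_tau_ms, 1)
      exp(lf$burst_sigma * g - lf$burst_sigma^2 / 2)
    }
    env_low <- lf$band_amp * tpl_low * pmax(mod_hand * mod_rt * mod_tot, 0.05) * burst()
    env_high <- lf$band_amp * tpl_high * pmax(mod_gaze * mod_tot, 0.05) * burst()
    carrier_phase <- function(fc) {
      fj <- fc + ar1_process(n, 200, lf$freq_jitter_hz)
      cumsum(2 * pi * fj / 1000) + stats::runif(1, 0, 2 * pi)
    }
    ph_low <- carrier_phase(lf$low_center)
    ph_high <- carrier_phase(lf$high_center)
    w_low <- mix; w_high <- 1 - mix
    x <- bg + w_low * env_low * cos(ph_low) + w_high * env_high * cos(ph_high)
    rec <- continuous_record(paste0("lfp_", site$site_id), "lfp", 1000, x,
                             units = "uV")
    list(record = rec, env_low = w_low * env_low, env_high = w_high * env_high,
         phase_low = ph_low, phase_high = ph_high, mixture = mix)
  })
}

#' Simulate spike trains phase-locked to the site-dominant beta band
#'
#' Inhomogeneous point process with rate
#' `baseline * exp(kappa * cos(phase - preferred)) / I0(kappa)`, which keeps
#' the mean rate at baseline under a uniform phase distribution.
#'
#' @param params generator parameters.
#' @param phase carrier phase of the site's dominant band (1 kHz).
#' @param site site row (used for ids).
#' @param seed integer seed.
#' @return list of [spike_train()]s (`n_units_per_site` of them).
#' @export
simulate_spikes <- function(params, phase, site, seed = 1) {
  sp <- params$spikes
  if (sp$kappa < 0) stop("simulate_spikes: kappa must be >= 0")
  n <- length(phase)
  with_seed(derive_seed(seed, paste0("spk_", site$site_id)), {
    out <- list()
    for (u in seq_len(sp$n_units_per_site)) {
      if (sp$baseline_rate_hz <= 0) {
        out[[u]] <- spike_train(sprintf("%s_u%d", site$site_id, u),
                                site$site_id, numeric(0))
        next
      }
      rate <- sp$baseline_rate_hz *
        exp(sp$kappa * cos(phase - sp$preferred_phase)) /
        besselI(sp$kappa, 0)
      p <- pmin(rate / 1000, 1)
      hit <- which(stats::runif(n) < p)
      times <- hit - 1 + stats::runif(length(hit), 0.1, 0.9)
      out[[u]] <- spike_train(sprintf("%s_u%d", site$site_id, u),
                              site$site_id, times)
    }
    out
  })
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes the trial sequence, hand, eye, LFP and spike simulators into a
#' [session_store()] plus a ground-truth sidecar. Deterministic for a fixed
#' seed.
#'
#' @param params a [generator_params()] list.
#' @param seed integer master seed.
#' @param dir optional directory: when given, the store is written there
#'   (plus `truth.json` and truth CSV tables).
#' @param keep_envelopes keep per-ms planted band envelopes and phases in
#'   the returned truth (memory-heavy for large sessions).
#' @return list with `store` (session_store) and `truth` (list).
#' @export
generate_session <- function(params = generator_params(), seed = 1,
                             dir = NULL, keep_envelopes = TRUE) {
  trials <- generate_trial_sequence(params, seed)
  hand <- simulate_hand(params, trials, seed)
  eye <- simulate_eye(params, trials, seed)
  n_sites <- params$n_sites
  sites <- data.frame(
    site_id = sprintf("s%02d", seq_len(n_sites)),
    monkey_id = "sim",
    ap_coord = if (n_sites > 1) seq(-7.5, 7.5, length.out = n_sites) else 0,
    ml_coord = with_seed(derive_seed(seed, "ml"),
                         round(stats::runif(n_sites, -5, 5), 2)),
    electrode_kind = "linear_array",
    n_trials = nrow(trials),
    stringsAsFactors = FALSE)
  records <- list(hand$hand_x, hand$hand_y, eye$eye_x, eye$eye_y)
  spikes <- list()
  truth_sites <- list()
  for (s in seq_len(n_sites)) {
    site <- sites[s, ]
    lfp <- simulate_lfp(params, trials, site, hand$speed_1k, eye$gaze_in_1k, seed)
    records[[length(records) + 1L]] <- lfp$record
    dom_band <- if (lfp$mixture >= 0.5) "low" else "high"
    dom_phase <- if (dom_band == "low") lfp$phase_low else lfp$phase_high
    spikes <- c(spikes, simulate_spikes(params, dom_phase, site, seed))
    truth_sites[[site$site_id]] <- list(
      mixture = lfp$mixture, dominant_band = dom_band,
      env_low = if (keep_envelopes) lfp$env_low,
      env_high = if (keep_envelopes) lfp$env_high,
      phase_dom = if (keep_envelopes) dom_phase)
  }
  store <- session_store(records, trials, sites, spikes,
                         meta = list(generator = "duobeta", seed = seed,
                                     n_ms = session_length_ms(params, trials)))
  truth <- list(
    sites = truth_sites,
    trials = data.frame(trial_id = trials$trial_id,
                        rt_true_ms = trials$rt_true_ms,
                        true_onset_ms = hand$true_onset_ms,
                        trial_frac = trials$trial_frac),
    saccades = eye$saccades, blinks = eye$blinks,
    gaze_label_1k = eye$label_1k, gaze_in_1k = eye$gaze_in_1k,
    latent_eye_cm = eye$latent_cm, hand_speed_1k = hand$speed_1k,
    coupling = params$coupling)
  if (!is.null(dir)) {
    write_session(store, dir)
    utils::write.csv(truth$trials, file.path(dir, "truth_trials.csv"), row.names = FALSE)
    utils::write.csv(truth$saccades, file.path(dir, "truth_saccades.csv"), row.names = FALSE)
    utils::write.csv(truth$blinks, file.path(dir, "truth_blinks.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(coupling = params$coupling[setdiff(names(params$coupling), character(0))],
           sites = lapply(truth_sites, function(ts) ts[c("mixture", "dominant_band")])),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(store = store, truth = truth)
}
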