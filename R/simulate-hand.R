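## Hand trajectory simulation: bounded mean-reverting micro-movements during
## central hold (axis-specific scales; the Y rail has less friction), a
## condition-specific rise in micro-movement velocity after the attended
## spatial cue, and a minimum-jerk center-out reach after GO + RT.

## AR(1) / Ornstein-Uhlenbeck sample with time-varying innovation scale.
ar1_process <- function(n, tau_samples, sd_stationary, scale = NULL) {
  a <- exp(-1 / tau_samples)
  sd_e <- sd_stationary * sqrt(1 - a^2)
  e <- stats::rnorm(n, sd = sd_e)
  if (!is.null(scale)) e <- e * scale
  as.numeric(stats::filter(e, a, method = "recursive"))
}

## Minimum-jerk position profile from 0 to 1 over n samples.
min_jerk <- function(n) {
  tau <- seq_len(n) / n
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Simulate hand position signals
#'
#' @param params generator parameters.
#' @param trials trial table from [generate_trial_sequence()].
#' @param seed integer seed.
#' @return list with `hand_x`, `hand_y` ([continuous_record()]s at the hand
#'   sampling rate, cm), `true_onset_ms` per trial (NA when no reach), and
#'   `speed_1k` — the planted 1 kHz hand speed trace used for coupling.
#' @export
simulate_hand <- function(params, trials, seed = 1) {
  h <- params$hand
  tk <- params$task
  rate <- h$rate_hz
  n_ms <- session_length_ms(params, trials)
  n <- ceiling(n_ms * rate / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / rate
  with_seed(derive_seed(seed, "hand"), {
    ## per-sample innovation scale: rises after the attended SC, per condition
    scale <- rep(1, n)
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      if (is.na(tr$t_go)) next
      att <- tr$attended %||% tr$condition
      von <- tr[[c("t_sc1_on", "t_sc2_on", "t_sc3_on")[valid_sc_index(att)]]]
      g <- h$post_valid_gain[[att]]
      idx <- which(t_ms >= von & t_ms < tr$t_go)
      if (length(idx)) {
        ramp <- pmin((t_ms[idx] - von) / 600, 1)
        scale[idx] <- 1 + g * ramp
      }
    }
    ## smooth micro-movements: OU velocity, leaky-integrated into position
    ## (bounded around the central fixation)
    tau_v <- h$micro_tau_ms * rate / 1000
    a_p <- exp(-1 / (h$pos_leak_tau_ms * rate / 1000))
    vx <- ar1_process(n, tau_v, h$micro_v_sd_x, scale)
    vy <- ar1_process(n, tau_v, h$micro_v_sd_y, scale)
    px <- as.numeric(stats::filter(vx / rate, a_p, method = "recursive"))
    py <- as.numeric(stats::filter(vy / rate, a_p, method = "recursive"))
    ## deterministic reach path
    tc <- target_coords_cm()
    rx <- numeric(n); ry <- numeric(n)
    reach_n <- round(h$reach_dur_ms * rate / 1000)
    hold_n <- round(300 * rate / 1000)
    back_n <- round(500 * rate / 1000)
    true_onset <- rep(NA_real_, nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      if (is.na(tr$t_move_on)) next
      tgt <- tc[match(tr$reach_target, tc$label), c("x", "y")]
      i0 <- round(tr$t_move_on * rate / 1000) + 1
      if (i0 + reach_n + hold_n + back_n >= n) next
      prof <- min_jerk(reach_n)
      seg <- i0 + seq_len(reach_n) - 1
      rx[seg] <- tgt$x * prof; ry[seg] <- tgt$y * prof
      hseg <- max(seg) + seq_len(hold_n)
      rx[hseg] <- tgt$x; ry[hseg] <- tgt$y
      bseg <- max(hseg) + seq_len(back_n)
      bprof <- 1 - min_jerk(back_n)
      rx[bseg] <- tgt$x * bprof; ry[bseg] <- tgt$y * bprof
      true_onset[i] <- tr$t_move_on
    }
    x <- px + rx; y <- py + ry
    hand_x <- continuous_record("hand_x", "hand_x", rate, x, units = "cm")
    hand_y <- continuous_record("hand_y", "hand_y", rate, y, units = "cm")
    ## planted speed at 1 kHz (linear upsample + light smoothing)
    t1 <- seq_len(n_ms) - 1
    x1 <- stats::approx(t_ms, x, xout = t1, rule = 2)$y
    y1 <- stats::approx(t_ms, y, xout = t1, rule = 2)$y
    sp <- c(0, sqrt(diff(x1)^2 + diff(y1)^2)) * 1000  # cm/s
    sp <- gauss_smooth(sp, 1000, 60, 40)
    list(hand_x = hand_x, hand_y = hand_y, true_onset_ms = true_onset,
         speed_1k = sp)
  })
}

## Total session length in ms implied by the trial layout.
session_length_ms <- function(params, trials) {
  tk <- params$task
  span <- tk$pre_touch_ms + tk$hold_ms + 4 * (tk$cue_ms + tk$delay_ms) +
    tk$post_go_ms + tk$iti_ms
  ceiling(tk$pre_touch_ms + nrow(trials) * span)
}
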