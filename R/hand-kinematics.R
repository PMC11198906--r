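## Hand kinematics: Savitzky-Golay velocity/acceleration estimation,
## reaction-time (movement onset) detection by velocity + acceleration
## thresholds, micro-movement epoch profiles and positional drift.

#' Kinematics parameters
#'
#' The speed estimate uses a relatively wide Savitzky-Golay window (stable
#' supra-threshold period detection); the acceleration used for the onset
#' crossing uses a short window so that the steep rise of the reach is not
#' smeared backwards in time.
#'
#' @param sg_window_ms Savitzky-Golay window for the speed (ms, odd sample
#'   count at 1 kHz).
#' @param acc_window_ms Savitzky-Golay window for the acceleration.
#' @param sg_order polynomial order.
#' @param vel_thresh velocity threshold, cm/s.
#' @param acc_thresh acceleration threshold, cm/s^2.
#' @param min_dur_ms minimum duration of a supra-threshold velocity period.
#' @param search_window_ms window centered on GO searched for the reach.
#' @export
kinematics_params <- function(sg_window_ms = 51, acc_window_ms = 9,
                              sg_order = 3,
                              vel_thresh = 6, acc_thresh = 6,
                              min_dur_ms = 50, search_window_ms = 2000) {
  stopifnot(vel_thresh > 0, acc_thresh > 0)
  list(sg_window_ms = sg_window_ms, acc_window_ms = acc_window_ms,
       sg_order = sg_order,
       vel_thresh = vel_thresh, acc_thresh = acc_thresh,
       min_dur_ms = min_dur_ms, search_window_ms = search_window_ms)
}

## Savitzky-Golay m-th derivative in per-second units, odd window length.
sg_deriv <- function(x, p, n, m, rate_hz) {
  signal::sgolayfilt(x, p = p, n = n, m = m) * rate_hz^m
}

#' Hand velocity and acceleration
#'
#' Upsamples the X/Y records to 1 kHz (linear) when needed, smooths and
#' differentiates them with a Savitzky-Golay filter, and returns the speed
#' (Euclidean norm of the axis velocities, cm/s) and its derivative
#' (cm/s^2).
#'
#' @param x_rec,y_rec hand position [continuous_record()]s (cm).
#' @param params a [kinematics_params()] list.
#' @return list: `speed`, `accel` (numeric, 1 kHz), `rate_hz`, `t0_ms`.
#' @export
hand_kinematics <- function(x_rec, y_rec, params = kinematics_params()) {
  if (length(x_rec$samples) != length(y_rec$samples))
    stop("hand_kinematics: X/Y length mismatch")
  if (x_rec$rate_hz != 1000) x_rec <- resample_record(x_rec, 1000, "linear")
  if (y_rec$rate_hz != 1000) y_rec <- resample_record(y_rec, 1000, "linear")
  n <- params$sg_window_ms
  if (n %% 2 == 0) n <- n + 1
  na <- params$acc_window_ms %||% n
  if (na %% 2 == 0) na <- na + 1
  vx <- sg_deriv(x_rec$samples, params$sg_order, n, 1, 1000)
  vy <- sg_deriv(y_rec$samples, params$sg_order, n, 1, 1000)
  speed <- sqrt(vx^2 + vy^2)
  ## onset detection needs a sharp acceleration estimate: short window on
  ## the lightly smoothed speed
  vxs <- sg_deriv(x_rec$samples, params$sg_order, na, 1, 1000)
  vys <- sg_deriv(y_rec$samples, params$sg_order, na, 1, 1000)
  accel <- sg_deriv(sqrt(vxs^2 + vys^2), params$sg_order, na, 1, 1000)  # cm/s^2
  list(speed = speed, accel = accel, rate_hz = 1000, t0_ms = x_rec$t0_ms)
}

#' Detect reach movement onset around GO
#'
#' Finds periods longer than `min_dur_ms` with speed above `vel_thresh`
#' inside a `search_window_ms` window centered on GO; the onset is the last
#' upward crossing of `acc_thresh` by the acceleration preceding the first
#' such period. Reaction time is onset - GO.
#'
#' @param kin output of [hand_kinematics()].
#' @param go_time_ms GO time in session ms.
#' @param params a [kinematics_params()] list.
#' @return list: `onset_ms` (NA when absent), `rt_ms`, `reason`
#'   (`"ok"`, `"no_velocity_period"`, `"no_acc_crossing"`, `"no_coverage"`).
#' @export
detect_movement_onset <- function(kin, go_time_ms, params = kinematics_params()) {
  half <- params$search_window_ms / 2
  i0 <- round(go_time_ms - half - kin$t0_ms) + 1
  i1 <- round(go_time_ms + half - kin$t0_ms)
  if (i0 < 1 || i1 > length(kin$speed))
    return(list(onset_ms = NA_real_, rt_ms = NA_real_, reason = "no_coverage"))
  v <- kin$speed[i0:i1]; a <- kin$accel[i0:i1]
  above <- v > params$vel_thresh
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths > params$min_dur_ms)
  if (!length(ok))
    return(list(onset_ms = NA_real_, rt_ms = NA_real_, reason = "no_velocity_period"))
  vstart <- starts[ok[1]]
  up <- which(a[-1] > params$acc_thresh & a[-length(a)] <= params$acc_thresh) + 1
  up <- up[up <= vstart]
  if (!length(up))
    return(list(onset_ms = NA_real_, rt_ms = NA_real_, reason = "no_acc_crossing"))
  onset <- kin$t0_ms + (i0 - 1) + (max(up) - 1)
  list(onset_ms = onset, rt_ms = onset - go_time_ms, reason = "ok")
}

#' Redetect reaction times for a whole trial table
#'
#' @param store session store with `hand_x`/`hand_y` records.
#' @param params a [kinematics_params()] list.
#' @return copy of the trial table with `rt_detected_ms`,
#'   `onset_detected_ms` and `onset_reason` columns (input store untouched).
#' @export
detect_session_rts <- function(store, params = kinematics_params()) {
  kin <- hand_kinematics(store$records$hand_x, store$records$hand_y, params)
  tr <- store$trials
  tr$onset_detected_ms <- NA_real_
  tr$rt_detected_ms <- NA_real_
  tr$onset_reason <- NA_character_
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$t_go[i])) next
    d <- detect_movement_onset(kin, tr$t_go[i], params)
    tr$onset_detected_ms[i] <- d$onset_ms
    tr$rt_detected_ms[i] <- d$rt_ms
    tr$onset_reason[i] <- d$reason
  }
  tr
}

#' Per-trial mean hand speed in the delay after each spatial cue
#'
#' @param kin output of [hand_kinematics()].
#' @param trials trial table.
#' @return data frame: trial_id, condition, and mean speed in the 1-s delay
#'   after SC1, SC2, SC3 (`after_sc1` ...), NA when the epoch is missing.
#' @export
micromovement_profile <- function(kin, trials) {
  grab <- function(t_on) {
    vapply(t_on, function(t0) {
      if (is.na(t0)) return(NA_real_)
      i0 <- round(t0 + 300 - kin$t0_ms) + 1  # delay after cue offset
      i1 <- i0 + 999
      if (i0 < 1 || i1 > length(kin$speed)) return(NA_real_)
      mean(kin$speed[i0:i1])
    }, 0)
  }
  data.frame(trial_id = trials$trial_id, condition = trials$condition,
             after_sc1 = grab(trials$t_sc1_on),
             after_sc2 = grab(trials$t_sc2_on),
             after_sc3 = grab(trials$t_sc3_on))
}

#' Hand drift between SC2 onset and 1 s later
#'
#' @param x_rec,y_rec hand position records (cm, any rate).
#' @param trials trial table.
#' @return data frame trial_id, dx_cm, dy_cm (NA when samples missing).
#' @export
drift_offset <- function(x_rec, y_rec, trials) {
  pos_at <- function(rec, t_ms) {
    idx <- round((t_ms - rec$t0_ms) * rec$rate_hz / 1000) + 1
    ifelse(is.na(idx) | idx < 1 | idx > length(rec$samples), NA_real_,
           rec$samples[pmin(pmax(idx, 1), length(rec$samples))])
  }
  t0 <- trials$t_sc2_on
  data.frame(trial_id = trials$trial_id,
             dx_cm = pos_at(x_rec, t0 + 1000) - pos_at(x_rec, t0),
             dy_cm = pos_at(y_rec, t0 + 1000) - pos_at(y_rec, t0))
}
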