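## Gaze simulation: a latent fixation sequence over the 5 task positions
## (center + 4 targets), between-item points and out-of-work-area points,
## with smooth 10-40 ms saccadic transitions, fixational jitter, eyeblink
## artifacts, and a quadratic camera distortion applied when emitting the
## raw "voltage" signal at the camera rate.
##
## Distortion convention: the true screen position (cm) is an exact
## degree-2 polynomial of the raw camera coordinates, so that an offline
## polynomial calibration of the same degree can be exact. The generator
## therefore inverts that polynomial (Newton iteration) when producing the
## raw trace from the latent screen trajectory.

## screen cm -> camera-plane coordinates (inverse of the quadratic map q)
distort_inverse <- function(x, y, c1, c2) {
  u <- x; v <- y
  for (k in 1:8) {
    fx <- u + c1 * u^2 + c2 * u * v - x
    fy <- v + c1 * v^2 + c2 * u * v - y
    j11 <- 1 + 2 * c1 * u + c2 * v; j12 <- c2 * u
    j21 <- c2 * v; j22 <- 1 + 2 * c1 * v + c2 * u
    det <- j11 * j22 - j12 * j21
    u <- u - (j22 * fx - j12 * fy) / det
    v <- v - (-j21 * fx + j11 * fy) / det
  }
  cbind(u, v)
}

## camera-plane -> screen cm (the forward quadratic map)
distort_forward <- function(u, v, c1, c2) {
  cbind(u + c1 * u^2 + c2 * u * v, v + c1 * v^2 + c2 * u * v)
}

#' Simulate eye position signals
#'
#' @param params generator parameters.
#' @param trials trial table.
#' @param seed integer seed.
#' @return list with raw `eye_x`, `eye_y` records (volts, camera rate),
#'   ground-truth fields: `latent_cm` (n_ms x 2 latent screen position),
#'   `label_1k` (per-ms gaze label), `gaze_in_1k` (0/1), `saccades`
#'   (data frame onset/offset/displacement), `blinks` (onset/offset).
#' @export
simulate_eye <- function(params, trials, seed = 1) {
  e <- params$eye
  n_ms <- session_length_ms(params, trials)
  tc <- target_coords_cm()
  with_seed(derive_seed(seed, "eye"), {
    ## --- latent fixation sequence ----------------------------------------
    ## per-ms attended-position preference and out-of-area probability
    p_out <- rep(e$p_out_base, n_ms)
    pref <- rep(0L, n_ms)  # 0 none, 1..5 index into tc (center,UR,LR,LL,UL)
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      if (is.na(tr$t_go)) next
      att <- tr$attended %||% tr$condition
      vidx <- valid_sc_index(att)
      von <- tr[[c("t_sc1_on", "t_sc2_on", "t_sc3_on")[vidx]]]
      vpos <- tr[[c("sc1_pos", "sc2_pos", "sc3_pos")[vidx]]]
      ## focused (gaze In) in the delay before + during the attended SC,
      ## and approaching GO
      w1 <- max(1, von - 800):min(n_ms, von + 500)
      p_out[w1] <- e$p_out_attend
      pref[w1] <- match(vpos, tc$label)
      w2 <- max(1, tr$t_go - 600):min(n_ms, tr$t_go + 600)
      p_out[w2] <- e$p_out_attend
      pref[w2] <- 1L  # center before the reach
      ## each SC draws the gaze while displayed
      for (k in 1:3) {
        on <- tr[[c("t_sc1_on", "t_sc2_on", "t_sc3_on")[k]]]
        wk <- max(1, on):min(n_ms, on + params$task$cue_ms + 150)
        pref[wk] <- match(tr[[c("sc1_pos", "sc2_pos", "sc3_pos")[k]]], tc$label)
        p_out[wk] <- pmin(p_out[wk], 0.2)
      }
    }
    ## fixation-by-fixation walk
    fx_start <- integer(0); fx_end <- integer(0); fx_x <- numeric(0); fx_y <- numeric(0)
    fx_kind <- integer(0)  # 0 out, 1..5 cluster, 6 between
    t_cur <- 1L
    cx <- 0; cy <- 0
    while (t_cur < n_ms) {
      dwell <- round(e$dwell_min_ms + stats::rexp(1, 1 / e$dwell_mean_ms))
      t_end <- min(n_ms, t_cur + dwell)
      u <- stats::runif(1)
      if (u < p_out[t_cur]) {
        kind <- 0L
        x <- e$out_point_cm[1] + stats::rnorm(1, sd = 1.5)
        y <- e$out_point_cm[2] + stats::rnorm(1, sd = 1.5)
      } else if (pref[t_cur] > 0L && u < p_out[t_cur] + 0.60) {
        kind <- pref[t_cur]
        x <- tc$x[kind] + stats::rnorm(1, sd = 0.30)
        y <- tc$y[kind] + stats::rnorm(1, sd = 0.30)
      } else {
        ## in-area exploration: mostly on the task items (fixations cluster
        ## at the 5 positions), occasionally between them
        w <- stats::runif(1)
        if (w < 0.15) {
          kind <- 6L  # between items, inside the work area
          x <- stats::runif(1, -0.55, 0.55) * e$work_half_w_cm
          y <- stats::runif(1, -0.55, 0.55) * e$work_half_h_cm
        } else {
          kind <- if (w < 0.55) 1L else sample(2:5, 1)
          x <- tc$x[kind] + stats::rnorm(1, sd = 0.30)
          y <- tc$y[kind] + stats::rnorm(1, sd = 0.30)
        }
      }
      fx_start <- c(fx_start, t_cur); fx_end <- c(fx_end, t_end)
      fx_x <- c(fx_x, x); fx_y <- c(fx_y, y); fx_kind <- c(fx_kind, kind)
      t_cur <- t_end + 1L
    }
    ## build the latent trace with smooth saccadic transitions
    lat_x <- numeric(n_ms); lat_y <- numeric(n_ms)
    sacc <- list()
    prev_x <- fx_x[1]; prev_y <- fx_y[1]
    lat_x[1:fx_end[1]] <- fx_x[1]; lat_y[1:fx_end[1]] <- fx_y[1]
    for (k in 2:length(fx_x)) {
      d <- sqrt((fx_x[k] - prev_x)^2 + (fx_y[k] - prev_y)^2)
      dur <- round(min(40, max(10, 10 + 2.2 * d)))
      i0 <- fx_start[k]
      i1 <- min(n_ms, i0 + dur - 1L)
      prof <- min_jerk(i1 - i0 + 1L)
      lat_x[i0:i1] <- prev_x + (fx_x[k] - prev_x) * prof
      lat_y[i0:i1] <- prev_y + (fx_y[k] - prev_y) * prof
      if (i1 < fx_end[k]) {
        lat_x[(i1 + 1L):fx_end[k]] <- fx_x[k]
        lat_y[(i1 + 1L):fx_end[k]] <- fx_y[k]
      }
      sacc[[length(sacc) + 1L]] <- data.frame(
        onset_ms = i0 - 1, offset_ms = i1 - 1, displacement_cm = d)
      prev_x <- fx_x[k]; prev_y <- fx_y[k]
    }
    saccades <- do.call(rbind, sacc)
    ## fixational jitter
    lat_x <- lat_x + ar1_process(n_ms, e$fix_tau_ms, e$fix_jitter_cm)
    lat_y <- lat_y + ar1_process(n_ms, e$fix_tau_ms, e$fix_jitter_cm)
    ## --- blinks (restricted to delays) ------------------------------------
    blink_on <- numeric(0)
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      if (is.na(tr$t_go)) next
      delays <- rbind(c(tr$t_sel_off, tr$t_sc1_on), c(tr$t_sc1_off, tr$t_sc2_on),
                      c(tr$t_sc2_off, tr$t_sc3_on), c(tr$t_sc3_off, tr$t_go))
      for (r in seq_len(nrow(delays))) {
        if (stats::runif(1) < e$blink_p_per_delay) {
          t0 <- round(stats::runif(1, delays[r, 1] + 100,
                                   delays[r, 2] - e$blink_plateau_ms - 100))
          blink_on <- c(blink_on, t0)
        }
      }
    }
    blinks <- data.frame(onset_ms = blink_on,
                         offset_ms = blink_on + e$blink_plateau_ms)
    ## --- per-ms ground-truth labels ---------------------------------------
    label <- rep("between", n_ms)
    din <- abs(lat_x) <= e$work_half_w_cm & abs(lat_y) <= e$work_half_h_cm
    label[!din] <- "out"
    for (k in seq_len(nrow(tc))) {
      dk <- sqrt((lat_x - tc$x[k])^2 + (lat_y - tc$y[k])^2)
      hit <- dk < 2 & din
      lab <- if (tc$label[k] == "center") "center" else paste0("target_", tc$label[k])
      label[hit] <- lab
    }
    for (r in seq_len(nrow(blinks))) {
      idx <- max(1, blinks$onset_ms[r] - 8):min(n_ms, blinks$offset_ms[r] + 8)
      label[idx] <- "blink"
    }
    gaze_in <- as.numeric(din & label != "blink")
    ## --- raw emission at the camera rate ----------------------------------
    rate <- e$rate_hz
    t_cam <- seq(0, n_ms - 1, by = 1000 / rate)
    xi <- stats::approx(seq_len(n_ms) - 1, lat_x, xout = t_cam)$y
    yi <- stats::approx(seq_len(n_ms) - 1, lat_y, xout = t_cam)$y
    uv <- distort_inverse(xi, yi, e$distort_c1, e$distort_c2)
    raw_x <- e$gain_v_per_cm * uv[, 1] + e$offset_v[1] + stats::rnorm(length(t_cam), sd = e$noise_v)
    raw_y <- e$gain_v_per_cm * uv[, 2] + e$offset_v[2] + stats::rnorm(length(t_cam), sd = e$noise_v)
    ## blink artifact: plateau at the saturation bound (sharp edges produce
    ## two above-threshold velocity excursions < 150 ms apart)
    for (r in seq_len(nrow(blinks))) {
      i0 <- findInterval(blinks$onset_ms[r], t_cam)
      i1 <- findInterval(blinks$offset_ms[r], t_cam)
      if (i1 > i0 && i0 >= 1) {
        raw_x[i0:i1] <- e$sat_bound_v
        raw_y[i0:i1] <- e$sat_bound_v
      }
    }
    raw_x <- pmin(pmax(raw_x, -e$sat_bound_v), e$sat_bound_v)
    raw_y <- pmin(pmax(raw_y, -e$sat_bound_v), e$sat_bound_v)
    list(eye_x = continuous_record("eye_x", "eye_x", rate, raw_x, units = "V"),
         eye_y = continuous_record("eye_y", "eye_y", rate, raw_y, units = "V"),
         latent_cm = cbind(lat_x, lat_y), label_1k = label,
         gaze_in_1k = gaze_in, saccades = saccades, blinks = blinks)
  })
}
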