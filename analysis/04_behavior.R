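#!/usr/bin/env Rscript
# Stage 4 -- hand kinematics and gaze processing.
#
# Redetects reaction times from the hand trajectories (velocity/acceleration
# thresholds around GO), computes micro-movement profiles per delay,
# calibrates the raw eye signal offline (k-means clusters + degree-2
# polynomial), labels the gaze timeline, and detects blinks and saccades.
# Writes results/trials_rt.csv and results/eye_events.csv.

library(duobeta)

st <- read_session("results/session")

trt <- detect_session_rts(st)
write.csv(trt[, c("trial_id", "outcome", "rt_ms", "rt_detected_ms",
                  "onset_reason")],
          "results/trials_rt.csv", row.names = FALSE)
ok <- !is.na(trt$t_go)
err <- (trt$rt_detected_ms - trt$rt_ms)[ok]
message(sprintf("RT redetection: %d reaches, median |error| %.0f ms, %.0f%% within 10 ms",
                sum(ok), median(abs(err), na.rm = TRUE),
                100 * mean(abs(err) <= 10, na.rm = TRUE)))

eye <- process_eye(st, seed = 1)
message(sprintf("calibration residual at cluster centers: %.3f cm",
                eye$cal$residual_cm))
message("gaze In fraction: ", round(mean(eye$gaze_in_1k), 2),
        "; blinks detected: ", nrow(eye$blinks))

## saccades per trial over the task span
tr <- st$trials[!is.na(st$trials$t_go), ]
rate <- eye$cal$rate_hz
ev <- list()
for (i in seq_len(nrow(tr))) {
  i0 <- round((tr$t_touch[i] - 1200) * rate / 1000) + 1
  i1 <- round((tr$t_go[i] + 400) * rate / 1000)
  e <- detect_saccades(eye$cal$cal_x[i0:i1], eye$cal$cal_y[i0:i1], rate,
                       t0_ms = (i0 - 1) * 1000 / rate)$events
  if (nrow(e)) e$trial_id <- tr$trial_id[i]
  ev[[i]] <- e
}
events <- do.call(rbind, ev)
write.csv(events, "results/eye_events.csv", row.names = FALSE)
message("saccades: ", sum(events$kind == "saccade"),
        "; microsaccades: ", sum(events$kind == "microsaccade"))
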