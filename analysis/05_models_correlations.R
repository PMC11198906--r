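#!/usr/bin/env Rscript
# Stage 5 -- time-resolved models and cross-correlations.
#
# Builds the 7-regressor matrix on 10-ms bins (-1200..5600 ms around the
# selection cue), runs the 247-model BIC scan per band, the shuffle-
# corrected eq-jpsth between hand velocity and low-beta amplitude with its
# diagonal cross-correlogram (most negative lag), and the gaze In/Out lag
# scan against high-beta amplitude. Writes results/bic_winners_<band>.csv
# and results/lag_summary.csv.

library(duobeta)

st <- read_session("results/session")
dom <- read.csv("results/dominance.csv")
tr <- st$trials[st$trials$outcome %in% c("correct", "non_hold"), ]
kin <- hand_kinematics(st$records$hand_x, st$records$hand_y)
eye <- process_eye(st, seed = 1)
n_ms <- st$meta$n_ms
window <- c(-1200, 5600)

reg <- build_regressor_matrix(tr, kin$speed[seq_len(n_ms)], eye$speed_1k,
                              eye$gaze_in_1k, eye$blink_mask_1k)
message(length(reg$bin_centers_ms), " bins x ", nrow(reg$trials), " trials; ",
        nrow(enumerate_models(7)), " candidate models per bin")

lag_rows <- list()
for (bnd in c("low", "high")) {
  site <- dom$site_id[dom$label == bnd][1]
  if (is.na(site)) next
  env <- site_envelope_record(st, site, bnd)
  cutE <- align_and_cut(env, reg$trials, "sel_on", window)
  eb <- bin_matrix(cutE$values, 1000, 10, time0_ms = window[1])
  sc <- bic_scan(eb$values, reg)
  write.csv(sc, sprintf("results/bic_winners_%s.csv", bnd), row.names = FALSE)
  regressors <- c("condition", "direction", "rt", "time_on_task",
                  "hand_velocity", "eye_velocity", "gaze")
  pres <- colMeans(sc[, intersect(names(sc), regressors)])
  message(bnd, " band winner composition (fraction of bins): ",
          paste(names(pres), round(pres, 2), collapse = ", "))

  if (bnd == "low") {
    hrec <- continuous_record("hs", "lfp", 1000, kin$speed[seq_len(n_ms)])
    hb <- bin_matrix(align_and_cut(hrec, reg$trials, "sel_on", window)$values,
                     1000, 10, time0_ms = window[1])
    jp <- eq_jpsth(hb$values, eb$values, n_shuffles = 100, seed = 2,
                   bin_centers_ms = eb$bin_centers_ms)
    cc <- cross_correlogram(jp, split_ms = 1300, max_lag_ms = 400)
    message(sprintf("hand vs low beta: most negative lag %d ms (pre-cue), %d ms (post-cue)",
                    cc$most_negative_lag_ms_pre, cc$most_negative_lag_ms_post))
    lag_rows$hand <- data.frame(coupling = "hand_lowbeta",
                                lag_ms = cc$most_negative_lag_ms_pre)
  } else {
    grec <- continuous_record("gz", "lfp", 1000, eye$gaze_in_1k)
    gb <- bin_matrix(align_and_cut(grec, reg$trials, "sel_on", window)$values,
                     1000, 10, time0_ms = window[1])
    ls <- lag_scan_gaze(eb$values, (gb$values > 0.5) * 1, eb$bin_centers_ms,
                        lags_ms = seq(-1000, 1000, 40))
    message("gaze vs high beta: optimal lag ", ls$optimal_lag_ms,
            " ms (positive = gaze leading)")
    lag_rows$gaze <- data.frame(coupling = "gaze_highbeta",
                                lag_ms = ls$optimal_lag_ms)
  }
}
write.csv(do.call(rbind, lag_rows), "results/lag_summary.csv", row.names = FALSE)
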