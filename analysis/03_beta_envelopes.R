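#!/usr/bin/env Rscript
# Stage 3 -- band-limited Hilbert envelopes pooled by dominance.
#
# Each site contributes its dominant band (16+/-4 Hz or 26+/-5 Hz,
# zero-phase 8th-order Butterworth + Hilbert amplitude, z-scored over the
# session). Trials are cut -1200..5600 ms around the selection cue and
# pooled across sites per band. Writes per-band trial-averaged amplitude
# profiles to results/envelope_profiles.csv.

library(duobeta)

st <- read_session("results/session")
dom <- read.csv("results/dominance.csv")
pools <- pool_by_dominance(st, dom)

prof <- list()
for (bnd in c("low", "high")) {
  pool <- pools[[bnd]]
  if (pool$empty) next
  tr <- st$trials[match(pool$trial_id, st$trials$trial_id), ]
  for (cc in c("blue", "green", "pink")) {
    v <- pool$values[tr$condition == cc, , drop = FALSE]
    prof[[paste(bnd, cc)]] <- data.frame(
      band = bnd, condition = cc, time_ms = pool$time_ms,
      mean_z = colMeans(v), sem = apply(v, 2, sd) / sqrt(nrow(v)))
  }
  message(sprintf("%s band: %d pooled trials from %d sites", bnd,
                  nrow(pool$values), length(unique(pool$site_id))))
}
write.csv(do.call(rbind, prof), "results/envelope_profiles.csv",
          row.names = FALSE)
message("wrote results/envelope_profiles.csv")
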