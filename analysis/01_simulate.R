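#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic sessions used by the downstream stages.
#
# Writes a session store (feather signals + CSV tables) with its ground
# truth sidecar under results/session/. The session carries two beta
# rhythms (low ~16 Hz, high ~26 Hz) whose dominance follows the
# antero-posterior site coordinate, with planted behavioral couplings:
# hand velocity -> low beta (negative, beta lagging by 125 ms),
# gaze In -> high beta (positive, gaze leading by 240 ms), RT -> low beta
# during movement preparation, and a time-on-task amplitude drift.

library(duobeta)

seed <- 1
out <- "results/session"
dir.create("results", showWarnings = FALSE)

params <- generator_params(n_sites = 6, n_trials = 120)
message("simulating ", params$n_sites, " sites x ", params$n_trials,
        " trials (seed ", seed, ") ...")
g <- generate_session(params, seed = seed, dir = out, keep_envelopes = FALSE)

tab <- table(g$store$trials$outcome)
message("outcomes: ", paste(names(tab), tab, collapse = ", "))
message("session written to ", out)
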