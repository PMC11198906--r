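## Task structure: delayed match-to-sample with fixed cue order.
##
## Trial timeline (ms, relative to central touch):
##   touch 0 -> hold 1000 -> SEL on (300) -> delay 1000 -> SC1 on (300)
##   -> delay 1000 -> SC2 on (300) -> delay 1000 -> SC3 on (300)
##   -> delay 1000 -> GO -> movement onset at GO + RT.
## Conditions blue/green/pink make SC1/SC2/SC3 the valid cue respectively.

CONDITIONS <- c("blue", "green", "pink")
POSITIONS <- c("UR", "LR", "LL", "UL")

#' Number of unique trial types
#'
#' Enumerates all (condition, SC1, SC2, SC3 position) combinations.
#' @param n_conditions number of color conditions.
#' @param n_positions number of peripheral target positions in use.
#' @return integer count (e.g. 3 conditions x 4 positions -> 192).
#' @export
count_unique_trial_types <- function(n_conditions = 3, n_positions = 4) {
  g <- expand.grid(cond = seq_len(n_conditions), p1 = seq_len(n_positions),
                   p2 = seq_len(n_positions), p3 = seq_len(n_positions))
  nrow(unique(g))
}

## Which SC index is valid for a condition.
valid_sc_index <- function(condition) match(condition, CONDITIONS)

#' Generate a trial sequence with event times and outcomes
#'
#' Conditions are presented in blocks of approximately `block_size` unique
#' trials, cycling across the three conditions; within each block the unique
#' trials are drawn pseudo-randomly. Error outcomes (aborted before GO,
#' distractor-error reaches, broken target hold) are injected at the
#' configured rates. Reaction times are lognormal with a time-on-task drift
#' (+0.1 sd per session third).
#'
#' @param params a [generator_params()] list (uses `$task` and `$hand`).
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @return trial table data frame with the columns in `TRIAL_COLUMNS`, plus
#'   planted helper columns `rt_true_ms` and `trial_frac` (time-on-task).
#' @export
generate_trial_sequence <- function(params, seed = 1) {
  tk <- params$task
  stopifnot(tk$n_conditions == 3, tk$n_positions %in% c(3, 4))
  pos <- POSITIONS[seq_len(tk$n_positions)]
  n_trials <- params$n_trials
  if (n_trials < tk$block_size) stop("n_trials smaller than one block")
  with_seed(derive_seed(seed, "trials"), {
    conds <- character(0)
    bi <- 0L
    while (length(conds) < n_trials) {
      conds <- c(conds, rep(CONDITIONS[bi %% 3 + 1], tk$block_size))
      bi <- bi + 1L
    }
    conds <- conds[seq_len(n_trials)]
    sc <- matrix(sample(pos, 3 * n_trials, replace = TRUE), ncol = 3)
    vidx <- valid_sc_index(conds)
    valid <- sc[cbind(seq_len(n_trials), vidx)]
    ambiguous <- logical(n_trials)
    for (i in seq_len(n_trials))
      ambiguous[i] <- any(sc[i, -vidx[i]] == valid[i])
    ## outcomes
    u <- stats::runif(n_trials)
    outcome <- rep("correct", n_trials)
    outcome[u < tk$p_abort] <- "aborted"
    sel <- u >= tk$p_abort & u < tk$p_abort + tk$p_distractor_error
    outcome[sel] <- "distractor_error"
    sel2 <- u >= tk$p_abort + tk$p_distractor_error &
      u < tk$p_abort + tk$p_distractor_error + tk$p_non_hold
    outcome[sel2] <- "non_hold"
    attended <- conds
    for (i in which(outcome == "distractor_error"))
      attended[i] <- sample(setdiff(CONDITIONS, conds[i]), 1)
    ## reaction times: lognormal, +0.1 sd per session third (time-on-task)
    h <- params$hand
    third <- floor(3 * (seq_len(n_trials) - 1) / n_trials)  # 0,1,2
    mu <- log(h$rt_mean_ms) + 0.1 * h$rt_sdlog * third
    rt <- stats::rlnorm(n_trials, meanlog = mu, sdlog = h$rt_sdlog)
    rt <- pmin(pmax(round(rt), 160), 490)
    ## event times
    iti <- tk$iti_ms
    span <- tk$pre_touch_ms + tk$hold_ms + 4 * (tk$cue_ms + tk$delay_ms) +
      tk$post_go_ms + iti
    touch <- tk$pre_touch_ms + (seq_len(n_trials) - 1) * span
    sel_on <- touch + tk$hold_ms
    sel_off <- sel_on + tk$cue_ms
    sc1_on <- sel_off + tk$delay_ms; sc1_off <- sc1_on + tk$cue_ms
    sc2_on <- sc1_off + tk$delay_ms; sc2_off <- sc2_on + tk$cue_ms
    sc3_on <- sc2_off + tk$delay_ms; sc3_off <- sc3_on + tk$cue_ms
    go <- sc3_off + tk$delay_ms
    move_on <- go + rt
    tr <- data.frame(
      trial_id = seq_len(n_trials), condition = conds,
      sc1_pos = sc[, 1], sc2_pos = sc[, 2], sc3_pos = sc[, 3],
      valid_target = valid, outcome = outcome, attended = attended,
      ambiguous = ambiguous,
      t_touch = touch, t_sel_on = sel_on, t_sel_off = sel_off,
      t_sc1_on = sc1_on, t_sc1_off = sc1_off, t_sc2_on = sc2_on,
      t_sc2_off = sc2_off, t_sc3_on = sc3_on, t_sc3_off = sc3_off,
      t_go = go, t_move_on = move_on, rt_ms = rt,
      rt_true_ms = rt, trial_frac = (seq_len(n_trials) - 1) / max(1, n_trials - 1),
      stringsAsFactors = FALSE)
    ## aborted trials: hold lost during the cue sequence; later events missing
    ab <- which(outcome == "aborted")
    if (length(ab)) {
      abort_t <- touch[ab] + round(stats::runif(length(ab), tk$hold_ms, 4500))
      for (k in seq_along(ab)) {
        i <- ab[k]
        for (colnm in c("t_sel_on", "t_sel_off", "t_sc1_on", "t_sc1_off",
                        "t_sc2_on", "t_sc2_off", "t_sc3_on", "t_sc3_off",
                        "t_go", "t_move_on"))
          if (!is.na(tr[[colnm]][i]) && tr[[colnm]][i] > abort_t[k])
            tr[[colnm]][i] <- NA
        tr$rt_ms[i] <- NA; tr$rt_true_ms[i] <- NA
      }
    }
    ## the reach goes to the attended SC's position (equals the valid target
    ## except on distractor errors)
    aidx <- valid_sc_index(tr$attended)
    tr$reach_target <- sc[cbind(seq_len(n_trials), aidx)]
    tr
  })
}

## target geometry (cm on the display): center + 4 diagonal targets at
## 9 cm distance (+-9/sqrt(2) on each axis)
target_coords_cm <- function() {
  d <- 9 / sqrt(2)
  data.frame(label = c("center", POSITIONS),
             x = c(0, d, d, -d, -d), y = c(0, d, -d, -d, d))
}
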