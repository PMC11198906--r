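## End-to-end pipeline driver: simulate (optional) -> spectral -> envelope
## -> hand -> eye -> statistics -> decoding, with a machine-readable
## results file. Each stage consumes the in-memory outputs of the previous
## ones; a missing dependency raises an error naming the stage.

#' Run the analysis pipeline on a session
#'
#' @param config list with fields:
#'   \describe{
#'     \item{stages}{character vector among `simulate`, `spectral`,
#'       `envelope`, `hand`, `eye`, `stats`, `decode`.}
#'     \item{session_dir}{existing session directory (when not simulating).}
#'     \item{params}{[generator_params()] for the simulate stage.}
#'     \item{seed}{master seed.}
#'     \item{out_dir}{output directory for `results.json` and CSV tables
#'       (optional).}
#'   }
#' @return list of stage outputs plus `results` (the summary list written
#'   to JSON).
#' @export
run_pipeline <- function(config) {
  stages <- config$stages %||% c("simulate", "spectral", "envelope", "hand",
                                 "eye", "stats", "decode")
  seed <- config$seed %||% 1
  need <- function(x, stage, dep)
    if (is.null(x)) stop("run_pipeline: stage '", stage, "' requires '", dep, "'")
  out <- list()
  results <- list(seed = seed, stages = stages)

  if ("simulate" %in% stages) {
    sim <- generate_session(config$params %||% generator_params(), seed = seed)
    out$store <- sim$store; out$truth <- sim$truth
  } else if (!is.null(config$session_dir)) {
    out$store <- read_session(config$session_dir)
  }
  need(out$store, stages[1], "a session (simulate stage or session_dir)")

  if ("spectral" %in% stages) {
    out$dominance <- session_dominance_table(out$store)
    results$n_low_sites <- sum(out$dominance$label == "low")
    results$n_high_sites <- sum(out$dominance$label == "high")
    if (nrow(out$dominance) >= 5 && stats::sd(out$dominance$ap_coord) > 0) {
      ac <- dominance_ap_correlation(out$dominance)
      results$dominance_ap_rho <- ac$rho
      results$dominance_ap_p <- ac$p
    }
  }
  if ("envelope" %in% stages) {
    need(out$dominance, "envelope", "spectral")
    out$pools <- pool_by_dominance(out$store, out$dominance)
    results$n_pooled_low <- if (!out$pools$low$empty) nrow(out$pools$low$values) else 0
    results$n_pooled_high <- if (!out$pools$high$empty) nrow(out$pools$high$values) else 0
  }
  if ("hand" %in% stages) {
    out$trials_rt <- detect_session_rts(out$store)
    ok <- !is.na(out$trials_rt$rt_detected_ms) & !is.na(out$trials_rt$rt_ms)
    results$rt_detection_rate <- mean(!is.na(
      out$trials_rt$rt_detected_ms[!is.na(out$trials_rt$t_go)]))
    results$rt_median_abs_err_ms <-
      stats::median(abs(out$trials_rt$rt_detected_ms - out$trials_rt$rt_ms)[ok])
    out$kin <- hand_kinematics(out$store$records$hand_x, out$store$records$hand_y)
  }
  if ("eye" %in% stages) {
    out$eye <- process_eye(out$store, seed = seed)
    results$n_blinks <- nrow(out$eye$blinks)
    results$calibration_residual_cm <- out$eye$cal$residual_cm
  }
  if ("stats" %in% stages) {
    need(out$pools, "stats", "envelope")
    need(out$kin, "stats", "hand")
    need(out$eye, "stats", "eye")
    tr <- out$store$trials
    keep <- tr$outcome %in% c("correct", "non_hold")
    reg <- build_regressor_matrix(
      tr[keep, ], out$kin$speed[seq_len(out$eye$n_ms)],
      out$eye$speed_1k, out$eye$gaze_in_1k,
      out$eye$blink_mask_1k)
    out$reg <- reg
    results$n_bins <- length(reg$bin_centers_ms)
    results$n_models <- nrow(enumerate_models(7))
  }
  if ("decode" %in% stages) {
    need(out$pools, "decode", "envelope")
    dec <- list()
    for (bnd in c("low", "high")) {
      pool <- out$pools[[bnd]]
      if (pool$empty) next
      tr <- out$store$trials[match(pool$trial_id, out$store$trials$trial_id), ]
      ok <- !tr$ambiguous
      fz <- featurize_trials(pool$values[ok, , drop = FALSE], pool$time_ms)
      y <- factor(tr$condition[ok][fz$kept], levels = CONDITIONS)
      if (min(table(y)) >= 10) {
        dr <- train_decode(fz$X, y, seed = seed)
        dec[[bnd]] <- dr
        results[[paste0("decode_", bnd, "_accuracy")]] <- dr$mean_accuracy
      }
    }
    out$decode <- dec
  }
  out$results <- results
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(out$dominance))
      utils::write.csv(out$dominance, file.path(config$out_dir, "dominance.csv"),
                       row.names = FALSE)
  }
  out
}
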