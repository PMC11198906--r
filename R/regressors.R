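## Time-resolved linear-model machinery: the 7-regressor design
## (condition, movement direction, RT, time-on-task, hand velocity, eye
## velocity, gaze In/Out) on 10-ms bins over -1200..5600 ms around the
## selection cue, exhaustive model enumeration with pairwise interactions,
## and the per-bin BIC scan.

REGRESSOR_NAMES <- c("condition", "direction", "rt", "time_on_task",
                     "hand_velocity", "eye_velocity", "gaze")

#' Bin a trials x time matrix into non-overlapping windows
#'
#' @param values trials x time matrix at `rate_hz`.
#' @param rate_hz sampling rate; @param bin_ms bin width.
#' @param mask optional logical matrix (TRUE = missing); a bin cell is
#'   masked when any sample in it is masked.
#' @return list `values` (trials x bins means), `mask`, `bin_centers_ms`
#'   (relative to the matrix's first column at `time0_ms`).
#' @export
bin_matrix <- function(values, rate_hz, bin_ms = 10, mask = NULL, time0_ms = 0) {
  spb <- round(bin_ms * rate_hz / 1000)
  nb <- floor(ncol(values) / spb)
  idx <- rep(seq_len(nb), each = spb)
  vb <- matrix(NA_real_, nrow(values), nb)
  mb <- matrix(FALSE, nrow(values), nb)
  for (b in seq_len(nb)) {
    cols <- ((b - 1) * spb + 1):(b * spb)
    vb[, b] <- rowMeans(values[, cols, drop = FALSE])
    if (!is.null(mask)) mb[, b] <- rowSums(mask[, cols, drop = FALSE]) > 0
  }
  list(values = vb, mask = mb,
       bin_centers_ms = time0_ms + (seq_len(nb) - 0.5) * bin_ms)
}

#' Build the regressor matrix for the time-resolved model scan
#'
#' Continuous behavior streams are cut around the alignment event and
#' averaged per 10-ms bin; gaze is binarized In/Out; single-trial bins with
#' a blink or saturated eye signal are masked; trials missing a whole
#' signal are dropped from all bins. RT is z-scored within the session.
#'
#' @param trials trial table (already filtered to the included outcomes).
#' @param hand_speed_1k session-long hand speed (cm/s, 1 kHz).
#' @param eye_speed_1k session-long eye speed (cm/s, 1 kHz), or NULL.
#' @param gaze_in_1k session-long gaze In/Out indicator (0/1, 1 kHz).
#' @param eye_mask_1k logical, TRUE where the eye signal is unusable
#'   (blink/saturation).
#' @param align_event,window_ms,bin_ms binning scheme (defaults: selection
#'   cue, -1200..5600 ms, 10-ms bins -> 680 bins).
#' @return list of class `regressor_matrix`: `trials` (the retained rows),
#'   `condition`, `direction` (factors), `rt_z`, `time_on_task` (per
#'   trial), `hand_velocity`, `eye_velocity` (trials x bins), `gaze`
#'   (trials x bins, 0/1), `mask` (trials x bins), `bin_centers_ms`.
#' @export
build_regressor_matrix <- function(trials, hand_speed_1k, eye_speed_1k,
                                   gaze_in_1k, eye_mask_1k = NULL,
                                   align_event = "sel_on",
                                   window_ms = c(-1200, 5600), bin_ms = 10) {
  n_ms <- length(hand_speed_1k)
  as_rec <- function(x, mask = NULL) continuous_record("tmp", "lfp", 1000, x, mask = mask)
  cut_stream <- function(x, mask = NULL) {
    cut <- align_and_cut(as_rec(x, mask), trials, align_event, window_ms)
    cut
  }
  hand_cut <- cut_stream(hand_speed_1k)
  keep_ids <- hand_cut$trial_ids
  if (!length(keep_ids)) stop("build_regressor_matrix: all trials masked")
  have_eye <- !is.null(eye_speed_1k) && !is.null(gaze_in_1k)
  eye_cut <- gaze_cut <- NULL
  if (have_eye) {
    eye_cut <- cut_stream(eye_speed_1k, eye_mask_1k)
    gaze_cut <- cut_stream(gaze_in_1k, eye_mask_1k)
    keep_ids <- intersect(keep_ids, eye_cut$trial_ids)
  }
  tr <- trials[match(keep_ids, trials$trial_id), ]
  sd_rt <- stats::sd(tr$rt_ms)
  if (!is.finite(sd_rt) || sd_rt == 0)
    stop("build_regressor_matrix: zero RT variance, cannot z-score")
  sel <- function(cut) {
    i <- match(keep_ids, cut$trial_ids)
    list(values = cut$values[i, , drop = FALSE], mask = cut$mask[i, , drop = FALSE])
  }
  h <- sel(hand_cut)
  hb <- bin_matrix(h$values, 1000, bin_ms, h$mask, window_ms[1])
  if (have_eye) {
    e <- sel(eye_cut); g <- sel(gaze_cut)
    eb <- bin_matrix(e$values, 1000, bin_ms, e$mask, window_ms[1])
    gb <- bin_matrix(g$values, 1000, bin_ms, g$mask, window_ms[1])
    gb$values <- (gb$values > 0.5) * 1
    mask <- hb$mask | eb$mask | gb$mask
  } else {
    eb <- gb <- NULL
    mask <- hb$mask
  }
  structure(list(
    trials = tr,
    condition = factor(tr$condition, levels = CONDITIONS),
    direction = factor(tr$reach_target %||% tr$valid_target, levels = POSITIONS),
    rt_z = (tr$rt_ms - mean(tr$rt_ms)) / sd_rt,
    time_on_task = tr$trial_frac %||% ((seq_len(nrow(tr)) - 1) / max(1, nrow(tr) - 1)),
    hand_velocity = hb$values,
    eye_velocity = if (have_eye) eb$values,
    gaze = if (have_eye) gb$values,
    mask = mask,
    bin_centers_ms = hb$bin_centers_ms), class = "regressor_matrix")
}

#' Enumerate all candidate model specifications
#'
#' All nonempty subsets of the regressors, plus, for each subset of two or
#' more, the same subset with all of its pairwise interactions. For 7
#' regressors this gives 247 models.
#'
#' @param n_regressors number of regressors (default 7).
#' @param names regressor names.
#' @return data frame with list-column `subset` and flag
#'   `with_interactions`; one row per model.
#' @export
enumerate_models <- function(n_regressors = 7,
                             names = REGRESSOR_NAMES[seq_len(n_regressors)]) {
  stopifnot(n_regressors >= 1)
  specs <- list(); wi <- logical(0)
  for (m in seq_len(2^n_regressors - 1)) {
    subset <- names[bitwAnd(m, 2^(seq_len(n_regressors) - 1)) > 0]
    specs[[length(specs) + 1L]] <- subset; wi <- c(wi, FALSE)
    if (length(subset) >= 2) {
      specs[[length(specs) + 1L]] <- subset; wi <- c(wi, TRUE)
    }
  }
  out <- data.frame(spec_id = seq_along(specs), with_interactions = wi)
  out$subset <- specs
  out
}

## Build the full per-bin design blocks once: a named list of column-index
## groups into the assembled design matrix (intercept excluded).
design_blocks <- function(reg, bin) {
  n <- nrow(reg$trials)
  cols <- list()
  cm <- stats::model.matrix(~condition, data.frame(condition = reg$condition))[, -1, drop = FALSE]
  dm <- stats::model.matrix(~direction, data.frame(direction = reg$direction))[, -1, drop = FALSE]
  cols$condition <- cm
  cols$direction <- dm
  cols$rt <- matrix(reg$rt_z, ncol = 1)
  cols$time_on_task <- matrix(reg$time_on_task, ncol = 1)
  cols$hand_velocity <- matrix(reg$hand_velocity[, bin], ncol = 1)
  if (!is.null(reg$eye_velocity)) {
    cols$eye_velocity <- matrix(reg$eye_velocity[, bin], ncol = 1)
    cols$gaze <- matrix(reg$gaze[, bin], ncol = 1)
  }
  cols
}

## interaction columns between two blocks: all pairwise column products
interact_cols <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), ncol(A) * ncol(B))
  k <- 0
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    k <- k + 1; out[, k] <- A[, i] * B[, j]
  }
  out
}

#' Per-bin BIC model scan
#'
#' Fits every candidate model by OLS in every 10-ms bin on a common trial
#' set (rows unmasked in that bin) and selects the winner by the Gaussian
#' BIC `n log(RSS/n) + k log(n)` with `k` counting all coefficients
#' including the intercept. Ties prefer fewer parameters, then the earlier
#' spec in enumeration order.
#'
#' @param y_bins trials x bins response matrix (binned beta amplitude).
#' @param reg a `regressor_matrix` (same trial rows).
#' @param specs model list from [enumerate_models()]; defaults to all
#'   models over the regressors available in `reg`.
#' @return data frame per bin: `bin`, `bin_center_ms`, `spec_id`, `n`,
#'   `k`, `bic`, `with_interactions`, and one logical column per regressor
#'   (present in the winning model's subset).
#' @export
bic_scan <- function(y_bins, reg, specs = NULL) {
  have <- names(design_blocks(reg, 1))
  if (is.null(specs)) specs <- enumerate_models(length(have), have)
  nb <- ncol(y_bins)
  res <- vector("list", nb)
  for (b in seq_len(nb)) {
    keep <- !reg$mask[, b] & is.finite(y_bins[, b])
    n <- sum(keep)
    blocks <- design_blocks(reg, b)
    blocks <- lapply(blocks, function(m) m[keep, , drop = FALSE])
    y <- y_bins[keep, b]
    ## assemble main columns and pairwise interaction columns
    pair_names <- utils::combn(have, 2, simplify = FALSE)
    inter <- lapply(pair_names, function(p) interact_cols(blocks[[p[1]]], blocks[[p[2]]]))
    names(inter) <- vapply(pair_names, paste, "", collapse = ":")
    X <- cbind(1, do.call(cbind, blocks), do.call(cbind, inter))
    main_idx <- list(); off <- 1L
    for (nm in have) {
      main_idx[[nm]] <- off + seq_len(ncol(blocks[[nm]]))
      off <- off + ncol(blocks[[nm]])
    }
    int_idx <- list()
    for (nm in names(inter)) {
      int_idx[[nm]] <- off + seq_len(ncol(inter[[nm]]))
      off <- off + ncol(inter[[nm]])
    }
    G <- crossprod(X); hvec <- crossprod(X, y); yty <- sum(y * y)
    ## intercept-only baseline: the "no regressor" outcome a null bin
    ## should select
    rss0 <- max(sum((y - mean(y))^2), 1e-12)
    best <- list(spec_id = 0L, bic = n * log(rss0 / n) + 1 * log(n), k = 1L,
                 subset = character(0), wi = FALSE)
    for (s in seq_len(nrow(specs))) {
      subset <- specs$subset[[s]]
      idx <- c(1L, unlist(main_idx[subset], use.names = FALSE))
      if (specs$with_interactions[s]) {
        for (key in names(int_idx)) {
          parts <- strsplit(key, ":", fixed = TRUE)[[1]]
          if (all(parts %in% subset)) idx <- c(idx, int_idx[[key]])
        }
      }
      k <- length(idx)
      if (n <= k) next
      sol <- tryCatch(solve(G[idx, idx, drop = FALSE], hvec[idx]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      rss <- max(yty - sum(hvec[idx] * sol), 1e-12)
      bic <- n * log(rss / n) + k * log(n)
      if (is.null(best) || bic < best$bic - 1e-9 ||
          (abs(bic - best$bic) <= 1e-9 && k < best$k)) {
        best <- list(spec_id = specs$spec_id[s], bic = bic, k = k,
                     subset = subset, wi = specs$with_interactions[s])
      }
    }
    row <- data.frame(bin = b, bin_center_ms = reg$bin_centers_ms[b],
                      spec_id = best$spec_id, n = n, k = best$k, bic = best$bic,
                      with_interactions = best$wi)
    for (nm in have) row[[nm]] <- nm %in% best$subset
    res[[b]] <- row
  }
  do.call(rbind, res)
}
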