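## Random-forest decoding of the color condition from temporal profiles of
## beta amplitude or behavior, with shuffle-based chance bounds and
## error-trial prediction.

RF_HYPER <- list(num_trees = 200, mtry = 3, min_node_size = 3, max_depth = 80)

#' Featurize trial-aligned signals into per-bin means
#'
#' Averages each trial's signal in 50-ms non-overlapping bins over the
#' given span. Masked cells are imputed with the trial mean (flagged);
#' trials with more than 50% masked samples are dropped.
#'
#' @param values trials x time matrix (1 kHz).
#' @param time_ms column times (ms relative to the alignment event).
#' @param span `c(start, stop)` ms within `time_ms`.
#' @param bin_ms feature bin width.
#' @param mask optional trials x time logical mask.
#' @return list: `X` (trials x features), `kept` (row indices into the
#'   input), `imputed` (logical per kept trial), `bin_centers_ms`.
#' @export
featurize_trials <- function(values, time_ms, span = NULL, bin_ms = 50,
                             mask = NULL) {
  if (is.null(span)) span <- c(min(time_ms), max(time_ms) + diff(time_ms[1:2]))
  cols <- which(time_ms >= span[1] & time_ms < span[2])
  if (!length(cols)) stop("featurize_trials: span outside the matrix")
  v <- values[, cols, drop = FALSE]
  m <- if (is.null(mask)) matrix(FALSE, nrow(v), ncol(v)) else mask[, cols, drop = FALSE]
  frac_masked <- rowMeans(m)
  kept <- which(frac_masked <= 0.5)
  v <- v[kept, , drop = FALSE]; m <- m[kept, , drop = FALSE]
  v[m] <- NA
  b <- bin_matrix(v, 1000, bin_ms, NULL, time_ms[cols[1]])
  X <- b$values
  imputed <- rep(FALSE, nrow(X))
  for (i in seq_len(nrow(X))) {
    bad <- !is.finite(X[i, ])
    if (any(bad)) {
      X[i, bad] <- mean(X[i, !bad])
      imputed[i] <- TRUE
    }
  }
  colnames(X) <- sprintf("bin%03d", seq_len(ncol(X)))
  list(X = X, kept = kept, imputed = imputed, bin_centers_ms = b$bin_centers_ms)
}

## stratified 60/40 split with class balance (by downsampling) in training
balanced_split <- function(y, train_frac = 0.6) {
  idx_by <- split(seq_along(y), y)
  train <- unlist(lapply(idx_by, function(ix) sample(ix, round(train_frac * length(ix)))))
  n_min <- min(vapply(split(train, y[train]), length, 0L))
  train_bal <- unlist(lapply(split(train, y[train]), function(ix) sample(ix, n_min)))
  list(train = sort(train_bal), test = setdiff(seq_along(y), sort(train)))
}

#' Train and evaluate a random-forest condition decoder
#'
#' Random forest (200 trees, mtry 3, minimum node size 3, depth cap 80)
#' over `n_splits` stratified 60/40 train/test splits with class-balanced
#' training sets; the row-normalized confusion matrix is averaged across
#' splits. A final model trained on all trials is returned for error-trial
#' prediction.
#'
#' @param X trials x features; @param y condition labels (factor).
#' @param n_splits number of train/test splits.
#' @param seed RNG seed.
#' @return list of class `decode_result`: `confusion` (rows sum to 1),
#'   `accuracy` (per class), `mean_accuracy`, `n_splits`, `model`
#'   (ranger fit on all trials), `levels`.
#' @export
train_decode <- function(X, y, n_splits = 20, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 3) stop("train_decode: need >= 3 classes")
  if (min(table(y)) < 10) stop("train_decode: class with < 10 trials")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  lev <- levels(y)
  conf <- matrix(0, nlevels(y), nlevels(y), dimnames = list(lev, lev))
  with_seed(derive_seed(seed, "decode"), {
    for (s in seq_len(n_splits)) {
      sp <- balanced_split(y)
      fit <- ranger::ranger(x = X[sp$train, , drop = FALSE], y = y[sp$train],
                            num.trees = RF_HYPER$num_trees,
                            mtry = min(RF_HYPER$mtry, ncol(X)),
                            min.node.size = RF_HYPER$min_node_size,
                            max.depth = RF_HYPER$max_depth,
                            num.threads = 1, verbose = FALSE,
                            seed = derive_seed(seed, paste0("rf", s)))
      pred <- stats::predict(fit, data = X[sp$test, , drop = FALSE],
                             num.threads = 1)$predictions
      tab <- table(factor(y[sp$test], lev), factor(pred, lev))
      conf <- conf + tab / pmax(rowSums(tab), 1)
    }
    conf <- conf / n_splits
    conf <- conf / rowSums(conf)
    ## final model (for error-trial prediction): class-balanced like the
    ## split training sets
    n_min <- min(table(y))
    bal <- unlist(lapply(split(seq_along(y), y), function(ix) sample(ix, n_min)))
    final <- ranger::ranger(x = X[bal, , drop = FALSE], y = y[bal],
                            num.trees = RF_HYPER$num_trees,
                            mtry = min(RF_HYPER$mtry, ncol(X)),
                            min.node.size = RF_HYPER$min_node_size,
                            max.depth = RF_HYPER$max_depth,
                            num.threads = 1, verbose = FALSE,
                            seed = derive_seed(seed, "rf_final"))
    structure(list(confusion = conf, accuracy = diag(conf),
                   mean_accuracy = mean(diag(conf)), n_splits = n_splits,
                   model = final, levels = lev), class = "decode_result")
  })
}

#' Shuffle-label chance bound
#'
#' Maximum test accuracy over `n_shuffles` label-shuffled train/test fits;
#' real accuracies are compared against this bound.
#'
#' @param X,y as in [train_decode()].
#' @param n_shuffles number of shuffled splits.
#' @param seed RNG seed.
#' @return list: `bound` (max shuffled accuracy), `accuracies`.
#' @export
chance_level <- function(X, y, n_shuffles = 100, seed = 1) {
  y <- droplevels(factor(y))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  acc <- numeric(n_shuffles)
  with_seed(derive_seed(seed, "chance"), {
    for (s in seq_len(n_shuffles)) {
      ys <- sample(y)
      sp <- balanced_split(ys)
      fit <- ranger::ranger(x = X[sp$train, , drop = FALSE], y = ys[sp$train],
                            num.trees = RF_HYPER$num_trees,
                            mtry = min(RF_HYPER$mtry, ncol(X)),
                            min.node.size = RF_HYPER$min_node_size,
                            max.depth = RF_HYPER$max_depth,
                            num.threads = 1, verbose = FALSE,
                            seed = derive_seed(seed, paste0("ch", s)))
      pred <- stats::predict(fit, data = X[sp$test, , drop = FALSE],
                             num.threads = 1)$predictions
      acc[s] <- mean(pred == ys[sp$test])
    }
  })
  list(bound = max(acc), accuracies = acc)
}

#' Predict distractor-error trials with a decoder trained on correct trials
#'
#' @param decode a `decode_result` (model trained on unambiguous correct
#'   trials).
#' @param X_err error-trial features.
#' @param attended attended-distractor labels (what the animal did).
#' @param instructed selection-cue labels (what it should have done).
#' @return list: `accuracy_attended`, `accuracy_instructed`, `n_trials`,
#'   `status` (`"ok"` or `"no_error_trials"`).
#' @export
predict_error_trials <- function(decode, X_err, attended, instructed) {
  if (is.null(X_err) || nrow(X_err) == 0)
    return(list(accuracy_attended = NA_real_, accuracy_instructed = NA_real_,
                n_trials = 0L, status = "no_error_trials"))
  colnames(X_err) <- decode$model$forest$independent.variable.names
  pred <- stats::predict(decode$model, data = X_err, num.threads = 1)$predictions
  list(accuracy_attended = mean(as.character(pred) == as.character(attended)),
       accuracy_instructed = mean(as.character(pred) == as.character(instructed)),
       n_trials = nrow(X_err), status = "ok")
}
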