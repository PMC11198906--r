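## Per-bin single-regressor models, scramble importance, factor splits,
## gaze-lag scans and spike-field phase locking.

#' Per-bin single-regressor linear models
#'
#' Fits one regressor per 10-ms bin against the binned beta amplitude. The
#' condition regressor is fitted across conditions; any other regressor is
#' fitted within each condition separately (set `condition = NULL` to fit
#' across all trials). Significance is the F test of the regressor
#' (equivalently, the model ANOVA for a single term).
#'
#' @param y_bins trials x bins response.
#' @param x per-trial vector (factor or numeric) or trials x bins matrix
#'   (time-varying regressor, taken bin by bin).
#' @param condition optional per-trial condition factor (for the
#'   within-condition convention).
#' @param mask optional trials x bins logical mask (TRUE = exclude).
#' @param min_trials bins with fewer usable trials are masked.
#' @return list: `p` (bins x groups matrix of p-values; one column per
#'   condition or a single `all` column), `beta` (matching slope/effect
#'   sign for numeric regressors; NA for factors).
#' @export
single_regressor_lm <- function(y_bins, x, condition = NULL, mask = NULL,
                                min_trials = 10) {
  nb <- ncol(y_bins)
  groups <- if (is.null(condition)) list(all = seq_len(nrow(y_bins)))
            else split(seq_len(nrow(y_bins)), condition)
  p <- matrix(NA_real_, nb, length(groups),
              dimnames = list(NULL, names(groups)))
  beta <- p
  xmat <- is.matrix(x)
  for (b in seq_len(nb)) {
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      xb <- if (xmat) x[rows, b] else x[rows]
      yb <- y_bins[rows, b]
      ok <- is.finite(yb) & (if (is.factor(xb)) !is.na(xb) else is.finite(xb))
      if (!is.null(mask)) ok <- ok & !mask[rows, b]
      if (sum(ok) < min_trials) next
      xb <- xb[ok]; yb <- yb[ok]
      if (is.factor(xb)) xb <- droplevels(xb)
      if ((is.factor(xb) && nlevels(xb) < 2) ||
          (!is.factor(xb) && stats::sd(xb) == 0)) next
      fit <- stats::lm(yb ~ xb)
      a <- stats::anova(fit)
      p[b, gi] <- a$`Pr(>F)`[1]
      if (!is.factor(xb)) beta[b, gi] <- stats::coef(fit)[2]
    }
  }
  list(p = p, beta = beta)
}

#' Significance-gradient coding of per-bin p values
#'
#' Buckets p values at thresholds 1e-2 .. 1e-8 (figure-shading convention);
#' 0 means not significant.
#' @param p numeric vector/matrix of p values.
#' @export
significance_gradient <- function(p) {
  br <- 10^(-(2:8))
  g <- p * 0
  for (k in seq_along(br)) g[!is.na(p) & p <= br[k]] <- k
  g[is.na(p)] <- NA
  g
}

#' Scramble importance of regressors in a multi-regressor model
#'
#' For each bin and regressor: R^2 of the full OLS model minus the mean
#' R^2 over `n_perm` refits with that regressor's values permuted across
#' trials. A regressor is significant in a bin when the full-model R^2
#' exceeds all permuted R^2 values.
#'
#' @param y_bins trials x bins response.
#' @param regs named list of regressors (per-trial vectors or trials x
#'   bins matrices).
#' @param mask optional trials x bins mask.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list of per-regressor lists with `delta_r2` (bins) and
#'   `significant` (bins, logical), plus `r2_full` (bins).
#' @export
scramble_importance <- function(y_bins, regs, mask = NULL, n_perm = 100,
                                seed = 1) {
  nb <- ncol(y_bins); n <- nrow(y_bins)
  r2 <- function(X, y) {
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  col_of <- function(r, rows, b) {
    v <- if (is.matrix(r)) r[rows, b] else r[rows]
    if (is.factor(v)) stats::model.matrix(~v)[, -1, drop = FALSE] else matrix(v, ncol = 1)
  }
  out <- lapply(regs, function(.) list(delta_r2 = rep(NA_real_, nb),
                                       significant = rep(FALSE, nb)))
  r2_full_v <- rep(NA_real_, nb)
  with_seed(derive_seed(seed, "scramble"), {
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    for (b in seq_len(nb)) {
      rows <- which(is.finite(y_bins[, b]) & (if (is.null(mask)) TRUE else !mask[, b]))
      if (length(rows) < 10) next
      y <- y_bins[rows, b]
      Xs <- lapply(regs, col_of, rows = rows, b = b)
      X <- do.call(cbind, Xs)
      r2f <- r2(X, y)
      r2_full_v[b] <- r2f
      for (ri in seq_along(regs)) {
        r2p <- numeric(n_perm)
        for (pi in seq_len(n_perm)) {
          shuf <- rows[order(perms[[pi]][rows])]  # permute within usable rows
          Xp <- Xs
          Xp[[ri]] <- col_of(regs[[ri]], shuf, b)
          r2p[pi] <- r2(do.call(cbind, Xp), y)
        }
        out[[ri]]$delta_r2[b] <- r2f - mean(r2p)
        out[[ri]]$significant[b] <- all(r2f > r2p)
      }
    }
  })
  c(out, list(r2_full = r2_full_v))
}

#' Split trials by a factor and report group curves with significance
#'
#' @param y_bins trials x bins response.
#' @param factor_values per-trial values (numeric for quartile/third
#'   schemes, or a factor/character for a direct split).
#' @param scheme `"quartiles"` (bottom vs top quartile), `"thirds"`
#'   (first vs last third, in the given order: time-on-task convention),
#'   `"binary"` (two factor levels), `"levels"` (all levels).
#' @param mask optional trials x bins mask.
#' @return list: `groups` (named list of row indices), `mean` (bins x
#'   groups), `sem`, `p` (per-bin significance across all trials:
#'   correlation test for numeric factors, two-group t test otherwise).
#' @export
split_by_factor <- function(y_bins, factor_values, scheme = c("quartiles",
                            "thirds", "binary", "levels"), mask = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(y_bins)
  groups <- switch(scheme,
    quartiles = {
      q <- stats::quantile(factor_values, c(0.25, 0.75), na.rm = TRUE)
      list(short = which(factor_values <= q[1]), long = which(factor_values >= q[2]))
    },
    thirds = list(early = seq_len(floor(n / 3)),
                  late = (n - floor(n / 3) + 1):n),
    binary = {
      lv <- unique(stats::na.omit(factor_values))
      if (length(lv) != 2) stop("split_by_factor: binary scheme needs 2 levels")
      stats::setNames(lapply(lv, function(l) which(factor_values == l)), as.character(lv))
    },
    levels = split(seq_len(n), factor_values))
  if (any(vapply(groups, length, 0L) == 0)) stop("split_by_factor: empty group")
  nb <- ncol(y_bins)
  mu <- matrix(NA_real_, nb, length(groups), dimnames = list(NULL, names(groups)))
  sem <- mu
  for (gi in seq_along(groups)) {
    v <- y_bins[groups[[gi]], , drop = FALSE]
    if (!is.null(mask)) v[mask[groups[[gi]], , drop = FALSE]] <- NA
    mu[, gi] <- colMeans(v, na.rm = TRUE)
    nn <- colSums(is.finite(v))
    sem[, gi] <- apply(v, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  }
  p <- rep(NA_real_, nb)
  numericf <- is.numeric(factor_values) && scheme %in% c("quartiles", "thirds")
  for (b in seq_len(nb)) {
    yb <- y_bins[, b]
    ok <- is.finite(yb)
    if (!is.null(mask)) ok <- ok & !mask[, b]
    if (sum(ok) < 10) next
    p[b] <- if (numericf) {
      fv <- if (scheme == "thirds") seq_len(n) else factor_values
      suppressWarnings(stats::cor.test(yb[ok], fv[ok])$p.value)
    } else {
      g1 <- intersect(groups[[1]], which(ok)); g2 <- intersect(groups[[2]], which(ok))
      if (length(g1) < 5 || length(g2) < 5) NA_real_
      else stats::t.test(y_bins[g1, b], y_bins[g2, b])$p.value
    }
  }
  list(groups = groups, mean = mu, sem = sem, p = p)
}

#' Lag scan between gaze In/Out and beta amplitude
#'
#' For each lag, relates each envelope bin to the gaze label `lag` ms
#' earlier (positive lag = gaze leading beta) and counts bins whose
#' two-level test is significant at `alpha`. The first and last 1000 ms of
#' the window are excluded.
#'
#' @param y_bins trials x bins envelope.
#' @param gaze_bins trials x bins gaze indicator (0/1) on the same grid.
#' @param bin_centers_ms bin centers (ms from the alignment event).
#' @param lags_ms lags to scan (ms; must be multiples of the bin width).
#' @param mask optional trials x bins mask (applied to the gaze signal).
#' @param alpha per-bin threshold.
#' @param min_per_level minimum trials per gaze level in a bin.
#' @param exclude_edge_ms excluded margin at both window ends.
#' @return list: `lags_ms`, `n_significant` per lag, `optimal_lag_ms`.
#' @export
lag_scan_gaze <- function(y_bins, gaze_bins, bin_centers_ms,
                          lags_ms = seq(-1000, 1000, by = 40), mask = NULL,
                          alpha = 0.01, min_per_level = 10,
                          exclude_edge_ms = 1000) {
  bin_ms <- diff(bin_centers_ms[1:2])
  stopifnot(all(abs(lags_ms / bin_ms - round(lags_ms / bin_ms)) < 1e-9))
  nb <- ncol(y_bins)
  core <- which(bin_centers_ms >= min(bin_centers_ms) + exclude_edge_ms &
                  bin_centers_ms <= max(bin_centers_ms) - exclude_edge_ms)
  counts <- integer(length(lags_ms))
  for (li in seq_along(lags_ms)) {
    shift <- round(lags_ms[li] / bin_ms)
    nsig <- 0L
    usable <- FALSE
    for (b in core) {
      bg <- b - shift  # gaze bin `lag` earlier
      if (bg < 1 || bg > nb) next
      g <- gaze_bins[, bg]; yv <- y_bins[, b]
      ok <- is.finite(g) & is.finite(yv)
      if (!is.null(mask)) ok <- ok & !mask[, bg]
      n1 <- sum(g[ok] == 1); n0 <- sum(g[ok] == 0)
      if (n1 < min_per_level || n0 < min_per_level) next
      usable <- TRUE
      pv <- stats::t.test(yv[ok & g == 1], yv[ok & g == 0])$p.value
      if (is.finite(pv) && pv < alpha) nsig <- nsig + 1L
    }
    counts[li] <- if (usable) nsig else NA_integer_
  }
  list(lags_ms = lags_ms, n_significant = counts,
       optimal_lag_ms = lags_ms[which.max(counts)])
}

#' Spike-field phase locking with a trial-shuffle null
#'
#' Rayleigh test of the spike-phase distribution in the pre-SC1 delay,
#' compared with `n_shuffles` recomputations in which beta phases and
#' spike times come from different trials. Significant when the observed
#' Rayleigh z exceeds at least 95% of the shuffled values. Units with
#' <= `min_spikes` spikes in the epoch are excluded.
#'
#' @param spikes a [spike_train()].
#' @param phase_1k session-long instantaneous phase of the site-dominant
#'   beta band (1 kHz).
#' @param trials trial table (epoch: SEL offset + 700 -> SC1 onset by
#'   default, i.e. the delay before SC1; configurable).
#' @param epoch_event,epoch_window_ms epoch definition relative to an event.
#' @param n_shuffles,min_spikes,seed null parameters.
#' @return list of class `phase_lock_result`: `unit_id`, `n_spikes`,
#'   `rayleigh_z`, `p_rayleigh`, `shuffle_rank` (shuffles below observed),
#'   `significant`, `excluded`, `mean_phase`.
#' @export
phase_locking <- function(spikes, phase_1k, trials,
                          epoch_event = "sc1_on", epoch_window_ms = c(-1000, 0),
                          n_shuffles = 1000, min_spikes = 100, seed = 1) {
  col <- event_column(trials, epoch_event)
  ev <- trials[[col]]
  ev <- ev[!is.na(ev)]
  n_ms <- length(phase_1k)
  ## per-trial phase segments and spike offsets
  seg_len <- round(epoch_window_ms[2] - epoch_window_ms[1])
  segs <- list(); offs <- list()
  for (i in seq_along(ev)) {
    i0 <- round(ev[i] + epoch_window_ms[1])
    if (i0 < 0 || i0 + seg_len > n_ms) next
    segs[[length(segs) + 1L]] <- phase_1k[(i0 + 1):(i0 + seg_len)]
    st <- spikes$spike_times_ms
    inwin <- st[st >= i0 & st < i0 + seg_len]
    offs[[length(offs) + 1L]] <- floor(inwin - i0) + 1L
  }
  n_spk <- sum(lengths(offs))
  if (n_spk <= min_spikes)
    return(structure(list(unit_id = spikes$unit_id, n_spikes = n_spk,
                          rayleigh_z = NA_real_, p_rayleigh = NA_real_,
                          shuffle_rank = NA_integer_, significant = NA,
                          excluded = TRUE, mean_phase = NA_real_),
                     class = "phase_lock_result"))
  obs_phases <- unlist(mapply(function(ph, o) ph[o], segs, offs, SIMPLIFY = FALSE))
  obs <- rayleigh_test(obs_phases)
  nt <- length(segs)
  zs <- numeric(n_shuffles)
  with_seed(derive_seed(seed, paste0("pl_", spikes$unit_id)), {
    for (s in seq_len(n_shuffles)) {
      prm <- sample.int(nt)
      ph <- unlist(mapply(function(k, o) segs[[prm[k]]][o],
                          seq_len(nt), offs, SIMPLIFY = FALSE))
      zs[s] <- rayleigh_test(ph)$z
    }
  })
  rank_below <- sum(zs < obs$z)
  structure(list(unit_id = spikes$unit_id, n_spikes = n_spk,
                 rayleigh_z = obs$z, p_rayleigh = obs$p,
                 shuffle_rank = rank_below,
                 significant = rank_below >= 0.95 * n_shuffles,
                 excluded = FALSE, mean_phase = circular_mean(obs_phases)),
            class = "phase_lock_result")
}

#' Pool phase-locking counts into a percentage
#'
#' @param n_locked significant-unit counts (e.g. per monkey).
#' @param n_total tested-unit counts.
#' @return pooled percentage `100 * sum(n_locked) / sum(n_total)`.
#' @export
pool_phase_locking <- function(n_locked, n_total) {
  100 * sum(n_locked) / sum(n_total)
}
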