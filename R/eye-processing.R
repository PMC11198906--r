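## Offline gaze calibration and eye-event detection.
##
## Calibration: low-velocity (fixation) samples inside the work area are
## clustered (k-means, k = 5); cluster centers are matched to the known
## target geometry by the permutation minimizing total affine-fit error; a
## full bivariate degree-2 polynomial per screen coordinate maps raw signal
## to screen cm. Saturation is marked beyond the 0.99 percentiles of the
## raw signal bounds.

#' Eye velocity from raw or calibrated traces
#'
#' Savitzky-Golay derivative per axis; returns the 2D speed in input units
#' per second.
#' @param x,y numeric vectors (same rate).
#' @param rate_hz sampling rate.
#' @param sg_window odd window length in samples (default scales with rate).
#' @param sg_order polynomial order.
#' @export
eye_speed <- function(x, y, rate_hz, sg_window = NULL, sg_order = 3) {
  if (is.null(sg_window)) sg_window <- max(5, round(rate_hz * 0.025) * 2 + 1)
  vx <- signal::sgolayfilt(x, p = sg_order, n = sg_window, m = 1) * rate_hz
  vy <- signal::sgolayfilt(y, p = sg_order, n = sg_window, m = 1) * rate_hz
  sqrt(vx^2 + vy^2)
}

#' Select likely-fixation samples
#'
#' Samples whose 2D velocity is below the lower 10th percentile of the
#' total velocity distribution.
#' @param x,y raw eye traces; @param rate_hz sampling rate.
#' @return logical mask.
#' @export
select_fixation_samples <- function(x, y, rate_hz) {
  if (length(x) < rate_hz) stop("select_fixation_samples: need >= 1 s of data")
  v <- eye_speed(x, y, rate_hz)
  sel <- v < stats::quantile(v, 0.10)
  if (mean(sel) < 0.02) {
    ## degenerate (tied) velocity distribution: fall back to the lowest
    ## decile by rank so that ~10% of samples are always selected
    sel <- rank(v, ties.method = "first") <= ceiling(0.1 * length(v))
  }
  sel
}

## match a set of candidate centers to the 5 targets: choose the subset of
## 5 centers and the permutation minimizing the total squared error of a
## least-squares affine fit (handles extra clusters from out-of-area gaze)
match_centers <- function(centers, targets) {
  k <- nrow(centers)
  if (k < 5) return(NULL)
  perms <- permutations_5()
  subsets <- utils::combn(k, 5, simplify = FALSE)
  best <- NULL; best_err <- Inf
  tg <- as.matrix(targets)
  for (sub in subsets) {
    X <- cbind(1, centers[sub, , drop = FALSE])
    for (p in seq_len(nrow(perms))) {
      fit <- tryCatch(qr.solve(X, tg[perms[p, ], ]), error = function(e) NULL)
      if (is.null(fit)) next
      ## orientation constraint: the camera does not flip or swap axes
      if (fit[2, 1] <= 0 || fit[3, 2] <= 0 ||
          abs(fit[2, 2]) > abs(fit[2, 1]) || abs(fit[3, 1]) > abs(fit[3, 2])) next
      err <- sum((X %*% fit - tg[perms[p, ], ])^2)
      if (err < best_err) {
        best_err <- err
        best <- list(subset = sub, perm = perms[p, ], err = err)
      }
    }
  }
  best
}

permutations_5 <- function() {
  p4 <- as.matrix(expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5))
  p4[apply(p4, 1, function(r) length(unique(r)) == 5), , drop = FALSE]
}

#' Offline gaze calibration
#'
#' @param eye_x,eye_y raw eye [continuous_record()]s (same rate).
#' @param targets data frame `label`, `x`, `y` of the 5 task positions in
#'   screen cm (default [target_coords_cm()]).
#' @param kmeans_restarts k-means restarts.
#' @param seed seed for k-means.
#' @return list of class `eye_calibration`: `poly_x`, `poly_y` (degree-2
#'   coefficient vectors), `cluster_centers_raw` (5 x 2, ordered as
#'   `targets`), `sat_lo`, `sat_hi` (per-axis saturation bounds),
#'   `residual_cm` (max center residual), plus `cal_x`, `cal_y` —
#'   calibrated traces (cm) with a `saturated` mask.
#' @export
calibrate_eye <- function(eye_x, eye_y, targets = target_coords_cm(),
                          kmeans_restarts = 20, seed = 1) {
  x <- eye_x$samples; y <- eye_y$samples
  rate <- eye_x$rate_hz
  sat_lo <- c(stats::quantile(x, 0.005), stats::quantile(y, 0.005))
  sat_hi <- c(stats::quantile(x, 0.995), stats::quantile(y, 0.995))
  saturated <- x <= sat_lo[1] | x >= sat_hi[1] | y <= sat_lo[2] | y >= sat_hi[2]
  fix <- select_fixation_samples(x, y, rate) & !saturated
  pts <- cbind(x, y)[fix, , drop = FALSE]
  ## cluster with k from 5 upward (extra centers absorb diffuse
  ## out-of-area / between-item fixations) and keep the clustering whose
  ## best 5-center subset matches the target geometry most closely
  n_distinct <- nrow(unique(round(pts, 6)))
  km <- NULL; m <- NULL
  with_seed(derive_seed(seed, "kmeans"), {
    for (k in 5:min(8L, n_distinct)) {
      res <- tryCatch(stats::kmeans(pts, centers = k, nstart = kmeans_restarts,
                                    iter.max = 50), error = function(e) NULL)
      if (is.null(res)) next
      ## only compact clusters can be target anchors; diffuse clusters
      ## (between-item or out-of-area fixations) are excluded up front
      msr <- res$withinss / pmax(res$size, 1)
      compact <- which(msr <= 8 * (min(msr) + 1e-12))
      if (length(compact) < 5) next
      cand <- match_centers(res$centers[compact, , drop = FALSE],
                            targets[, c("x", "y")])
      if (!is.null(cand)) cand$subset <- compact[cand$subset]
      if (!is.null(cand) && (is.null(m) || cand$err < m$err)) {
        m <- cand; km <- res
      }
    }
  })
  if (is.null(km) || is.null(m))
    stop("calibrate_eye: fixation samples do not cover 5 clusters")
  if (sqrt(m$err / 5) > 2.5)
    stop("calibrate_eye: ambiguous cluster-to-target assignment")
  sub <- m$subset; perm <- m$perm
  anchor <- km$cluster %in% sub
  cl5 <- match(km$cluster, sub)  # 1..5 within the chosen subset, NA if out
  if (min(table(cl5[anchor])) < 5 || length(unique(cl5[anchor])) < 5)
    stop("calibrate_eye: fixation samples do not cover 5 clusters")
  ## degree-2 bivariate design over anchor-cluster samples; samples far
  ## from their cluster center (stray between-item fixations captured by
  ## the Voronoi cell) are trimmed before fitting
  design <- function(u, v) cbind(1, u, v, u^2, u * v, v^2)
  apts <- pts[anchor, , drop = FALSE]
  acl <- cl5[anchor]
  ctr <- km$centers[sub, , drop = FALSE]
  dctr <- sqrt(rowSums((apts - ctr[acl, , drop = FALSE])^2))
  keep_s <- rep(TRUE, length(dctr))
  for (c5 in 1:5) {
    ii <- which(acl == c5)
    thr <- max(3 * stats::median(dctr[ii]), 1e-9)
    keep_s[ii[dctr[ii] > thr]] <- FALSE
  }
  apts <- apts[keep_s, , drop = FALSE]
  acl <- acl[keep_s]
  ## re-center on the trimmed members
  for (c5 in 1:5) {
    ii <- which(acl == c5)
    if (length(ii)) ctr[c5, ] <- colMeans(apts[ii, , drop = FALSE])
  }
  km$centers[sub, ] <- ctr
  tgt_of_sample <- targets[perm[acl], c("x", "y")]
  D <- design(apts[, 1], apts[, 2])
  fit <- qr(D, LAPACK = TRUE)
  poly_x <- qr.coef(fit, tgt_of_sample$x)
  poly_y <- qr.coef(fit, tgt_of_sample$y)
  poly_x[is.na(poly_x)] <- 0; poly_y[is.na(poly_y)] <- 0
  Dall <- design(x, y)
  cal_x <- as.numeric(Dall %*% poly_x)
  cal_y <- as.numeric(Dall %*% poly_y)
  centers5 <- km$centers[sub, , drop = FALSE]
  Dc <- design(centers5[, 1], centers5[, 2])
  res <- sqrt((Dc %*% poly_x - targets$x[perm])^2 +
                (Dc %*% poly_y - targets$y[perm])^2)
  ord <- order(perm)  # centers reordered to targets' row order
  structure(list(poly_x = poly_x, poly_y = poly_y,
                 cluster_centers_raw = centers5[ord, , drop = FALSE],
                 sat_lo = sat_lo, sat_hi = sat_hi,
                 residual_cm = max(res),
                 cal_x = cal_x, cal_y = cal_y, saturated = saturated,
                 rate_hz = rate, t0_ms = eye_x$t0_ms,
                 targets = targets),
            class = "eye_calibration")
}

#' Apply a calibration to raw eye traces
#' @param cal an `eye_calibration`; @param x,y raw traces.
#' @return two-column matrix of screen cm.
#' @export
apply_calibration <- function(cal, x, y) {
  D <- cbind(1, x, y, x^2, x * y, y^2)
  cbind(as.numeric(D %*% cal$poly_x), as.numeric(D %*% cal$poly_y))
}

#' Gaze timeline labels from calibrated traces
#'
#' Each sample gets exactly one label: a cluster label when within 2 cm of
#' a target center, otherwise `between` (inside the work area), `out`
#' (outside), `saturated`, and `blink` overrides all others.
#'
#' @param cal an `eye_calibration` (with calibrated traces).
#' @param blinks optional blink event data frame (onset_ms, offset_ms).
#' @param work_half_w_cm,work_half_h_cm monitor half-extent.
#' @return character vector of labels at the calibration's rate, plus
#'   attributes `rate_hz` and `t0_ms`.
#' @export
assign_clusters <- function(cal, blinks = NULL,
                            work_half_w_cm = 13, work_half_h_cm = 10) {
  x <- cal$cal_x; y <- cal$cal_y
  lab <- rep("between", length(x))
  out <- abs(x) > work_half_w_cm | abs(y) > work_half_h_cm
  lab[out] <- "out"
  tg <- cal$targets
  d2best <- rep(Inf, length(x)); best <- rep(0L, length(x))
  for (k in seq_len(nrow(tg))) {
    d2 <- (x - tg$x[k])^2 + (y - tg$y[k])^2
    upd <- d2 < d2best
    d2best[upd] <- d2[upd]; best[upd] <- k
  }
  hit <- d2best < 4 & !out
  labels_k <- ifelse(tg$label == "center", "center", paste0("target_", tg$label))
  lab[hit] <- labels_k[best[hit]]
  lab[cal$saturated] <- "saturated"
  if (!is.null(blinks) && nrow(blinks)) {
    t_ms <- cal$t0_ms + (seq_along(x) - 1) * 1000 / cal$rate_hz
    for (r in seq_len(nrow(blinks)))
      lab[t_ms >= blinks$onset_ms[r] - 10 & t_ms <= blinks$offset_ms[r] + 10] <- "blink"
  }
  structure(lab, rate_hz = cal$rate_hz, t0_ms = cal$t0_ms)
}

#' Detect eyeblinks from eye velocity
#'
#' Two subsequent (< 150 ms apart) crossings of the velocity threshold are
#' one blink spanning the gap plus two flanker samples on each side.
#'
#' @param velocity 2D eye speed (cm/s or V/s, matching the threshold).
#' @param rate_hz sampling rate.
#' @param thresh velocity threshold (convention: 500 cm/s at 50 Hz,
#'   800 cm/s at 240 Hz).
#' @param t0_ms time of the first sample.
#' @return data frame `onset_ms`, `offset_ms` (possibly empty).
#' @export
detect_blinks <- function(velocity, rate_hz,
                          thresh = if (rate_hz <= 60) 500 else 800,
                          t0_ms = 0) {
  above <- velocity > thresh
  cross <- which(above & !c(FALSE, above[-length(above)]))  # upward crossings
  on <- numeric(0); off <- numeric(0)
  i <- 1
  flank <- 2 / rate_hz * 1000
  while (i < length(cross)) {
    gap_ms <- (cross[i + 1] - cross[i]) * 1000 / rate_hz
    if (gap_ms < 150) {
      on <- c(on, t0_ms + (cross[i] - 1) * 1000 / rate_hz - flank)
      off <- c(off, t0_ms + (cross[i + 1] - 1) * 1000 / rate_hz + flank)
      i <- i + 2
    } else i <- i + 1
  }
  data.frame(onset_ms = on, offset_ms = off)
}

## prior-mean minus posterior-mean scan statistic; returns the index
## maximizing |difference| and the value
breakpoint_stat <- function(x) {
  n <- length(x)
  cs <- cumsum(x)
  i <- seq_len(n - 1)
  prior <- cs[i] / i
  post <- (cs[n] - cs[i]) / (n - i)
  d <- abs(prior - post)
  j <- which.max(d)
  list(index = j, value = d[j])
}

#' Recursive saccade detection
#'
#' Works on the cumulative 2D speed trace of one trial: (1) steps in the
#' highest decile of the velocity distribution mark coarse boundaries;
#' (2) within each steady period the mean slope is subtracted (noise
#' compensation); (3) a recursive breakpoint search splits each window at
#' the sample maximizing |prior mean - posterior mean| whenever that
#' difference exceeds the displacement a reference saccade (10 ms duration,
#' 60 cm/s peak triangular profile, i.e. 0.3 cm path) would produce, with a
#' +/- 15 ms refractory period around accepted transitions; (4) transitions
#' are classified saccade vs microsaccade by the distance between the
#' isobarycenters of the flanking fixation periods (>= / < 0.5 cm).
#'
#' @param x,y calibrated eye traces (cm) for one trial.
#' @param rate_hz sampling rate.
#' @param t0_ms time of the first sample.
#' @param ref_displacement_cm detection threshold in cumulative-path cm.
#' @param refractory_ms refractory period around accepted transitions.
#' @param min_window_ms smallest splittable window.
#' @return list: `events` data frame (onset_ms, offset_ms,
#'   displacement_cm, kind) and `fixations` (start_ms, end_ms, x, y).
#' @export
detect_saccades <- function(x, y, rate_hz, t0_ms = 0,
                            ref_displacement_cm = 0.3,
                            refractory_ms = 15, min_window_ms = 30) {
  n <- length(x)
  if (n * 1000 / rate_hz < 2 * refractory_ms)
    return(list(events = data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                                    displacement_cm = numeric(0), kind = character(0)),
                fixations = NULL, skipped = "trial shorter than refractory"))
  v <- eye_speed(x, y, rate_hz)
  cumv <- cumsum(v) / rate_hz  # path length, cm
  ## (1) coarse boundaries: runs of samples in the highest velocity decile;
  ## a run is an accepted transition when the path it covers exceeds the
  ## reference displacement (rejects threshold exceedances from noise in
  ## trials with few saccades)
  coarse <- v >= stats::quantile(v, 0.9)
  r <- rle(coarse)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  steady <- which(!r$values)
  refr <- max(1L, round(refractory_ms * rate_hz / 1000))
  min_win <- max(3L, round(min_window_ms * rate_hz / 1000))
  transitions <- integer(0)
  big <- which(r$values)
  accepted_run <- logical(length(r$lengths))
  for (b in big) {
    step <- cumv[ends[b]] - cumv[max(1L, starts[b] - 1L)]
    if (step > ref_displacement_cm) {
      transitions <- c(transitions, starts[b])
      accepted_run[b] <- TRUE
    }
  }
  ## (2-3) recursive split inside each steady period; the smoothed tails of
  ## large saccades leak past the decile cut, so a refractory margin is
  ## trimmed from period edges that touch a high-velocity run (twice the
  ## margin when that run was an accepted transition)
  for (s in steady) {
    i0 <- starts[s]; i1 <- ends[s]
    if (s > 1) i0 <- i0 + refr * (1L + accepted_run[s - 1])
    if (s < length(r$lengths)) i1 <- i1 - refr * (1L + accepted_run[s + 1])
    if (i1 - i0 + 1 < min_win) next
    seg <- cumv[i0:i1]
    slope <- (seg[length(seg)] - seg[1]) / (length(seg) - 1)
    seg <- seg - slope * (seq_along(seg) - 1)  # noise compensation
    splits <- integer(0)
    recurse <- function(a, b) {
      if (b - a + 1 < min_win) return(invisible())
      st <- breakpoint_stat(seg[a:b])
      if (st$value > ref_displacement_cm) {
        j <- a + st$index - 1
        splits <<- c(splits, j)
        if (j - refr - 1 >= a) recurse(a, j - refr)
        if (j + refr + 1 <= b) recurse(j + refr, b)
      }
      invisible()
    }
    recurse(1L, length(seg))
    transitions <- c(transitions, i0 - 1L + splits)
  }
  transitions <- sort(unique(transitions))
  ## merge transitions within the refractory period
  if (length(transitions) > 1) {
    keep <- c(TRUE, diff(transitions) > refr)
    transitions <- transitions[keep]
  }
  if (!length(transitions))
    return(list(events = data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                                    displacement_cm = numeric(0), kind = character(0)),
                fixations = data.frame(start_ms = t0_ms,
                                       end_ms = t0_ms + (n - 1) * 1000 / rate_hz,
                                       x = mean(x), y = mean(y))))
  ## (4) fixation isobarycenters between transitions -> classify
  bounds <- c(1L, transitions, n)
  fx <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  fx$start_in <- pmin(fx$start + refr, fx$end)
  fx$end_in <- pmax(fx$end - refr, fx$start)
  fx$x <- NA_real_; fx$y <- NA_real_
  for (i in seq_len(nrow(fx))) {
    idx <- fx$start_in[i]:fx$end_in[i]
    fx$x[i] <- mean(x[idx]); fx$y[i] <- mean(y[idx])
  }
  ev <- data.frame(onset = transitions)
  ev$disp <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  ev$kind <- ifelse(ev$disp >= 0.5, "saccade", "microsaccade")
  events <- data.frame(
    onset_ms = t0_ms + (ev$onset - 1) * 1000 / rate_hz,
    offset_ms = t0_ms + (ev$onset - 1 + refr) * 1000 / rate_hz,
    displacement_cm = ev$disp, kind = ev$kind,
    stringsAsFactors = FALSE)
  fixations <- data.frame(
    start_ms = t0_ms + (fx$start - 1) * 1000 / rate_hz,
    end_ms = t0_ms + (fx$end - 1) * 1000 / rate_hz,
    x = fx$x, y = fx$y)
  list(events = events, fixations = fixations)
}

#' Full eye-processing for a session store
#'
#' Calibrates the raw eye records, detects blinks (on raw-derived cm
#' velocity), assigns gaze labels, and upsamples the label/gaze-In
#' timelines to 1 kHz (nearest neighbor) and eye speed (linear).
#'
#' @param store a session store.
#' @param seed seed for k-means restarts.
#' @return list: `cal`, `blinks`, `labels_1k`, `gaze_in_1k`, `speed_1k`,
#'   `n_ms`.
#' @export
process_eye <- function(store, seed = 1) {
  ex <- store$records$eye_x; ey <- store$records$eye_y
  if (is.null(ex) || is.null(ey)) stop("process_eye: no eye records")
  cal <- calibrate_eye(ex, ey, seed = seed)
  v_cm <- eye_speed(cal$cal_x, cal$cal_y, cal$rate_hz)
  blinks <- detect_blinks(v_cm, cal$rate_hz, t0_ms = cal$t0_ms)
  labels <- assign_clusters(cal, blinks)
  n_ms <- store$meta$n_ms %||% ceiling(length(cal$cal_x) * 1000 / cal$rate_hz)
  idx <- pmin(pmax(round((seq_len(n_ms) - 1 - cal$t0_ms) * cal$rate_hz / 1000) + 1, 1),
              length(labels))
  labels_1k <- labels[idx]
  gaze_in_1k <- as.numeric(!labels_1k %in% c("out", "saturated", "blink"))
  sp <- stats::approx(cal$t0_ms + (seq_along(v_cm) - 1) * 1000 / cal$rate_hz,
                      v_cm, xout = seq_len(n_ms) - 1, rule = 2)$y
  list(cal = cal, blinks = blinks, labels_1k = labels_1k,
       gaze_in_1k = gaze_in_1k, speed_1k = sp, n_ms = n_ms,
       blink_mask_1k = labels_1k == "blink" | labels_1k == "saturated")
}
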