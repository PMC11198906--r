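test_that("fixation sample selection takes the lowest velocity decile", {
  set.seed(11)
  n <- 2400
  x <- cumsum(rnorm(n, sd = 0.01)); y <- cumsum(rnorm(n, sd = 0.01))
  m <- select_fixation_samples(x, y, 240)
  expect_equal(mean(m), 0.1, tolerance = 0.02)
  expect_error(select_fixation_samples(x[1:100], y[1:100], 240), "1 s")
})

test_that("calibration is exact for a planted degree-2 raw-to-screen map", {
  tc <- target_coords_cm()
  # raw cluster points; screen = quadratic polynomial of raw (many samples
  # per cluster, zero noise)
  set.seed(2)
  raw <- tc[, c("x", "y")] / 4
  reps <- 400
  u <- rep(raw$x, each = reps) + rnorm(5 * reps, sd = 1e-8)
  v <- rep(raw$y, each = reps) + rnorm(5 * reps, sd = 1e-8)
  px <- c(0.01, 3.9, 0.1, 0.08, 0.02, -0.05)
  py <- c(-0.02, -0.08, 4.1, 0.03, -0.04, 0.06)
  D <- cbind(1, u, v, u^2, u * v, v^2)
  # targets must be the exact image of the raw clusters
  scr_x <- as.numeric(D %*% px); scr_y <- as.numeric(D %*% py)
  tg <- data.frame(label = tc$label,
                   x = scr_x[seq(1, length(u), by = reps)],
                   y = scr_y[seq(1, length(u), by = reps)])
  ex <- continuous_record("eye_x", "eye_x", 240, u)
  ey <- continuous_record("eye_y", "eye_y", 240, v)
  cal <- suppressWarnings(calibrate_eye(ex, ey, targets = tg))
  expect_lt(cal$residual_cm, 1e-6)
})

test_that("calibration recovers planted camera distortion on sessions", {
  g <- fixture_small_session()
  ey <- process_eye(g$store, seed = 5)
  expect_lt(ey$cal$residual_cm, 0.2)
  # per-ms gaze label accuracy against the planted timeline
  expect_gt(mean(ey$labels_1k == g$truth$gaze_label_1k), 0.9)
  expect_gt(mean(ey$gaze_in_1k == g$truth$gaze_in_1k), 0.95)
})

test_that("cluster assignment applies the 2-cm rule with exhaustive labels", {
  tc <- target_coords_cm()
  cal <- structure(list(
    cal_x = c(0.5, tc$x[2] + 1, 3.1, 20, 1),
    cal_y = c(0.1, tc$y[2] + 1.5, 3.2, 5, 1),
    saturated = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    rate_hz = 240, t0_ms = 0, targets = tc), class = "eye_calibration")
  lab <- assign_clusters(cal)
  expect_equal(lab[1], "center")       # 0.51 cm from the center
  expect_equal(lab[2], "target_UR")    # 1.8 cm from UR: inside the 2-cm rule
  expect_equal(lab[3], "between")
  expect_equal(lab[4], "out")
  expect_equal(lab[5], "saturated")
  expect_true(all(nchar(lab) > 0))
})

test_that("blink detection pairs velocity crossings under 150 ms apart", {
  rate <- 240
  v <- rep(10, 480)
  v[c(100, 124)] <- 1000   # 100 ms apart
  b <- detect_blinks(v, rate)
  expect_equal(nrow(b), 1)
  expect_lt(b$onset_ms[1], 100 / 240 * 1000)
  v2 <- rep(10, 480); v2[c(100, 148)] <- 1000  # 200 ms apart
  expect_equal(nrow(detect_blinks(v2, rate)), 0)
})

test_that("planted blinks are fully recovered while the gaze is in-area", {
  g <- fixture_small_session()
  ey <- process_eye(g$store, seed = 5)
  tb <- g$truth$blinks
  # blinks visible in the raw signal: gaze in-area both before and after
  # (out-of-area gaze sits at the saturation bound, hiding the artifact)
  vis <- which(g$truth$gaze_in_1k[pmax(1, tb$onset_ms - 60)] == 1 &
                 g$truth$gaze_in_1k[pmin(length(g$truth$gaze_in_1k),
                                         tb$offset_ms + 60)] == 1)
  overlap <- function(a0, a1, b0, b1) a0 <= b1 + 50 & b0 <= a1 + 50
  rec <- vapply(vis, function(i)
    any(overlap(ey$blinks$onset_ms, ey$blinks$offset_ms,
                tb$onset_ms[i], tb$offset_ms[i])), TRUE)
  expect_equal(mean(rec), 1)
  fp <- vapply(seq_len(nrow(ey$blinks)), function(i)
    !any(overlap(ey$blinks$onset_ms[i], ey$blinks$offset_ms[i],
                 tb$onset_ms - 120, tb$offset_ms + 120)), TRUE)
  expect_equal(sum(fp), 0)
})

test_that("saccade detector finds planted saccades and classifies size", {
  # single synthetic trial: 4 fixations, two large saccades, one 0.4-cm step
  rate <- 240
  seg <- function(x, y, n) cbind(rep(x, n), rep(y, n))
  jump <- function(x0, y0, x1, y1, n) {
    p <- min_jerk_profile <- (1:n) / n
    s <- 10 * p^3 - 15 * p^4 + 6 * p^5
    cbind(x0 + (x1 - x0) * s, y0 + (y1 - y0) * s)
  }
  tr <- rbind(seg(0, 0, 100), jump(0, 0, 4, 0, 6), seg(4, 0, 100),
              jump(4, 0, 4, 0.4, 5), seg(4, 0.4, 100),
              jump(4, 0.4, -2, -3, 7), seg(-2, -3, 100))
  set.seed(6)
  tr <- tr + rnorm(length(tr), sd = 0.01)
  d <- detect_saccades(tr[, 1], tr[, 2], rate)
  sac <- d$events[d$events$kind == "saccade", ]
  mic <- d$events[d$events$kind == "microsaccade", ]
  expect_equal(nrow(sac), 2)
  expect_equal(nrow(mic), 1)
  expect_lt(abs(mic$displacement_cm - 0.4), 0.1)
  # onset near the planted first jump start (sample 101), within the
  # smoothing-induced spread of the velocity pulse
  expect_lt(abs(sac$onset_ms[1] - 100 / rate * 1000), 35)
  # no eye movement at all -> no events
  still <- matrix(0.3, 500, 2) + rnorm(1000, sd = 0.005)
  d0 <- detect_saccades(still[, 1], still[, 2], rate)
  expect_equal(nrow(d0$events[d0$events$kind == "saccade", ]), 0)
  # uniform time shift leaves the count unchanged
  d1 <- detect_saccades(tr[, 1], tr[, 2], rate, t0_ms = 5000)
  expect_equal(nrow(d1$events), nrow(d$events))
})

test_that("saccade detection reaches F1 >= 0.9 on planted clean sessions", {
  g <- fixture_eye_session()
  st <- g$store
  ey <- process_eye(st, seed = 3)
  cal <- ey$cal
  tr <- st$trials[!is.na(st$trials$t_go), ]
  rate <- cal$rate_hz
  allev <- list()
  for (i in seq_len(nrow(tr))) {
    i0 <- round((tr$t_touch[i] - 1200) * rate / 1000) + 1
    i1 <- round((tr$t_go[i] + 400) * rate / 1000)
    allev[[i]] <- detect_saccades(cal$cal_x[i0:i1], cal$cal_y[i0:i1], rate,
                                  t0_ms = (i0 - 1) * 1000 / rate)$events
  }
  det <- do.call(rbind, allev)
  dsac <- det[det$kind == "saccade", ]
  tru <- g$truth$saccades
  spans <- cbind(tr$t_touch - 1200, tr$t_go + 400)
  insp <- vapply(tru$onset_ms, function(t)
    any(t >= spans[, 1] & t <= spans[, 2]), TRUE)
  tru5 <- tru[insp & tru$displacement_cm >= 0.5, ]
  tp <- vapply(tru5$onset_ms, function(t)
    any(abs(dsac$onset_ms - t) <= 20), TRUE)
  fp <- vapply(dsac$onset_ms, function(t)
    !any(abs(tru5$onset_ms - t) <= 20), TRUE)
  prec <- 1 - mean(fp); rec <- mean(tp)
  expect_gte(2 * prec * rec / (prec + rec), 0.9)
})
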