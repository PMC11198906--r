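test_that("regressor matrix has the documented bin geometry and masking", {
  g <- fixture_coupling_session()
  st <- g$store
  keep <- st$trials$outcome %in% c("correct", "non_hold")
  ey <- process_eye(st, seed = 2)
  kin <- hand_kinematics(st$records$hand_x, st$records$hand_y)
  reg <- build_regressor_matrix(st$trials[keep, ], kin$speed[seq_len(ey$n_ms)],
                                ey$speed_1k, ey$gaze_in_1k, ey$blink_mask_1k)
  expect_equal(length(reg$bin_centers_ms), 680)
  expect_equal(reg$bin_centers_ms[1], -1195)
  expect_equal(mean(reg$rt_z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(reg$rt_z), 1, tolerance = 1e-10)
  expect_true(all(reg$gaze %in% c(0, 1)))
  # blink bins are masked, neighbors intact
  bl <- g$truth$blinks
  tr <- reg$trials
  i <- which(tr$t_sel_on + 1200 < bl$onset_ms[1] &
               bl$offset_ms[1] < tr$t_sel_on + 5600)[1]
  if (!is.na(i)) {
    b <- findInterval(bl$onset_ms[1] - (tr$t_sel_on[i] - 1200),
                      seq(0, 6800, by = 10))
    expect_true(any(reg$mask[i, pmax(1, b - 1):pmin(680, b + 1)]))
    expect_false(all(reg$mask[i, ]))
  }
  # constant RT is a z-scoring error
  tr2 <- st$trials[keep, ]
  tr2$rt_ms <- 300
  expect_error(build_regressor_matrix(tr2, kin$speed[seq_len(ey$n_ms)],
                                      ey$speed_1k, ey$gaze_in_1k),
               "zero RT variance")

  assign("coupling_reg", reg, envir = .fixture_env)
})

test_that("model enumeration matches the closed-form count", {
  expect_equal(nrow(enumerate_models(7)), 247)
  n <- 7
  expect_equal(nrow(enumerate_models(n)), (2^n - 1) + (2^n - 1 - n))
  e2 <- enumerate_models(2, c("a", "b"))
  expect_equal(nrow(e2), 4)
  expect_equal(nrow(enumerate_models(1, "a")), 1)
  expect_equal(nrow(enumerate_models(4)), 15 + 11)
})

test_that("BIC scan recovers planted effects and ignores null regressors", {
  reg <- synth_regressors(400, 120, seed = 5)
  set.seed(6)
  y <- matrix(rnorm(400 * 120), 400, 120)
  eff <- 40:80
  y[, eff] <- y[, eff] + 0.333 * reg$hand_velocity[, eff]  # ~10% variance
  sc <- bic_scan(y, reg)
  expect_gte(mean(sc$hand_velocity[eff]), 0.8)
  nullb <- setdiff(seq_len(120), eff)
  expect_lte(mean(sc$hand_velocity[nullb]), 0.05)
  for (nm in c("condition", "direction", "rt", "gaze"))
    expect_lte(mean(sc[[nm]][nullb]), 0.05)
})

test_that("BIC scan prefers the smaller model on duplicated regressors", {
  reg <- synth_regressors(300, 20, seed = 7)
  reg$eye_velocity <- reg$hand_velocity  # identical columns
  set.seed(8)
  y <- matrix(rnorm(300 * 20), 300, 20) + 0.5 * reg$hand_velocity
  sc <- bic_scan(y, reg)
  # one of the two duplicated regressors wins alone, never both together
  expect_true(all(xor(sc$hand_velocity, sc$eye_velocity) |
                    (!sc$hand_velocity & !sc$eye_velocity)))
  expect_gte(mean(sc$hand_velocity | sc$eye_velocity), 0.9)
  expect_true(all(sc$k <= 3))
})

test_that("single-regressor models are calibrated under the null", {
  set.seed(9)
  n <- 200; nb <- 300
  y <- matrix(rnorm(n * nb), n, nb)
  x <- rnorm(n)
  out <- single_regressor_lm(y, x)
  ks <- stats::ks.test(out$p[, 1], "punif")
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(out$p[, 1] < 0.01), 0.01, tolerance = 0.015)
  # constant regressor: bins masked (NA)
  outc <- single_regressor_lm(y[, 1:5], rep(1, n))
  expect_true(all(is.na(outc$p)))
  # condition effect: significant from its onset
  cond <- factor(sample(c("blue", "green", "pink"), n, TRUE))
  y2 <- matrix(rnorm(n * 50), n, 50)
  y2[, 26:50] <- y2[, 26:50] + (as.integer(cond) - 2) * 0.8
  o2 <- single_regressor_lm(y2, cond)
  expect_lt(stats::median(o2$p[26:50, 1]), 1e-4)
  expect_gt(min(o2$p[1:25, 1]), 1e-4)
  g <- significance_gradient(o2$p[, 1])
  expect_true(all(g[o2$p[, 1] > 0.01] == 0, na.rm = TRUE))
})

test_that("scramble importance isolates the causal regressor", {
  set.seed(10)
  n <- 250; nb <- 40
  hand <- matrix(rnorm(n * nb), n, nb)
  rt <- rnorm(n); tot <- runif(n); gaze <- rbinom(n, 1, 0.5)
  y <- matrix(rnorm(n * nb), n, nb) + 0.6 * hand
  si <- scramble_importance(y, list(rt = rt, hand = hand, gaze = gaze,
                                    tot = tot), n_perm = 60, seed = 2)
  expect_gt(mean(si$hand$delta_r2), 5 * max(mean(abs(si$rt$delta_r2)),
                                            mean(abs(si$tot$delta_r2))))
  expect_gte(mean(si$hand$significant), 0.95)
  expect_lte(mean(si$rt$significant), 0.1)
  # duplicated regressors: neither is individually important
  si2 <- scramble_importance(y, list(h1 = hand, h2 = hand), n_perm = 40,
                             seed = 3)
  expect_lt(mean(abs(si2$h1$delta_r2)), 0.02)
  expect_lt(mean(abs(si2$h2$delta_r2)), 0.02)
})

test_that("eq-jpsth is unit-diagonal on identity and calibrated on noise", {
  set.seed(11)
  A <- matrix(rnorm(40 * 80), 40, 80)
  jp <- eq_jpsth(A, A, n_shuffles = 60, seed = 1)
  expect_lt(max(abs(diag(jp$corrected) - 1)), 0.1)
  # affine rescaling of one signal leaves the corrected matrix unchanged
  jp2 <- eq_jpsth(A, 3 * A + 2, n_shuffles = 60, seed = 1)
  expect_equal(jp2$corrected, jp$corrected, tolerance = 1e-9)
  # independent noise: significant-cell rate ~ 2/(n_shuffles+1)
  B <- matrix(rnorm(40 * 80), 40, 80)
  set.seed(12)
  jp3 <- eq_jpsth(matrix(rnorm(60 * 150), 60), matrix(rnorm(60 * 150), 60),
                  n_shuffles = 100, seed = 4)
  rate <- mean(jp3$sig != 0)
  expect_gt(rate, 0.01); expect_lt(rate, 0.03)
  expect_true(all(abs(jp3$corrected) <= 1 + 1e-9))
  expect_error(eq_jpsth(A[1:10, ], A[1:10, ]), "20 trials")
})

test_that("cross-correlogram finds planted lags and is even for symmetric input", {
  set.seed(13)
  n <- 120; nb <- 200
  drive <- matrix(rnorm(n * nb), n, nb)
  for (k in 2:nb) drive[, k] <- 0.7 * drive[, k - 1] + 0.3 * drive[, k]
  lagb <- 12  # 125 ms at 10-ms bins -> use 12 bins + interpolation check
  beta <- matrix(rnorm(n * nb), n, nb) * 0.6
  beta[, (lagb + 1):nb] <- beta[, (lagb + 1):nb] - 0.8 * drive[, 1:(nb - lagb)]
  jp <- eq_jpsth(drive, beta, n_shuffles = 100, seed = 5,
                 bin_centers_ms = seq(5, by = 10, length.out = nb))
  cc <- cross_correlogram(jp, split_ms = NULL, max_lag_ms = 400)
  expect_equal(cc$most_negative_lag_ms_all, lagb * 10, tolerance = 11)
  # symmetric matrix -> even correlogram
  S <- jp$corrected + t(jp$corrected)
  jps <- jp; jps$corrected <- S
  ccs <- cross_correlogram(jps, split_ms = NULL, max_lag_ms = 200)
  v <- ccs$all$value
  expect_equal(v, rev(v), tolerance = 1e-9)
})

test_that("gaze lag scan recovers the planted lead and stays flat under null", {
  set.seed(14)
  n <- 150; nb <- 400
  gaze <- matrix(rbinom(n * nb, 1, 0.5), n, nb)
  for (k in 2:nb) {  # persistence, as real gaze has
    flip <- stats::runif(n) < 0.9
    gaze[flip, k] <- gaze[flip, k - 1]
  }
  lagb <- 24  # 240 ms at 10-ms bins
  y <- matrix(rnorm(n * nb), n, nb) * 0.8
  y[, (lagb + 1):nb] <- y[, (lagb + 1):nb] + 0.5 * (gaze[, 1:(nb - lagb)] - 0.5)
  bc <- seq(5, by = 10, length.out = nb)
  ls <- lag_scan_gaze(y, gaze, bc, lags_ms = seq(-400, 400, 40))
  expect_lt(abs(ls$optimal_lag_ms - 240), 50)
  y0 <- matrix(rnorm(n * nb), n, nb)
  ls0 <- lag_scan_gaze(y0, gaze, bc, lags_ms = seq(-400, 400, 40))
  expect_lt(max(ls0$n_significant, na.rm = TRUE) / sum(bc > 1000 & bc < max(bc) - 1000),
            0.05)
})

test_that("factor splits produce ordered group curves with significance", {
  set.seed(15)
  n <- 200; nb <- 60
  rt <- rnorm(n)
  y <- matrix(rnorm(n * nb), n, nb)
  y[, 31:60] <- y[, 31:60] + 0.5 * rt
  sp <- split_by_factor(y, rt, "quartiles")
  expect_true(all(sp$mean[31:60, "long"] > sp$mean[31:60, "short"]))
  expect_lt(stats::median(sp$p[31:60]), 1e-4)
  expect_gt(mean(sp$p[1:30] > 0.01), 0.9)
  # identical groups: no separation
  y0 <- matrix(rnorm(n * nb), n, nb)
  sp0 <- split_by_factor(y0, rt, "quartiles")
  expect_lt(mean(sp0$p < 0.01, na.rm = TRUE), 0.05)
  # thirds scheme: late above early when a slope is planted
  slope_y <- y0 + outer(seq(0, 1, length.out = n), rep(0.8, nb))
  spt <- split_by_factor(slope_y, seq_len(n), "thirds")
  expect_true(all(spt$mean[, "late"] > spt$mean[, "early"]))
  expect_error(split_by_factor(y, factor(rep("a", n)), "binary"), "2 levels")
})

test_that("phase locking separates locked units from trial-shuffled nulls", {
  g <- fixture_small_session()
  st <- g$store
  site1 <- g$truth$sites$s01
  ph <- hilbert_phase(bandpass_beta(st$records$lfp_s01$samples,
                                    site1$dominant_band, 1000))
  tr <- st$trials[!is.na(st$trials$t_sc1_on), ]
  res <- phase_locking(st$spikes[[1]], ph, tr, n_shuffles = 300, seed = 7)
  expect_false(res$excluded)
  expect_gt(res$n_spikes, 100)
  expect_true(res$significant)
  d <- Arg(exp(1i * (res$mean_phase - pi / 3)))
  expect_lt(abs(d), 0.5)
  # a sparse unit is excluded
  sparse <- spike_train("sp", "s01", sort(sample(seq_len(400000), 80)) + 0.5)
  res2 <- phase_locking(sparse, ph, tr, n_shuffles = 50, seed = 7)
  expect_true(res2$excluded)
  # pooled percentage of printed per-group counts
  expect_equal(pool_phase_locking(c(22, 38), c(269, 218)), 100 * 60 / 487)
})
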