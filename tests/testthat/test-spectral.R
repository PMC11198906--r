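test_that("spectrogram geometry, peak location and quadratic scaling", {
  t <- (0:2999) / 1000
  x <- matrix(rep(sin(2 * pi * 16 * t), 3), nrow = 3, byrow = TRUE)
  sp <- compute_spectrogram(x, 1000)
  expect_equal(dim(sp$power)[2], length(seq(1, 3000 - 300 + 1, by = 50)))
  peak <- apply(sp$power[1, , ], 1, function(w) sp$freqs_hz[which.max(w)])
  expect_true(all(peak == 16))
  sp10 <- compute_spectrogram(10 * x, 1000)
  expect_equal(sp10$power, 100 * sp$power, tolerance = 1e-8)
})

test_that("normalization fixes the 10-40 Hz grand mean at 1 and removes gain", {
  set.seed(1)
  x <- matrix(rnorm(8 * 2000), nrow = 8)
  sp <- normalize_spectrogram(compute_spectrogram(x, 1000))
  sel <- sp$freqs_hz >= 10 & sp$freqs_hz <= 40
  expect_equal(mean(sp$power[, , sel]), 1, tolerance = 1e-12)
  sp7 <- normalize_spectrogram(compute_spectrogram(7 * x, 1000))
  expect_equal(sp7$power, sp$power, tolerance = 1e-10)
})

test_that("white-noise spectrogram is flat within 3 dB over 10-40 Hz", {
  set.seed(2)
  x <- matrix(rnorm(200 * 1200), nrow = 200)
  sp <- compute_spectrogram(x, 1000)
  m <- apply(sp$power, 3, mean)
  sel <- sp$freqs_hz >= 10 & sp$freqs_hz <= 40
  db <- 10 * log10(m[sel] / mean(m[sel]))
  expect_lt(max(abs(db)), 3)
})

test_that("pre-SC1 power uses exactly five windows and finds sinusoid peaks", {
  t <- (0:899) / 1000
  x26 <- matrix(rep(sin(2 * pi * 26 * t), 4), nrow = 4, byrow = TRUE)
  ps <- pre_sc1_power(x26, 1000)
  expect_equal(ps$n_windows, 5)
  peaks <- apply(ps$power, 1, function(r) ps$freqs_hz[which.max(r)])
  expect_true(all(peaks == 26))
  # constant signal (no high-pass): spectrum concentrated at/near 0 Hz
  xc <- matrix(1, 2, 900)
  pc <- pre_sc1_power(xc, 1000, highpass_hz = 0)
  expect_lte(pc$freqs_hz[which.max(pc$power[1, ])], 1)
  expect_lt(max(pc$power[, pc$freqs_hz >= 10 & pc$freqs_hz <= 40]) /
              max(pc$power), 1e-5)
  expect_error(pre_sc1_power(x26[, 1:500, drop = FALSE], 1000), "900")
})

test_that("two-minima aperiodic estimator anchors on local minima exactly", {
  freqs <- 1:100
  # flat aperiodic floor with tiny notches: the line connects the notch
  # points and the residual vanishes strictly between them
  y <- rep(0.8, 100)
  y[freqs == 8] <- y[freqs == 8] - 1e-12
  y[freqs == 45] <- y[freqs == 45] - 1e-12
  fit <- fit_aperiodic(y, freqs)
  expect_false(fit$fallback)
  expect_equal(fit$f_lo_anchor, 8)
  expect_equal(fit$f_hi_anchor, 45)
  between <- freqs > 8 & freqs < 45 & freqs != 8 & freqs != 45
  resid <- periodic_component(matrix(rep(0.8, 100), 1), fit, freqs)
  expect_lt(max(abs(resid[1, between])), 1e-9)

  # sloped line with genuine (V-shaped) minima at 9 and 42 Hz
  line <- 1.2 - 1.5 * log10(freqs)
  y2 <- line
  y2[freqs == 9] <- y2[freqs == 9] - 0.12
  y2[freqs == 42] <- y2[freqs == 42] - 0.03
  fit2 <- fit_aperiodic(y2, freqs)
  expect_false(fit2$fallback)
  expect_equal(fit2$f_lo_anchor, 9)
  expect_equal(fit2$f_hi_anchor, 42)

  # monotone spectrum without local minima: documented fallback
  fitm <- fit_aperiodic(line, freqs)
  expect_true(fitm$fallback)
  expect_equal(fitm$f_lo_anchor, 10)
  expect_true(fitm$f_hi_anchor >= 35 && fitm$f_hi_anchor <= 50)
})

test_that("periodic residuals recover planted bump locations and heights", {
  s <- synth_spectrum(noise_sd = 0)
  fit <- fit_aperiodic(colMeans(s$trial_log_power), s$freqs)
  per <- periodic_component(s$trial_log_power, fit, s$freqs)
  mper <- colMeans(per)
  expect_equal(s$freqs[which.max(mper[s$freqs <= 21])], unname(s$low["f"]))
  expect_lt(abs(max(mper[s$freqs >= 12 & s$freqs <= 21]) - s$low["h"]) /
              s$low["h"], 0.05)
  hsel <- s$freqs >= 21 & s$freqs <= 31
  expect_lt(abs(max(mper[hsel]) - s$high["h"]) / s$high["h"], 0.05)
  # with a fixed fit, adding a constant to all trials shifts residuals by it
  per2 <- periodic_component(s$trial_log_power + 0.3, fit, s$freqs)
  expect_equal(per2, per + 0.3, tolerance = 1e-12)
})

test_that("peak frequency uses the stated range and low-frequency tie-break", {
  freqs <- 1:100
  per <- matrix(0, 2, 100)
  per[1, freqs == 26] <- 1
  per[2, freqs == 16] <- 1; per[2, freqs == 26] <- 1  # exact tie
  pk <- peak_frequency(per, freqs)
  expect_equal(pk$peak_hz, c(26, 16))
  flat <- peak_frequency(matrix(0, 1, 100), freqs)
  expect_true(flat$degenerate)
  expect_equal(flat$peak_hz, 10)
})

test_that("band dominance index follows its formula and is antisymmetric", {
  freqs <- 1:100
  mk <- function(lo, hi, n = 12) {
    per <- matrix(0, n, 100)
    per[, freqs >= 13 & freqs <= 19] <- lo
    per[, freqs >= 23 & freqs <= 29] <- hi
    per + stats::rnorm(length(per), sd = 1e-3)
  }
  set.seed(3)
  expect_equal(band_dominance(mk(1, 1), freqs)$index, 0, tolerance = 5e-3)
  expect_equal(band_dominance(mk(1, 0), freqs)$index, 1, tolerance = 5e-3)
  m21 <- mk(2, 1)
  d <- band_dominance(m21, freqs)
  expect_equal(d$index, 1 / 3, tolerance = 5e-3)
  expect_equal(d$label, "low")
  expect_lt(d$p_value, 1e-6)
  # antisymmetry under swapping the band definitions (same data)
  swapped <- band_dominance(m21, freqs, low_band = c(23, 29),
                            high_band = c(13, 19))
  expect_equal(swapped$index, -d$index, tolerance = 1e-6)
  # degenerate: both band means negative
  dd <- band_dominance(mk(-1, -0.5), freqs)
  expect_true(dd$degenerate)
})

test_that("dominance correlates with the antero-posterior coordinate", {
  df <- data.frame(index = seq(-0.8, 0.8, length.out = 9),
                   ap_coord = seq(8, -8, length.out = 9))
  ac <- dominance_ap_correlation(df)
  expect_equal(ac$rho, -1)
  expect_error(dominance_ap_correlation(data.frame(index = 1:6, ap_coord = 0)),
               "constant")
  expect_error(dominance_ap_correlation(df[1:3, ]), ">= 5")
})

test_that("site spectral summary recovers planted dominance and peaks", {
  g <- fixture_small_session()
  s1 <- site_spectral_summary(g$store, "s01")  # posterior: low dominant
  s2 <- site_spectral_summary(g$store, "s02")  # anterior: high dominant
  expect_equal(s1$dominance$label, "low")
  expect_equal(s2$dominance$label, "high")
  modal <- function(pk) as.numeric(names(which.max(table(pk$peak_hz))))
  expect_lt(abs(modal(s1$peaks) - 16), 1.5)
  expect_lt(abs(modal(s2$peaks) - 26), 1.5)
})
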