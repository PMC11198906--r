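test_that("beta band-pass preserves in-band tones and rejects out-of-band", {
  t <- (0:9999) / 1000
  s16 <- sin(2 * pi * 16 * t)
  y <- bandpass_beta(s16, "low", 1000)
  mid <- 3000:7000
  expect_lt(abs(max(abs(y[mid])) - 1), 0.02)
  # 26 Hz through the low band: > 20 dB attenuation
  y26 <- bandpass_beta(sin(2 * pi * 26 * t), "low", 1000)
  expect_lt(20 * log10(max(abs(y26[mid]))), -20)
  # DC
  ydc <- bandpass_beta(rep(1, 10000), "low", 1000)
  expect_lt(max(abs(ydc[mid])), 1e-4)
  # stopband one octave outside the band: >= 30 dB down
  y6 <- bandpass_beta(sin(2 * pi * 6 * t), "low", 1000)
  expect_lt(20 * log10(max(abs(y6[mid]))), -30)
  expect_error(bandpass_beta(s16, c(200, 400), 1000), "4x band top")
})

test_that("Hilbert envelope recovers amplitudes and modulators", {
  t <- (0:19999) / 1000
  x <- 2.5 * sin(2 * pi * 16 * t)
  env <- hilbert_envelope(x)
  mid <- 2000:18000
  expect_lt(max(abs(env[mid] - 2.5)) / 2.5, 0.02)
  # amplitude-modulated tone: envelope tracks the modulator
  m <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  envm <- hilbert_envelope(m * sin(2 * pi * 16 * t))
  expect_gt(stats::cor(envm[mid], m[mid]), 0.99)
  expect_equal(hilbert_envelope(rep(0, 100)), rep(0, 100))
})

test_that("z-normalization yields zero mean, unit sd and affine invariance", {
  set.seed(4)
  x <- abs(rnorm(5000)) + 1
  z <- znormalize_envelope(x, 1000)
  core <- 201:4800
  expect_equal(mean(z[core]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z[core]), 1, tolerance = 1e-6)
  z2 <- znormalize_envelope(3 * x + 7, 1000)
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-10)
  expect_error(znormalize_envelope(rep(2, 1000), 1000), "constant")
})

test_that("envelope of band-passed white noise is Rayleigh distributed", {
  set.seed(7)
  x <- rnorm(1e5)
  env <- hilbert_envelope(bandpass_beta(x, "low", 1000))
  env <- env[5000:95000]
  sigma <- sqrt(mean(env^2) / 2)
  ks <- stats::ks.test(env[seq(1, length(env), by = 40)],  # decorrelate
                       function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("pooling by dominance conserves trials and flags empty bands", {
  g <- fixture_small_session()
  dom <- session_dominance_table(g$store)
  pools <- pool_by_dominance(g$store, dom)
  n_inc <- sum(g$store$trials$outcome %in% c("correct", "non_hold"))
  n_rows <- nrow(pools$low$values) + nrow(pools$high$values)
  expect_equal(n_rows, n_inc * nrow(dom))
  # every pooled row maps back to a unique (site, trial)
  keys <- paste(c(pools$low$site_id, pools$high$site_id),
                c(pools$low$trial_id, pools$high$trial_id))
  expect_false(anyDuplicated(keys) > 0)
  # all sites forced low-dominant -> empty high pool with explicit status
  dom_low <- dom; dom_low$label <- "low"
  p2 <- pool_by_dominance(g$store, dom_low)
  expect_true(p2$high$empty)
  expect_false(p2$low$empty)
  # strong filter honors the 0.25 threshold
  dom_w <- dom; dom_w$index <- c(0.1, -0.3)
  dom_w$label <- c("low", "high")
  p3 <- pool_by_dominance(g$store, dom_w, strong_only = TRUE)
  expect_true(p3$low$empty)      # |0.1| <= 0.25 excluded
  expect_false(p3$high$empty)    # index -0.3 included in the high pool
  expect_error(pool_by_dominance(g$store, dom[1, , drop = FALSE]), "missing")
})

test_that("MUA extraction normalizes to mean 1 and localizes bursts", {
  set.seed(9)
  rate <- 20000
  n <- rate * 4
  x <- rnorm(n)
  burst <- round(1.5 * rate):round(1.7 * rate)  # 200 ms of doubled variance
  x[burst] <- x[burst] * 2
  mua <- extract_mua(continuous_record("wb", "wideband", rate, x))
  expect_equal(mua$rate_hz, 1000)
  expect_equal(mean(mua$samples), 1, tolerance = 1e-9)
  inb <- mean(mua$samples[1501:1700])
  outb <- mean(mua$samples[c(500:1400, 1800:3500)])
  expect_gt(inb / outb, 1.2)
  expect_error(extract_mua(continuous_record("wb", "wideband", 20000, rep(0, 100))),
               "zero")
  expect_error(extract_mua(continuous_record("wb", "wideband", 2000, rnorm(100))),
               "rate")
})

test_that("EMG conditioning rectifies, smooths and keeps burst timing", {
  rate <- 2000
  xc <- continuous_record("emg", "emg", rate, rep(1.3, 4 * rate))
  out <- condition_emg(xc)
  expect_equal(out$rate_hz, 1000)
  expect_equal(mean(out$samples[500:3500]), 1.3, tolerance = 0.01)
  # sign flip leaves the output unchanged
  set.seed(1)
  x <- rnorm(4 * rate)
  a <- condition_emg(continuous_record("emg", "emg", rate, x))
  b <- condition_emg(continuous_record("emg", "emg", rate, -x))
  expect_equal(a$samples, b$samples, tolerance = 1e-9)
  # planted 300-ms burst: smoothed peak within +/- 20 ms of its center
  x2 <- rnorm(4 * rate) * 0.1
  ctr_ms <- 2000
  idx <- round((ctr_ms - 150) * rate / 1000):round((ctr_ms + 150) * rate / 1000)
  tri <- 1 - abs(seq(-1, 1, length.out = length(idx)))  # peaked at center
  x2[idx] <- x2[idx] + rnorm(length(idx)) * 6 * tri
  out2 <- condition_emg(continuous_record("emg", "emg", rate, x2))
  expect_lt(abs(which.max(out2$samples) - 1 - ctr_ms), 20)
})
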