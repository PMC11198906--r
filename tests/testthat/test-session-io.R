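test_that("session store round-trips losslessly and flags missing components", {
  g <- fixture_small_session()
  dir <- withr::local_tempdir()
  write_session(g$store, dir)
  s2 <- read_session(dir)
  expect_equal(s2$trials$t_go, g$store$trials$t_go)
  expect_equal(s2$trials$condition, g$store$trials$condition)
  expect_equal(s2$sites, g$store$sites)
  expect_equal(s2$records$lfp_s01$samples, g$store$records$lfp_s01$samples)
  expect_equal(s2$records$hand_x$rate_hz, g$store$records$hand_x$rate_hz)
  expect_equal(vapply(s2$spikes, function(s) length(s$spike_times_ms), 0L),
               vapply(g$store$spikes, function(s) length(s$spike_times_ms), 0L))
  expect_equal(s2$spikes[[1]]$spike_times_ms, g$store$spikes[[1]]$spike_times_ms)

  file.remove(file.path(dir, "trials.csv"))
  expect_error(read_session(dir), "trials.csv")
})

test_that("trial-table validation enforces the task timing structure", {
  g <- fixture_small_session()
  st <- g$store
  bad <- st
  i <- which(!is.na(bad$trials$t_go))[1]
  bad$trials$t_sc1_on[i] <- bad$trials$t_sc1_on[i] + 50  # breaks the 1-s delay
  expect_error(validate_session(bad), "300/1000")
  bad2 <- st
  bad2$trials$rt_ms[i] <- bad2$trials$rt_ms[i] + 5
  expect_error(validate_session(bad2), "rt_ms")
})

test_that("resampling preserves values, duration and label alphabets", {
  ramp <- continuous_record("r", "hand_x", 250, seq(0, 1, length.out = 250))
  up <- resample_record(ramp, 1000, "linear")
  expect_equal(length(up$samples), 1000, tolerance = 0)
  # linear method reproduces the input at original sample times
  expect_equal(up$samples[seq(1, 1000, by = 4)], ramp$samples, tolerance = 1e-12)

  labels <- continuous_record("l", "eye_x", 50, rep(c(0, 1), 25))
  upl <- resample_record(labels, 1000, "nearest")
  expect_true(all(upl$samples %in% c(0, 1)))

  # 5 Hz sine sampled at 240 Hz, upsampled to 1 kHz: near-analytic
  t240 <- (0:479) / 240
  s <- continuous_record("s", "eye_x", 240, sin(2 * pi * 5 * t240))
  s1k <- resample_record(s, 1000, "linear")
  t1k <- (seq_along(s1k$samples) - 1) / 1000
  inside <- t1k <= max(t240)  # beyond the last input sample values are held
  expect_lt(max(abs(s1k$samples - sin(2 * pi * 5 * t1k))[inside]), 1e-2)

  # idempotent at equal rate
  expect_identical(resample_record(ramp, 250, "linear"), ramp)
})

test_that("align_and_cut produces the documented window geometry", {
  g <- fixture_small_session()
  st <- g$store
  rec <- st$records$lfp_s01
  tr <- st$trials[!is.na(st$trials$t_go), ]
  cut <- align_and_cut(rec, tr, "sel_on", c(-1200, 5600))
  expect_equal(ncol(cut$values), 6800)
  expect_equal(length(cut$trial_ids), nrow(cut$values))

  # constant signal -> constant rows
  const <- continuous_record("c", "lfp", 1000, rep(3.5, length(rec$samples)))
  cc <- align_and_cut(const, tr, "sel_on", c(-1200, 5600))
  expect_true(all(cc$values == 3.5))

  # impulse at SEL + 100 ms lands at the column whose time is 100 ms
  imp <- rep(0, length(rec$samples))
  k <- 3
  imp[round(tr$t_sel_on[k]) + 100 + 1] <- 1
  ic <- align_and_cut(continuous_record("i", "lfp", 1000, imp),
                      tr, "sel_on", c(-1200, 5600))
  expect_equal(ic$time_ms[which.max(ic$values[k, ])], 100)

  # cut rows reproduce the original samples over covered spans
  i0 <- round(tr$t_sel_on[k]) - 1200 + 1
  expect_equal(cut$values[k, ], rec$samples[i0:(i0 + 6799)])

  expect_error(align_and_cut(rec, tr, "nonsense_event", c(-100, 100)),
               "unknown event")
})
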