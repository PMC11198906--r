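# Shared fixtures, generated once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small default-condition session: 2 sites (one low-, one high-dominant),
# 60 initiated trials
fixture_small_session <- function() {
  fixture("small_session", function() {
    generate_session(generator_params(n_sites = 2, n_trials = 60), seed = 101)
  })
}

# mid-size session for coupling recovery (lags, regressor scan)
fixture_coupling_session <- function() {
  fixture("coupling_session", function() {
    generate_session(generator_params(n_sites = 2, n_trials = 120), seed = 21)
  })
}

# clean eye scenario for saccade detection: no out-of-area gaze, no blinks,
# ~300 ms fixations
fixture_eye_session <- function() {
  fixture("eye_session", function() {
    p <- generator_params(
      n_sites = 1, n_trials = 40,
      eye = list(p_out_base = 0, p_out_attend = 0, blink_p_per_delay = 0,
                 dwell_mean_ms = 150, dwell_min_ms = 250))
    generate_session(p, seed = 55)
  })
}

# larger session for condition decoding (several sites per band)
fixture_decode_session <- function() {
  fixture("decode_session", function() {
    generate_session(generator_params(n_sites = 6, n_trials = 300), seed = 31)
  })
}

# synthetic per-trial log10 spectra: power law + two Gaussian bumps.
# Returns list(freqs, trial_log_power, true_line, bumps = list(f, h, sd))
synth_spectrum <- function(low_f = 16, low_h = 0.4, high_f = 26, high_h = 0.25,
                           slope = -1.5, intercept = 1, sd_hz = 2,
                           n_trials = 30, noise_sd = 0.02) {
  freqs <- 1:100
  line <- intercept + slope * log10(freqs)
  bump <- function(f0, h) h * exp(-0.5 * ((freqs - f0) / sd_hz)^2)
  mean_spec <- line + bump(low_f, low_h) + bump(high_f, high_h)
  tl <- t(replicate(n_trials, mean_spec + stats::rnorm(length(freqs), sd = noise_sd)))
  list(freqs = freqs, trial_log_power = tl, true_line = line,
       low = c(f = low_f, h = low_h), high = c(f = high_f, h = high_h))
}

# synthetic regressor matrix with iid regressors (for model-scan tests)
synth_regressors <- function(n, nb, seed = 1) {
  set.seed(seed)
  structure(list(
    trials = data.frame(trial_id = seq_len(n)),
    condition = factor(sample(c("blue", "green", "pink"), n, TRUE),
                       levels = c("blue", "green", "pink")),
    direction = factor(sample(c("UR", "LR", "LL", "UL"), n, TRUE),
                       levels = c("UR", "LR", "LL", "UL")),
    rt_z = stats::rnorm(n), time_on_task = stats::runif(n),
    hand_velocity = matrix(stats::rnorm(n * nb), n, nb),
    eye_velocity = matrix(stats::rnorm(n * nb), n, nb),
    gaze = matrix(stats::rbinom(n * nb, 1, 0.5), n, nb),
    mask = matrix(FALSE, n, nb),
    bin_centers_ms = seq(5, by = 10, length.out = nb)),
    class = "regressor_matrix")
}
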