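test_that("washout detection: step, constant, and noisy-ramp backgrounds", {
  t <- 0:60
  step <- data.frame(time_s = t, intensity = ifelse(t < 30, 100, 10))
  w <- detect_washout(step)
  expect_true(w$found)
  expect_equal(w$t_init_s, 30)

  flat <- data.frame(time_s = t, intensity = rep(100, 61))
  expect_false(detect_washout(flat)$found)

  durs <- vapply(1:20, function(s) {
    set.seed(s)
    # 5-s linear drop 100 -> 10 beginning between samples 29 and 30
    ramp <- pmin(100, pmax(10, 100 - 18 * (t - 29.5)))
    bg <- data.frame(time_s = t, intensity = ramp + rnorm(61))
    detect_washout(bg)$duration_s
  }, numeric(1))
  expect_lt(abs(mean(durs) - 5), 1)   # the ~5 s washout ramp is recovered
})

test_that("pre-washout rate is the OLS slope over the prior 10 s", {
  t <- 0:40
  tr <- length_trace(t, 1.5 / 60 * t, frame_interval_s = 1)
  expect_equal(prewashout_rate(tr, 30), 1.5, tolerance = 1e-9)
  tr0 <- length_trace(t, rep(2, 41), frame_interval_s = 1)
  expect_equal(prewashout_rate(tr0, 30), 0)
  expect_error(prewashout_rate(tr, 5), "before washout")
})

test_that("catastrophe calling equals the exhaustive window oracle", {
  # deterministic construction: flat then -200 nm/s from t = 15
  t <- 0:40
  L <- ifelse(t <= 15, 2, 2 - 0.2 * (t - 15))               # um; 200 nm/s loss
  tr <- length_trace(t, pmax(L, 0), frame_interval_s = 1)
  d <- detect_catastrophe(tr, 0)
  expect_true(d$found)
  expect_equal(d$t_cat_s, oracle_catastrophe(tr, 0))   # OLS window: t = 14

  # sub-threshold uniform loss is never called
  tr2 <- length_trace(t, 5 - 0.1 * t, frame_interval_s = 1)
  expect_false(detect_catastrophe(tr2, 0)$found)

  # random traces: detector == oracle everywhere (including not-found)
  set.seed(99)
  for (i in 1:300) {
    y <- cumsum(rnorm(30, mean = -0.08, sd = 0.12))
    tr3 <- length_trace(0:29, pmax(y - min(y), 0) + 0.2, frame_interval_s = 1)
    d3 <- detect_catastrophe(tr3, 0)
    o3 <- oracle_catastrophe(tr3, 0)
    if (is.na(o3)) expect_false(d3$found) else expect_equal(d3$t_cat_s, o3)
  }
})

test_that("raising the slope threshold never gives an earlier catastrophe", {
  set.seed(5)
  for (i in 1:30) {
    y <- cumsum(rnorm(40, mean = -0.06, sd = 0.1))
    tr <- length_trace(0:39, pmax(y - min(y), 0) + 0.1, frame_interval_s = 1)
    t_lo <- detect_catastrophe(tr, 0, threshold_nm_s = 100)$t_cat_s
    t_hi <- detect_catastrophe(tr, 0, threshold_nm_s = 200)$t_cat_s
    if (!is.na(t_lo) && !is.na(t_hi)) expect_gte(t_hi, t_lo)
    if (is.na(t_lo)) expect_true(is.na(t_hi))
  }
})

test_that("phase rates recover the constructed slow/fast slopes", {
  pre <- di_params(1.2, 0, 0, 0)
  sim <- simulate_washout_trace(pre, washout_protocol(delay_s = 20),
                                duration_s = 120, rng_seed = 1,
                                noise_sd_um = 0, initial_length_um = 3)
  truth <- sim$truth
  pr <- phase_rates(sim$trace, truth$t_washout_s, truth$t_cat_s, 0)
  expect_true(pr$has_slow_phase)
  expect_equal(pr$slow_rate_subunits_s, 35, tolerance = 1e-6)
  expect_equal(pr$fast_rate_subunits_s, 537, tolerance = 0.002)
  expect_gte(pr$fast_rate_um_min, pr$slow_rate_um_min)

  # delay 0: no slow phase
  sim0 <- simulate_washout_trace(pre, washout_protocol(delay_s = 0),
                                 duration_s = 100, rng_seed = 1)
  pr0 <- phase_rates(sim0$trace, sim0$truth$t_washout_s, sim0$truth$t_cat_s, 0)
  expect_false(pr0$has_slow_phase)
  expect_true(is.na(pr0$slow_rate_um_min))
})

test_that("full washout pipeline: delay recovered within the anchoring offset", {
  pre <- di_params(1.2, 0, 0, 0)
  for (delay in c(10, 20, 35)) {
    sim <- simulate_washout_trace(pre, washout_protocol(delay_s = delay,
                                                        washout_duration_s = 1),
                                  duration_s = 150, rng_seed = 3,
                                  noise_sd_um = 0, initial_length_um = 4)
    res <- analyze_washout(sim$trace, sim$background,
                           analysis_config(frame_interval_s = 1))
    expect_true(res$washout_found)
    # first-frame anchoring reports the qualifying window's start: the
    # recovered delay sits within 3 frames below the protocol delay
    expect_lte(res$delay_s, delay)
    expect_gte(res$delay_s, delay - 3)
    expect_false(is.na(res$slow_rate_subunits_s))
    expect_equal(res$slow_rate_subunits_s, 35, tolerance = 0.02)
  }
})

test_that("delay is zero exactly when the slow phase is absent", {
  pre <- di_params(1.2, 0, 0, 0)
  co <- simulate_washout_cohort(40, pre, delay_range_s = c(0.2, 25),
                                rng_seed = 21)
  cfg <- analysis_config(frame_interval_s = 1)
  res <- do.call(rbind, lapply(co, function(s)
    analyze_washout(s$trace, s$background, cfg)))
  res <- res[res$washout_found & !is.na(res$t_cat_s), ]
  expect_true(all(res$delay_s >= 0))
  expect_true(all(res$has_slow_phase == (res$delay_s > 0)))
})

test_that("cohort summary: proportions, SE, and median CI coverage", {
  fake <- data.frame(washout_found = TRUE, t_cat_s = 1,
                     has_slow_phase = rep(c(FALSE, TRUE), c(55, 45)),
                     delay_s = 10, slow_rate_subunits_s = 35,
                     fast_rate_subunits_s = 537,
                     excluded_zero_slow = FALSE)
  s <- summarize_washouts(fake)
  expect_equal(s$frac_no_slow, 0.55)
  expect_equal(s$se_no_slow, sqrt(0.55 * 0.45 / 100), tolerance = 1e-12)

  all_slow <- fake; all_slow$has_slow_phase <- TRUE
  s2 <- summarize_washouts(all_slow)
  expect_equal(s2$frac_no_slow, 0)
  expect_equal(s2$se_no_slow, 0)

  # order-statistic median CI: coverage near nominal on lognormal cohorts
  hit <- vapply(1:300, function(s) {
    set.seed(s)
    x <- exp(rnorm(25, 0, 0.6))
    ci <- median_ci(x)
    ci$lower <= 1 && 1 <= ci$upper
  }, logical(1))
  expect_gte(mean(hit), 0.93)
})
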