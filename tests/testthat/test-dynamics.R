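test_that("noiseless piecewise-linear trace yields exactly two exact events", {
  tr <- make_switch_trace(1.2, 8.57, t_switch_s = 60, duration_s = 90, dt_s = 3)
  ev <- segment_phases(tr, phase_cfg(min_slope_shrink_nm_s = 100))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$kind, c("growth", "shrinkage"))
  expect_equal(ev$rate_um_min, c(1.2, 8.57), tolerance = 1e-9)
  expect_equal(ev$r_squared, c(1, 1), tolerance = 1e-9)
})

test_that("constant traces yield no events; short traces are rejected", {
  t <- seq(0, 60, 3)
  expect_equal(nrow(segment_phases(length_trace(t, rep(1, length(t))))), 0)
  expect_error(segment_phases(length_trace(c(0, 3, 6), c(1, 2, 3))), "window")
})

test_that("events are time-ordered, non-overlapping, within the trace", {
  p <- di_params(1.2, 12, 1.5, 2, seed_length_um = 0)
  for (s in 1:10) {
    tr <- simulate_length_trace(p, 300, 1, rng_seed = s, noise_sd_um = 0.02)
    ev <- segment_phases(tr)
    if (nrow(ev) < 2) next
    expect_true(all(diff(ev$start_idx) > 0))
    expect_true(all(ev$end_idx[-nrow(ev)] <= ev$start_idx[-1]))
    expect_lte(sum(ev$duration_s), diff(range(tr$time_s)))
  }
})

test_that("segmentation boundaries agree with a least-squares changepoint oracle", {
  for (s in 1:12) {
    tr <- make_switch_trace(1.5, 14, t_switch_s = 40, duration_s = 62,
                            dt_s = 1, noise_sd_um = 0.02, seed = s)
    k_oracle <- oracle_changepoint(tr$time_s, tr$length_um)
    ev <- segment_phases(tr, phase_cfg())
    shr <- ev[ev$kind == "shrinkage", ]
    expect_equal(nrow(shr), 1)
    expect_lte(abs(shr$start_idx - k_oracle), 2)
  }
})

test_that("event_rate is the first-to-last arithmetic rate", {
  expect_equal(event_rate(0.5, 30), 1.0)
  expect_equal(event_rate(0.9, 12), 4.5)
  expect_equal(event_rate(-0.9, 12), 4.5)
  expect_error(event_rate(1, 0), "duration")
})

test_that("rate-vs-concentration fit recovers exact lines and errors on one conc", {
  d <- data.frame(tubulin_conc_uM = rep(c(1, 2, 4, 8), each = 3))
  d$rate_um_min <- 0.5 * d$tubulin_conc_uM - 0.2
  fit <- fit_rate_vs_concentration(d)
  expect_equal(fit$slope_um_min_per_uM, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept_um_min, -0.2, tolerance = 1e-12)
  expect_equal(fit$critical_conc_uM, 0.4, tolerance = 1e-12)
  expect_error(fit_rate_vs_concentration(d[d$tubulin_conc_uM == 2, ]),
               "concentrations")
})

test_that("concentration-fit slope is unbiased under symmetric noise", {
  slopes <- vapply(1:40, function(s) {
    set.seed(s)
    d <- data.frame(tubulin_conc_uM = rep(c(2, 4, 6, 9), each = 15))
    d$rate_um_min <- 0.25 * d$tubulin_conc_uM - 0.1 + rnorm(nrow(d), 0, 0.3)
    fit_rate_vs_concentration(d)$slope_um_min_per_uM
  }, numeric(1))
  expect_equal(mean(slopes), 0.25, tolerance = 0.02)
})

test_that("subunit conversions reproduce the printed rate constants", {
  # 14 protofilaments x 1000/8 nm = 1750 dimers per um
  expect_equal(SUBUNITS_PER_UM, 1750)
  expect_equal(on_rate_constant(0), 0)
  expect_equal(on_rate_constant(0.1358), 3.96, tolerance = 0.002)
  expect_equal(on_rate_constant(0.2537), 7.40, tolerance = 0.002)
  expect_equal(to_subunits_per_s(1.2), 35)
  expect_equal(to_subunits_per_s(18.41), 537, tolerance = 0.1 / 537)
  expect_equal(to_subunits_per_s(0), 0)
  # exact linearity
  x <- c(0.3, 1.7, 12.2)
  expect_equal(on_rate_constant(5 * x), 5 * on_rate_constant(x))
  expect_equal(to_subunits_per_s(5 * x), 5 * to_subunits_per_s(x))
})

test_that("catastrophe-length CDF has k/n steps and matches the closed form", {
  cdf <- catastrophe_length_cdf(c(1, 2, 3))
  expect_equal(cdf$cum_fraction, c(1, 2, 3) / 3)
  cdf2 <- catastrophe_length_cdf(c(2, 1, 2))
  expect_equal(cdf2$length_um, c(1, 2))
  expect_equal(cdf2$cum_fraction, c(1 / 3, 1))
  expect_error(catastrophe_length_cdf(numeric()), "empty")

  # two-state model: length at catastrophe ~ Exp(f_cat / v_grow)
  p <- di_params(1.5, 20, 1.2, 0, seed_length_um = 0)
  lens <- unlist(lapply(1:400, function(s) {
    sw <- attr(simulate_length_trace(p, 400, 2, rng_seed = s), "truth")$switches
    i <- which(sw$state == "shrinking")[1]
    if (is.na(i)) NULL else sw$length_um[i]
  }))
  cdf3 <- catastrophe_length_cdf(lens)
  theo <- 1 - exp(-(1.2 / 1.5) * cdf3$length_um)
  expect_lt(max(abs(cdf3$cum_fraction - theo)), 0.08)   # ~KS bound at n=400
})
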