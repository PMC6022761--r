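test_that("three-rule classification: exact line, sub-threshold change, errors", {
  tr <- length_trace(c(0, 4, 8, 12), c(0, 0.3, 0.6, 0.9), frame_interval_s = 4)
  ev <- classify_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "assembly")
  expect_equal(ev$delta_length_um, 0.9)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$rate_um_min, 4.5)

  tr2 <- length_trace(c(0, 4, 8), c(0, 0.2, 0.4), frame_interval_s = 4)
  expect_equal(nrow(classify_events(tr2)), 0)
  expect_error(classify_events(length_trace(c(0, 4), c(0, 1))), ">= 3")
})

test_that("every emitted event satisfies the three rules as stated", {
  p <- di_params(1.59, 2.8, 1.0, 1.67, seed_length_um = 0)
  co <- simulate_astral_cohort(15, p, duration_s = 600, dt_s = 4,
                               noise_sd_um = 0.05, rng_seed = 2)
  for (tr in co) {
    ev <- classify_events(tr)
    if (!nrow(ev)) next
    expect_true(all(ev$n_points >= 3))
    expect_true(all(abs(ev$delta_length_um) >= 0.5))
    expect_true(all(ev$r_squared >= 0.80))
    expect_true(all(ev$end_idx > ev$start_idx))
  }
})

test_that("tightening any threshold never increases the event count", {
  p <- di_params(1.59, 2.8, 1.0, 1.67, seed_length_um = 0)
  co <- simulate_astral_cohort(10, p, duration_s = 600, dt_s = 4,
                               noise_sd_um = 0.05, rng_seed = 4)
  for (tr in co) {
    n0 <- nrow(classify_events(tr))
    expect_lte(nrow(classify_events(tr, min_points = 4L)), n0)
    expect_lte(nrow(classify_events(tr, min_delta_um = 0.8)), n0)
    expect_lte(nrow(classify_events(tr, min_r2 = 0.9)), n0)
  }
})

test_that("classifier matches the window-enumeration oracle on single-switch traces", {
  for (s in 1:12) {
    tr <- make_switch_trace(1.59, 2.8, t_switch_s = 80, duration_s = 150,
                            dt_s = 4, noise_sd_um = 0.04, seed = s)
    tru <- attr(tr, "truth")
    oracle <- oracle_single_switch_events(tr, tru$k_switch,
                                          last_idx = tru$k_floor)
    got <- classify_events(tr)
    expect_equal(nrow(got), nrow(oracle))
    expect_equal(got$kind, oracle$kind)
    expect_true(all(abs(got$start_idx - oracle$start_idx) <= 2))
    expect_true(all(abs(got$end_idx - oracle$end_idx) <= 2))
  }
})

test_that("frequency formulas are the stated arithmetic", {
  expect_equal(catastrophe_frequency(2, 300, 60), 0.5)
  expect_equal(catastrophe_frequency(0, 300, 60), 0)
  expect_error(catastrophe_frequency(1, 60, 60), "lifetime")
  expect_equal(rescue_frequency(1, 240, 120), 0.5)
  expect_equal(rescue_frequency(0, 240, 120), 0)
})

test_that("catastrophe hazard is recovered from deep-excursion cohorts", {
  # fast velocities, slow switching, 1-s sampling: essentially every
  # excursion clears the 0.5-um / 3-point rules, so the counting and
  # denominator logic is tested with minimal censoring
  p <- di_params(6, 12, 0.3, 0.6, seed_length_um = 0)
  co <- simulate_astral_cohort(90, p, duration_s = 1800, dt_s = 2,
                               noise_sd_um = 0.03, rng_seed = 6)
  per <- do.call(rbind, lapply(co, summarize_microtubule))
  expect_gt(sum(per$n_catastrophes), 500)
  est <- median(per$catastrophe_freq_per_min, na.rm = TRUE)
  # exponential dwells always leave some mass below the 3-point/0.5-um
  # rules, so the classifier-based estimate sits slightly under the hazard
  expect_equal(est, 0.3, tolerance = 0.15)
})

test_that("recovered frequencies are invariant to the frame interval (3-5 s)", {
  p <- di_params(26.5 * 60 / 1000, 46.7 * 60 / 1000, 1.0, 1.67,
                 seed_length_um = 0)
  est_at <- function(dt) {
    co <- simulate_astral_cohort(60, p, duration_s = 600, dt_s = dt,
                                 noise_sd_um = 0.05, rng_seed = 31)
    per <- do.call(rbind, lapply(co, summarize_microtubule))
    median(per$catastrophe_freq_per_min, na.rm = TRUE)
  }
  f3 <- est_at(3); f5 <- est_at(5)
  expect_lt(abs(f3 - f5) / f3, 0.2)
})

test_that("condition summary pools events and degenerates for one microtubule", {
  tr <- length_trace(seq(0, 40, 4), c(0, 0.3, 0.6, 0.9, 1.2, 1.5, 1.2, 0.8,
                                      0.4, 0.0, 0.0), frame_interval_s = 4)
  sc <- summarize_condition(list(tr))
  expect_equal(sc$n_microtubules, 1)
  expect_equal(sc$pooled$poly_rate_um_min$median,
               sc$pooled$poly_rate_um_min$lower)
  # odd-n medians equal the middle order statistic
  x <- c(5, 1, 9, 3, 7)
  expect_equal(median_ci(x)$median, sort(x)[3])
})

test_that("rank-sum test equals the enumeration oracle for small samples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-9)
  o <- oracle_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, o$p_value, tolerance = 1e-9)

  set.seed(8)
  for (i in 1:10) {
    a <- round(runif(sample(3:6, 1), 0, 100), 3)
    b <- round(runif(sample(3:6, 1), 0, 100), 3)
    got <- rank_sum_test(a, b)
    ora <- oracle_rank_sum(a, b)
    expect_equal(got$U, ora$U)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-9)
  }
  # identical samples: two-sided midrank p of 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(), 1:3), "empty")
})

test_that("Fisher test equals hypergeometric enumeration on all small tables", {
  f <- fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))
  expect_equal(f$p_value, 2 / 252, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    tab <- matrix(c(a, c, b, d), 2)
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})
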