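test_that("pure growth and frozen-velocity traces are exact", {
  tr <- simulate_length_trace(di_params(1.2, 8.57, 0, 0), 60, 3, rng_seed = 1)
  expect_equal(tail(tr$length_um, 1), 1.2, tolerance = 1e-12)
  expect_equal(diff(tr$length_um), rep(1.2 / 60 * 3, 20), tolerance = 1e-12)

  tr0 <- simulate_length_trace(di_params(0, 0, 1, 2, seed_length_um = 0.5),
                               60, 1, rng_seed = 1)
  expect_true(all(tr0$length_um == 0.5))
})

test_that("invalid simulator arguments are rejected", {
  expect_error(simulate_length_trace(di_params(1, 1, 1, 1), 60, 0),
               "dt_s")
  expect_error(simulate_length_trace(di_params(1, 1, 1, 1), 0.5, 1),
               "duration")
  expect_error(di_params(-1, 1, 1, 1))
})

test_that("two-state occupancy matches the stationary distribution", {
  # closed form: P(growing) = f_res/(f_cat + f_res) = 2/3
  p <- di_params(1, 1, 1, 2, seed_length_um = 0)
  tr <- simulate_length_trace(p, 6e5, 10, rng_seed = 7)
  expect_equal(mean(tr$state == "growing"), 2 / 3, tolerance = 0.02)
})

test_that("per-minute catastrophe count over growth time converges to f_cat", {
  p <- di_params(1.5, 2.5, 1.2, 2.5, seed_length_um = 0)
  tr <- simulate_length_trace(p, 4e5, 5, rng_seed = 11)
  sw <- attr(tr, "truth")$switches
  n_cat <- sum(sw$state == "shrinking")
  t_grow_min <- sum(tr$state == "growing") * 5 / 60
  est <- n_cat / t_grow_min
  se <- sqrt(n_cat) / t_grow_min
  expect_gt(n_cat, 500)
  expect_lt(abs(est - 1.2), 3 * se)
})

test_that("traces never fall below the seed and are bit-reproducible", {
  for (s in 1:5) {
    p <- di_params(2, 3, 2, 1, seed_length_um = 0.8)
    tr <- simulate_length_trace(p, 500, 2, rng_seed = s)
    expect_true(all(tr$length_um >= 0.8 - 1e-12))
    expect_true(all(diff(tr$time_s) > 0))
    tr2 <- simulate_length_trace(p, 500, 2, rng_seed = s)
    expect_identical(tr$length_um, tr2$length_um)
  }
})

test_that("washout trace arithmetic matches the protocol", {
  pre <- di_params(1.2, 0, 0, 0)
  # delay 0: no slow phase, catastrophe at washout
  s0 <- simulate_washout_trace(pre, washout_protocol(delay_s = 0),
                               duration_s = 100, rng_seed = 1)
  expect_equal(s0$truth$t_cat_s, s0$truth$t_washout_s)
  # v_slow 1.2 um/min over 20 s removes exactly 0.4 um
  s1 <- simulate_washout_trace(pre, washout_protocol(delay_s = 20,
                                                     v_slow_um_min = 1.2),
                               duration_s = 120, rng_seed = 1)
  expect_equal(s1$truth$length_at_washout_um - s1$truth$length_at_cat_um, 0.4,
               tolerance = 1e-12)
  # a slow phase that would pass the seed is rejected
  expect_error(simulate_washout_trace(
    pre, washout_protocol(delay_s = 3000, v_slow_um_min = 1.2),
    duration_s = 4000), "seed")
})

test_that("growth curve follows od0 * 2^((t - lag)/Td) exactly when noiseless", {
  gp <- growth_params(od0 = 0.1, doubling_time_min = 90, lag_min = 0,
                      noise_sd = 0, duration_h = 6)
  gc <- simulate_growth_curve(gp, rng_seed = 1)
  expect_equal(gc$od600[gc$time_min == 90], 0.2, tolerance = 1e-12)
  expect_equal(gc$od600[gc$time_min == 180], 0.4, tolerance = 1e-12)
})
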