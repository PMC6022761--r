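make_profile <- function(mu = 4000, sigma = 300, amp = 500, bg = 100,
                         px = 65, n = 120, noise_sd = 0, seed = 1) {
  x <- (seq_len(n) - 0.5) * px
  y <- bg + amp * gauss_survival((x - mu) / sigma)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  data.frame(x_nm = x, intensity = y)
}

test_that("profile extraction reproduces bars and single-pixel line scans", {
  img <- matrix(10, 32, 80)
  img[15:17, 10:50] <- 200
  ax <- list(origin = c(16, 10), angle_deg = 0)
  pr <- extract_profile(img, ax, halfwidth_px = 1, pixel_size_nm = 65)
  expect_equal(pr$intensity[1:35], rep(200, 35))
  expect_equal(pr$intensity[45:60], rep(10, 16))
  pr0 <- extract_profile(img, ax, halfwidth_px = 0, pixel_size_nm = 65)
  expect_equal(pr0$intensity[1:35], rep(200, 35))
  expect_error(extract_profile(img, list(origin = c(200, 10), angle_deg = 0), 1),
               "outside")
})

test_that("profile of a rendered kymograph row equals the 1D model", {
  tr <- length_trace(c(0, 3), c(4, 4), frame_interval_s = 3)
  im <- imaging_params(psf_sigma_nm = 130, tip_sd_nm = 250, noise_model = "none")
  ky <- render_kymograph(tr, im, seed_length_um = 0, width_px = 120)
  prof <- kymo_profile(ky, 1)
  sig_eff <- sqrt(250^2 + 130^2)
  amp <- im$photons_per_um * 65 / 1000
  model <- im$background_level +
    amp * gauss_survival((prof$x_nm - 4000) / sig_eff)
  # away from the seed-edge rise at x = 0 the row is exactly the 1D model
  far <- prof$x_nm > 6 * 130
  expect_equal(prof$intensity[far], model[far], tolerance = 1e-6)
})

test_that("Gaussian-survival fit recovers mu/sigma and degenerates cleanly", {
  ft <- fit_tip_profile(make_profile(sigma = 400))
  expect_true(ft$converged)
  expect_equal(ft$sigma_nm, 400, tolerance = 0.05)
  expect_equal(ft$mu_nm, 4000, tolerance = 0.01)

  # blunt limit: noiseless step fits sigma below half a pixel
  step <- make_profile(sigma = 1e-6)
  fs <- fit_tip_profile(step)
  expect_true(fs$converged)
  expect_lte(fs$sigma_nm, 0.5 * 65)

  # flat and rising profiles do not converge
  flat <- data.frame(x_nm = (1:50) * 65, intensity = rep(100, 50))
  expect_false(fit_tip_profile(flat)$converged)
  rising <- data.frame(x_nm = (1:50) * 65, intensity = seq(100, 600, length.out = 50))
  expect_false(fit_tip_profile(rising)$converged)
})

test_that("fit is shift- and scale-equivariant", {
  base <- make_profile(sigma = 350, noise_sd = 3)
  f0 <- fit_tip_profile(base)
  shifted <- base; shifted$x_nm <- base$x_nm + 500
  f1 <- fit_tip_profile(shifted)
  expect_equal(f1$mu_nm - f0$mu_nm, 500, tolerance = 1)
  expect_equal(f1$sigma_nm, f0$sigma_nm, tolerance = 1e-3)
  scaled <- base; scaled$intensity <- base$intensity * 3
  f2 <- fit_tip_profile(scaled)
  expect_equal(f2$amplitude, 3 * f0$amplitude, tolerance = 1e-3)
  expect_equal(f2$mu_nm, f0$mu_nm, tolerance = 1e-3)
  expect_equal(f2$sigma_nm, f0$sigma_nm, tolerance = 1e-3)
})

test_that("with a PSF and a blunt tip, fitted sigma is the PSF SD", {
  tr <- length_trace(c(0, 3), c(4, 4), frame_interval_s = 3)
  im <- imaging_params(psf_sigma_nm = 130, tip_sd_nm = 0, noise_model = "none")
  ky <- render_kymograph(tr, im, seed_length_um = 0, width_px = 120)
  ft <- fit_tip_profile(kymo_profile(ky, 1), psf_sigma_nm = 130)
  expect_equal(ft$sigma_nm, 130, tolerance = 0.1)
  expect_lte(ft$sigma_corrected_nm, 0.3 * 130)
})

test_that("sigma recovery error shrinks with SNR", {
  err_at <- function(noise_sd) {
    mean(vapply(1:15, function(s) {
      f <- fit_tip_profile(make_profile(sigma = 300, amp = 500,
                                        noise_sd = noise_sd, seed = s))
      abs(f$sigma_nm - 300)
    }, numeric(1)))
  }
  expect_lt(err_at(10), err_at(100))
})

test_that("tip SD binned by rate: exact means and monotone construction", {
  f1 <- data.frame(rate_um_min = runif(30, 0, 3), sigma_nm = 300)
  tab <- mean_tipsd_by_rate(f1, breaks = c(0, 1, 2, 3))
  expect_true(all(tab$mean_sigma_nm == 300))
  expect_true(all(tab$upper - tab$lower == 0))

  f2 <- data.frame(rate_um_min = c(rep(0.5, 10), rep(1.5, 10)),
                   sigma_nm = c(rep(200, 10), rep(400, 10)))
  tab2 <- mean_tipsd_by_rate(f2, breaks = c(0, 1, 2))
  expect_equal(tab2$mean_sigma_nm, c(200, 400))

  # renderer sweep: true sigma rising with rate gives monotone bin means
  rates <- seq(0.5, 3.5, length.out = 12)
  fits <- do.call(rbind, lapply(seq_along(rates), function(i) {
    sig <- 150 + 100 * rates[i]
    f <- fit_tip_profile(make_profile(sigma = sig, noise_sd = 5, seed = i))
    data.frame(rate_um_min = rates[i], sigma_nm = f$sigma_nm)
  }))
  tab3 <- mean_tipsd_by_rate(fits, breaks = c(0, 1, 2, 3, 4))
  expect_true(all(diff(tab3$mean_sigma_nm) > 0))
  expect_error(mean_tipsd_by_rate(fits[0, ], breaks = c(0, 1)), "pairs")
})
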