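# Tubulin washout analysis: washout window detection from the background
# channel, pre-washout polymerization fit, catastrophe calling by iterative
# 5-point regressions against a 150 nm/s slope threshold, and slow/fast
# depolymerization rates.

#' Detect the washout window from a background-intensity series
#'
#' Washout initiation is the first time point whose background is lower than
#' the mean of the previous three points by more than `k` times the robust
#' noise SD; termination is the first subsequent point that is no longer
#' higher than the mean of its next three points by the same margin (the
#' drop has finished).
#'
#' @param background data frame with `time_s` and `intensity` (>= 5 samples).
#' @param k significance multiple (default 3).
#' @return list with `found` (logical), `t_init_s`, `t_term_s`,
#'   `duration_s`, and `sigma_noise`. `found = FALSE` (values `NA`) when no
#'   significant drop exists.
#' @export
detect_washout <- function(background, k = 3) {
  stopifnot(is.data.frame(background),
            all(c("time_s", "intensity") %in% names(background)))
  y <- background$intensity; t <- background$time_s
  n <- length(y)
  if (n < 5) stopf("detect_washout: need >= 5 samples")
  sigma <- mad(diff(y)) / sqrt(2)
  init <- NA_integer_
  for (i in 4:(n - 1)) {
    # the drop must persist at the next sample too, so an isolated noise
    # spike in the background channel cannot trigger a washout call
    ref <- mean(y[(i - 3):(i - 1)]) - k * sigma
    if (y[i] < ref && y[i + 1] < ref) { init <- i; break }
  }
  if (is.na(init))
    return(list(found = FALSE, t_init_s = NA_real_, t_term_s = NA_real_,
                duration_s = NA_real_, sigma_noise = sigma))
  term <- n
  for (j in init:(n - 3)) {
    if (!(y[j] > mean(y[(j + 1):(j + 3)]) + k * sigma)) { term <- j; break }
  }
  list(found = TRUE, t_init_s = t[init], t_term_s = t[term],
       duration_s = t[term] - t[init], sigma_noise = sigma)
}

#' Pre-washout polymerization rate
#'
#' OLS slope of the length trace over the `window_s` seconds preceding
#' washout initiation, in um/min.
#'
#' @param trace a `length_trace`.
#' @param t_init_s washout initiation time (s).
#' @param window_s regression window before washout (default 10 s).
#' @return rate in um/min (signed; positive = growth).
#' @export
prewashout_rate <- function(trace, t_init_s, window_s = 10) {
  idx <- which(trace$time_s >= t_init_s - window_s & trace$time_s <= t_init_s)
  if (length(idx) < 2 || trace$time_s[idx[1]] > t_init_s - window_s + 1e-9)
    stopf("prewashout_rate: need >= %g s of trace before washout", window_s)
  ols_fit(trace$time_s[idx], trace$length_um[idx])$slope * 60
}

#' Call catastrophe after washout by iterative 5-point regressions
#'
#' Slides a `window`-frame regression forward from washout initiation; the
#' catastrophe is the first window whose OLS slope is below
#' `-threshold_nm_s`. The reported time anchors to the window's first frame
#' by default (`anchor = "first"`); `"center"`/`"last"` are provided for
#' sensitivity analysis.
#'
#' @param trace a `length_trace`.
#' @param t_init_s washout initiation time (s).
#' @param threshold_nm_s slope-loss threshold (default 150 nm/s, about two
#'   65-nm pixels per 1-s frame).
#' @param window regression window in frames (default 5).
#' @param anchor which frame of the qualifying window is reported.
#' @return list with `found`, `t_cat_s` (`NA` when no window qualifies),
#'   `window_slope_nm_s` (slope of the qualifying window).
#' @export
detect_catastrophe <- function(trace, t_init_s, threshold_nm_s = 150,
                               window = 5L,
                               anchor = c("first", "center", "last")) {
  anchor <- match.arg(anchor)
  i0 <- which(trace$time_s >= t_init_s)[1]
  if (is.na(i0)) stopf("detect_catastrophe: t_init beyond trace")
  n <- nrow(trace)
  if (n - i0 + 1 < window)
    stopf("detect_catastrophe: fewer than %d frames after washout", window)
  t <- trace$time_s; y <- trace$length_um * 1000      # nm
  for (s in i0:(n - window + 1L)) {
    idx <- s:(s + window - 1L)
    sl <- ols_fit(t[idx], y[idx])$slope               # nm/s
    if (sl < -threshold_nm_s) {
      a <- switch(anchor, first = s, center = s + window %/% 2L,
                  last = s + window - 1L)
      return(list(found = TRUE, t_cat_s = t[a], window_slope_nm_s = sl))
    }
  }
  list(found = FALSE, t_cat_s = NA_real_, window_slope_nm_s = NA_real_)
}

#' Slow and fast depolymerization rates of a washout trace
#'
#' The slow rate is the OLS slope magnitude from washout initiation to
#' catastrophe; the fast rate from catastrophe until the microtubule first
#' returns to the seed (length <= seed length + one pixel). Rates are
#' reported in um/min and subunits/s. A slow rate is absent when catastrophe
#' coincides with washout; a slow rate of exactly zero is flagged
#' `excluded_zero_slow` (such microtubules are excluded from slow-rate
#' summaries).
#'
#' @param trace a `length_trace`.
#' @param t_init_s,t_cat_s washout initiation and catastrophe times (s).
#' @param seed_length_um stable-seed length (um).
#' @param pixel_size_nm pixel size used for the "reached seed" margin
#'   (default 65).
#' @param subunits_per_um lattice constant (default 1750).
#' @return list with `has_slow_phase`, `slow_rate_um_min`,
#'   `slow_rate_subunits_s`, `fast_rate_um_min`, `fast_rate_subunits_s`,
#'   `excluded_zero_slow`, `t_seed_s`.
#' @export
phase_rates <- function(trace, t_init_s, t_cat_s, seed_length_um = 0,
                        pixel_size_nm = 65,
                        subunits_per_um = SUBUNITS_PER_UM) {
  t <- trace$time_s; y <- trace$length_um
  out <- list(has_slow_phase = FALSE, slow_rate_um_min = NA_real_,
              slow_rate_subunits_s = NA_real_, fast_rate_um_min = NA_real_,
              fast_rate_subunits_s = NA_real_, excluded_zero_slow = FALSE,
              t_seed_s = NA_real_)
  if (is.na(t_cat_s)) return(out)
  slow_idx <- which(t >= t_init_s & t <= t_cat_s)
  if (t_cat_s > t_init_s && length(slow_idx) >= 2) {
    sl <- -ols_fit(t[slow_idx], y[slow_idx])$slope * 60   # loss, um/min
    out$has_slow_phase <- TRUE
    out$slow_rate_um_min <- sl
    out$slow_rate_subunits_s <- to_subunits_per_s(sl, subunits_per_um)
    if (sl == 0) out$excluded_zero_slow <- TRUE
  }
  at_seed <- which(t >= t_cat_s & y <= seed_length_um + pixel_size_nm / 1000)
  i_seed <- if (length(at_seed)) at_seed[1] else nrow(trace)
  out$t_seed_s <- t[i_seed]
  fast_idx <- which(t >= t_cat_s & t <= t[i_seed])
  # the first at-seed frame sits past the depolymerization endpoint (the
  # length is clamped at the seed); keep the regression on the moving part
  if (length(fast_idx) > 3 && tail(fast_idx, 1) == i_seed &&
      length(at_seed) > 0)
    fast_idx <- head(fast_idx, -1)
  if (length(fast_idx) >= 2) {
    fl <- -ols_fit(t[fast_idx], y[fast_idx])$slope * 60
    out$fast_rate_um_min <- fl
    out$fast_rate_subunits_s <- to_subunits_per_s(fl, subunits_per_um)
  }
  out
}

#' Full washout analysis of one microtubule
#'
#' Chains [detect_washout()], [prewashout_rate()], [detect_catastrophe()],
#' and [phase_rates()] into one record.
#'
#' @param trace a `length_trace`.
#' @param background background-intensity data frame.
#' @param cfg [analysis_config()].
#' @param seed_length_um stable-seed length (um).
#' @return one-row data frame (a `WashoutResult`): washout window, pre-washout
#'   rate, catastrophe time, delay, slow/fast rates and flags.
#' @export
analyze_washout <- function(trace, background, cfg = analysis_config(),
                            seed_length_um = 0) {
  w <- detect_washout(background)
  if (!w$found)
    return(data.frame(t_init_s = NA_real_, t_term_s = NA_real_,
                      washout_duration_s = NA_real_,
                      prewashout_rate_um_min = NA_real_, t_cat_s = NA_real_,
                      delay_s = NA_real_, has_slow_phase = FALSE,
                      slow_rate_um_min = NA_real_,
                      slow_rate_subunits_s = NA_real_,
                      fast_rate_um_min = NA_real_,
                      fast_rate_subunits_s = NA_real_,
                      excluded_zero_slow = FALSE, washout_found = FALSE))
  pre <- prewashout_rate(trace, w$t_init_s, cfg$prewashout_window_s)
  cat <- detect_catastrophe(trace, w$t_init_s,
                            threshold_nm_s = cfg$catastrophe_slope_threshold_nm_s,
                            window = cfg$regression_window)
  pr <- phase_rates(trace, w$t_init_s, cat$t_cat_s, seed_length_um,
                    pixel_size_nm = cfg$pixel_size_nm,
                    subunits_per_um = cfg$subunits_per_um)
  data.frame(t_init_s = w$t_init_s, t_term_s = w$t_term_s,
             washout_duration_s = w$duration_s,
             prewashout_rate_um_min = pre,
             t_cat_s = cat$t_cat_s,
             delay_s = if (cat$found) cat$t_cat_s - w$t_init_s else NA_real_,
             has_slow_phase = pr$has_slow_phase,
             slow_rate_um_min = pr$slow_rate_um_min,
             slow_rate_subunits_s = pr$slow_rate_subunits_s,
             fast_rate_um_min = pr$fast_rate_um_min,
             fast_rate_subunits_s = pr$fast_rate_subunits_s,
             excluded_zero_slow = pr$excluded_zero_slow,
             washout_found = TRUE)
}

#' Summarize a cohort of washout results
#'
#' Reports the fraction of microtubules without a slow depolymerization
#' phase (with the standard error of the proportion), medians with
#' order-statistic 95% CIs for delay and slow/fast rates, and exclusion
#' counts. Zero slow rates are excluded from the slow-rate summary.
#'
#' @param results data frame of rows from [analyze_washout()].
#' @return list with `n`, `frac_no_slow`, `se_no_slow`, `delay`, `slow_rate_subunits_s`,
#'   `fast_rate_subunits_s` (each a [median_ci()] list), `n_excluded_zero_slow`.
#' @export
summarize_washouts <- function(results) {
  if (!nrow(results)) stopf("summarize_washouts: empty input")
  res <- results[results$washout_found & !is.na(results$t_cat_s), ]
  n <- nrow(res)
  if (!n) stopf("summarize_washouts: no analyzable washouts")
  p <- mean(!res$has_slow_phase)
  slow <- res$slow_rate_subunits_s[res$has_slow_phase & !res$excluded_zero_slow]
  list(n = n,
       frac_no_slow = p,
       se_no_slow = sqrt(p * (1 - p) / n),
       delay = median_ci(res$delay_s),
       slow_rate_subunits_s = if (length(slow)) median_ci(slow) else NULL,
       fast_rate_subunits_s = median_ci(res$fast_rate_subunits_s),
       n_excluded_zero_slow = sum(res$excluded_zero_slow))
}
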