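# Two-state dynamic-instability simulator and derived protocol generators.
# Switching is a continuous-time Markov process: exponential dwell times with
# hazard f_cat while growing and f_res while shrinking, constant velocities
# within a phase. Traces are simulated event-exactly and then sampled.

new_length_trace <- function(time_s, length_um, state = NULL,
                             frame_interval_s = NA_real_, condition = NA,
                             tubulin_conc_uM = NA_real_, truth = NULL) {
  if (length(time_s) != length(length_um))
    stopf("length_trace: time and length must have equal length")
  if (any(diff(time_s) <= 0)) stopf("length_trace: times must be strictly increasing")
  if (any(!is.finite(length_um)) || any(length_um < -1e-9))
    stopf("length_trace: lengths must be finite and >= 0")
  df <- data.frame(time_s = time_s, length_um = pmax(length_um, 0))
  if (!is.null(state)) df$state <- state
  structure(df, class = c("length_trace", "data.frame"),
            frame_interval_s = frame_interval_s, condition = condition,
            tubulin_conc_uM = tubulin_conc_uM, truth = truth)
}

#' Construct a length trace
#'
#' @param time_s strictly increasing times (s).
#' @param length_um lengths (um, finite, >= 0).
#' @param frame_interval_s sampling interval (s); default inferred from the
#'   median time step.
#' @param state optional per-sample state labels.
#' @param condition optional condition label.
#' @return a `length_trace` data frame.
#' @export
length_trace <- function(time_s, length_um,
                         frame_interval_s = median(diff(time_s)),
                         state = NULL, condition = NA) {
  new_length_trace(time_s, length_um, state = state,
                   frame_interval_s = frame_interval_s, condition = condition)
}

#' Simulate a dynamic-instability length trace
#'
#' Event-exact simulation of the two-state model: growth at `v_grow` with
#' catastrophe hazard `f_cat`, shrinkage at `v_shrink` with rescue hazard
#' `f_res`. At the seed boundary the microtubule either resumes growth
#' immediately (`renucleate = TRUE`) or terminates and holds at the seed.
#' The exact piecewise-linear path is then sampled every `dt_s`.
#'
#' @param params [di_params()].
#' @param duration_s total simulated time (s), >= `dt_s`.
#' @param dt_s sampling interval (s), > 0.
#' @param rng_seed integer seed; the trace is bit-reproducible given the seed.
#' @param noise_sd_um optional Gaussian measurement noise SD (um) added to
#'   the sampled lengths (clamped at >= 0); the noiseless path and switch
#'   times are kept in the `truth` attribute.
#' @return a `length_trace` data frame (`time_s`, `length_um`, `state`) with
#'   attributes `frame_interval_s` and `truth` (list: `params`, `switches`,
#'   `length_true_um`, `rng_seed`).
#' @export
simulate_length_trace <- function(params, duration_s, dt_s, rng_seed = 1L,
                                  noise_sd_um = 0) {
  stopifnot(inherits(params, "di_params"))
  if (!is.finite(dt_s) || dt_s <= 0) stopf("simulate_length_trace: dt_s must be > 0")
  if (!is.finite(duration_s) || duration_s < dt_s)
    stopf("simulate_length_trace: duration_s must be >= dt_s")
  vg <- params$v_grow_um_min / 60      # um/s
  vs <- params$v_shrink_um_min / 60
  kc <- params$f_cat_per_min / 60      # 1/s
  kr <- params$f_res_per_min / 60
  seedL <- params$seed_length_um

  with_seed(rng_seed, {
    # breakpoints of the exact piecewise-linear path
    bt <- 0; bl <- seedL; bstate <- "growing"
    t <- 0; L <- seedL; state <- "growing"; terminated <- FALSE
    while (t < duration_s && !terminated) {
      if (state == "growing") {
        dwell <- if (kc > 0) rexp(1, kc) else Inf
        t2 <- min(t + dwell, duration_s)
        L <- L + vg * (t2 - t)
        t <- t2
        if (t < duration_s) state <- "shrinking"
      } else {
        dwell <- if (kr > 0) rexp(1, kr) else Inf
        t_seed <- if (vs > 0) t + (L - seedL) / vs else Inf
        t2 <- min(t + dwell, t_seed, duration_s)
        L <- max(L - vs * (t2 - t), seedL)
        reached_seed <- (t2 == t_seed && t_seed <= min(t + dwell, duration_s))
        t <- t2
        if (t < duration_s) {
          if (reached_seed) {
            if (params$renucleate) state <- "growing" else terminated <- TRUE
          } else state <- "growing"
        }
      }
      bt <- c(bt, t); bl <- c(bl, L); bstate <- c(bstate, state)
      if (terminated && t < duration_s) {     # hold at seed to the end
        bt <- c(bt, duration_s); bl <- c(bl, seedL)
        bstate <- c(bstate, "terminated")
        t <- duration_s
      }
    }
    times <- seq(0, duration_s, by = dt_s)
    lengths <- approx(bt, bl, xout = times, rule = 2)$y
    seg <- findInterval(times, bt, left.open = TRUE) # segment ending state
    seg[seg < 1] <- 1
    states <- bstate[pmin(seg, length(bstate))]
    states <- c(bstate[1], states[-1])
    obs <- lengths
    if (noise_sd_um > 0) obs <- pmax(lengths + rnorm(length(lengths), 0, noise_sd_um), 0)
    new_length_trace(times, obs, state = states, frame_interval_s = dt_s,
                     truth = list(params = params,
                                  switches = data.frame(time_s = bt, length_um = bl,
                                                        state = bstate),
                                  length_true_um = lengths,
                                  rng_seed = rng_seed))
  })
}

#' Add Gaussian measurement noise to a length trace
#'
#' @param trace a `length_trace`.
#' @param sd_um noise SD in micrometers.
#' @param rng_seed integer seed.
#' @return a `length_trace` with perturbed lengths (clamped at >= 0); the
#'   original lengths are stored in `truth$length_true_um`.
#' @export
add_measurement_noise <- function(trace, sd_um, rng_seed = 1L) {
  truth <- attr(trace, "truth")
  if (is.null(truth)) truth <- list()
  truth$length_true_um <- trace$length_um
  noisy <- with_seed(rng_seed,
                     pmax(trace$length_um + rnorm(nrow(trace), 0, sd_um), 0))
  new_length_trace(trace$time_s, noisy, state = trace$state,
                   frame_interval_s = attr(trace, "frame_interval_s"),
                   condition = attr(trace, "condition"), truth = truth)
}

#' Simulate a tubulin washout experiment
#'
#' Deterministic protocol: growth at `pre$v_grow_um_min` from `initial_length_um`
#' until `protocol$t_washout_s`; slow depolymerization at `v_slow` for
#' `delay_s`; fast depolymerization at `v_fast` until the seed; hold at the
#' seed. The background channel steps from `background_pre` to
#' `background_post` linearly over `washout_duration_s` starting at washout.
#' Default sampling is 1 s (continuous acquisition during washout).
#'
#' @param pre [di_params()]; only `v_grow_um_min` and `seed_length_um` are
#'   used (the pre-washout phase is steady growth).
#' @param protocol [washout_protocol()].
#' @param duration_s,dt_s total time and sampling interval (s).
#' @param rng_seed integer seed for the noise draws.
#' @param noise_sd_um Gaussian measurement noise SD on lengths (um).
#' @param initial_length_um dynamic length already present at t = 0 (um).
#' @return list with `trace` (a `length_trace`), `background` (data frame
#'   `time_s`, `intensity`), and `truth` (protocol, catastrophe time,
#'   seed-arrival time, rates).
#' @export
simulate_washout_trace <- function(pre, protocol, duration_s = 120, dt_s = 1,
                                   rng_seed = 1L, noise_sd_um = 0,
                                   initial_length_um = 3) {
  stopifnot(inherits(pre, "di_params"), inherits(protocol, "washout_protocol"))
  if (protocol$t_washout_s >= duration_s)
    stopf("simulate_washout_trace: t_washout_s must fall within duration")
  vg <- pre$v_grow_um_min / 60
  vs <- protocol$v_slow_um_min / 60
  vf <- protocol$v_fast_um_min / 60
  seedL <- pre$seed_length_um
  t_w <- protocol$t_washout_s
  L_w <- seedL + initial_length_um + vg * t_w
  L_cat <- L_w - vs * protocol$delay_s
  if (L_cat <= seedL)
    stopf("simulate_washout_trace: slow phase would pass the seed (delay too long)")
  t_cat <- t_w + protocol$delay_s
  t_seed <- if (vf > 0) t_cat + (L_cat - seedL) / vf else Inf

  times <- seq(0, duration_s, by = dt_s)
  L <- numeric(length(times))
  L[times <= t_w] <- seedL + initial_length_um + vg * times[times <= t_w]
  i2 <- times > t_w & times <= t_cat
  L[i2] <- L_w - vs * (times[i2] - t_w)
  i3 <- times > t_cat
  L[i3] <- pmax(L_cat - vf * (times[i3] - t_cat), seedL)
  state <- ifelse(times <= t_w, "growing",
                  ifelse(times <= t_cat, "slow", "fast"))
  state[times >= t_seed] <- "seed"

  bg <- ifelse(times < t_w, protocol$background_pre,
               ifelse(times >= t_w + protocol$washout_duration_s,
                      protocol$background_post,
                      protocol$background_pre +
                        (protocol$background_post - protocol$background_pre) *
                        (times - t_w) / protocol$washout_duration_s))
  with_seed(rng_seed, {
    if (noise_sd_um > 0) L_obs <- pmax(L + rnorm(length(L), 0, noise_sd_um), 0)
    else L_obs <- L
    if (protocol$background_noise_sd > 0)
      bg <- bg + rnorm(length(bg), 0, protocol$background_noise_sd)
    truth <- list(pre = pre, protocol = protocol, t_washout_s = t_w,
                  t_cat_s = t_cat, t_seed_s = t_seed,
                  length_at_washout_um = L_w, length_at_cat_um = L_cat,
                  length_true_um = L, rng_seed = rng_seed)
    list(trace = new_length_trace(times, L_obs, state = state,
                                  frame_interval_s = dt_s, truth = truth),
         background = data.frame(time_s = times, intensity = bg),
         truth = truth)
  })
}

#' Simulate a cohort of washout experiments
#'
#' Convenience wrapper drawing one washout trace per microtubule with
#' per-trace delays uniform in `delay_range_s` and initial lengths uniform in
#' `initial_length_range_um`.
#'
#' @param n number of microtubules.
#' @param pre [di_params()] for the pre-washout growth.
#' @param v_slow_um_min,v_fast_um_min depolymerization speeds (um/min).
#' @param delay_range_s range of delays from washout to catastrophe (s).
#' @param initial_length_range_um range of dynamic lengths at t = 0 (um).
#' @param t_washout_s,duration_s,dt_s protocol timing (s).
#' @param noise_sd_um length measurement noise SD (um).
#' @param rng_seed integer seed for the cohort.
#' @return list of `simulate_washout_trace()` results.
#' @export
simulate_washout_cohort <- function(n, pre, v_slow_um_min = 1.2,
                                    v_fast_um_min = 18.41,
                                    delay_range_s = c(5, 40),
                                    initial_length_range_um = c(2.5, 5),
                                    t_washout_s = 30, duration_s = 150,
                                    dt_s = 1, noise_sd_um = 0.02,
                                    rng_seed = 1L) {
  with_seed(rng_seed, {
    delays <- runif(n, delay_range_s[1], delay_range_s[2])
    inits <- runif(n, initial_length_range_um[1], initial_length_range_um[2])
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    lapply(seq_len(n), function(i) {
      proto <- washout_protocol(t_washout_s = t_washout_s,
                                delay_s = delays[i],
                                v_slow_um_min = v_slow_um_min,
                                v_fast_um_min = v_fast_um_min)
      simulate_washout_trace(pre, proto, duration_s = duration_s, dt_s = dt_s,
                             rng_seed = seeds[i], noise_sd_um = noise_sd_um,
                             initial_length_um = inits[i])
    })
  })
}

#' Simulate a cohort of astral-microtubule traces
#'
#' One two-state trace per microtubule with shared kinetic parameters and
#' independent sub-seeds, plus Gaussian measurement noise, emulating
#' live-cell length measurements at a few-second cadence.
#'
#' @param n number of microtubules.
#' @param params [di_params()].
#' @param duration_s,dt_s trace length and sampling interval (s).
#' @param noise_sd_um measurement noise SD (um; default 0.05 = 50 nm).
#' @param rng_seed integer seed for the cohort.
#' @return list of `length_trace` objects.
#' @export
simulate_astral_cohort <- function(n, params, duration_s = 600, dt_s = 4,
                                   noise_sd_um = 0.05, rng_seed = 1L) {
  with_seed(rng_seed, {
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    lapply(seq_len(n), function(i)
      simulate_length_trace(params, duration_s, dt_s, rng_seed = seeds[i],
                            noise_sd_um = noise_sd_um))
  })
}

#' Simulate a plate-reader growth curve
#'
#' OD600(t) = od0 * 2^((t - lag)/doubling_time) for t >= lag (flat at od0
#' before the lag), plus additive Gaussian measurement noise.
#'
#' @param params [growth_params()].
#' @param rng_seed integer seed.
#' @return data frame (`time_min`, `od600`) of class `growth_curve` with the
#'   generating parameters in attribute `truth`.
#' @export
simulate_growth_curve <- function(params, rng_seed = 1L) {
  stopifnot(inherits(params, "growth_params"))
  times <- seq(0, params$duration_h * 60, by = params$interval_min)
  od <- ifelse(times < params$lag_min, params$od0,
               params$od0 * 2^((times - params$lag_min) / params$doubling_time_min))
  od_obs <- with_seed(rng_seed, {
    if (params$noise_sd > 0) od + rnorm(length(od), 0, params$noise_sd) else od
  })
  structure(data.frame(time_min = times, od600 = od_obs),
            class = c("growth_curve", "data.frame"),
            truth = list(params = params, od_true = od, rng_seed = rng_seed))
}
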