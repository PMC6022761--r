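# In vitro dynamics: sliding-window phase segmentation of length traces,
# per-event rates from first/last points, rate-vs-concentration regression,
# and conversion of length rates to subunit fluxes on the 14-protofilament
# lattice (1750 dimers per um).

#' Configuration for in vitro phase segmentation
#'
#' @param window sliding-regression window in frames (odd; default 5).
#' @param min_slope_grow_um_min slope above which a window is classified as
#'   growth (default 0.1 um/min).
#' @param min_slope_shrink_nm_s magnitude of the negative slope beyond which
#'   a window is classified as shrinkage (default 150 nm/s, the catastrophe
#'   calling threshold; lower it to segment slow depolymerizers).
#' @param min_points minimum frames per event (default 3).
#' @return list of class `phase_cfg`.
#' @export
phase_cfg <- function(window = 5L, min_slope_grow_um_min = 0.1,
                      min_slope_shrink_nm_s = 150, min_points = 3L) {
  if (window < 3) stopf("phase_cfg: window must be >= 3")
  structure(list(window = as.integer(window),
                 min_slope_grow_um_min = min_slope_grow_um_min,
                 min_slope_shrink_nm_s = min_slope_shrink_nm_s,
                 min_points = as.integer(min_points)),
            class = "phase_cfg")
}

#' Segment a length trace into polymerization/depolymerization events
#'
#' A centered sliding-window OLS slope is computed at every frame; frames are
#' classified growth (slope > `min_slope_grow_um_min`), shrinkage
#' (slope < -`min_slope_shrink_nm_s`), or neither. Maximal runs of one class
#' are merged into events; events with fewer than `min_points` frames are
#' discarded. Event rates use the first and last points of the event.
#'
#' @param trace a `length_trace` (>= window frames).
#' @param cfg [phase_cfg()].
#' @return data frame of events: `kind` ("growth"/"shrinkage"), `start_idx`,
#'   `end_idx` (1-based frame indices), `start_s`, `end_s`,
#'   `delta_length_um` (signed), `duration_s`, `rate_um_min` (magnitude),
#'   `r_squared` (OLS fit over the event).
#' @export
segment_phases <- function(trace, cfg = phase_cfg()) {
  stopifnot(inherits(trace, "length_trace"))
  n <- nrow(trace)
  if (n < cfg$window) stopf("segment_phases: trace shorter than window (%d < %d)",
                            n, cfg$window)
  t <- trace$time_s; y <- trace$length_um
  slopes <- rolling_slope(t, y, cfg$window)          # um/s
  up <- cfg$min_slope_grow_um_min / 60               # um/s
  dn <- cfg$min_slope_shrink_nm_s / 1000             # um/s
  cls <- ifelse(is.na(slopes), "none",
                ifelse(slopes > up, "growth",
                       ifelse(slopes < -dn, "shrinkage", "none")))
  ev <- list()
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    kind <- r$values[k]
    if (kind == "none") next
    i0 <- starts[k]; i1 <- ends[k]
    sgn <- if (kind == "growth") 1 else -1
    med <- median(abs(diff(y[i0:i1])))
    if (!is.finite(med) || med <= 0) med <- Inf   # degenerate run: no extension
    # the centered window blurs changepoints, so the labelled run can both
    # overhang a switch and stop short of the phase's true extremum; extend
    # over unlabelled frames while the steps stay full-sized and of the
    # phase's sign (a changepoint or boundary hold breaks both), ...
    lo_lim <- if (k > 1 && r$values[k - 1] != "none") starts[k] else
      if (k > 1) starts[k - 1] else 1L
    hi_lim <- if (k < length(r$values) && r$values[k + 1] != "none") ends[k] else
      if (k < length(r$values)) ends[k + 1] else n
    while (i0 > lo_lim && sign(y[i0] - y[i0 - 1]) == sgn &&
           abs(y[i0] - y[i0 - 1]) >= 0.5 * med) i0 <- i0 - 1L
    while (i1 < hi_lim && sign(y[i1 + 1] - y[i1]) == sgn &&
           abs(y[i1 + 1] - y[i1]) >= 0.5 * med) i1 <- i1 + 1L
    # ... then trim to the run's extrema, ...
    seg <- y[i0:i1]
    if (kind == "growth") {
      j0 <- i0 - 1L + which.min(seg); j1 <- i0 - 1L + which.max(seg)
    } else {
      j0 <- i0 - 1L + which.max(seg); j1 <- i0 - 1L + which.min(seg)
    }
    if (j1 > j0) { i0 <- j0; i1 <- j1 }
    # ... and drop boundary frames in which the phase ran only partway
    # through the sampling interval (mid-frame switch, or arrival at the
    # seed): such frames stretch the first-to-last duration, while removing
    # full steps leaves the first-to-last rate unbiased
    tt <- trim_partial_steps(y, i0, i1, cfg$min_points)
    i0 <- tt[1]; i1 <- tt[2]
    if (i1 - i0 + 1L < cfg$min_points) next
    fit <- ols_fit(t[i0:i1], y[i0:i1])
    dl <- y[i1] - y[i0]
    dur <- t[i1] - t[i0]
    ev[[length(ev) + 1]] <- data.frame(
      kind = kind, start_idx = i0, end_idx = i1,
      start_s = t[i0], end_s = t[i1],
      delta_length_um = dl, duration_s = dur,
      rate_um_min = abs(dl) / dur * 60, r_squared = fit$r2)
  }
  if (!length(ev))
    return(data.frame(kind = character(), start_idx = integer(),
                      end_idx = integer(), start_s = numeric(),
                      end_s = numeric(), delta_length_um = numeric(),
                      duration_s = numeric(), rate_um_min = numeric(),
                      r_squared = numeric()))
  do.call(rbind, ev)
}

#' Event rate from first and last points
#'
#' @param delta_length_um signed or unsigned length change over the event.
#' @param duration_s event duration in seconds (> 0).
#' @return rate magnitude in um/min: |dL| / dt * 60.
#' @export
event_rate <- function(delta_length_um, duration_s) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stopf("event_rate: duration must be > 0")
  abs(delta_length_um) / duration_s * 60
}

#' Fit polymerization rate versus tubulin concentration
#'
#' Ordinary least squares through all event-level points (one point per
#' event), with per-concentration means and t-based 95% CIs. The x-intercept
#' is reported as the apparent critical concentration.
#'
#' @param rates data frame with columns `tubulin_conc_uM` and `rate_um_min`.
#' @param conf confidence level for the per-concentration CIs.
#' @return list with `slope_um_min_per_uM`, `intercept_um_min`,
#'   `critical_conc_uM` (x-intercept), `fit` (the `lm` object), and
#'   `per_conc` (data frame: conc, n, mean, lower, upper).
#' @export
fit_rate_vs_concentration <- function(rates, conf = 0.95) {
  stopifnot(is.data.frame(rates),
            all(c("tubulin_conc_uM", "rate_um_min") %in% names(rates)))
  concs <- unique(rates$tubulin_conc_uM)
  if (length(concs) < 2)
    stopf("fit_rate_vs_concentration: need >= 2 distinct concentrations")
  fit <- lm(rate_um_min ~ tubulin_conc_uM, data = rates)
  b <- coef(fit)
  per <- do.call(rbind, lapply(sort(concs), function(cc) {
    x <- rates$rate_um_min[rates$tubulin_conc_uM == cc]
    ci <- mean_ci_t(x, conf)
    data.frame(tubulin_conc_uM = cc, n = ci$n, mean_rate_um_min = ci$mean,
               lower = ci$lower, upper = ci$upper)
  }))
  list(slope_um_min_per_uM = unname(b[2]), intercept_um_min = unname(b[1]),
       critical_conc_uM = unname(-b[1] / b[2]), fit = fit, per_conc = per)
}

#' Apparent on-rate constant from a concentration-dependence slope
#'
#' Converts the slope of the polymerization-rate-versus-concentration line
#' (um min^-1 uM^-1) to subunits uM^-1 s^-1 by multiplying by the number of
#' dimers per micrometer and dividing by 60.
#'
#' @param slope_um_min_per_uM linear-model slope.
#' @param subunits_per_um dimers per um (default 1750, 14 protofilaments at
#'   8-nm repeat).
#' @return apparent on-rate constant, subunits uM^-1 s^-1.
#' @export
on_rate_constant <- function(slope_um_min_per_uM,
                             subunits_per_um = SUBUNITS_PER_UM) {
  if (any(!is.finite(slope_um_min_per_uM)))
    stopf("on_rate_constant: slope must be finite")
  slope_um_min_per_uM * subunits_per_um / 60
}

#' Convert a length rate to a subunit flux
#'
#' @param rate_um_min rate magnitude in um/min.
#' @param subunits_per_um dimers per um (default 1750).
#' @return rate in subunits/s: rate * subunits_per_um / 60.
#' @export
to_subunits_per_s <- function(rate_um_min, subunits_per_um = SUBUNITS_PER_UM) {
  if (any(!is.finite(rate_um_min))) stopf("to_subunits_per_s: rate must be finite")
  rate_um_min * subunits_per_um / 60
}

#' Empirical CDF of microtubule length at catastrophe
#'
#' @param lengths_um lengths at catastrophe (>= 1 value).
#' @return data frame `length_um` (sorted unique values) and `cum_fraction`
#'   (k/n); duplicated lengths share a single step.
#' @export
catastrophe_length_cdf <- function(lengths_um) {
  if (!length(lengths_um)) stopf("catastrophe_length_cdf: empty input")
  n <- length(lengths_um)
  s <- sort(lengths_um)
  u <- unique(s)
  data.frame(length_um = u,
             cum_fraction = cumsum(tabulate(match(s, u))) / n)
}
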