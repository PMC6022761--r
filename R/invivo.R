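# Astral-microtubule event classification and dynamics statistics. An event
# is at least `min_points` contiguous data points producing a length change
# of at least `min_delta_um` with a coefficient of determination of at least
# `min_r2` (the "three-rule" criterion); catastrophe/rescue frequencies
# divide transition counts by the lifetime excluding the opposing phase.

#' Classify assembly/disassembly events in a length trace
#'
#' Candidate phases are maximal runs over which the local (centered
#' three-point) slope keeps one sign; each run is trimmed to its extrema and
#' relieved of partial boundary frames (a frame in which the phase ran only
#' part of the sampling interval), then kept as an event if it satisfies the
#' three-rule criterion: at least `min_points` contiguous points, a
#' first-to-last length change of at least `min_delta_um`, and an OLS
#' coefficient of determination of at least `min_r2`. Consecutive events may
#' share the single extremum frame at a switch; they never overlap
#' otherwise. Requiring one local slope sign throughout keeps a window from
#' straddling a catastrophe or rescue, which a global R^2 rule alone does
#' not exclude once the window is long.
#'
#' @param trace a `length_trace` (>= 3 points).
#' @param min_points minimum points per event (default 3).
#' @param min_delta_um minimum |first-to-last length change| (default 0.5).
#' @param min_r2 minimum coefficient of determination (default 0.80).
#' @return data frame of events: `kind` ("assembly"/"disassembly"),
#'   `start_idx`, `end_idx`, `n_points`, `delta_length_um` (signed),
#'   `duration_s`, `rate_um_min`, `r_squared`.
#' @export
classify_events <- function(trace, min_points = 3L, min_delta_um = 0.5,
                            min_r2 = 0.80) {
  stopifnot(inherits(trace, "length_trace"))
  n <- nrow(trace)
  if (n < 3) stopf("classify_events: trace must have >= 3 points")
  t <- trace$time_s; y <- trace$length_um
  # local slope sign at interior points (centered three-point difference)
  s3 <- sign(y[3:n] - y[1:(n - 2)])          # sign at points 2..n-1
  r <- rle(as.vector(s3))
  ends <- cumsum(r$lengths) + 1L             # back to point indices
  starts <- ends - r$lengths + 1L
  ev <- list()
  for (k in seq_along(r$values)) {
    sgn <- r$values[k]
    if (sgn == 0) next
    i0 <- max(1L, starts[k] - 1L)            # include the flanking points
    i1 <- min(n, ends[k] + 1L)
    # trim to the run's extrema ...
    seg <- y[i0:i1]
    if (sgn > 0) {
      j0 <- i0 - 1L + which.min(seg); j1 <- i0 - 1L + which.max(seg)
    } else {
      j0 <- i0 - 1L + which.max(seg); j1 <- i0 - 1L + which.min(seg)
    }
    if (j1 > j0) { i0 <- j0; i1 <- j1 } else next
    # the three rules judge the extremum-to-extremum window
    if (i1 - i0 + 1L < min_points || abs(y[i1] - y[i0]) < min_delta_um) next
    if (ols_fit(t[i0:i1], y[i0:i1])$r2 < min_r2) next
    # ... then drop a boundary frame holding only a partial step (mid-frame
    # switch) before measuring the rate — full steps keep the first-to-last
    # rate unbiased — but only when the trimmed window still satisfies the
    # three rules, so every emitted event satisfies them as stated
    tt <- trim_partial_steps(y, i0, i1, min_points)
    if ((tt[1] != i0 || tt[2] != i1) &&
        abs(y[tt[2]] - y[tt[1]]) >= min_delta_um &&
        ols_fit(t[tt[1]:tt[2]], y[tt[1]:tt[2]])$r2 >= min_r2) {
      i0 <- tt[1]; i1 <- tt[2]
    }
    npts <- i1 - i0 + 1L
    dl <- y[i1] - y[i0]
    fit <- ols_fit(t[i0:i1], y[i0:i1])
    ev[[length(ev) + 1L]] <- data.frame(
      kind = if (dl > 0) "assembly" else "disassembly",
      start_idx = i0, end_idx = i1, n_points = npts,
      delta_length_um = dl, duration_s = t[i1] - t[i0],
      rate_um_min = abs(dl) / (t[i1] - t[i0]) * 60,
      r_squared = fit$r2)
  }
  if (!length(ev))
    return(data.frame(kind = character(), start_idx = integer(),
                      end_idx = integer(), n_points = integer(),
                      delta_length_um = numeric(), duration_s = numeric(),
                      rate_um_min = numeric(), r_squared = numeric()))
  do.call(rbind, ev)
}

#' In vivo event rate
#'
#' @param delta_length_um first-to-last length change (um).
#' @param duration_s event duration (s).
#' @return |dL| / dt * 60, um/min.
#' @export
event_rate_invivo <- function(delta_length_um, duration_s) {
  event_rate(delta_length_um, duration_s)
}

#' Catastrophe frequency of one microtubule
#'
#' Number of catastrophes divided by (lifetime minus time spent in
#' disassembly), in events/min.
#'
#' @param n_catastrophes catastrophe count.
#' @param lifetime_s total observed lifetime (s).
#' @param time_in_disassembly_s summed duration of disassembly events (s).
#' @return events/min.
#' @export
catastrophe_frequency <- function(n_catastrophes, lifetime_s,
                                  time_in_disassembly_s) {
  denom <- lifetime_s - time_in_disassembly_s
  if (denom <= 0) stopf("catastrophe_frequency: lifetime must exceed disassembly time")
  n_catastrophes / (denom / 60)
}

#' Rescue frequency of one microtubule
#'
#' Number of rescues divided by (lifetime minus time spent in assembly), in
#' events/min.
#'
#' @param n_rescues rescue count.
#' @param lifetime_s total observed lifetime (s).
#' @param time_in_assembly_s summed duration of assembly events (s).
#' @return events/min.
#' @export
rescue_frequency <- function(n_rescues, lifetime_s, time_in_assembly_s) {
  denom <- lifetime_s - time_in_assembly_s
  if (denom <= 0) stopf("rescue_frequency: lifetime must exceed assembly time")
  n_rescues / (denom / 60)
}

#' Per-microtubule dynamics summary
#'
#' Classifies events and tabulates phase times, transition counts, and
#' catastrophe/rescue frequencies. A catastrophe is an entry into a
#' disassembly event from an assembly event or an unclassified interlude
#' (consecutive disassembly fragments are not re-counted); a rescue is an
#' entry into an assembly event following a disassembly event. Unclassified
#' gaps count toward the lifetime but toward neither phase.
#'
#' @param trace a `length_trace`.
#' @param min_points,min_delta_um,min_r2 the three-rule thresholds.
#' @return one-row data frame: lifetime, phase times, event counts, rates
#'   (medians of per-event rates), transition counts, and frequencies.
#' @export
summarize_microtubule <- function(trace, min_points = 3L, min_delta_um = 0.5,
                                  min_r2 = 0.80) {
  ev <- classify_events(trace, min_points, min_delta_um, min_r2)
  lifetime <- diff(range(trace$time_s))
  t_asm <- sum(ev$duration_s[ev$kind == "assembly"])
  t_dis <- sum(ev$duration_s[ev$kind == "disassembly"])
  # every maximal disassembly event is an entry into disassembly from an
  # assembly event or an unclassified interlude, i.e. one catastrophe;
  # likewise for rescues, except that an event beginning at the first frame
  # was not entered from anything
  n_cat <- sum(ev$kind == "disassembly" & ev$start_idx > 1L)
  n_res <- sum(ev$kind == "assembly" & ev$start_idx > 1L)
  poly <- ev$rate_um_min[ev$kind == "assembly"]
  depoly <- ev$rate_um_min[ev$kind == "disassembly"]
  data.frame(lifetime_s = lifetime,
             time_in_assembly_s = t_asm, time_in_disassembly_s = t_dis,
             n_events = nrow(ev), n_catastrophes = n_cat, n_rescues = n_res,
             catastrophe_freq_per_min = if (lifetime > t_dis)
               catastrophe_frequency(n_cat, lifetime, t_dis) else NA_real_,
             rescue_freq_per_min = if (lifetime > t_asm)
               rescue_frequency(n_res, lifetime, t_asm) else NA_real_,
             median_poly_rate_um_min = if (length(poly)) median(poly) else NA_real_,
             median_depoly_rate_um_min = if (length(depoly)) median(depoly) else NA_real_,
             median_poly_duration_s = if (any(ev$kind == "assembly"))
               median(ev$duration_s[ev$kind == "assembly"]) else NA_real_,
             median_depoly_duration_s = if (any(ev$kind == "disassembly"))
               median(ev$duration_s[ev$kind == "disassembly"]) else NA_real_)
}

#' Pool microtubules into a condition summary
#'
#' Event-level rates and durations are pooled across microtubules; medians
#' are reported with order-statistic 95% CIs. Frequencies are summarized over
#' per-microtubule values.
#'
#' @param traces list of `length_trace` objects for one condition.
#' @param min_points,min_delta_um,min_r2 the three-rule thresholds.
#' @return list with `n_microtubules`, `per_mt` (data frame of
#'   [summarize_microtubule()] rows), and `pooled` — a list of [median_ci()]
#'   summaries for `poly_rate_um_min`, `depoly_rate_um_min`,
#'   `poly_duration_s`, `depoly_duration_s`, `catastrophe_freq_per_min`,
#'   `rescue_freq_per_min`.
#' @export
summarize_condition <- function(traces, min_points = 3L, min_delta_um = 0.5,
                                min_r2 = 0.80) {
  if (!length(traces)) stopf("summarize_condition: empty input")
  per <- do.call(rbind, lapply(traces, summarize_microtubule,
                               min_points = min_points,
                               min_delta_um = min_delta_um, min_r2 = min_r2))
  evs <- lapply(traces, classify_events, min_points = min_points,
                min_delta_um = min_delta_um, min_r2 = min_r2)
  all_ev <- do.call(rbind, evs)
  pooled <- list(
    poly_rate_um_min = median_ci(all_ev$rate_um_min[all_ev$kind == "assembly"]),
    depoly_rate_um_min = median_ci(all_ev$rate_um_min[all_ev$kind == "disassembly"]),
    poly_duration_s = median_ci(all_ev$duration_s[all_ev$kind == "assembly"]),
    depoly_duration_s = median_ci(all_ev$duration_s[all_ev$kind == "disassembly"]),
    catastrophe_freq_per_min = median_ci(per$catastrophe_freq_per_min),
    rescue_freq_per_min = median_ci(per$rescue_freq_per_min))
  list(n_microtubules = length(traces), per_mt = per, pooled = pooled)
}

#' Two-sample Mann-Whitney rank-sum test
#'
#' Wraps [stats::wilcox.test()]: exact null distribution for small samples
#' without ties, normal approximation with tie correction otherwise. The U
#' statistic counts pairs (a_i, b_j) with a_i > b_j (plus half-ties).
#'
#' @param a,b numeric samples (both nonempty).
#' @return list with `U`, `p_value` (two-sided), `exact` (logical).
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stopf("rank_sum_test: empty sample")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- !has_ties && length(a) <= 8 && length(b) <= 8
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Fisher's exact test for a 2x2 table
#'
#' Wraps [stats::fisher.test()]: hypergeometric exact test, two-sided by
#' summing tables with probability not exceeding the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `p_value` (two-sided) and `odds_ratio` (conditional MLE).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("fisher_exact_2x2: table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("fisher_exact_2x2: counts must be nonnegative integers")
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
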