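# Culture growth assays: doubling time from the maximal log-linear window of
# an OD600 curve, normalization to a reference, and proportion statistics.

#' Fit a doubling time to an OD600 growth curve
#'
#' The exponential window is the maximal span of consecutive samples with OD
#' between `od_lo` and `od_hi` whose log2(OD)-versus-time regression keeps
#' R^2 >= `min_r2`; the doubling time is 1/slope of that fit. Ties between
#' equally long windows are broken by R^2. Cultures with no qualifying
#' window (or no net growth) are flagged as non-growers.
#'
#' @param curve a `growth_curve` (or data frame with `time_min`, `od600`).
#' @param min_r2 minimum R^2 of the log-linear window (default 0.99).
#' @param od_lo,od_hi OD bounds of the fitted window (defaults 0.1 and 1.0;
#'   the lower bound clears typical inoculation densities and the additive
#'   noise floor, so lag-phase points cannot dilute the fitted slope).
#' @param min_points minimum samples in the window (default 10).
#' @param blank constant blank OD subtracted before fitting (default 0).
#' @return list with `doubling_time_min` (`NA` for non-growers), `no_growth`
#'   (flag), `window_idx` (first/last sample of the fitted window),
#'   `window_min` (times), `r_squared`, `n`.
#' @export
fit_doubling_time <- function(curve, min_r2 = 0.99, od_lo = 0.1, od_hi = 1.0,
                              min_points = 10L, blank = 0) {
  stopifnot(all(c("time_min", "od600") %in% names(curve)))
  t <- curve$time_min
  od <- curve$od600 - blank
  usable <- which(od >= od_lo & od <= od_hi)
  no_fit <- list(doubling_time_min = NA_real_, no_growth = TRUE,
                 window_idx = c(NA_integer_, NA_integer_),
                 window_min = c(NA_real_, NA_real_),
                 r_squared = NA_real_, n = 0L)
  if (length(usable) < min_points) return(no_fit)
  l2 <- log2(od)
  # maximal-span window search over runs of usable samples
  best <- NULL
  runs <- split(usable, cumsum(c(1, diff(usable) != 1)))
  for (run in runs) {
    n <- length(run)
    if (n < min_points) next
    # longest sub-window first; stop once a qualifying span is found that
    # cannot be beaten by a shorter one
    for (len in n:min_points) {
      if (!is.null(best) && len < best$len) break
      for (s in 1:(n - len + 1)) {
        idx <- run[s:(s + len - 1)]
        fit <- ols_fit(t[idx], l2[idx])
        if (fit$r2 >= min_r2 && fit$slope > 0) {
          if (is.null(best) || len > best$len ||
              (len == best$len && fit$r2 > best$r2)) {
            best <- list(len = len, idx = idx, slope = fit$slope, r2 = fit$r2)
          }
        }
      }
      if (!is.null(best) && best$len == len) break
    }
  }
  if (is.null(best)) return(no_fit)
  list(doubling_time_min = 1 / best$slope, no_growth = FALSE,
       window_idx = c(best$idx[1], best$idx[best$len]),
       window_min = c(t[best$idx[1]], t[best$idx[best$len]]),
       r_squared = best$r2, n = best$len)
}

#' Normalize a doubling time to a reference
#'
#' @param sample,reference doubling times (reference > 0).
#' @return ratio sample/reference.
#' @export
normalize_doubling <- function(sample, reference) {
  if (!is.finite(reference) || reference <= 0)
    stopf("normalize_doubling: reference must be > 0")
  sample / reference
}

#' Proportion with its standard error
#'
#' @param k number of positives (0 <= k <= n).
#' @param n total count (> 0).
#' @return list with `k`, `n`, `p = k/n`, and `se = sqrt(p(1-p)/n)`.
#' @export
proportion_with_se <- function(k, n) {
  if (n <= 0) stopf("proportion_with_se: n must be > 0")
  if (k < 0 || k > n) stopf("proportion_with_se: need 0 <= k <= n")
  p <- k / n
  list(k = k, n = n, p = p, se = sqrt(p * (1 - p) / n))
}
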