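# Shared numerical helpers: seeded RNG scoping, rolling regressions,
# order-statistic confidence intervals, bilinear image sampling.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so that all generators in the package are
#' bit-reproducible without side effects on the session.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Ordinary least-squares slope and R-squared of a short series
#'
#' Closed-form simple regression of `y` on `x`; used by the sliding-window
#' classifiers where calling [lm()] per window would dominate runtime.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with `slope`, `intercept`, `r2` (defined as 1 when the fit is
#'   exact or n = 2; 0 when `y` is constant over a longer window).
#' @keywords internal
ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  sst <- sum((y - my)^2)
  r2 <- if (n <= 2) 1 else if (sst <= 0) 0 else {
    sse <- sst - slope * sxy
    max(0, min(1, 1 - sse / sst))
  }
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Centered rolling OLS slope of a sampled series
#'
#' @param t,y numeric vectors (equally spaced `t` assumed for speed is not
#'   required; the true `t` is used).
#' @param window odd integer window width in samples.
#' @return numeric vector of slopes (units of y per unit of t); `NA` at the
#'   edges where the window does not fit.
#' @keywords internal
rolling_slope <- function(t, y, window = 5L) {
  n <- length(y)
  half <- window %/% 2L
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (i in (half + 1L):(n - half)) {
    idx <- (i - half):(i + half)
    out[i] <- ols_fit(t[idx], y[idx])$slope
  }
  out
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial) interval: ranks are chosen from the binomial
#' (n, 1/2) distribution so that coverage is at least `conf` without any
#' distributional assumption on the data.
#'
#' @param x numeric vector.
#' @param conf confidence level (default 0.95).
#' @return list with `median`, `lower`, `upper`, `n`. For n < 3 the interval
#'   degenerates to the sample range.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("median_ci: empty input", call. = FALSE)
  m <- median(x)
  if (n < 3) return(list(median = m, lower = x[1], upper = x[n], n = n))
  alpha <- 1 - conf
  lo <- qbinom(alpha / 2, n, 0.5)        # P(X <= lo) >= alpha/2 boundary
  hi <- qbinom(1 - alpha / 2, n, 0.5) + 1L
  lo <- max(1L, lo)
  hi <- min(n, hi)
  list(median = m, lower = x[lo], upper = x[hi], n = n)
}

#' t-based confidence interval for a mean
#' @param x numeric vector.
#' @param conf confidence level.
#' @return list with `mean`, `lower`, `upper`, `n`.
#' @keywords internal
mean_ci_t <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(list(mean = m, lower = m, upper = m, n = n))
  half <- qt(1 - (1 - conf) / 2, n - 1) * sd(x) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Bilinear interpolation of a matrix at arbitrary points
#'
#' Treats `img[r, c]` as the intensity at integer coordinates (r, c);
#' points outside the matrix return `fill`.
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of (row, column) sample coordinates.
#' @param fill value for out-of-bounds samples.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  out <- rep(fill, length(r))
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  # points exactly on the last row/col
  edge <- (r >= 1 & r <= nr & c >= 1 & c <= nc) & !ok
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1)
    i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i11] * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    out[edge] <- img[cbind(pmin(pmax(round(r[edge]), 1), nr),
                           pmin(pmax(round(c[edge]), 1), nc))]
  }
  out
}

#' Standard Gaussian survival function
#'
#' S(z) = 1 - Phi(z), the complement of the standard normal CDF. This is the
#' model for the fluorescence decay at a tapered microtubule plus end: blunt
#' ends give a step (sigma -> 0), tapered ends a gradual decay.
#'
#' @param z numeric.
#' @return numeric in (0, 1).
#' @export
gauss_survival <- function(z) pnorm(z, lower.tail = FALSE)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Trim partial boundary frames from a phase window
#'
#' A frame in which the phase ran only part of the sampling interval (a
#' mid-frame switch, or arrival at a boundary hold) stretches first-to-last
#' durations while contributing less than a full step. Frames with steps
#' clearly below the phase's median step (< 0.5x) are dropped iteratively
#' from either end, then at most one more frame per end below 0.9x; removing
#' full steps leaves the first-to-last rate unbiased.
#'
#' @param y length series.
#' @param i0,i1 window bounds (indices into `y`).
#' @param min_points smallest window to preserve.
#' @return integer vector `c(i0, i1)` of the trimmed bounds.
#' @keywords internal
trim_partial_steps <- function(y, i0, i1, min_points = 3L) {
  if (i1 - i0 < 3L) return(c(i0, i1))
  med <- median(abs(diff(y[i0:i1])))
  if (!is.finite(med) || med <= 0) return(c(i0, i1))
  while (i1 - i0 + 1L > min_points && abs(y[i1] - y[i1 - 1L]) < 0.5 * med)
    i1 <- i1 - 1L
  while (i1 - i0 + 1L > min_points && abs(y[i0 + 1L] - y[i0]) < 0.5 * med)
    i0 <- i0 + 1L
  if (i1 - i0 + 1L > min_points && abs(y[i1] - y[i1 - 1L]) < 0.9 * med)
    i1 <- i1 - 1L
  if (i1 - i0 + 1L > min_points && abs(y[i0 + 1L] - y[i0]) < 0.9 * med)
    i0 <- i0 + 1L
  c(i0, i1)
}
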