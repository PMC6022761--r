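# Plus-end morphology: axial intensity profiles and Gaussian-survival fits.
# The fitted model is I(x) = background + amplitude * S((x - mu)/sigma) with
# S the standard normal survival function; sigma ("tip SD") measures the
# axial extent of the tapered tip. Blunt ends give sigma near zero (or near
# the PSF SD when the profile is diffraction-limited).

#' Extract an axial intensity profile from an image
#'
#' Samples the image along the given axis at one-pixel steps and aggregates
#' intensities across `halfwidth_px` perpendicular pixels on each side
#' (mean by default, max optionally), using bilinear interpolation.
#'
#' @param image numeric matrix.
#' @param axis list with `centroid` (row, col) and `angle_deg` (as produced
#'   by [detect_seeds()]), or a list with `origin` and `angle_deg` where
#'   `origin` is the axial zero point.
#' @param halfwidth_px perpendicular half-width (>= 0; 0 = single-pixel line
#'   scan).
#' @param pixel_size_nm pixel calibration.
#' @param stat `"mean"` or `"max"` across the perpendicular span.
#' @return data frame `x_nm` (axial position) and `intensity`.
#' @export
extract_profile <- function(image, axis, halfwidth_px = 1,
                            pixel_size_nm = 65, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (halfwidth_px < 0) stopf("extract_profile: halfwidth_px must be >= 0")
  ctr <- if (!is.null(axis$origin)) axis$origin else axis$centroid
  if (ctr[1] < 1 || ctr[1] > nrow(image) || ctr[2] < 1 || ctr[2] > ncol(image))
    stopf("extract_profile: axis origin outside the image")
  th <- axis$angle_deg * pi / 180
  u <- c(-sin(th), cos(th)); nvec <- c(u[2], -u[1])
  tmax <- 0
  repeat {
    p <- ctr + (tmax + 1) * u
    if (p[1] < 1 || p[1] > nrow(image) || p[2] < 1 || p[2] > ncol(image)) break
    tmax <- tmax + 1
  }
  ts <- 0:tmax
  offs <- if (halfwidth_px > 0) seq(-halfwidth_px, halfwidth_px) else 0
  prof <- vapply(ts, function(tt) {
    pr <- ctr[1] + tt * u[1] + offs * nvec[1]
    pc <- ctr[2] + tt * u[2] + offs * nvec[2]
    v <- bilinear_sample(image, pr, pc, fill = NA)
    if (stat == "mean") mean(v, na.rm = TRUE) else max(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(x_nm = ts * pixel_size_nm, intensity = prof)
}

#' Extract the axial profile of one kymograph row
#'
#' @param kymo a `kymograph`.
#' @param frame frame (row) index.
#' @return data frame `x_nm`, `intensity` at pixel centers.
#' @export
kymo_profile <- function(kymo, frame) {
  stopifnot(inherits(kymo, "kymograph"))
  row <- kymo$intensity[frame, ]
  data.frame(x_nm = (seq_along(row) - 0.5) * kymo$pixel_size_nm,
             intensity = row)
}

#' Fit a Gaussian survival curve to a plus-end intensity decay
#'
#' Least-squares fit of
#' `I(x) = background + amplitude * S((x - mu)/sigma)` by variable
#' projection: background and amplitude are linear and profiled out, and
#' `(mu, log sigma)` is optimized by multi-start Nelder-Mead (gradient-free,
#' so the blunt limit where the sigma sensitivity saturates stays well
#' behaved). Initialization: `mu` at the half-maximum crossing of a lightly
#' smoothed profile, `sigma` from its 16th/84th percentile crossings,
#' amplitude and background from the plateau levels. Fitting is restricted
#' to a window around the decay
#' (`plateau_px` pixels of plateau before the half-max crossing to
#' `tail_px` pixels of background after), so that upstream lattice
#' variations do not bias the tip fit.
#'
#' @param profile data frame with `x_nm` and `intensity`, spanning the tip
#'   (high plateau to background) with >= 10 points.
#' @param psf_sigma_nm optional PSF SD; when given, a quadrature-corrected
#'   `sigma_corrected_nm = sqrt(max(sigma^2 - psf^2, 0))` is reported.
#' @param plateau_px,tail_px fit-window margins (default 10 each).
#' @return object of class `tip_fit`: list with `mu_nm`, `sigma_nm`,
#'   `amplitude`, `background`, `rmse`, `converged`, `reason`,
#'   `sigma_pinned`, and optionally `sigma_corrected_nm`.
#' @export
fit_tip_profile <- function(profile, psf_sigma_nm = NULL,
                            plateau_px = 10, tail_px = 10) {
  stopifnot(is.data.frame(profile),
            all(c("x_nm", "intensity") %in% names(profile)))
  x <- profile$x_nm; y <- profile$intensity
  fail <- function(reason)
    structure(list(mu_nm = NA_real_, sigma_nm = NA_real_,
                   amplitude = NA_real_, background = NA_real_,
                   rmse = NA_real_, converged = FALSE, reason = reason,
                   sigma_pinned = FALSE),
              class = "tip_fit")
  if (length(x) < 10) return(fail("fewer than 10 points"))
  npl <- max(3, min(5, length(y) %/% 4))
  hi <- median(head(y, npl)); lo <- median(tail(y, npl))
  if (!(hi > lo)) return(fail("profile does not decay"))
  amp0 <- hi - lo
  # initialize from a lightly smoothed profile so plateau noise cannot fake
  # a level crossing; the fit itself uses the raw data
  ys <- stats::runmed(y, 5)
  norm <- (ys - lo) / amp0
  crossing <- function(level) {
    below <- which(norm <= level)
    below <- below[below > 1]
    if (!length(below)) return(NA_real_)
    i <- below[1]
    x0 <- x[i - 1]; x1 <- x[i]; y0 <- norm[i - 1]; y1 <- norm[i]
    if (y0 == y1) return(x1)
    x0 + (y0 - level) / (y0 - y1) * (x1 - x0)
  }
  mu0 <- crossing(0.5)
  if (is.na(mu0)) return(fail("no half-maximum crossing"))
  x84 <- crossing(0.16); x16 <- crossing(0.84)    # decay: 84% level first
  sig0 <- if (!is.na(x84) && !is.na(x16)) max((x84 - x16) / 2, 1) else
    max(mean(diff(x)), 1)
  px <- mean(diff(x))
  # fit window: plateau/background margins in pixels, widened to cover the
  # full decay when the initial sigma estimate is broad
  keep <- x >= mu0 - max(plateau_px * px, 3 * sig0) &
    x <= mu0 + max((tail_px + 2) * px, 4 * sig0)
  if (sum(keep) < 8) keep <- rep(TRUE, length(x))
  xw <- x[keep]; yw <- y[keep]
  sig_lo <- px / 20
  # variable projection: for a given (mu, sigma) the background and
  # amplitude are linear, so profile them out and search only (mu, log s).
  # Nelder-Mead needs no gradients, which keeps the blunt limit (where the
  # sigma gradient saturates to zero) well behaved.
  sse_of <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    s <- pnorm((mu - xw) / sig)
    X <- cbind(1, s)
    cf <- tryCatch(qr.coef(qr(X), yw), error = function(e) c(NA, NA))
    if (any(!is.finite(cf))) return(sum((yw - mean(yw))^2))
    sum((yw - X %*% cf)^2)
  }
  starts <- list(c(mu0, log(max(sig0, sig_lo))),
                 c(mu0, log(max(3 * sig0, 2 * px))),
                 c(mu0, log(max(sig0 / 3, sig_lo))),
                 c(mu0, log(6 * px)))
  opts <- lapply(starts, function(s0)
    stats::optim(s0, sse_of, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12)))
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  mu_f <- opt$par[1]; sig_f <- exp(opt$par[2])
  s <- pnorm((mu_f - xw) / sig_f)
  cf <- qr.coef(qr(cbind(1, s)), yw)
  res <- yw - cf[1] - cf[2] * s
  if (!all(is.finite(cf)) || cf[2] <= 0)
    return(fail("degenerate fit (nonpositive amplitude)"))
  if (sig_f > diff(range(xw)))
    return(fail("sigma exceeds the profile span (no resolvable decay)"))
  out <- list(mu_nm = mu_f, sigma_nm = max(sig_f, sig_lo),
              amplitude = unname(cf[2]), background = unname(cf[1]),
              rmse = sqrt(mean(res^2)),
              converged = opt$convergence == 0, reason = NA_character_,
              sigma_pinned = sig_f <= sig_lo * 1.01)
  if (!is.null(psf_sigma_nm))
    out$sigma_corrected_nm <- sqrt(max(out$sigma_nm^2 - psf_sigma_nm^2, 0))
  structure(out, class = "tip_fit")
}

#' Instantaneous polymerization rate per frame
#'
#' Centered sliding-window OLS slope of the length trace, in um/min, used to
#' pair each tip fit with a concurrent polymerization rate.
#'
#' @param trace a `length_trace`.
#' @param window window width in frames (default 5).
#' @return numeric vector (um/min), `NA` at the edges.
#' @export
instantaneous_rate <- function(trace, window = 5L) {
  rolling_slope(trace$time_s, trace$length_um, window) * 60
}

#' Mean tip SD binned by polymerization rate
#'
#' @param fits data frame with columns `rate_um_min` and `sigma_nm` (one row
#'   per fitted time point).
#' @param breaks numeric vector of bin edges for the rate (um/min).
#' @param conf confidence level for the t-based CI.
#' @return data frame per nonempty bin: `rate_bin`, `rate_mid_um_min`, `n`,
#'   `mean_sigma_nm`, `lower`, `upper`.
#' @export
mean_tipsd_by_rate <- function(fits, breaks, conf = 0.95) {
  stopifnot(is.data.frame(fits),
            all(c("rate_um_min", "sigma_nm") %in% names(fits)))
  ok <- is.finite(fits$rate_um_min) & is.finite(fits$sigma_nm)
  fits <- fits[ok, ]
  if (!nrow(fits)) stopf("mean_tipsd_by_rate: no rate/tip-SD pairs")
  bin <- cut(fits$rate_um_min, breaks, include.lowest = TRUE)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  rows <- lapply(which(tabulate(bin, nbins = nlevels(bin)) > 0), function(b) {
    s <- fits$sigma_nm[as.integer(bin) == b]
    ci <- mean_ci_t(s, conf)
    data.frame(rate_bin = levels(bin)[b], rate_mid_um_min = mids[b],
               n = ci$n, mean_sigma_nm = ci$mean,
               lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, rows)
}
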