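# From movies to kymographs to length traces: seed detection, drift
# correction by phase correlation, axis resampling with bilinear
# interpolation, max-projection, and intensity-threshold length tracking.

#' Otsu threshold of an intensity matrix
#'
#' Rescales to [0, 1], applies Otsu's method (via EBImage), and returns the
#' threshold on the original intensity scale.
#'
#' @param img numeric matrix.
#' @return scalar threshold; `Inf` for a constant image (nothing above).
#' @export
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(Inf)
  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  rng[1] + th * diff(rng)
}

#' Detect stabilized seeds in a single-channel image
#'
#' Thresholds the image (Otsu by default), labels connected components, and
#' returns one record per component at least `min_length_px` long, with the
#' centroid, principal-axis angle, and endpoints.
#'
#' @param seed_image 2D numeric matrix (the seed channel).
#' @param threshold intensity threshold; `NULL` for Otsu.
#' @param min_length_px minimum end-to-end extent in pixels (default 5).
#' @return list of records, each with `centroid` (row, col), `angle_deg`
#'   (counterclockwise from the +column direction, in (-90, 90]),
#'   `endpoints` (2 x 2 matrix, rows = (row, col) of the two ends), and
#'   `length_px`. An empty/uniform image yields an empty list.
#' @export
detect_seeds <- function(seed_image, threshold = NULL, min_length_px = 5) {
  if (!is.matrix(seed_image)) stopf("detect_seeds: seed_image must be a matrix")
  th <- if (is.null(threshold)) otsu_threshold(seed_image) else threshold
  mask <- seed_image > th
  if (!any(mask)) return(list())
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- as.matrix(EBImage::imageData(labels))
  out <- list()
  for (k in seq_len(max(labels))) {
    idx <- which(labels == k, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    ctr <- colMeans(idx)
    centered <- sweep(idx, 2, ctr)
    ev <- eigen(crossprod(centered) / nrow(idx), symmetric = TRUE)
    v <- ev$vectors[, 1]                        # principal direction (row, col)
    ang <- atan2(-v[1], v[2]) * 180 / pi        # CCW from +col; row grows down
    if (ang <= -90) ang <- ang + 180
    if (ang > 90) ang <- ang - 180
    proj <- centered %*% v
    len <- diff(range(proj)) + 1
    if (len < min_length_px) next
    # refine the endpoints to the subpixel half-maximum crossings of the
    # axial profile (a PSF-symmetric edge lies at half-max, so thresholded
    # extents, which overshoot by the blur, are pulled back to the true edge)
    ts <- seq(min(proj) - 4, max(proj) + 4, by = 0.25)
    prof <- bilinear_sample(seed_image, ctr[1] + ts * v[1],
                            ctr[2] + ts * v[2], fill = NA)
    lo <- median(seed_image[!mask])
    hi <- median(prof[ts > quantile(proj, 0.25) & ts < quantile(proj, 0.75)],
                 na.rm = TRUE)
    half <- (hi + lo) / 2
    above <- which(!is.na(prof) & prof > half)
    if (length(above) >= 2) {
      t_lo <- ts[above[1]]; t_hi <- ts[above[length(above)]]
      if (t_hi - t_lo + 1 >= min_length_px) {
        proj <- c(t_lo, t_hi)
        len <- t_hi - t_lo + 1
      }
    }
    ep <- rbind(ctr + min(proj) * v, ctr + max(proj) * v)
    colnames(ep) <- c("row", "col")
    out[[length(out) + 1]] <- list(centroid = ctr, angle_deg = ang,
                                   endpoints = ep, length_px = len)
  }
  out
}

# Upsampled inverse DFT of a cross-power spectrum over a small neighborhood
# (matrix-multiply formulation); returns the |CC| matrix on the refined grid.
dft_upsample <- function(R, nor, noc, usfac, roff, coff) {
  nr <- nrow(R); nc <- ncol(R)
  fr <- (seq_len(nr) - 1 + floor(nr / 2)) %% nr - floor(nr / 2)
  fc <- (seq_len(nc) - 1 + floor(nc / 2)) %% nc - floor(nc / 2)
  kr <- exp(2i * pi / (nr * usfac) * outer((0:(nor - 1)) - roff, fr))
  kc <- exp(2i * pi / (nc * usfac) * outer(fc, (0:(noc - 1)) - coff))
  Mod(kr %*% R %*% kc)
}

#' Cross-correlation shift between two images
#'
#' Estimates the translation that maps `ref` onto `img` (i.e. `img` is `ref`
#' shifted by the returned amount) from the Fourier cross-power spectrum;
#' the integer peak is refined on a `usfac`-times upsampled local grid.
#' By default the spectrum keeps its energy weighting, which is robust when
#' shot noise dominates the high frequencies; `whiten = TRUE` gives the
#' classical phase-only correlation (sharper peak, noise-sensitive).
#'
#' @param ref,img numeric matrices of identical size.
#' @param usfac upsampling factor for subpixel refinement (1 = integer only).
#' @param whiten normalize every frequency to unit magnitude.
#' @return numeric (dy, dx) in pixels (row shift, column shift).
#' @export
phase_correlate <- function(ref, img, usfac = 20, whiten = FALSE) {
  stopifnot(all(dim(ref) == dim(img)))
  A <- fft(ref - mean(ref)); B <- fft(img - mean(img))
  R <- A * Conj(B)
  if (whiten) R <- R / pmax(Mod(R), .Machine$double.eps)
  cc <- Mod(fft(R, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(ref); nc <- ncol(ref)
  sh <- c(pk[1] - 1, pk[2] - 1)
  sh[1] <- if (sh[1] > nr / 2) sh[1] - nr else sh[1]
  sh[2] <- if (sh[2] > nc / 2) sh[2] - nc else sh[2]
  sh <- -sh                     # peak sits at minus the displacement
  if (usfac > 1) {
    half <- ceiling(1.5 * usfac / 2)
    ccu <- dft_upsample(R, 2 * half + 1, 2 * half + 1, usfac,
                        -(-sh[1] * usfac - half), -(-sh[2] * usfac - half))
    pku <- which(ccu == max(ccu), arr.ind = TRUE)[1, ]
    sh <- sh - (c(pku[1], pku[2]) - 1 - half) / usfac
  }
  unname(sh)
}

#' Translate an image by a (fractional) pixel shift
#'
#' @param img numeric matrix.
#' @param dy,dx shift in rows/columns; output pixel (r, c) samples
#'   `img(r - dy, c - dx)` bilinearly, `fill` outside.
#' @param fill out-of-bounds fill value.
#' @return shifted matrix.
#' @export
translate_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc) - dy
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  matrix(bilinear_sample(img, as.vector(rows), as.vector(cols), fill = fill),
         nr, nc)
}

#' Register a movie against its first frame
#'
#' Phase-correlation drift correction: each frame of the reference channel is
#' aligned to the first frame; the estimated shifts are removed from all
#' supplied channels. Featureless (constant) frames get zero shift and a
#' warning flag.
#'
#' @param movie ny x nx x nframes array (reference channel, e.g. the seeds),
#'   or an `mt_movie` (its `seed` channel is the reference and both channels
#'   are corrected).
#' @param usfac phase-correlation upsampling factor (default 20, ~0.05 px).
#' @return for an array: list with `movie` (registered array), `shifts`
#'   (nframes x 2, dy/dx of each frame relative to frame 1) and `flags`
#'   (logical, featureless frames). For an `mt_movie`: the movie with both
#'   channels registered plus the same `shifts`/`flags` fields.
#' @export
register_frames <- function(movie, usfac = 20) {
  if (inherits(movie, "mt_movie")) {
    res <- register_frames(movie$seed, usfac = usfac)
    out <- movie
    out$seed <- res$movie
    dyn <- movie$dynamic
    for (f in seq_len(dim(dyn)[3]))
      dyn[, , f] <- translate_image(dyn[, , f, drop = TRUE],
                                    -res$shifts[f, 1], -res$shifts[f, 2])
    out$dynamic <- dyn
    out$shifts <- res$shifts; out$flags <- res$flags
    return(out)
  }
  stopifnot(length(dim(movie)) == 3)
  nf <- dim(movie)[3]
  if (nf < 2) stopf("register_frames: need at least 2 frames")
  ref <- movie[, , 1, drop = TRUE]
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  flags <- logical(nf)
  out <- movie
  for (f in 2:nf) {
    fr <- movie[, , f, drop = TRUE]
    if (sd(fr) < .Machine$double.eps || sd(ref) < .Machine$double.eps) {
      flags[f] <- TRUE
      next
    }
    shifts[f, ] <- phase_correlate(ref, fr, usfac = usfac)
    out[, , f] <- translate_image(fr, -shifts[f, 1], -shifts[f, 2])
  }
  list(movie = out, shifts = shifts, flags = flags)
}

#' Build a kymograph from a registered movie
#'
#' For every frame the image is resampled along the seed axis (equivalent to
#' rotating the axis horizontal with bilinear interpolation), cropped to
#' `crop_halfwidth_px` rows above and below the axis, and max-projected into
#' a single line; lines are stacked in time order. Axial pixel 0 is at the
#' seed end given by `direction`.
#'
#' @param movie `mt_movie`, or ny x nx x nframes array (the channel to
#'   project, normally the dynamic channel).
#' @param seed one seed record from [detect_seeds()] (axis from the seed
#'   channel only).
#' @param imaging [imaging_params()]; supplies calibration and the default
#'   crop half-width.
#' @param crop_halfwidth_px rows kept above/below the axis (>= 1).
#' @param direction +1 to read out along the seed's principal axis, -1 for
#'   the opposite sense.
#' @return a `kymograph` (list with `intensity`, `pixel_size_nm`,
#'   `frame_interval_s`, `seed_span_px`).
#' @export
build_kymograph <- function(movie, seed, imaging,
                            crop_halfwidth_px = imaging$crop_halfwidth_px,
                            direction = 1) {
  if (crop_halfwidth_px < 1)
    stopf("build_kymograph: crop_halfwidth_px must be >= 1")
  arr <- if (inherits(movie, "mt_movie")) movie$dynamic else movie
  stopifnot(length(dim(arr)) == 3)
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nf <- dim(arr)[3]
  th <- seed$angle_deg * pi / 180
  u <- direction * c(-sin(th), cos(th))
  nvec <- c(u[2], -u[1])
  ctr <- seed$centroid
  # seed endpoints projected on the axis
  proj <- as.numeric(sweep(seed$endpoints, 2, ctr) %*% u)
  t0 <- min(proj)
  # sample axial positions from the trailing seed end forward to the border
  tmax <- t0
  repeat {
    p <- ctr + (tmax + 1) * u
    if (p[1] < 1 || p[1] > ny || p[2] < 1 || p[2] > nx) break
    tmax <- tmax + 1
  }
  ts <- seq(t0, tmax, by = 1)
  # perpendicular margin check over the seed region
  for (o in c(-crop_halfwidth_px, crop_halfwidth_px)) {
    p1 <- ctr + t0 * u + o * nvec
    p2 <- ctr + max(proj) * u + o * nvec
    if (any(c(p1, p2) < 1) || p1[1] > ny || p2[1] > ny || p1[2] > nx || p2[2] > nx)
      stopf("build_kymograph: axis too close to the image border for a crop half-width of %d px",
            crop_halfwidth_px)
  }
  offs <- seq(-crop_halfwidth_px, crop_halfwidth_px)
  rr <- outer(ts, rep(1, length(offs))) * u[1] +
    outer(rep(1, length(ts)), offs) * nvec[1] + ctr[1]
  cc <- outer(ts, rep(1, length(offs))) * u[2] +
    outer(rep(1, length(ts)), offs) * nvec[2] + ctr[2]
  kymo <- matrix(NA_real_, nf, length(ts))
  for (f in seq_len(nf)) {
    vals <- matrix(bilinear_sample(arr[, , f, drop = TRUE],
                                   as.vector(rr), as.vector(cc),
                                   fill = NA),
                   length(ts), length(offs))
    kymo[f, ] <- apply(vals, 1, max, na.rm = TRUE)
  }
  seed_len_px <- diff(range(proj))
  structure(list(intensity = kymo,
                 pixel_size_nm = imaging$pixel_size_nm,
                 frame_interval_s = imaging$frame_interval_s,
                 seed_span_px = c(0L, as.integer(round(seed_len_px)) + 1L)),
            class = "kymograph")
}

#' Track microtubule length from a kymograph
#'
#' Per frame, the length is the distance (pixels times pixel size) from the
#' chosen seed end to the farthest contiguous above-threshold pixel; a run of
#' more than `max_gap_px` below-threshold pixels terminates the microtubule
#' (guarding against speckle). Frames entirely below threshold get length 0
#' and a flag.
#'
#' @param kymo a `kymograph`.
#' @param threshold_method `"otsu"` (default; whole-kymograph Otsu),
#'   `"fixed"` (use `threshold`), or `"bg_ksd"` (background mean + k SD,
#'   background taken from the far 10% of axial columns).
#' @param direction `"forward"` tracks outward from the high end of
#'   `seed_span_px`, `"reverse"` from the low end, `"auto"` picks the end
#'   with the larger net length change over the movie (the faster end is
#'   taken as the plus end).
#' @param threshold fixed threshold (for `"fixed"`).
#' @param k multiplier for `"bg_ksd"` (default 3).
#' @param max_gap_px largest below-threshold run bridged within a
#'   microtubule (default 1, i.e. a gap of >= 2 pixels terminates).
#' @return a `length_trace` with columns `time_s`, `length_um`, `flag`.
#' @export
track_length <- function(kymo, threshold_method = c("otsu", "fixed", "bg_ksd"),
                         direction = c("auto", "forward", "reverse"),
                         threshold = NULL, k = 3, max_gap_px = 1) {
  threshold_method <- match.arg(threshold_method)
  direction <- match.arg(direction)
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$intensity
  if (nrow(m) < 5) stopf("track_length: need at least 5 frames")
  th <- switch(threshold_method,
               otsu = otsu_threshold(m),
               fixed = {
                 if (is.null(threshold)) stopf("track_length: threshold required")
                 threshold
               },
               bg_ksd = {
                 bgcols <- max(1, ncol(m) - ceiling(ncol(m) * 0.1) + 1):ncol(m)
                 bg <- m[, bgcols]
                 mean(bg) + k * sd(bg)
               })
  track_one <- function(dirn) {
    n <- ncol(m)
    s_hi <- kymo$seed_span_px[2]        # first dynamic column (1-based) = s_hi + 1
    lengths <- numeric(nrow(m)); flags <- logical(nrow(m))
    for (f in seq_len(nrow(m))) {
      mask <- m[f, ] > th
      if (dirn > 0) {
        jseq <- seq.int(s_hi + 1, n)
        boundary <- s_hi
      } else {
        jseq <- seq.int(kymo$seed_span_px[1] + 1, 1)  # not reached for span at 0
        boundary <- kymo$seed_span_px[1] + 1
      }
      tip <- NA_integer_; gap <- 0
      for (j in jseq) {
        if (j < 1 || j > n) break
        if (mask[j]) { tip <- j; gap <- 0 } else {
          gap <- gap + 1
          if (gap > max_gap_px) break
        }
      }
      if (is.na(tip)) { lengths[f] <- 0; flags[f] <- TRUE }
      else lengths[f] <- abs(tip - boundary) * kymo$pixel_size_nm / 1000
    }
    list(lengths = lengths, flags = flags)
  }
  if (direction == "auto") {
    fwd <- track_one(1); rev <- track_one(-1)
    pick <- if (abs(diff(range(fwd$lengths))) >= abs(diff(range(rev$lengths))))
      fwd else rev
  } else pick <- track_one(if (direction == "forward") 1 else -1)
  times <- (seq_len(nrow(m)) - 1) * kymo$frame_interval_s
  df <- data.frame(time_s = times, length_um = pick$lengths, flag = pick$flags)
  structure(df, class = c("length_trace", "data.frame"),
            frame_interval_s = kymo$frame_interval_s,
            threshold = th, threshold_method = threshold_method)
}
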