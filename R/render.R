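# TIRF image formation. The axial intensity of a microtubule whose plus end
# tapers with SD sigma_tip is modelled as amplitude * S((x - tip)/sigma_tip)
# with S the standard Gaussian survival function; convolution with a Gaussian
# PSF of SD sigma_psf is again a Gaussian survival with
# sigma_eff = sqrt(sigma_tip^2 + sigma_psf^2), so profiles are rendered
# analytically at pixel centers.

# axial profile (counts above background) for a polymer spanning [x0, x1] nm,
# with a sharp (PSF-blurred) minus edge at x0 and a tapered plus edge at x1
axial_profile <- function(x_nm, x0_nm, x1_nm, amplitude, psf_sigma_nm,
                          tip_sd_nm = 0) {
  rise <- if (psf_sigma_nm > 0) pnorm((x_nm - x0_nm) / psf_sigma_nm)
          else as.numeric(x_nm >= x0_nm)
  sig_eff <- sqrt(tip_sd_nm^2 + psf_sigma_nm^2)
  fall <- if (sig_eff > 0) gauss_survival((x_nm - x1_nm) / sig_eff)
          else as.numeric(x_nm < x1_nm)
  amplitude * rise * fall
}

apply_noise <- function(img, imaging) {
  switch(imaging$noise_model,
         none = img,
         gaussian = img + matrix(rnorm(length(img), 0, imaging$read_noise_sd),
                                 nrow(img)),
         poisson = matrix(rpois(length(img), pmax(img, 0)), nrow(img)) +
           matrix(rnorm(length(img), 0, imaging$read_noise_sd), nrow(img)))
}

#' Render a kymograph from a length trace
#'
#' Each row is the axial intensity profile of a microtubule of the trace's
#' length at that frame: background plus amplitude times the Gaussian
#' survival of the tip position, convolved analytically with the PSF, with
#' noise per `imaging$noise_model`. Axial pixel 0 starts at the seed minus
#' end; the seed occupies `[0, seed_length)` and is rendered into a separate
#' seed channel. `tip_sd_nm = 0` with `psf_sigma_nm = 0` yields a step edge.
#'
#' @param trace a `length_trace`; lengths are dynamic length beyond the seed.
#' @param imaging [imaging_params()].
#' @param rng_seed integer seed for the noise draws.
#' @param width_px field of view in axial pixels; default fits the longest
#'   length with 10% margin. An error names the required width when the trace
#'   does not fit.
#' @param seed_length_um stable-seed length rendered in the seed channel.
#' @return object of class `kymograph`: list with `intensity` (frames x
#'   axial px, dynamic channel), `seed_channel`, `pixel_size_nm`,
#'   `frame_interval_s`, `seed_span_px` ([start, end) 0-based), and `truth`
#'   (tip positions in px and nm per frame).
#' @export
render_kymograph <- function(trace, imaging, rng_seed = 1L, width_px = NULL,
                             seed_length_um = 2) {
  stopifnot(inherits(trace, "length_trace"), inherits(imaging, "imaging_params"))
  px <- imaging$pixel_size_nm
  tip_nm <- (seed_length_um + trace$length_um) * 1000
  need_px <- ceiling(max(tip_nm) / px + 5 * (imaging$psf_sigma_nm +
                                               imaging$tip_sd_nm + px) / px)
  if (is.null(width_px)) width_px <- ceiling(need_px * 1.1)
  if (width_px < need_px)
    stopf("render_kymograph: trace needs a field of view of >= %d px (got %d)",
          need_px, width_px)
  x <- (seq_len(width_px) - 0.5) * px          # pixel-center coordinates, nm
  amp <- imaging$photons_per_um * px / 1000
  nf <- nrow(trace)
  dyn <- matrix(imaging$background_level, nf, width_px)
  for (f in seq_len(nf)) {
    dyn[f, ] <- dyn[f, ] + axial_profile(x, seed_length_um * 1000, tip_nm[f],
                                         amp, imaging$psf_sigma_nm,
                                         imaging$tip_sd_nm)
  }
  seed_row <- imaging$background_level +
    axial_profile(x, 0, seed_length_um * 1000, amp, imaging$psf_sigma_nm, 0)
  seed_ch <- matrix(seed_row, nf, width_px, byrow = TRUE)
  with_seed(rng_seed, {
    dyn <- apply_noise(dyn, imaging)
    seed_ch <- apply_noise(seed_ch, imaging)
  })
  structure(list(intensity = dyn, seed_channel = seed_ch,
                 pixel_size_nm = px,
                 frame_interval_s = attr(trace, "frame_interval_s"),
                 seed_span_px = c(0L, as.integer(ceiling(seed_length_um * 1000 / px))),
                 truth = list(trace = trace, imaging = imaging,
                              seed_length_um = seed_length_um,
                              tip_nm = tip_nm, tip_px = tip_nm / px,
                              rng_seed = rng_seed)),
            class = "kymograph")
}

#' Render a two-channel TIRF movie from a length trace
#'
#' Produces an image stack in which a microtubule grows from a stable seed
#' along an axis at `angle_deg` through `origin_px`. Channel 1 is the
#' (static) seed, channel 2 the dynamic polymer. Transverse intensity falls
#' off as a Gaussian of SD `psf_sigma_nm` about the axis.
#'
#' @param trace a `length_trace`.
#' @param imaging [imaging_params()].
#' @param ny,nx image size in pixels (rows, columns).
#' @param origin_px numeric (row, col) of the seed minus end, in pixels.
#' @param angle_deg axis angle, degrees counterclockwise from the +column
#'   direction.
#' @param seed_length_um stable-seed length (um).
#' @param rng_seed integer seed for noise.
#' @return object of class `mt_movie`: list with `seed` and `dynamic`
#'   (ny x nx x frames arrays), `imaging`, `origin_px`, `angle_deg`,
#'   `seed_length_um`, and `truth`.
#' @export
render_movie <- function(trace, imaging, ny = 64, nx = 256,
                         origin_px = c(ny / 2, 20), angle_deg = 0,
                         seed_length_um = 2, rng_seed = 1L) {
  stopifnot(inherits(trace, "length_trace"), inherits(imaging, "imaging_params"))
  px <- imaging$pixel_size_nm
  th <- angle_deg * pi / 180
  u <- c(-sin(th), cos(th))   # (row, col) step per axial pixel
  # axial (s) and perpendicular (d) coordinates of every pixel, in nm
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  dr <- (rows - origin_px[1]) * px
  dc <- (cols - origin_px[2]) * px
  s <- dr * u[1] + dc * u[2]
  d <- -dr * u[2] + dc * u[1]
  sig_t <- max(imaging$psf_sigma_nm, px / 2)   # transverse footprint
  transverse <- exp(-d^2 / (2 * sig_t^2))
  amp <- imaging$photons_per_um * px / 1000
  tip_nm <- (seed_length_um + trace$length_um) * 1000
  nf <- nrow(trace)
  dyn <- array(0, c(ny, nx, nf))
  seed_img <- imaging$background_level +
    axial_profile(s, 0, seed_length_um * 1000, amp, imaging$psf_sigma_nm, 0) *
    transverse
  seed_arr <- array(0, c(ny, nx, nf))
  for (f in seq_len(nf)) {
    dyn[, , f] <- imaging$background_level +
      axial_profile(s, seed_length_um * 1000, tip_nm[f], amp,
                    imaging$psf_sigma_nm, imaging$tip_sd_nm) * transverse
    seed_arr[, , f] <- seed_img
  }
  with_seed(rng_seed, {
    for (f in seq_len(nf)) {
      dyn[, , f] <- apply_noise(dyn[, , f, drop = TRUE], imaging)
      seed_arr[, , f] <- apply_noise(seed_arr[, , f, drop = TRUE], imaging)
    }
  })
  structure(list(seed = seed_arr, dynamic = dyn, imaging = imaging,
                 origin_px = origin_px, angle_deg = angle_deg,
                 seed_length_um = seed_length_um,
                 truth = list(trace = trace, tip_nm = tip_nm,
                              rng_seed = rng_seed)),
            class = "mt_movie")
}
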