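# Parameter containers. Plain validated lists with S3 classes; defaults carry
# the acquisition calibrations used throughout (65-nm pixels, 3-s TIRF frames,
# 1-s washout frames) and the 14-protofilament lattice constant.

#' Number of tubulin dimers per micrometer of microtubule
#'
#' A 14-protofilament lattice with an 8-nm dimer repeat carries
#' 14 x 1000/8 = 1750 dimers per micrometer; this constant converts length
#' rates (um/min) to subunit fluxes (subunits/s).
#' @export
SUBUNITS_PER_UM <- 14 * 1000 / 8

#' Dynamic-instability parameters
#'
#' Ground-truth kinetic parameters of the two-state (growth/shrinkage) model:
#' constant velocities and first-order switching hazards.
#'
#' @param v_grow_um_min polymerization velocity, um/min (>= 0).
#' @param v_shrink_um_min depolymerization speed (magnitude), um/min (>= 0).
#' @param f_cat_per_min catastrophe frequency, events/min, hazard while
#'   growing (>= 0).
#' @param f_res_per_min rescue frequency, events/min, hazard while shrinking
#'   (>= 0).
#' @param seed_length_um length of the stable seed; the dynamic length never
#'   falls below it.
#' @param renucleate if `TRUE` (default) a microtubule that depolymerizes to
#'   the seed resumes growth immediately; if `FALSE` it terminates and holds
#'   at the seed.
#' @return object of class `di_params`.
#' @export
di_params <- function(v_grow_um_min, v_shrink_um_min,
                      f_cat_per_min, f_res_per_min,
                      seed_length_um = 0, renucleate = TRUE) {
  vals <- c(v_grow_um_min, v_shrink_um_min, f_cat_per_min, f_res_per_min,
            seed_length_um)
  if (any(!is.finite(vals)) || any(vals < 0))
    stopf("di_params: all kinetic parameters must be finite and >= 0")
  structure(list(v_grow_um_min = v_grow_um_min,
                 v_shrink_um_min = v_shrink_um_min,
                 f_cat_per_min = f_cat_per_min,
                 f_res_per_min = f_res_per_min,
                 seed_length_um = seed_length_um,
                 renucleate = isTRUE(renucleate)),
            class = "di_params")
}

#' Imaging / rendering parameters
#'
#' Calibration and image-formation parameters for the TIRF renderer and for
#' kymograph construction.
#'
#' @param pixel_size_nm length per pixel (default 65).
#' @param frame_interval_s time per frame (default 3, single-plane TIRF).
#' @param psf_sigma_nm Gaussian point-spread SD (default 130, ~ lambda/2NA
#'   FWHM of 300 nm for a 1.49 NA objective).
#' @param tip_sd_nm ground-truth taper SD of the rendered plus end (0 = blunt
#'   step edge).
#' @param photons_per_um mean signal density (counts per um of polymer per
#'   pixel row).
#' @param background_level mean background intensity (counts).
#' @param noise_model one of `"none"`, `"gaussian"`, `"poisson"`; `"poisson"`
#'   applies shot noise to signal plus background and then additive Gaussian
#'   read noise.
#' @param read_noise_sd SD of the additive Gaussian read noise (counts).
#' @param crop_halfwidth_px rows kept above/below the microtubule axis when
#'   cropping (default 4).
#' @return object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size_nm = 65, frame_interval_s = 3,
                           psf_sigma_nm = 130, tip_sd_nm = 0,
                           photons_per_um = 2000, background_level = 100,
                           noise_model = c("none", "gaussian", "poisson"),
                           read_noise_sd = 2, crop_halfwidth_px = 4L) {
  noise_model <- match.arg(noise_model)
  if (pixel_size_nm <= 0) stopf("imaging_params: pixel_size_nm must be > 0")
  if (frame_interval_s <= 0) stopf("imaging_params: frame_interval_s must be > 0")
  if (psf_sigma_nm < 0 || tip_sd_nm < 0)
    stopf("imaging_params: psf_sigma_nm and tip_sd_nm must be >= 0")
  if (crop_halfwidth_px < 1) stopf("imaging_params: crop_halfwidth_px must be >= 1")
  structure(list(pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 psf_sigma_nm = psf_sigma_nm, tip_sd_nm = tip_sd_nm,
                 photons_per_um = photons_per_um,
                 background_level = background_level,
                 noise_model = noise_model, read_noise_sd = read_noise_sd,
                 crop_halfwidth_px = as.integer(crop_halfwidth_px)),
            class = "imaging_params")
}

#' Tubulin washout protocol
#'
#' Timing and kinetics of a simulated washout experiment: growth until
#' washout, a slow depolymerization phase of `delay_s`, then fast
#' depolymerization to the seed. The background channel drops from
#' `background_pre` to `background_post` over `washout_duration_s`.
#'
#' @param t_washout_s time washout begins (s).
#' @param washout_duration_s ramp length of the background drop (s).
#' @param delay_s time from washout to catastrophe (s); 0 means no slow phase.
#' @param v_slow_um_min,v_fast_um_min slow/fast depolymerization speeds
#'   (magnitudes, um/min), `v_fast >= v_slow >= 0`.
#' @param background_pre,background_post background intensity before/after
#'   washout (`post < pre`).
#' @param background_noise_sd SD of Gaussian noise on the background series.
#' @return object of class `washout_protocol`.
#' @export
washout_protocol <- function(t_washout_s = 30, washout_duration_s = 5,
                             delay_s = 20, v_slow_um_min = 1.2,
                             v_fast_um_min = 18.41,
                             background_pre = 100, background_post = 10,
                             background_noise_sd = 1) {
  if (any(c(t_washout_s, washout_duration_s, delay_s) < 0))
    stopf("washout_protocol: times must be >= 0")
  if (background_post >= background_pre)
    stopf("washout_protocol: background_post must be < background_pre")
  if (!(v_fast_um_min >= v_slow_um_min && v_slow_um_min >= 0))
    stopf("washout_protocol: need v_fast >= v_slow >= 0")
  structure(list(t_washout_s = t_washout_s,
                 washout_duration_s = washout_duration_s, delay_s = delay_s,
                 v_slow_um_min = v_slow_um_min, v_fast_um_min = v_fast_um_min,
                 background_pre = background_pre,
                 background_post = background_post,
                 background_noise_sd = background_noise_sd),
            class = "washout_protocol")
}

#' Culture growth-curve parameters
#'
#' @param od0 initial optical density (> 0).
#' @param doubling_time_min doubling time in minutes (> 0).
#' @param lag_min lag before exponential phase (min).
#' @param noise_sd additive OD measurement noise SD.
#' @param duration_h total duration (default 21 h).
#' @param interval_min sampling interval (default 5 min).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(od0 = 0.05, doubling_time_min = 90, lag_min = 60,
                          noise_sd = 0, duration_h = 21, interval_min = 5) {
  if (od0 <= 0 || doubling_time_min <= 0 || interval_min <= 0)
    stopf("growth_params: od0, doubling_time_min, interval_min must be > 0")
  if (lag_min < 0 || duration_h <= 0)
    stopf("growth_params: lag_min >= 0 and duration_h > 0 required")
  if (duration_h * 60 - lag_min < doubling_time_min)
    stopf("growth_params: duration must cover at least one doubling after lag")
  structure(list(od0 = od0, doubling_time_min = doubling_time_min,
                 lag_min = lag_min, noise_sd = noise_sd,
                 duration_h = duration_h, interval_min = interval_min),
            class = "growth_params")
}

#' Analysis configuration
#'
#' One container for every tunable threshold of the pipeline, with the
#' defaults used throughout the analyses. All thresholds are echoed into
#' output manifests so a run is fully specified by its config and seed.
#'
#' @param subunits_per_um lattice constant for rate conversion (default 1750).
#' @param catastrophe_slope_threshold_nm_s washout catastrophe-calling slope
#'   threshold (default 150 nm/s, ~ 2 pixels per 1-s frame).
#' @param regression_window sliding-regression window in frames (default 5).
#' @param invivo_min_points,invivo_min_delta_um,invivo_min_r2 the three-rule
#'   in vivo event criterion (defaults 3 points, 0.5 um, 0.80).
#' @param prewashout_window_s window for the pre-washout polymerization fit
#'   (default 10 s).
#' @param crop_halfwidth_px kymograph crop half-width (default 4).
#' @param pixel_size_nm,frame_interval_s acquisition calibration.
#' @param threshold_method length-tracking threshold method
#'   (`"otsu"`, `"fixed"`, `"bg_ksd"`).
#' @param min_slope_grow_um_min,min_slope_shrink_nm_s slope-sign thresholds of
#'   the in vitro phase classifier.
#' @param rng_seed integer seed recorded with outputs.
#' @return object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(subunits_per_um = SUBUNITS_PER_UM,
                            catastrophe_slope_threshold_nm_s = 150,
                            regression_window = 5L,
                            invivo_min_points = 3L,
                            invivo_min_delta_um = 0.5,
                            invivo_min_r2 = 0.80,
                            prewashout_window_s = 10,
                            crop_halfwidth_px = 4L,
                            pixel_size_nm = 65,
                            frame_interval_s = 3,
                            threshold_method = "otsu",
                            min_slope_grow_um_min = 0.1,
                            min_slope_shrink_nm_s = 150,
                            rng_seed = 1L) {
  cfg <- list(subunits_per_um = subunits_per_um,
              catastrophe_slope_threshold_nm_s = catastrophe_slope_threshold_nm_s,
              regression_window = as.integer(regression_window),
              invivo_min_points = as.integer(invivo_min_points),
              invivo_min_delta_um = invivo_min_delta_um,
              invivo_min_r2 = invivo_min_r2,
              prewashout_window_s = prewashout_window_s,
              crop_halfwidth_px = as.integer(crop_halfwidth_px),
              pixel_size_nm = pixel_size_nm,
              frame_interval_s = frame_interval_s,
              threshold_method = threshold_method,
              min_slope_grow_um_min = min_slope_grow_um_min,
              min_slope_shrink_nm_s = min_slope_shrink_nm_s,
              rng_seed = as.integer(rng_seed))
  pos <- c("subunits_per_um", "catastrophe_slope_threshold_nm_s",
           "regression_window", "invivo_min_points", "invivo_min_delta_um",
           "invivo_min_r2", "prewashout_window_s", "crop_halfwidth_px",
           "pixel_size_nm", "frame_interval_s", "min_slope_grow_um_min",
           "min_slope_shrink_nm_s")
  bad <- vapply(cfg[pos], function(v) !is.numeric(v) || v <= 0, logical(1))
  if (any(bad)) stopf("analysis_config: nonpositive threshold(s): %s",
                      paste(pos[bad], collapse = ", "))
  structure(cfg, class = "analysis_config")
}
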