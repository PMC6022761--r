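#!/usr/bin/env Rscript
# Stage 1: generate the synthetic datasets every later stage consumes -
# dynamic-instability traces, a rendered two-channel TIRF movie, washout
# traces with their background channel, and plate-reader growth curves.
# Everything is seeded and echoed into a manifest so reruns are identical.

suppressPackageStartupMessages(library(mtdi))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)
cfg <- analysis_config(rng_seed = 20260101L)

# -- in vitro style dynamic-instability trace (3-s TIRF frames) ------------
p_invitro <- di_params(v_grow_um_min = 1.2, v_shrink_um_min = 18.4,
                       f_cat_per_min = 0.5, f_res_per_min = 0.5,
                       seed_length_um = 0)
trace <- simulate_length_trace(p_invitro, duration_s = 600, dt_s = 3,
                               rng_seed = cfg$rng_seed)
write_trace_csv(trace, "results/simulated/invitro_trace.csv")

# -- rendered movie + kymograph for the imaging pipeline -------------------
imaging <- imaging_params(noise_model = "poisson", tip_sd_nm = 250)
short <- simulate_length_trace(p_invitro, duration_s = 150, dt_s = 3,
                               rng_seed = cfg$rng_seed + 1L)
movie <- render_movie(short, imaging, ny = 48, nx = 220,
                      origin_px = c(24, 20), angle_deg = 12,
                      seed_length_um = 2, rng_seed = cfg$rng_seed + 2L)
write_movie_tiff(movie, "results/simulated/movie_two_channel.tif")
kymo <- render_kymograph(short, imaging, seed_length_um = 2,
                         rng_seed = cfg$rng_seed + 3L)
write_kymograph(kymo, "results/simulated/kymograph.csv")

# -- washout cohort (1-s frames, untreated-like kinetics) ------------------
pre <- di_params(1.2, 0, 0, 0)
washouts <- simulate_washout_cohort(20, pre, rng_seed = cfg$rng_seed + 4L)
for (i in seq_along(washouts)) {
  write_trace_csv(washouts[[i]]$trace,
                  sprintf("results/simulated/washout_trace_%02d.csv", i))
  utils::write.csv(washouts[[i]]$background,
                   sprintf("results/simulated/washout_background_%02d.csv", i),
                   row.names = FALSE)
}

# -- growth curves ---------------------------------------------------------
gc <- simulate_growth_curve(growth_params(od0 = 0.05, doubling_time_min = 90,
                                          lag_min = 60, noise_sd = 0.005),
                            rng_seed = cfg$rng_seed + 5L)
utils::write.csv(gc, "results/simulated/growth_curve.csv", row.names = FALSE)

write_manifest("results/simulated/manifest.yaml", cfg,
               extra = list(stage = "01_simulate_cohorts"))
cat("Simulated: 1 DI trace, 1 movie (", dim(movie$dynamic)[3], "frames ),",
    length(washouts), "washouts, 1 growth curve -> results/simulated/\n")
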