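# File I/O: multi-page 16-bit TIFF movies (two channels, interleaved pages),
# kymographs as TIFF or CSV matrices, traces and events as CSV with unit
# suffixes in column names, configs and run manifests as YAML.

#' Write a two-channel movie as a multi-page 16-bit TIFF
#'
#' Pages are interleaved (seed, dynamic, seed, dynamic, ...). Intensities
#' are scaled by `scale` into the 16-bit range.
#'
#' @param movie an `mt_movie`.
#' @param path output path.
#' @param scale counts per 16-bit unit-range (default: max over both
#'   channels, recorded in the return value).
#' @return invisibly, the scale used.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "mt_movie"))
  nf <- dim(movie$seed)[3]
  if (is.null(scale)) scale <- max(movie$seed, movie$dynamic)
  pages <- vector("list", 2L * nf)
  for (f in seq_len(nf)) {
    pages[[2L * f - 1L]] <- pmin(pmax(movie$seed[, , f] / scale, 0), 1)
    pages[[2L * f]] <- pmin(pmax(movie$dynamic[, , f] / scale, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Read a two-channel multi-page TIFF movie
#'
#' @param path TIFF path written by [write_movie_tiff()] (or any
#'   channel-interleaved stack).
#' @param n_channels number of interleaved channels (default 2).
#' @param scale counts per unit-range used at write time (default 1).
#' @return list of ny x nx x nframes arrays, one per channel (named `seed`,
#'   `dynamic` for two channels).
#' @export
read_movie_tiff <- function(path, n_channels = 2L, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- length(pages) %/% n_channels
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  chans <- lapply(seq_len(n_channels), function(ch) {
    arr <- array(0, c(ny, nx, nf))
    for (f in seq_len(nf)) arr[, , f] <- pages[[(f - 1L) * n_channels + ch]] * scale
    arr
  })
  if (n_channels == 2L) names(chans) <- c("seed", "dynamic")
  chans
}

#' Write a kymograph as CSV (or TIFF)
#'
#' @param kymo a `kymograph`.
#' @param path output path; `.csv` writes the intensity matrix with a header
#'   of axial pixel indices, any other extension writes a single-page TIFF
#'   normalized to the matrix maximum.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    m <- kymo$intensity
    colnames(m) <- sprintf("px%d", seq_len(ncol(m)) - 1L)
    write.csv(m, path, row.names = FALSE)
  } else {
    tiff::writeTIFF(kymo$intensity / max(kymo$intensity), path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write a length trace as CSV
#'
#' Columns: `frame`, `time_s`, `length_um`, and `flag`/`state` when present.
#'
#' @param trace a `length_trace`.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(frame = seq_len(nrow(trace)) - 1L,
                   time_s = trace$time_s, length_um = trace$length_um)
  if (!is.null(trace$state)) df$state <- trace$state
  if (!is.null(trace$flag)) df$flag <- trace$flag
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a length trace from CSV
#'
#' @param path CSV with at least `time_s` and `length_um` columns.
#' @param condition optional condition label attached as an attribute.
#' @return a `length_trace`.
#' @export
read_trace_csv <- function(path, condition = NA) {
  df <- read.csv(path)
  if (!all(c("time_s", "length_um") %in% names(df)))
    stopf("read_trace_csv: %s lacks time_s/length_um columns", path)
  dt <- median(diff(df$time_s))
  new_length_trace(df$time_s, df$length_um, state = df$state,
                   frame_interval_s = dt, condition = condition)
}

#' Write an analysis config (or any named list) as YAML
#' @param cfg named list, e.g. [analysis_config()].
#' @param path output path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read an analysis config from YAML
#' @param path YAML path.
#' @return an `analysis_config` built from the stored fields (unknown fields
#'   are rejected by [analysis_config()]'s signature).
#' @export
read_config_yaml <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the config, the RNG seed, the
#' package version, input file hashes, and a timestamp.
#'
#' @param path output YAML path.
#' @param cfg [analysis_config()].
#' @param inputs character vector of input file paths (hashed if they exist).
#' @param extra named list of additional fields.
#' @export
write_manifest <- function(path, cfg, inputs = character(), extra = list()) {
  hashes <- vapply(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, character(1))
  man <- c(list(package = "mtdi",
                version = as.character(utils::packageVersion("mtdi")),
                timestamp = format(Sys.time(), tz = "UTC"),
                rng_seed = cfg$rng_seed,
                config = unclass(cfg),
                inputs = as.list(hashes)),
           extra)
  yaml::write_yaml(man, path)
  invisible(path)
}
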