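# Readers, writers and configuration shared across the pipeline.

#' Read a movie from a multi-page TIFF or an image sequence
#'
#' @param path a multi-page TIFF file, a directory of numbered TIFF/PNG
#'   frames, or a character vector of frame files.
#' @param frame_rate Hz, used to assign timestamps.
#' @param mm_per_px pixel size carried into each frame.
#' @return list of \code{worm_frame} objects in acquisition order.
#' @export
read_stack <- function(path, frame_rate = 5, mm_per_px = 0.01) {
  files <- NULL
  if (length(path) == 1 && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop(sprintf("I/O error: no frames found in '%s'", path))
  } else if (length(path) > 1) {
    files <- path
  } else if (!file.exists(path)) {
    stop(sprintf("I/O error: file '%s' does not exist", path))
  }
  imgs <- if (is.null(files)) {
    tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  } else {
    lapply(files, function(f) {
      if (!file.exists(f)) stop(sprintf("I/O error: missing frame '%s'", f))
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    })
  }
  if (!is.list(imgs)) imgs <- list(imgs)
  imgs <- lapply(imgs, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
  shp <- dim(imgs[[1]])
  for (i in seq_along(imgs))
    if (!all(dim(imgs[[i]]) == shp))
      stop(sprintf("I/O error: frame %d has a different shape", i))
  lapply(seq_along(imgs), function(i)
    new_worm_frame(imgs[[i]], timestamp = (i - 1) / frame_rate,
                   mm_per_px = mm_per_px))
}

#' Write a movie of binary masks as an 8-bit multi-page TIFF
#'
#' @param frames list of \code{worm_frame} objects or binary matrices.
#' @param path output file.
#' @export
write_stack <- function(frames, path) {
  mats <- lapply(frames, function(f) {
    m <- if (inherits(f, "worm_frame")) f$mask else f
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 8)
  invisible(path)
}

#' Write records to CSV with a fixed schema
#'
#' Header always written; deterministic column order; '.' decimal separator;
#' values round-trip at full double precision.
#'
#' @param records data.frame.
#' @param path output file.
#' @param schema optional character vector of required column names (and
#'   their order).
#' @export
write_table <- function(records, path, schema = NULL) {
  if (!is.null(schema)) {
    missing_cols <- setdiff(schema, names(records))
    extra_cols <- setdiff(names(records), schema)
    if (length(missing_cols) || length(extra_cols))
      stop(sprintf("schema mismatch: missing [%s], unexpected [%s]",
                   paste(missing_cols, collapse = ", "),
                   paste(extra_cols, collapse = ", ")))
    records <- records[, schema, drop = FALSE]
  }
  utils::write.csv(format(records, digits = 15, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a curvature kymograph to CSV
#'
#' One row per frame: frame index, time, per-frame body length, then one
#' column per segment.
#'
#' @param kymograph a \code{curvature_kymograph}.
#' @param path output file.
#' @export
write_kymograph <- function(kymograph, path) {
  mat <- unclass(kymograph)
  fr <- attr(kymograph, "frame_rate")
  lens <- attr(kymograph, "frame_lengths") %||%
    rep(attr(kymograph, "body_length"), nrow(mat))
  df <- data.frame(frame = seq_len(nrow(mat)),
                   time_s = (seq_len(nrow(mat)) - 1) / fr,
                   length_mm = lens)
  seg <- as.data.frame(mat)
  names(seg) <- sprintf("seg_%03d", seq_len(ncol(mat)))
  utils::write.csv(cbind(df, seg), path, row.names = FALSE)
  invisible(path)
}

#' Read a curvature kymograph written by \code{\link{write_kymograph}}
#'
#' @param path CSV file.
#' @return a \code{curvature_kymograph}.
#' @export
read_kymograph <- function(path) {
  df <- utils::read.csv(path)
  segcols <- grep("^seg_", names(df))
  mat <- as.matrix(df[, segcols])
  dimnames(mat) <- NULL
  fr <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else NA_real_
  new_kymograph(mat, fr, stats::median(df$length_mm, na.rm = TRUE),
                frame_lengths = df$length_mm)
}

#' Analysis configuration with the study's constants as defaults
#'
#' Central place for every pipeline constant: 100 body segments with an
#' 18-segment head region, a 20 s cross-correlation lag range with a 1 s
#' peak window, 150-frame (30 s at 5 Hz) minimum for amplitude, 10 s minimum
#' bout duration, and the turn-exclusion threshold.
#'
#' @param ... overrides of the named defaults.
#' @return a validated list of class \code{analysis_config}.
#' @export
analysis_config <- function(...) {
  cfg <- list(mm_per_px = 0.01, frame_rate = 5, n_segments = 100L,
              head_fraction = 0.18, xcorr_max_lag = 20, xcorr_window = 1,
              min_bout_duration = 10, min_frames = 150L,
              turn_threshold = pi / 2, smooth_df = 16, theta_cap = 60,
              n_boot = 1000, head_end = "auto", ventral_sign = 1, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config(unknown[1], "is not a recognised configuration key")
  cfg[names(over)] <- over
  for (f in c("mm_per_px", "frame_rate", "xcorr_max_lag", "xcorr_window",
              "min_bout_duration", "turn_threshold"))
    check_positive(cfg[[f]], f)
  nh <- cfg$head_fraction * cfg$n_segments
  if (abs(nh - round(nh)) > 1e-9)
    stop_config("head_fraction", "times n_segments must be an integer")
  cfg$n_head <- as.integer(round(nh))
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file of overrides of \code{\link{analysis_config}} keys.
#' @return an \code{analysis_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: config '%s' not found", path))
  do.call(analysis_config, yaml::read_yaml(path))
}

#' Run a chained analysis pipeline on synthetic or recorded data
#'
#' Executes the requested stages in order (\code{simulate} and/or
#' \code{track}, then \code{bend}, then \code{xcorr} and/or \code{rft}),
#' writes per-stage CSV outputs under \code{out_dir} and a YAML log of
#' parameters, seed and per-stage frame-exclusion counts.
#'
#' @param config an \code{\link{analysis_config}}.
#' @param stages character vector, subset of
#'   c("simulate", "track", "bend", "xcorr", "rft").
#' @param out_dir output directory (created if needed).
#' @param frames optional recorded movie (list of \code{worm_frame}) when not
#'   simulating.
#' @param wave optional \code{\link{wave_params}} for the simulate stage.
#' @return invisibly, a list of stage artifacts.
#' @export
run_pipeline <- function(config = analysis_config(),
                         stages = c("simulate", "track", "bend"),
                         out_dir = tempfile("pipeline"), frames = NULL,
                         wave = NULL) {
  valid <- c("simulate", "track", "bend", "xcorr", "rft")
  if (!all(stages %in% valid))
    stop_config("stages", sprintf("contains unknown stage '%s'",
                                  setdiff(stages, valid)[1]))
  if (!identical(stages, valid[valid %in% stages]))
    stop_config("stages", "must follow the order simulate, track, bend, xcorr, rft")
  needs_track <- any(stages %in% c("bend", "xcorr", "rft"))
  if (needs_track && !"track" %in% stages)
    stop_config("stages", "downstream stages require 'track'")
  if (!"simulate" %in% stages && "track" %in% stages && is.null(frames))
    stop_config("frames", "must be supplied when 'simulate' is not run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list(); log <- list(config = unclass(config), stages = stages)
  if ("simulate" %in% stages) {
    wave <- wave %||% wave_params(frame_rate = config$frame_rate,
                                  n_segments = config$n_segments,
                                  seed = config$seed)
    mv <- make_synthetic_movie(wave)
    frames <- mv$frames
    art$ground_truth <- mv$ground_truth
    write_kymograph(mv$ground_truth$kymograph,
                    file.path(out_dir, "ground_truth_kymograph.csv"))
    yaml::write_yaml(unclass(wave), file.path(out_dir, "wave_params.yaml"))
    log$simulate <- list(n_frames = length(frames))
  }
  if ("track" %in% stages) {
    kym <- build_kymograph(frames, n_segments = config$n_segments,
                           head_end = config$head_end,
                           smooth_df = config$smooth_df,
                           ventral_sign = config$ventral_sign)
    art$kymograph <- kym
    write_kymograph(kym, file.path(out_dir, "kymograph.csv"))
    write_table(attr(kym, "track"), file.path(out_dir, "track.csv"))
    log$track <- list(n_frames = nrow(kym),
                      n_failed = length(attr(kym, "failed_frames")))
  }
  if ("bend" %in% stages) {
    trace <- head_curvature(art$kymograph, n_head = config$n_head)
    amp <- head_bending_amplitude(trace, min_frames = min(config$min_frames,
                                                          nrow(art$kymograph)))
    art$head_trace <- trace; art$amplitude <- amp
    write_table(data.frame(frame = seq_along(trace$values),
                           head_curvature = trace$values),
                file.path(out_dir, "head_trace.csv"))
    write_table(data.frame(head_bending_amplitude = amp),
                file.path(out_dir, "amplitude.csv"))
    log$bend <- list(amplitude = amp)
  }
  if ("xcorr" %in% stages) {
    ca <- make_calcium_traces(art$kymograph, seed = config$seed,
                              n_head = config$n_head)
    cg <- cross_correlate(art$head_trace, normalize_trace(ca$ventral),
                          max_lag = min(config$xcorr_max_lag,
                                        (nrow(art$kymograph) - 2) /
                                          (2 * config$frame_rate)))
    tp <- reference_peak(cg)
    pk <- peak_correlation(cg, tp, window = config$xcorr_window)
    art$correlogram <- cg; art$peak <- pk
    write_table(as.data.frame(cg), file.path(out_dir, "correlogram.csv"))
    log$xcorr <- list(T_p = tp, peak = pk$value, peak_lag = pk$lag)
  }
  if ("rft" %in% stages) {
    bouts <- segment_bouts(art$kymograph, attr(art$kymograph, "track"),
                           min_duration = min(config$min_bout_duration,
                                              (nrow(art$kymograph) - 1) /
                                                config$frame_rate),
                           turn_threshold = config$turn_threshold)
    bk <- bout_kinematics(art$kymograph, bouts)
    art$bouts <- bk
    write_table(bk, file.path(out_dir, "bouts.csv"),
                schema = c("t_start", "t_end", "V_a", "V_w", "theta_a",
                           "efficiency", "head_amplitude"))
    log$rft <- list(n_bouts = nrow(bk))
    if (nrow(bk) >= 3) {
      fit <- fit_drag_ratio(bk, theta_cap = config$theta_cap,
                            n_boot = config$n_boot, seed = config$seed)
      art$fit <- fit
      yaml::write_yaml(list(K = fit$K, residual = fit$residual,
                            n_bouts = fit$n_bouts, boot_se = fit$boot_se,
                            boot_ci = fit$boot_ci),
                       file.path(out_dir, "rft_fit.yaml"))
      log$rft$K <- fit$K
    }
  }
  yaml::write_yaml(log, file.path(out_dir, "pipeline_log.yaml"))
  invisible(art)
}
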