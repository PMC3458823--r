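#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end chain with their documented
#' defaults. The phase-singularity sampling interval is constrained to the
#' 25-45 ms range used for clinical tip-locus construction unless
#' `force = TRUE`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    kind = "spiral",              # spiral | focal | planewave
    duration_ms = 2000,
    seed = 1L,
    noise_sd_mv = 0.02,
    meander_level = 0,
    cycle_length_ms = 220,        # focal pacing interval; plane waves pace at
                                  # their own unaliased default
    origin_u_cm = 2, origin_v_cm = 2,
    grid_spacing_cm = 0.1,
    filter_lo_hz = 0.05, filter_hi_hz = 500,
    min_apd_ms = 100,
    lockout_ms = 50,
    slope_threshold_mv_ms = NA,   # NA = adaptive
    detrend = "moving_mean",      # moving_mean | none
    sample_interval_ms = 30,
    max_jump_cm = 1,
    max_gap_ms = 90,
    min_rotations = 2,
    min_repeats = 2,
    max_cycles = 8,
    out_dir = NA,
    force = FALSE
  )
}

#' Validate a raw configuration document
#'
#' Fills defaults, rejects unknown keys, and enforces documented ranges
#' (e.g. `sample_interval_ms` in `[25, 45]` unless `force` is set). The
#' result round-trips through serialization unchanged.
#'
#' @param raw Named list (e.g. parsed from a JSON config file), possibly
#'   empty.
#' @return A `run_config` (validated named list).
#' @export
validate_config <- function(raw = list()) {
  if (inherits(raw, "run_config")) raw <- unclass(raw)
  defs <- default_config()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) {
    stop_fibmap(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
                "fibmap_config_error")
  }
  cfg <- utils::modifyList(defs, raw)
  if (!cfg$kind %in% c("spiral", "focal", "planewave")) {
    stop_fibmap("`kind` must be spiral, focal or planewave.", "fibmap_config_error")
  }
  if (!cfg$detrend %in% c("moving_mean", "none")) {
    stop_fibmap("`detrend` must be moving_mean or none.", "fibmap_config_error")
  }
  num_pos <- c("duration_ms", "cycle_length_ms", "grid_spacing_cm", "min_apd_ms",
               "lockout_ms", "sample_interval_ms", "max_jump_cm", "max_gap_ms",
               "min_rotations", "min_repeats", "max_cycles")
  for (k in num_pos) {
    if (!is_scalar_number(cfg[[k]]) || cfg[[k]] <= 0) {
      stop_fibmap(sprintf("Config key `%s` must be a positive number.", k),
                  "fibmap_config_error")
    }
  }
  if (!isTRUE(cfg$force) &&
      (cfg$sample_interval_ms < 25 || cfg$sample_interval_ms > 45)) {
    stop_fibmap("`sample_interval_ms` must lie in [25, 45] ms (set force = TRUE to override).",
                "fibmap_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read / write a configuration file (JSON)
#'
#' @param path File path.
#' @param config A `run_config` or raw list.
#' @return `read_config()` returns a validated `run_config`.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(validate_config(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full mapping pipeline on a simulated episode
#'
#' simulate -> condition -> activations (+ restitution filter) -> per-cycle
#' isochrones -> phase -> singularities -> tracks -> classified sources ->
#' report. All randomness flows from `config$seed`; identical configs give
#' identical reports.
#'
#' @param config A `run_config` (see [validate_config()]); a raw list is
#'   validated first.
#' @return A `run_report`: list with `config`, `sources` (tibble), `n_sources`,
#'   `cycle_length_ms`, `version`, plus non-serialized attachments (`episode`,
#'   `tracks`, `maps`) for interactive use.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  params <- tissue_params()
  ep <- switch(cfg$kind,
    spiral = simulate_episode("spiral", params, duration_ms = cfg$duration_ms,
                              noise_sd_mv = cfg$noise_sd_mv, seed = cfg$seed,
                              meander_level = cfg$meander_level),
    focal = simulate_episode("focal", params, duration_ms = cfg$duration_ms,
                             noise_sd_mv = cfg$noise_sd_mv, seed = cfg$seed,
                             origin = c(cfg$origin_u_cm, cfg$origin_v_cm),
                             cycle_length_ms = cfg$cycle_length_ms),
    planewave = simulate_episode("planewave", params, duration_ms = cfg$duration_ms,
                                 noise_sd_mv = cfg$noise_sd_mv, seed = cfg$seed))
  analyze_episode(ep, cfg)
}

#' Analyze an existing episode with the standard chain
#'
#' The mapping half of [run_pipeline()], usable on any `simulated_episode`
#' (or a list with `recording` and `geom`).
#'
#' @param ep Episode with `recording` (`egm_recording`) and `geom`
#'   (`electrode_grid`).
#' @param config A validated `run_config`.
#' @return A `run_report`.
#' @export
analyze_episode <- function(ep, config = list()) {
  cfg <- validate_config(config)
  rec <- ep$recording
  grid <- analysis_grid(ep$geom, spacing_cm = cfg$grid_spacing_cm)

  thr <- if (is.na(cfg$slope_threshold_mv_ms)) NULL else cfg$slope_threshold_mv_ms
  acts <- detect_activations(rec, slope_threshold_mv_ms = thr,
                             lockout_ms = cfg$lockout_ms)
  acts <- restitution_filter(acts, restitution_curve(min_apd_ms = cfg$min_apd_ms))
  cl <- cycle_length_stats(acts)

  maps <- list()
  windows <- tryCatch(segment_cycles(acts, max_cycles = cfg$max_cycles),
                      fibmap_error = function(e) NULL)
  if (!is.null(windows)) {
    for (i in seq_len(nrow(windows))) {
      m <- tryCatch(build_isochrone_map(acts, ep$geom,
                                        c(windows$t0_ms[i], windows$t1_ms[i]),
                                        grid),
                    fibmap_error = function(e) NULL)
      if (!is.null(m)) maps[[length(maps) + 1L]] <- m
    }
  }

  ph <- instantaneous_phase(rec, detrend = cfg$detrend)
  at_ms <- seq(min(ph$t_ms) + 100, max(ph$t_ms) - 10, by = cfg$sample_interval_ms)
  pmap <- phase_field(ph, ep$geom, grid, at_ms = at_ms)
  events <- detect_phase_singularities(pmap)
  tracks <- link_singularities(events, max_jump_cm = cfg$max_jump_cm,
                               max_gap_ms = cfg$max_gap_ms)
  tracks <- structure(lapply(tracks, function(tr) {
    suppressWarnings(remove_outlier_points(tr))
  }), class = "source_track_set")

  rotor_rows <- dplyr::bind_rows(lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    cls <- classify_rotor(tr, pmap, min_rotations = cfg$min_rotations,
                          max_gap_ms = cfg$max_gap_ms)
    if (!cls$is_rotor) return(NULL)
    tibble::tibble(kind = "rotor", chirality = tr$chirality,
                   n_rotations = cls$n_rotations, n_beats = NA_integer_,
                   u_cm = median(tr$samples$u_cm), v_cm = median(tr$samples$v_cm),
                   locus_area_cm2 = locus_area(suppressWarnings(smooth_locus_or_points(tr))),
                   t_start_ms = tr$time_span[1], t_end_ms = tr$time_span[2])
  }))

  focal <- focal_phase_scan(acts, ep$geom, grid, cfg)
  focal_rows <- dplyr::bind_rows(lapply(focal, function(tr) {
    tibble::tibble(kind = "focal", chirality = NA_real_,
                   n_rotations = NA_real_, n_beats = tr$n_beats %||% nrow(tr$samples),
                   u_cm = median(tr$samples$u_cm), v_cm = median(tr$samples$v_cm),
                   locus_area_cm2 = locus_area(tr),
                   t_start_ms = tr$time_span[1], t_end_ms = tr$time_span[2])
  }))

  empty_sources <- tibble::tibble(
    kind = character(), chirality = numeric(), n_rotations = numeric(),
    n_beats = integer(), u_cm = numeric(), v_cm = numeric(),
    locus_area_cm2 = numeric(), t_start_ms = numeric(), t_end_ms = numeric())
  sources <- dplyr::bind_rows(empty_sources, rotor_rows, focal_rows)
  report <- structure(list(
    config = unclass(cfg),
    version = as.character(utils::packageVersion("fibmap")),
    n_sources = nrow(sources),
    sources = sources,
    cycle_length = cl
  ), class = "run_report")
  attr(report, "episode") <- ep
  attr(report, "tracks") <- tracks
  attr(report, "focal_tracks") <- focal
  attr(report, "maps") <- maps
  attr(report, "phase_map") <- pmap
  attr(report, "events") <- events
  attr(report, "activations") <- acts

  if (!is.na(cfg$out_dir)) write_run_outputs(report, cfg$out_dir)
  report
}

# Focal detection with a deterministic window-phase scan. When the sheet
# crossing time approaches (or exceeds) the cycle length there is no global
# diastolic gap, and the phase at which per-cycle windows open decides whether
# the region around a focal origin is mapped within one beat. Six evenly
# spaced phase offsets are tried; the offset whose focal tracks accumulate the
# most repeated origins wins (ties go to the smallest offset).
focal_phase_scan <- function(acts, geom, grid, cfg, n_offsets = 6L) {
  empty <- structure(list(), class = "source_track_set")
  wins0 <- tryCatch(segment_cycles(acts, max_cycles = cfg$max_cycles),
                    fibmap_error = function(e) NULL)
  if (is.null(wins0) || nrow(wins0) < cfg$min_repeats) return(empty)
  cl <- attr(wins0, "cycle_length_ms")
  best <- empty
  best_score <- 0
  for (k in seq_len(n_offsets) - 1L) {
    off <- k / n_offsets * cl
    maps <- list()
    for (i in seq_len(nrow(wins0))) {
      m <- tryCatch(build_isochrone_map(acts, geom,
                                        c(wins0$t0_ms[i], wins0$t1_ms[i]) + off,
                                        grid),
                    fibmap_error = function(e) NULL)
      if (!is.null(m)) maps[[length(maps) + 1L]] <- m
    }
    if (length(maps) < cfg$min_repeats) next
    tracks <- detect_focal_sources(maps, min_repeats = cfg$min_repeats,
                                   max_jump_cm = cfg$max_jump_cm)
    score <- sum(vapply(tracks, function(tr) nrow(tr$samples), integer(1)))
    if (score > best_score) {
      best <- tracks
      best_score <- score
    }
  }
  best
}

smooth_locus_or_points <- function(tr) {
  if (nrow(tr$samples) >= 2 &&
      nrow(unique(tr$samples[, c("u_cm", "v_cm")])) >= 2) {
    smooth_locus(tr)
  } else {
    tr
  }
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s episode, seed %d: %d source(s)\n",
              x$config$kind, x$config$seed, x$n_sources))
  if (x$n_sources > 0) print(x$sources)
  invisible(x)
}

#' One-row summary of a run report
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return Tibble: episode kind, source counts by type, mean locus area,
#'   mean cycle length.
#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    kind = x$config$kind,
    seed = x$config$seed,
    n_sources = x$n_sources,
    n_rotors = sum(x$sources$kind == "rotor"),
    n_focal = sum(x$sources$kind == "focal"),
    mean_locus_area_cm2 = if (x$n_sources) mean(x$sources$locus_area_cm2) else NA_real_,
    mean_cl_ms = x$cycle_length$mean_cl_ms
  )
}

#' Serialize / load a run report (JSON)
#'
#' The serialized report contains the parameter echo, source table, cycle
#' length statistics, version and seed -- everything needed to reproduce the
#' run -- and round-trips identically (no timestamps).
#'
#' @param report A `run_report`.
#' @param path File path.
#' @return `read_run_report()` returns the report list.
#' @export
write_run_report <- function(report, path) {
  obj <- list(config = report$config, version = report$version,
              n_sources = report$n_sources,
              sources = as.data.frame(report$sources),
              cycle_length = as.data.frame(report$cycle_length))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sources <- tibble::as_tibble(obj$sources)
  obj$cycle_length <- tibble::as_tibble(obj$cycle_length)
  structure(obj, class = "run_report")
}

write_run_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- attr(report, "episode")
  if (!is.null(ep)) write_episode(ep, file.path(dir, "episode"))
  write_activations(attr(report, "activations"), file.path(dir, "activations.csv"))
  write_singularities(attr(report, "events"), file.path(dir, "singularities.csv"))
  write_tracks(attr(report, "tracks"), file.path(dir, "tracks.json"))
  maps <- attr(report, "maps")
  if (length(maps)) {
    mdir <- file.path(dir, "maps")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(maps)) {
      write_isochrone_map(maps[[i]], file.path(mdir, sprintf("cycle_%02d.csv", i)))
    }
  }
  write_run_report(report, file.path(dir, "report.json"))
  invisible(dir)
}

#' Write / read an episode bundle as plain text
#'
#' A directory with `recording.csv` (wide: `t_ms` plus one column per
#' channel, mV), `geometry.csv`, and `truth.json`.
#'
#' @param ep A `simulated_episode`.
#' @param dir Bundle directory (created if missing).
#' @return `read_episode()` returns the episode (without the state movie).
#' @export
write_episode <- function(ep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- ep$recording
  df <- data.frame(t_ms = rec_times(rec))
  m <- t(rec$samples)
  colnames(m) <- rec$channel_ids
  utils::write.csv(cbind(df, m), file.path(dir, "recording.csv"),
                   row.names = FALSE, quote = FALSE)
  write_geometry(ep$geom, file.path(dir, "geometry.csv"))
  tr <- ep$truth
  obj <- list(kind = tr$kind, period_ms = tr$period_ms,
              cycle_length_ms = tr$cycle_length_ms, origin = tr$origin,
              speed_cm_s = tr$speed_cm_s, direction = tr$direction,
              meander_level = tr$meander_level, seed = tr$seed,
              tip_path = if (!is.null(tr$tip_path)) as.data.frame(tr$tip_path))
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))],
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_episode
#' @export
read_episode <- function(dir) {
  df <- utils::read.csv(file.path(dir, "recording.csv"), check.names = FALSE)
  t_ms <- df$t_ms
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  fs <- 1000 / median(diff(t_ms))
  rec <- egm_recording(m, fs = fs, channel_ids = rownames(m), t0_ms = t_ms[1])
  geom <- read_geometry(file.path(dir, "geometry.csv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  if (!is.null(tr$tip_path)) tr$tip_path <- tibble::as_tibble(tr$tip_path)
  truth <- structure(tr, class = "ground_truth")
  structure(list(recording = rec, geom = geom, truth = truth, movie = NULL,
                 seed = tr$seed),
            class = "simulated_episode")
}
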