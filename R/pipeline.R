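#' Default pipeline configuration
#'
#' A single flat-ish configuration object covering every stage of the
#' force-gliding pipeline. Any subset can be overridden; unknown fields are
#' rejected at validation.
#'
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param out_dir Output directory.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1, out_dir = "forceglide-run") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, events = TRUE, render = FALSE,
                  track = FALSE, analyze = TRUE, mixture = TRUE,
                  rupture = TRUE),
    tether = list(),       # overrides for tether_model()
    motor = list(),        # overrides for motor_config()
    assay = list(duration = 60, motor_count = 3),
    calibration = list(),  # overrides for event_calibration()
    events = list(n_kinesins = 20, duration = 120, role_process = "iid",
                  motors_per_mt = 1),
    render = list(fov = c(96, 48), photons = 2000),
    classify = list(max_missing = 5),
    mixture = list(n = 5000, bin_width = 50, window = 1),
    rupture = list(rates = c(10, 100), n_pulls = 60, dt = 0.02)
  ), class = "run_config")
}

modify_defaults <- function(defaults, overrides, what) {
  if (is.null(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown ", what, " field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

#' Validate a pipeline configuration
#'
#' Checks the stage toggles and every parameter block against the
#' constructors' own validation, before anything runs.
#'
#' @param config A `run_config` (or plain list).
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  defaults <- default_config()
  config <- modify_defaults(unclass(defaults), unclass(config), "config")
  stopifnot(is.numeric(config$seed), length(config$seed) == 1)
  for (s in names(config$stages)) stopifnot(is.logical(config$stages[[s]]))
  do.call(tether_model, config$tether)
  do.call(motor_config, config$motor)
  do.call(event_calibration, config$calibration)
  if (isTRUE(config$stages$track) && !isTRUE(config$stages$render)) {
    stop("the track stage requires the render stage")
  }
  invisible(structure(config, class = "run_config"))
}

#' Stable hash of a configuration
#'
#' Invariant to field ordering: names are sorted recursively before hashing.
#'
#' @param config A `run_config` or list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm)) x <- x[order(nm)]
      lapply(x, canon)
    } else x
  }
  rlang::hash(canon(unclass(config)))
}

stage_seed <- function(master, stage) {
  offsets <- c(simulate = 101, events = 211, render = 307, track = 401,
               analyze = 503, mixture = 601, rupture = 701)
  (as.integer(master) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

write_csv_hash <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Run the force-gliding pipeline
#'
#' Executes the enabled stages in dependency order — mechanistic simulation,
#' event-level generation, rendering, tracking, state analysis, velocity
#' mixtures, rupture analysis — writing tables as CSV and summaries as JSON
#' (each stamped with the config hash), and returns a manifest of inputs,
#' outputs, seeds and timing.
#'
#' @param config A `run_config` (see [default_config()]).
#' @return The manifest, invisibly; also written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_run_config(config)
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  outputs <- character(0)
  summary <- list(config_hash = hash, seed = config$seed)
  tether <- do.call(tether_model, config$tether)
  motor <- do.call(motor_config, config$motor)
  cal <- do.call(event_calibration, config$calibration)
  op <- function(...) file.path(config$out_dir, paste0(...))
  glide <- NULL; esim <- NULL

  if (isTRUE(config$stages$simulate)) {
    assay <- do.call(assay_config, config$assay)
    glide <- simulate_gliding(assay, motor, tether,
                              seed = stage_seed(config$seed, "simulate"))
    outputs <- c(outputs,
                 write_csv_hash(glide$motors, op("sim_motors.csv"), hash),
                 write_csv_hash(glide$mt, op("sim_mt.csv"), hash))
    summary$sim_mean_mt_velocity <- mean(glide$mt$velocity, na.rm = TRUE)
    summary$sim_max_balance_residual <- glide$max_residual
  }
  if (isTRUE(config$stages$events)) {
    ep <- config$events
    esim <- generate_event_traces(cal, n_kinesins = ep$n_kinesins,
                                  duration = ep$duration,
                                  seed = stage_seed(config$seed, "events"),
                                  role_process = ep$role_process,
                                  motors_per_mt = ep$motors_per_mt)
    outputs <- c(outputs,
                 write_csv_hash(esim$tracks, op("event_tracks.csv"), hash),
                 write_csv_hash(esim$mt, op("event_mt.csv"), hash),
                 write_csv_hash(esim$events, op("event_truth.csv"), hash))
  }
  if (isTRUE(config$stages$render)) {
    src <- if (!is.null(glide)) {
      data.frame(frame = glide$motors$frame, id = glide$motors$kinesin,
                 x = glide$motors$position_true - min(glide$motors$position_true) + 1000,
                 y = 1000 + 2000 * (glide$motors$kinesin - 1))
    } else stop("render stage needs the simulate stage")
    movie <- render_frames(src, fov = config$render$fov,
                           photons = config$render$photons,
                           seed = stage_seed(config$seed, "render"))
    outputs <- c(outputs, write_stack_tiff(movie, op("movie.tif")))
    if (isTRUE(config$stages$track)) {
      spots <- track_stack_spots(movie)
      tracks <- link_tracks(spots)
      outputs <- c(outputs, write_spot_csv(tracks, op("tracks.csv")))
      summary$n_tracks <- length(unique(tracks$track))
    }
  }
  if (isTRUE(config$stages$analyze)) {
    if (is.null(esim)) stop("analyze stage needs the events stage")
    ev <- extract_events(esim$tracks, esim$mt,
                         frame_interval = cal$frame_interval, tether = tether,
                         max_missing = config$classify$max_missing)
    outputs <- c(outputs, write_csv_hash(
      ev[, setdiff(names(ev), "series")], op("events.csv"), hash))
    kin <- event_kinetics(ev)
    minutes <- length(unique(esim$tracks$kinesin)) * config$events$duration / 60
    tr <- count_transitions(ev, minutes)
    eng <- engagement_table(ev, cal$frame_interval, config$events$duration)
    fd <- fraction_driving(eng)
    outputs <- c(outputs,
                 write_csv_hash(as.data.frame(fd), op("fraction_driving.csv"), hash))
    summary$kinetics <- kin$summary
    summary$runlength_asymmetry <- kin$runlength_asymmetry
    summary$transition_rate_per_min <- tr$rate_per_min
    summary$transition_mix <- as.list(tr$mix)
    summary$fraction_driving_pooled <- attr(fd, "pooled")
  }
  if (isTRUE(config$stages$mixture)) {
    v <- if (!is.null(glide)) {
      mt_velocity_windows(glide, config$mixture$window)$velocity
    } else {
      sample_velocity_mixture(config$mixture$n,
                              seed = stage_seed(config$seed, "mixture"))
    }
    if (length(v) >= 200) {
      fit <- fit_two_gaussians(v, config$mixture$bin_width)
      summary$velocity_mixture <- fit[c("stuck_weight", "stuck_mean",
                                        "fast_mean", "fast_sd", "flag")]
    }
  }
  if (isTRUE(config$stages$rupture)) {
    set.seed(stage_seed(config$seed, "rupture"))
    bond <- bond_model()
    rec <- do.call(rbind, lapply(config$rupture$rates, function(r) {
      do.call(rbind, lapply(seq_len(config$rupture$n_pulls), function(i) {
        p <- simulate_pull(bond, tether, rate = r, dt = config$rupture$dt)
        data.frame(rate = r, rupture_force = p$rupture_force,
                   censored = p$censored)
      }))
    }))
    outputs <- c(outputs, write_csv_hash(rec, op("ruptures.csv"), hash))
    summary$rupture_median <- lapply(split(rec, rec$rate), function(g) {
      survival_curve(g$rupture_force, g$censored)$median
    })
  }

  summary_path <- op("summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  outputs <- c(outputs, summary_path)
  manifest <- list(
    config = unclass(config), config_hash = hash,
    outputs = basename(outputs),
    package_version = as.character(utils::packageVersion("forceglide")),
    r_version = R.version.string,
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Build the deterministic fixture bundle
#'
#' One call producing the synthetic objects the test-suite exercises:
#' an event-level simulation, a mechanistic gliding simulation, a short
#' rendered movie with truth, and a set of rupture pulls.
#'
#' @param scale `"small"` (fast, test-sized) or `"standard"`.
#' @param seed Master seed.
#' @return Named list with `events_sim`, `glide_sim`, `movie`, `pulls`.
#' @export
make_fixtures <- function(scale = c("small", "standard"), seed = 1) {
  scale <- match.arg(scale)
  big <- scale == "standard"
  esim <- generate_event_traces(event_calibration(),
                                n_kinesins = if (big) 60 else 8,
                                duration = if (big) 300 else 60,
                                seed = stage_seed(seed, "events"))
  glide <- simulate_gliding(
    assay_config(motor_count = 3, duration = if (big) 120 else 30),
    seed = stage_seed(seed, "simulate"))
  pos <- data.frame(frame = rep(0:9, each = 2), id = rep(1:2, 10),
                    x = rep(c(3000, 9000), 10) + rep(0:9, each = 2) * 150,
                    y = rep(c(2500, 5000), 10))
  movie <- render_frames(pos, fov = c(96, 48),
                         seed = stage_seed(seed, "render"))
  set.seed(stage_seed(seed, "rupture"))
  pulls <- lapply(seq_len(if (big) 200 else 30), function(i)
    simulate_pull(rate = if (i %% 2) 10 else 100, dt = 0.02))
  list(events_sim = esim, glide_sim = glide, movie = movie, pulls = pulls)
}

#' Write and read tracker-dialect spot tables
#'
#' The CSV dialect used by common particle-tracking exports: columns
#' `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y` with positions in
#' physical units (nm here).
#'
#' @param tracks Data frame with `track`, `frame`, `x`, `y`.
#' @param path File path.
#' @return The path ([write_spot_csv()]) or a `track`/`frame`/`x`/`y` data
#'   frame ([read_spot_csv()]).
#' @export
write_spot_csv <- function(tracks, path) {
  utils::write.csv(data.frame(TRACK_ID = tracks$track, FRAME = tracks$frame,
                              POSITION_X = tracks$x, POSITION_Y = tracks$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#")
  nm <- toupper(names(raw))
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% nm)) {
    stop("spot table must carry columns ", paste(need, collapse = ", "))
  }
  data.frame(track = raw[[which(nm == "TRACK_ID")]],
             frame = raw[[which(nm == "FRAME")]],
             x = raw[[which(nm == "POSITION_X")]],
             y = raw[[which(nm == "POSITION_Y")]])
}
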