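#' Calibration for the event-level trace generator
#'
#' Summary statistics that parameterize [generate_event_traces()]: the
#' driving fraction, per-role mean attachment durations and run lengths, the
#' per-motor drive/resist transition rate and type mix, nominal microtubule
#' speed, and localization noise. Defaults are the published operating point
#' of the multi-kinesin force-gliding assay.
#'
#' Internally the calibration is closed under a simple kinematic event model:
#' a motor's displacement from equilibrium ramps away at the difference
#' between its free-running speed and the cargo speed, plateaus once the
#' tether is taut (the motor then matches the cargo speed, i.e. is stationary
#' in the lab), and snaps back to equilibrium at detachment. Given the ramp
#' relative speeds (`v_rel_drive`, `v_rel_resist`, the initial relative
#' velocities of the two roles) the run-length and duration calibrations
#' jointly determine the cargo speed during engagement and the plateau
#' amplitude:
#' \deqn{v_c = (R_d + R_r)/(\bar d_d + \bar d_r), \qquad
#'       A = R_d - v_c \bar d_d = v_c \bar d_r - R_r,}
#' so that the expected per-role run lengths \eqn{\int (v_{MT}-v_{kin})\,dt}
#' equal the calibrated values exactly. `p_drive` is the fraction of engaged
#' motor-time spent driving (what the per-frame driving-fraction statistic
#' measures); the per-event role probability is derived from it and the two
#' mean durations.
#'
#' @param p_drive Target fraction of engaged motor-time in the driving state.
#' @param mean_duration_drive,mean_duration_resist Mean attachment durations
#'   in s.
#' @param mean_runlength_drive,mean_runlength_resist Mean run lengths in um.
#' @param transition_rate Per-motor transition rate between consecutive
#'   events, per minute.
#' @param transition_mix Probabilities of the four ordered transition types
#'   (drive-drive, drive-resist, resist-drive, resist-resist); must sum to 1.
#' @param mt_speed_mean Nominal (unloaded) microtubule gliding speed in nm/s,
#'   used when no motor is engaged.
#' @param localization_noise_sd Localization noise on motor positions, nm.
#' @param v_rel_drive,v_rel_resist Initial relative speeds (microtubule minus
#'   motor) of driving and resisting motors during the ramp phase, nm/s.
#' @param min_duration Shortest attachment scored as an event, s. Durations
#'   are drawn as `min_duration + Exponential(mean - min_duration)` so the
#'   per-role means are exact and every event is long enough to be detected
#'   at the camera frame rate.
#' @param frame_interval Camera frame interval in s.
#' @param mt_velocity_noise_sd Noise on the reported microtubule velocity
#'   series, nm/s.
#'
#' @return An object of class `event_calibration` with derived fields
#'   `cargo_speed` (nm/s), `amplitude` (nm), `ramp_drive`/`ramp_resist` (s)
#'   and `p_event`.
#' @examples
#' cal <- event_calibration()
#' cal$cargo_speed  # ~724 nm/s engaged cargo speed implied by the moments
#' cal$amplitude    # ~137 nm plateau displacement
#' @export
event_calibration <- function(p_drive = 0.65,
                              mean_duration_drive = 3.0,
                              mean_duration_resist = 2.15,
                              mean_runlength_drive = 2.31,
                              mean_runlength_resist = 1.42,
                              transition_rate = 4.9,
                              transition_mix = c(dd = 0.52, dr = 0.16,
                                                 rd = 0.16, rr = 0.16),
                              mt_speed_mean = 830,
                              localization_noise_sd = 20,
                              v_rel_drive = 1300,
                              v_rel_resist = 500,
                              min_duration = 0.7,
                              frame_interval = 0.2,
                              mt_velocity_noise_sd = 30) {
  stopifnot(p_drive >= 0, p_drive <= 1,
            mean_duration_drive > 0, mean_duration_resist > 0,
            mean_runlength_drive > 0, mean_runlength_resist > 0,
            transition_rate > 0, length(transition_mix) == 4,
            mt_speed_mean > 0, localization_noise_sd >= 0,
            min_duration > 0, frame_interval > 0)
  if (abs(sum(transition_mix) - 1) > 1e-8) {
    stop("transition_mix must sum to 1")
  }
  rl_d <- mean_runlength_drive * 1000   # nm
  rl_r <- mean_runlength_resist * 1000
  cargo_speed <- (rl_d + rl_r) / (mean_duration_drive + mean_duration_resist)
  amplitude <- rl_d - cargo_speed * mean_duration_drive
  if (amplitude <= 0) {
    stop("calibration infeasible: driving run length must exceed cargo_speed * duration")
  }
  if (cargo_speed >= v_rel_drive || cargo_speed <= v_rel_resist) {
    stop("calibration requires v_rel_resist < derived cargo speed < v_rel_drive")
  }
  ramp_drive <- amplitude / (v_rel_drive - cargo_speed)
  ramp_resist <- amplitude / (cargo_speed - v_rel_resist)
  if (ramp_drive >= min_duration || ramp_resist >= min_duration) {
    stop("calibration infeasible: tether ramp time exceeds min_duration, ",
         "so mean run lengths would not be realized; increase min_duration ",
         "or the ramp relative speeds")
  }
  # per-event role probability realizing p_drive as an engaged-time fraction
  p_event <- p_drive * mean_duration_resist /
    ((1 - p_drive) * mean_duration_drive + p_drive * mean_duration_resist)
  structure(list(
    p_drive = p_drive,
    mean_duration_drive = mean_duration_drive,
    mean_duration_resist = mean_duration_resist,
    mean_runlength_drive = mean_runlength_drive,
    mean_runlength_resist = mean_runlength_resist,
    transition_rate = transition_rate,
    transition_mix = transition_mix,
    mt_speed_mean = mt_speed_mean,
    localization_noise_sd = localization_noise_sd,
    v_rel_drive = v_rel_drive,
    v_rel_resist = v_rel_resist,
    min_duration = min_duration,
    frame_interval = frame_interval,
    mt_velocity_noise_sd = mt_velocity_noise_sd,
    cargo_speed = cargo_speed,
    amplitude = amplitude,
    ramp_drive = ramp_drive,
    ramp_resist = ramp_resist,
    p_event = p_event
  ), class = "event_calibration")
}

#' @export
print.event_calibration <- function(x, ...) {
  cat("Event-level force-gliding calibration\n")
  cat(sprintf("  p_drive (engaged-time) %.2f; durations %.2f / %.2f s; run lengths %.2f / %.2f um\n",
              x$p_drive, x$mean_duration_drive, x$mean_duration_resist,
              x$mean_runlength_drive, x$mean_runlength_resist))
  cat(sprintf("  transitions %.1f/min; derived cargo speed %.0f nm/s, plateau %.0f nm\n",
              x$transition_rate, x$cargo_speed, x$amplitude))
  invisible(x)
}

draw_roles <- function(n, cal, role_process) {
  if (n == 0) return(character(0))
  if (role_process == "markov") {
    mix <- cal$transition_mix
    p_from_d <- mix[[1]] + mix[[2]]
    p_from_r <- mix[[3]] + mix[[4]]
    p_dd <- mix[[1]] / p_from_d     # P(next = drive | drive)
    p_rd <- mix[[3]] / p_from_r     # P(next = drive | resist)
    # stationary drive probability of the two-state chain
    pi_d <- p_rd / (p_rd + (1 - p_dd))
    roles <- character(n)
    roles[1] <- if (stats::runif(1) < pi_d) "drive" else "resist"
    for (i in seq_len(n - 1L)) {
      p <- if (roles[i] == "drive") p_dd else p_rd
      roles[i + 1L] <- if (stats::runif(1) < p) "drive" else "resist"
    }
    roles
  } else {
    ifelse(stats::runif(n) < cal$p_event, "drive", "resist")
  }
}

#' Generate event-level synthetic force-gliding traces
#'
#' Direct generator of per-motor on-axis displacement traces and microtubule
#' velocity series with full ground truth, at the calibrated summary
#' statistics of [event_calibration()]. Each motor emits a renewal sequence
#' of drive/resist events separated by unbound gaps; within an event the
#' displacement ramps away from equilibrium, plateaus with the tether taut,
#' and returns to equilibrium at detachment. Gaussian localization noise is
#' added to positions.
#'
#' @param cal An [event_calibration()].
#' @param n_kinesins Number of motors to simulate.
#' @param duration Trace duration per motor, s.
#' @param seed Integer seed; the generator is bit-reproducible.
#' @param role_process `"iid"` draws each event's role independently with the
#'   calibrated per-event probability; `"markov"` draws consecutive roles from
#'   the two-state chain implied by `transition_mix` (reproducing the
#'   calibrated transition-type fractions).
#' @param motors_per_mt Number of motors sharing each microtubule. Either a
#'   single count or a vector (recycled over microtubules) to emulate cargoes
#'   carried by different team sizes.
#'
#' @return An object of class `fg_sim`: a list with `tracks` (per-frame motor
#'   positions, noisy and true, with true role labels), `mt` (per-frame
#'   microtubule velocity per cargo), `events` (ground-truth event table with
#'   durations and run lengths), the calibration and the seed.
#' @export
generate_event_traces <- function(cal = event_calibration(),
                                  n_kinesins = 20,
                                  duration = 120,
                                  seed = 1,
                                  role_process = c("iid", "markov"),
                                  motors_per_mt = 1) {
  role_process <- match.arg(role_process)
  stopifnot(duration > 0, n_kinesins >= 1)
  set.seed(seed)
  dt <- cal$frame_interval
  times <- seq(0, duration, by = dt)
  nf <- length(times)

  sizes <- rep_len(motors_per_mt, n_kinesins)
  mt_of_kin <- rep(seq_along(sizes), sizes)[seq_len(n_kinesins)]
  # expected cycle length chosen so that (#events - 1)/duration matches the
  # calibrated transition rate on a track of this duration
  cycle <- 60 / (cal$transition_rate + 60 / duration)
  mean_event <- cal$p_event * cal$mean_duration_drive +
    (1 - cal$p_event) * cal$mean_duration_resist
  gap_mean <- max(cycle - mean_event, 0.05)

  all_events <- vector("list", n_kinesins)
  tracks <- vector("list", n_kinesins)
  event_counter <- 0L

  for (k in seq_len(n_kinesins)) {
    # renewal sequence of events (roles drawn first so durations can depend on them)
    starts <- c(); durs <- c(); roles_k <- character(0)
    t <- stats::rexp(1, 1 / gap_mean)
    n_guess <- ceiling(duration / (gap_mean + mean_event) * 3 + 10)
    roles_seq <- draw_roles(n_guess, cal, role_process)
    i <- 0L
    while (t < duration) {
      i <- i + 1L
      if (i > length(roles_seq)) {
        roles_seq <- c(roles_seq, draw_roles(n_guess, cal, role_process))
      }
      role <- roles_seq[i]
      dm <- if (role == "drive") cal$mean_duration_drive else cal$mean_duration_resist
      d <- cal$min_duration + stats::rexp(1, 1 / (dm - cal$min_duration))
      starts <- c(starts, t)
      durs <- c(durs, d)
      roles_k <- c(roles_k, role)
      t <- t + d + stats::rexp(1, 1 / gap_mean)
    }
    ends <- starts + durs
    truncated <- ends > duration
    ends <- pmin(ends, duration)

    # build the true displacement series for this motor
    disp <- numeric(nf)
    role_f <- rep("none", nf)
    event_id_f <- rep(NA_integer_, nf)
    n_ev <- length(starts)
    run_len <- numeric(n_ev)
    for (j in seq_len(n_ev)) {
      role <- roles_k[j]
      sgn <- if (role == "drive") -1 else 1
      ramp <- if (role == "drive") cal$ramp_drive else cal$ramp_resist
      rate <- cal$amplitude / ramp
      vrel0 <- if (role == "drive") cal$v_rel_drive else cal$v_rel_resist
      idx <- which(times >= starts[j] & times < ends[j])
      tt <- times[idx] - starts[j]
      disp[idx] <- sgn * pmin(tt * rate, cal$amplitude)
      role_f[idx] <- role
      event_id_f[idx] <- event_counter + j
      dur_j <- ends[j] - starts[j]
      # exact integral of (v_MT - v_kin) over the event
      run_len[j] <- vrel0 * min(dur_j, ramp) +
        cal$cargo_speed * max(dur_j - ramp, 0)
    }
    ev <- data.frame(
      kinesin = k, mt = mt_of_kin[k],
      event_id = event_counter + seq_len(n_ev),
      role = roles_k, start = starts, end = ends,
      duration = ends - starts,
      run_length = run_len / 1000,  # um
      truncated = truncated,
      stringsAsFactors = FALSE
    )
    event_counter <- event_counter + n_ev
    all_events[[k]] <- ev
    tracks[[k]] <- data.frame(
      kinesin = k, mt = mt_of_kin[k], frame = seq_len(nf) - 1L, time = times,
      onaxis_true = disp,
      onaxis = disp + stats::rnorm(nf, 0, cal$localization_noise_sd),
      true_role = role_f, true_event = event_id_f,
      stringsAsFactors = FALSE
    )
  }

  tracks <- do.call(rbind, tracks)
  events <- do.call(rbind, all_events)

  # microtubule velocity: engaged cargo speed while any of its motors has an
  # active event, nominal gliding speed otherwise
  mt_ids <- sort(unique(mt_of_kin))
  mt <- do.call(rbind, lapply(mt_ids, function(m) {
    kin <- which(mt_of_kin == m)
    active <- rep(FALSE, nf)
    sub <- events[events$mt == m, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      active <- active | (times >= sub$start[j] & times < sub$end[j])
    }
    v <- ifelse(active, cal$cargo_speed, cal$mt_speed_mean) +
      stats::rnorm(nf, 0, cal$mt_velocity_noise_sd)
    data.frame(mt = m, frame = seq_len(nf) - 1L, time = times, velocity = v)
  }))

  structure(list(tracks = tracks, mt = mt, events = events,
                 calibration = cal, seed = seed,
                 frame_interval = dt, duration = duration),
            class = "fg_sim")
}

#' @export
print.fg_sim <- function(x, ...) {
  cat(sprintf("Synthetic force-gliding dataset: %d motors on %d microtubule(s), %.0f s, %d ground-truth events\n",
              length(unique(x$tracks$kinesin)), length(unique(x$tracks$mt)),
              x$duration, nrow(x$events)))
  invisible(x)
}
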