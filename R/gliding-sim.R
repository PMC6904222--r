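#' Motor (kinesin) kinetic and mechanical parameters
#'
#' Force-velocity and force-dependent unbinding parameters for a single
#' kinesin in the gliding geometry. The force-velocity relation is
#' piecewise linear with a plateau around zero load (no speed change between
#' -2 and +2 pN), a linear decrease to stall under hindering load, and a
#' modest linear increase under assisting load up to saturation. Unbinding
#' follows a Bell law per role, with resisting motors detaching faster under
#' load than driving motors (the asymmetry that drives the tug-of-war).
#'
#' @param unloaded_speed_mean,unloaded_speed_sd Mean and spread (nm/s) of the
#'   per-motor unloaded stepping speed (truncated normal, floor 100 nm/s),
#'   expressing natural motor-to-motor speed variation.
#' @param stall_force Hindering load at which stepping stops, pN.
#' @param plateau_threshold Load magnitude below which speed is unchanged, pN.
#' @param assisted_slope Speed gain per pN of assisting load beyond the
#'   plateau, (nm/s)/pN.
#' @param assisted_saturation Assisting load beyond which speed no longer
#'   increases, pN.
#' @param unbind_rate_drive_0,detach_force_drive Bell parameters (1/s, pN)
#'   for driving motors.
#' @param unbind_rate_resist_0,detach_force_resist Bell parameters for
#'   resisting motors.
#' @param bind_rate Attachment rate of an unbound motor whose anchor is
#'   within reach of the microtubule, 1/s.
#' @param capture_radius Anchor-to-microtubule distance within which binding
#'   is possible, nm.
#' @return Object of class `motor_config`.
#' @export
motor_config <- function(unloaded_speed_mean = 830,
                         unloaded_speed_sd = 250,
                         stall_force = 6,
                         plateau_threshold = 2,
                         assisted_slope = 15,
                         assisted_saturation = 6,
                         unbind_rate_drive_0 = 0.25,
                         detach_force_drive = 4,
                         unbind_rate_resist_0 = 0.35,
                         detach_force_resist = 2,
                         bind_rate = 2,
                         capture_radius = 400) {
  m <- as.list(environment())
  stopifnot(unloaded_speed_mean > 0, unloaded_speed_sd >= 0,
            stall_force > plateau_threshold, plateau_threshold >= 0,
            assisted_slope >= 0, assisted_saturation >= plateau_threshold,
            unbind_rate_drive_0 > 0, detach_force_drive > 0,
            unbind_rate_resist_0 > 0, detach_force_resist > 0,
            bind_rate > 0, capture_radius > 0)
  structure(m, class = "motor_config")
}

#' Assay geometry and simulation controls
#'
#' @param motor_count Number of anchored motors (ignored when
#'   `anchor_positions` given; when NULL, drawn from `surface_density`).
#' @param anchor_positions Anchor coordinates along the gliding axis, nm.
#' @param surface_density Motor surface density, motors/um^2 (assay sweeps
#'   used 0.03-0.46); converted to a linear density through `lane_width_um`,
#'   the strip within tether reach of the microtubule.
#' @param lane_width_um Width of the capture lane, um.
#' @param microtubule_length Cargo microtubule length, um.
#' @param roadblock_density Roadblocks per um of microtubule lattice
#'   (0, 0.75 or 2.5 in the assay).
#' @param drag_coefficient Effective viscous drag on the microtubule,
#'   pN s/nm; small, so cargo motion is quasi-static.
#' @param time_step Integration step, s (<= 0.01).
#' @param duration Simulated time, s.
#' @param frame_interval Camera sampling interval for the recorded series, s.
#' @param seed Integer seed.
#' @return Object of class `assay_config`.
#' @export
assay_config <- function(motor_count = 3,
                         anchor_positions = NULL,
                         surface_density = NULL,
                         lane_width_um = 0.8,
                         microtubule_length = 8,
                         roadblock_density = 0,
                         drag_coefficient = 1e-3,
                         time_step = 0.01,
                         duration = 60,
                         frame_interval = 0.2,
                         seed = 1) {
  stopifnot(time_step <= 0.01, time_step > 0, duration > 0,
            roadblock_density >= 0, microtubule_length > 0,
            drag_coefficient > 0, frame_interval >= time_step)
  structure(as.list(environment()), class = "assay_config")
}

#' Piecewise-linear force-velocity relation
#'
#' @param load Signed load on the motor, pN; negative = hindering (opposing
#'   the walking direction), positive = assisting.
#' @param base_speed Unloaded stepping speed, nm/s.
#' @param motor A [motor_config()].
#' @return Walking speed, nm/s (never negative; clamped to 0 beyond stall).
#' @export
force_velocity <- function(load, base_speed, motor = motor_config()) {
  stopifnot(all(base_speed > 0))
  p <- motor$plateau_threshold
  out <- ifelse(
    load >= -p & load <= p, base_speed,
    ifelse(load < -p,
           base_speed * pmax(0, 1 - (-load - p) / (motor$stall_force - p)),
           base_speed + motor$assisted_slope *
             (pmin(load, motor$assisted_saturation) - p)))
  pmax(out, 0)
}

#' Bell-law unbinding rate per role
#'
#' @param force Tension magnitude on the motor, pN (>= 0).
#' @param role `"drive"` or `"resist"`.
#' @param motor A [motor_config()].
#' @return Unbinding rate, 1/s.
#' @export
unbinding_rate <- function(force, role = c("drive", "resist"),
                           motor = motor_config()) {
  role <- match.arg(role)
  stopifnot(all(force >= 0))
  if (role == "drive") {
    motor$unbind_rate_drive_0 * exp(force / motor$detach_force_drive)
  } else {
    motor$unbind_rate_resist_0 * exp(force / motor$detach_force_resist)
  }
}

#' Place roadblocks on the microtubule lattice
#'
#' Poisson point process on the lattice arc with the given linear density.
#'
#' @param density Roadblocks per um.
#' @param length Microtubule length, um.
#' @param seed Integer seed (NULL to use the current RNG state).
#' @return Sorted roadblock arc positions, nm.
#' @export
place_roadblocks <- function(density, length, seed = NULL) {
  stopifnot(density >= 0, length > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, density * length)
  sort(stats::runif(n, 0, length * 1000))
}

#' Mechanistic multi-motor gliding simulation
#'
#' Stochastic tug-of-war simulation of anchored motors transporting a rigid
#' microtubule along one axis. Each step: (1) bound motors' tether tensions
#' follow from their displacement via the extensible WLC; (2) motors step
#' along the lattice at the force-velocity speed (stalling at roadblocks);
#' (3) the microtubule advances to the root of the quasi-static balance
#' between signed tether forces and viscous drag; (4) motors unbind with the
#' role- and force-dependent Bell rate and rebind at zero tension at the
#' lattice site nearest their anchor; optionally (5) anchors rupture under a
#' Bell-Evans hazard, after which the motor translocates with the cargo.
#'
#' Sign conventions: the microtubule glides in +x; driving motors are
#' displaced in -x (opposite the gliding) and push the cargo forward,
#' resisting motors in +x and hold it back.
#'
#' @param assay An [assay_config()].
#' @param motor A [motor_config()].
#' @param tether A [tether_model()].
#' @param bond Optional [bond_model()] for anchor rupture (NULL = anchors
#'   never rupture).
#' @param seed Integer seed overriding `assay$seed`.
#' @param localization_noise_sd Gaussian noise added to recorded motor
#'   positions, nm.
#' @return Object of class `fg_glide`: `motors` (per-frame positions, bound
#'   flags, truth roles, tensions), `mt` (per-frame position and velocity),
#'   `roadblocks`, `ruptures`, `anchors`, `max_residual` (worst quasi-static
#'   force-balance residual, pN), configs and seed.
#' @export
simulate_gliding <- function(assay = assay_config(), motor = motor_config(),
                             tether = tether_model(), bond = NULL,
                             seed = NULL, localization_noise_sd = 20) {
  if (is.null(seed)) seed <- assay$seed
  set.seed(seed)
  dt <- assay$time_step
  L <- assay$microtubule_length * 1000
  travel <- assay$duration * motor$unloaded_speed_mean * 1.2

  anchors <- assay$anchor_positions
  if (is.null(anchors)) {
    if (!is.null(assay$surface_density)) {
      lin <- assay$surface_density * assay$lane_width_um  # motors/um of axis
      n <- max(stats::rpois(1, lin * (L + travel) / 1000), 1)
      anchors <- sort(stats::runif(n, 0, L + travel))
    } else {
      anchors <- seq(0.15 * L, 0.85 * L, length.out = assay$motor_count)
    }
  }
  nm <- length(anchors)
  if (!any(abs(anchors - L / 2) < L / 2 + motor$capture_radius)) {
    stop("no anchor within capture radius of the initial microtubule span")
  }

  roadblocks <- place_roadblocks(assay$roadblock_density,
                                 assay$microtubule_length)

  # fast tether force lookup (displacement magnitude -> force)
  ext_grid <- seq(0, tether$contour_length * 1.12, by = 0.5)
  f_grid <- ems_force(ext_grid, tether)
  f_of_ext <- stats::approxfun(ext_grid, f_grid, rule = 2)
  tether_force <- function(dabs) {
    f_of_ext(pmax(0, dabs - tether$distance_offset))
  }

  speeds <- pmax(stats::rnorm(nm, motor$unloaded_speed_mean,
                              motor$unloaded_speed_sd), 100)
  bound <- rep(FALSE, nm)
  ruptured <- rep(FALSE, nm)
  u <- rep(NA_real_, nm)      # head arc coordinate on the lattice
  stalled <- rep(FALSE, nm)
  X <- 0                      # microtubule tail (minus end trails at X)
  nsteps <- ceiling(assay$duration / dt)
  rec_every <- round(assay$frame_interval / dt)
  nframes <- floor(nsteps / rec_every)

  rec_motor <- vector("list", nframes)
  rec_mt <- data.frame(frame = seq_len(nframes) - 1L,
                       time = (seq_len(nframes) - 1L) * assay$frame_interval,
                       position = NA_real_, velocity = NA_real_)
  ruptures <- list()
  max_resid <- 0
  X_prev_frame <- X
  frame_i <- 0L

  net_force <- function(Xc) {
    idx <- which(bound)
    if (!length(idx)) return(0)
    d <- (Xc + u[idx]) - anchors[idx]
    sum(-sign(d) * tether_force(abs(d)))
  }

  for (step in seq_len(nsteps)) {
    idx <- which(bound)
    # current tensions and signed loads
    if (length(idx)) {
      d <- (X + u[idx]) - anchors[idx]
      f <- tether_force(abs(d))
      load <- sign(d) * f  # hindering (negative) for driving motors
      w <- force_velocity(load, speeds[idx], motor)
      w[stalled[idx]] <- 0
      u_new <- u[idx] - w * dt
      # roadblock stalls: head cannot step through a roadblock
      if (length(roadblocks)) {
        for (k in seq_along(idx)) {
          if (w[k] <= 0) next
          hit <- roadblocks[roadblocks <= u[idx[k]] - 1e-9 &
                            roadblocks >= u_new[k]]
          if (length(hit)) {
            u_new[k] <- max(hit)
            stalled[idx[k]] <- TRUE
          }
        }
      }
      u[idx] <- u_new
    }
    # quasi-static cargo advance (implicit in the new head positions)
    if (length(idx)) {
      g <- function(Xn) net_force(Xn) - assay$drag_coefficient * (Xn - X) / dt
      span <- sum(tether_force(rep(tether$contour_length, 1))) * nm /
        assay$drag_coefficient * dt + 10
      lo <- X - span; hi <- X + span
      Xn <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-9)$root
      max_resid <- max(max_resid, abs(g(Xn)))
      X <- Xn
    } else {
      X <- X + stats::rnorm(1, 0, 2)  # untethered cargo: diffusive jitter
    }
    # unbinding (Bell, role from displacement sign) and anchor rupture
    idx <- which(bound)
    if (length(idx)) {
      d <- (X + u[idx]) - anchors[idx]
      f <- tether_force(abs(d))
      role <- ifelse(d < 0, "drive", "resist")
      k_off <- ifelse(role == "drive",
                      motor$unbind_rate_drive_0 * exp(f / motor$detach_force_drive),
                      motor$unbind_rate_resist_0 * exp(f / motor$detach_force_resist))
      unbind <- stats::runif(length(idx)) < 1 - exp(-k_off * dt)
      if (!is.null(bond)) {
        rupt <- anchor_rupture_step(f, dt, bond)
        newly <- idx[rupt & !unbind]
        if (length(newly)) {
          ruptured[newly] <- TRUE
          bound[newly] <- FALSE
          for (m_id in newly) {
            ruptures[[length(ruptures) + 1L]] <-
              data.frame(time = step * dt, kinesin = m_id,
                         force = f[idx == m_id][1])
          }
        }
      }
      rel <- idx[unbind]
      bound[rel] <- FALSE
      stalled[rel] <- FALSE
      u[rel] <- NA_real_
    }
    # anchor slots left behind by the gliding cargo are recycled to the front
    # of the lane (a fresh motor with a newly drawn speed takes the slot)
    behind <- which(!bound & !ruptured & anchors < X - motor$capture_radius)
    if (length(behind)) {
      anchors[behind] <- anchors[behind] +
        (L + 2 * motor$capture_radius) * ceiling((X - motor$capture_radius -
          anchors[behind]) / (L + 2 * motor$capture_radius))
      speeds[behind] <- pmax(stats::rnorm(length(behind),
                                          motor$unloaded_speed_mean,
                                          motor$unloaded_speed_sd), 100)
    }
    # binding at zero tension, head at the lattice site nearest the anchor
    cand <- which(!bound & !ruptured &
                  anchors >= X - motor$capture_radius &
                  anchors <= X + L + motor$capture_radius)
    if (length(cand)) {
      bind <- stats::runif(length(cand)) < 1 - exp(-motor$bind_rate * dt)
      nb <- cand[bind]
      if (length(nb)) {
        bound[nb] <- TRUE
        u[nb] <- pmin(pmax(anchors[nb] - X, 0), L)
        stalled[nb] <- FALSE
      }
    }
    # camera frame
    if (step %% rec_every == 0) {
      frame_i <- frame_i + 1L
      d_all <- (X + u) - anchors
      pos <- ifelse(bound, X + u, anchors)
      role <- ifelse(!bound, "none",
                     ifelse(stalled, "stuck",
                            ifelse(d_all < 0, "drive", "resist")))
      rec_motor[[frame_i]] <- data.frame(
        frame = frame_i - 1L, time = (frame_i - 1L) * assay$frame_interval,
        kinesin = seq_len(nm),
        position = pos + stats::rnorm(nm, 0, localization_noise_sd),
        position_true = pos, anchor = anchors,
        displacement = ifelse(bound, d_all, 0), bound = bound,
        tension = ifelse(bound, tether_force(abs(d_all)), 0),
        role = role, stringsAsFactors = FALSE)
      rec_mt$position[frame_i] <- X
      rec_mt$velocity[frame_i] <- (X - X_prev_frame) / assay$frame_interval
      X_prev_frame <- X
    }
  }

  structure(list(
    motors = do.call(rbind, rec_motor),
    mt = rec_mt,
    roadblocks = roadblocks,
    ruptures = if (length(ruptures)) do.call(rbind, ruptures) else NULL,
    anchors = anchors,
    speeds = speeds,
    max_residual = max_resid,
    assay = assay, motor = motor, tether = tether, bond = bond,
    seed = seed), class = "fg_glide")
}

#' @export
print.fg_glide <- function(x, ...) {
  cat(sprintf("Mechanistic gliding simulation: %d motors, %.0f s, mean MT speed %.0f nm/s\n",
              length(x$anchors), x$assay$duration,
              mean(x$mt$velocity, na.rm = TRUE)))
  invisible(x)
}

#' Windowed microtubule velocities with engaged-motor counts
#'
#' Averages the simulated microtubule velocity in fixed windows and counts
#' engaged motors per window; the sampling unit used for the stuck/fast
#' velocity decompositions.
#'
#' @param sim An `fg_glide` simulation.
#' @param window Window length, s.
#' @return Data frame with `time`, `velocity` (nm/s), `n_engaged`.
#' @export
mt_velocity_windows <- function(sim, window = 1) {
  mt <- sim$mt
  per <- max(1L, round(window / sim$assay$frame_interval))
  grp <- (mt$frame %/% per)
  eng <- tapply(sim$motors$bound, list(sim$motors$frame), sum)
  v <- tapply(mt$velocity, grp, mean, na.rm = TRUE)
  ne <- tapply(as.numeric(eng[as.character(mt$frame)]), grp, mean, na.rm = TRUE)
  out <- data.frame(time = as.numeric(names(v)) * window,
                    velocity = as.numeric(v),
                    n_engaged = round(as.numeric(ne)))
  out[is.finite(out$velocity), ]
}
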