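#' Estimate a motor's equilibrium position and baseline noise
#'
#' The equilibrium (anchor) position is the rest position of an unengaged
#' motor. It is estimated as the kernel-density peak of the on-axis position
#' restricted to quiescent (low-velocity) stretches, so that drive/resist
#' excursion plateaus do not pull the estimate away from the baseline. The
#' baseline noise is estimated from first differences of the trace
#' (`mad(diff(x))/sqrt(2)`), which is insensitive to the slow excursions.
#'
#' @param onaxis Numeric vector of on-axis positions (nm); may contain NA.
#' @param frame_interval Frame interval in s.
#' @param smooth_window Odd window (frames) of the Savitzky-Golay derivative
#'   used to find quiescent stretches.
#' @return A list of class `equilibrium_estimate` with `position` (nm),
#'   `noise_sd` (nm) and `flag` (`"ok"`, `"fallback"` or `"constant"`).
#' @export
find_equilibrium <- function(onaxis, frame_interval = 0.2, smooth_window = 5) {
  x <- onaxis[is.finite(onaxis)]
  if (length(x) < 50) stop("need at least 50 finite frames to estimate an equilibrium")
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (noise_sd == 0) {
    return(structure(list(position = stats::median(x), noise_sd = 0,
                          flag = "constant"), class = "equilibrium_estimate"))
  }
  v <- sg_derivative(x, frame_interval, smooth_window)
  vthr <- 3 * stats::mad(v, na.rm = TRUE)
  quiescent <- is.finite(v) & abs(v) <= max(vthr, 1e-9)
  if (sum(quiescent) < 25) {
    return(structure(list(position = stats::median(x), noise_sd = noise_sd,
                          flag = "fallback"), class = "equilibrium_estimate"))
  }
  dens <- stats::density(x[quiescent], bw = max(noise_sd / 2, 1))
  structure(list(position = dens$x[which.max(dens$y)], noise_sd = noise_sd,
                 flag = "ok"), class = "equilibrium_estimate")
}

#' @export
print.equilibrium_estimate <- function(x, ...) {
  cat(sprintf("equilibrium %.1f nm (noise sd %.1f nm, %s)\n",
              x$position, x$noise_sd, x$flag))
  invisible(x)
}

# Savitzky-Golay first derivative (order 2) with NA passthrough
sg_derivative <- function(x, dt, window = 5) {
  if (window %% 2 == 0) window <- window + 1
  n <- length(x)
  if (n < window) return(rep(NA_real_, n))
  filled <- x
  if (anyNA(filled)) {
    filled <- stats::approx(seq_len(n)[is.finite(x)], x[is.finite(x)],
                            xout = seq_len(n), rule = 2)$y
  }
  d <- signal::sgolayfilt(filled, p = 2, n = window, m = 1) / dt
  d[!is.finite(x)] <- NA_real_
  d
}

longest_na_gap <- function(x, dt) {
  r <- rle(!is.finite(x))
  if (!any(r$values)) return(0)
  max(r$lengths[r$values]) * dt
}

#' Classify drive/resist events in one motor trace
#'
#' Finds contiguous excursions of the on-axis displacement away from the
#' equilibrium position and scores them as driving or resisting events.
#' An excursion qualifies as an event when it contains at least two points
#' displaced by more than 100 nm or more than twice the baseline noise
#' (whichever bound is smaller, the two criteria being alternatives); traces
#' containing more than `max_missing` seconds of contiguous missing data are
#' discarded outright. Displacements are oriented so that positive means
#' along the gliding direction: positive excursions are resisting, negative
#' driving.
#'
#' Event boundaries: excursions are delimited at crossings of twice the
#' baseline noise; the start time is then extrapolated to the equilibrium
#' crossing using the local ramp slope (the threshold crossing itself would
#' systematically clip the ramp phase), and the end time is the midpoint
#' between the last displaced frame and the following frame. The run length
#' is the integral of the relative velocity over the event, computed exactly
#' as \eqn{\int v_{MT}\,dt - \Delta x_{kin}} since the motor-velocity
#' integral telescopes to its net displacement.
#'
#' @param onaxis On-axis position series (nm), one motor, evenly sampled.
#' @param mt_velocity Microtubule velocity series (nm/s) on the same frames.
#' @param eq An [find_equilibrium()] estimate, or NULL to estimate here.
#' @param frame_interval Frame interval in s (required).
#' @param tether A [tether_model()] used for per-frame event forces.
#' @param time Optional time stamps (s); defaults to `frame * frame_interval`.
#' @param max_missing Longest tolerated contiguous missing stretch, s.
#'
#' @return A data.frame of events (`role`, `start`, `end`, `duration`,
#'   `run_length` in um, `peak_displacement` nm, `mean_force` pN) with
#'   per-event displacement/force series in the list columns `series`.
#'   Zero-row when the trace is discarded (attribute `removed` explains why).
#' @export
classify_events <- function(onaxis, mt_velocity, eq = NULL,
                            frame_interval = 0.2,
                            tether = tether_model(),
                            time = NULL,
                            max_missing = 5) {
  if (is.null(frame_interval) || !is.finite(frame_interval)) {
    stop("frame_interval must be known to classify events")
  }
  n <- length(onaxis)
  stopifnot(length(mt_velocity) == n)
  if (is.null(time)) time <- (seq_len(n) - 1L) * frame_interval
  empty <- data.frame(role = character(0), start = numeric(0), end = numeric(0),
                      duration = numeric(0), run_length = numeric(0),
                      peak_displacement = numeric(0), mean_force = numeric(0))
  if (longest_na_gap(onaxis, frame_interval) > max_missing) {
    attr(empty, "removed") <- "missing-data"
    return(empty)
  }
  if (is.null(eq)) eq <- find_equilibrium(onaxis, frame_interval)
  g <- sign(mean(mt_velocity, na.rm = TRUE))
  if (!is.finite(g) || g == 0) g <- 1
  d <- (onaxis - eq$position) * g
  v_mt <- mt_velocity * g
  seg_thr <- 2 * eq$noise_sd
  qual_thr <- min(100, 2 * eq$noise_sd)

  events <- list()
  for (sgn in c(-1, 1)) {
    above <- is.finite(d) & (sgn * d > seg_thr)
    r <- rle(above)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (seg in which(r$values)) {
      i0 <- idx_start[seg]; i1 <- idx_end[seg]
      # inclusion: two points beyond 100 nm, or (to be robust against noise
      # doublets in an automated pipeline) three beyond twice the baseline sd
      n100 <- sum(sgn * d[i0:i1] > 100, na.rm = TRUE)
      nsd <- sum(sgn * d[i0:i1] > 2 * eq$noise_sd, na.rm = TRUE)
      if (n100 < 2 && nsd < 3) next
      # start: walk back to the first frame beyond the baseline noise, then
      # extrapolate the ramp to its equilibrium crossing with a local slope
      j <- i0
      while (j > 1 && j > i0 - 3L && is.finite(d[j - 1L]) &&
             sgn * d[j - 1L] > eq$noise_sd && sgn * d[j - 1L] <= seg_thr) j <- j - 1L
      kmax <- min(j + 4L, i1)
      run_d <- sgn * d[i0:i1]
      plateau_est <- stats::median(run_d[run_d >= 0.8 * max(run_d, na.rm = TRUE)],
                                   na.rm = TRUE)
      # slope of the stretching ramp, from pre-plateau frames when the ramp
      # is resolved, otherwise from single-frame bounds: the pre-excursion
      # frame sat below the baseline noise, and a next frame already at the
      # plateau dates the whole rise to about one frame interval
      steps <- diff(sgn * d[j:kmax]) / frame_interval
      slope <- if (length(steps)) max(steps, na.rm = TRUE) else NA_real_
      slope <- max(slope, (sgn * d[j] - eq$noise_sd) / frame_interval,
                   na.rm = TRUE)
      if (j < i1 && is.finite(d[j + 1L]) &&
          sgn * d[j + 1L] >= plateau_est - eq$noise_sd) {
        slope <- max(slope, plateau_est / frame_interval)
      }
      dt_back <- if (is.finite(slope) && slope > 0) sgn * d[j] / slope else frame_interval / 2
      # the frame before j sat below the baseline noise, bounding the crossing
      cap <- if (is.finite(slope) && slope > 0) {
        frame_interval + eq$noise_sd / slope
      } else frame_interval
      dt_back <- min(max(dt_back, 0), cap, 2 * frame_interval)
      t_start <- max(time[j] - dt_back, time[1] - frame_interval / 2)
      # end: midpoint between last displaced frame and the next frame
      t_end <- if (i1 < n) (time[i1] + time[i1 + 1L]) / 2 else time[i1] + frame_interval / 2
      dur <- t_end - t_start
      if (dur <= 0) next
      idx <- i0:i1
      vseg <- v_mt[idx]
      if (anyNA(vseg)) vseg[is.na(vseg)] <- mean(vseg, na.rm = TRUE)
      int_vmt <- sum(vseg) * frame_interval +
        vseg[1] * (time[i0] - t_start - frame_interval / 2) +
        vseg[length(vseg)] * (t_end - time[i1] - frame_interval / 2)
      run_nm <- int_vmt - d[i1]
      disp_or <- d[idx]
      force <- displacement_to_force(abs(disp_or), tether)
      events[[length(events) + 1L]] <- data.frame(
        role = if (sgn < 0) "drive" else "resist",
        start = t_start, end = t_end, duration = dur,
        run_length = max(run_nm, 0) / 1000,
        peak_displacement = disp_or[which.max(abs(disp_or))],
        mean_force = mean(force, na.rm = TRUE),
        series = I(list(data.frame(time = time[idx], displacement = disp_or,
                                   force = force))),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify events for every motor in a dataset
#'
#' Convenience wrapper applying [find_equilibrium()] and [classify_events()]
#' to each motor of a track table (for example the `tracks` element of a
#' [generate_event_traces()] simulation), matching each motor to its
#' microtubule's velocity series.
#'
#' @param tracks Data frame with columns `kinesin`, `mt`, `time`, `onaxis`.
#' @param mt Data frame with columns `mt`, `time`, `velocity`.
#' @param frame_interval Frame interval in s.
#' @param tether A [tether_model()].
#' @param ... Passed to [classify_events()].
#' @return Event table across motors with `kinesin` and `mt` columns.
#' @export
extract_events <- function(tracks, mt, frame_interval = 0.2,
                           tether = tether_model(), ...) {
  res <- lapply(split(tracks, tracks$kinesin), function(tr) {
    tr <- tr[order(tr$time), ]
    vm <- mt[mt$mt == tr$mt[1], ]
    v <- vm$velocity[match(round(tr$time / frame_interval),
                           round(vm$time / frame_interval))]
    ev <- classify_events(tr$onaxis, v, frame_interval = frame_interval,
                          tether = tether, time = tr$time, ...)
    if (nrow(ev)) {
      ev$kinesin <- tr$kinesin[1]
      ev$mt <- tr$mt[1]
    }
    ev
  })
  res <- res[vapply(res, nrow, 1L) > 0]
  if (!length(res)) {
    return(data.frame(role = character(0), start = numeric(0), end = numeric(0),
                      duration = numeric(0), run_length = numeric(0),
                      peak_displacement = numeric(0), mean_force = numeric(0),
                      kinesin = integer(0), mt = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count drive/resist transitions
#'
#' Every ordered pair of consecutive events of one motor is a transition,
#' typed by the two roles. The rate is the total number of transitions per
#' observed motor-minute.
#'
#' @param events Event table with `kinesin`, `role`, `start` columns.
#' @param observation_min Total observed motor-minutes (number of motors
#'   times minutes per motor).
#' @return List with `rate_per_min`, `mix` (fractions over dd/dr/rd/rr),
#'   `n_transitions`.
#' @export
count_transitions <- function(events, observation_min) {
  stopifnot(observation_min > 0)
  pairs <- lapply(split(events, events$kinesin), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(from = e$role[-nrow(e)], to = e$role[-1])
  })
  pairs <- do.call(rbind, pairs)
  types <- c("dd", "dr", "rd", "rr")
  if (is.null(pairs) || !nrow(pairs)) {
    return(list(rate_per_min = 0,
                mix = stats::setNames(rep(NA_real_, 4), types),
                n_transitions = 0L))
  }
  key <- paste0(substr(pairs$from, 1, 1), substr(pairs$to, 1, 1))
  counts <- table(factor(key, levels = types))
  list(rate_per_min = nrow(pairs) / observation_min,
       mix = stats::setNames(as.numeric(counts) / nrow(pairs), types),
       n_transitions = nrow(pairs))
}

#' Per-role event kinetics
#'
#' Mean attachment duration and run length per role with standard errors,
#' plus the run-length asymmetry (how much further driving motors walk than
#' resisting ones, as a fraction).
#'
#' @param events Event table from [classify_events()]/[extract_events()].
#' @return List with a per-role `summary` data.frame and
#'   `runlength_asymmetry`.
#' @export
event_kinetics <- function(events) {
  roles <- c("drive", "resist")
  rows <- lapply(roles, function(r) {
    e <- events[events$role == r, ]
    if (!nrow(e)) return(NULL)
    data.frame(role = r, n = nrow(e),
               mean_duration = mean(e$duration),
               sem_duration = stats::sd(e$duration) / sqrt(nrow(e)),
               mean_runlength = mean(e$run_length),
               sem_runlength = stats::sd(e$run_length) / sqrt(nrow(e)))
  })
  s <- do.call(rbind, rows)
  asym <- if (!is.null(s) && nrow(s) == 2) {
    s$mean_runlength[s$role == "drive"] / s$mean_runlength[s$role == "resist"] - 1
  } else NA_real_
  list(summary = s, runlength_asymmetry = asym)
}

#' Role-aligned mean force over time since binding
#'
#' Aligns every event's tether-force series at the event start and averages
#' within time bins, per role.
#'
#' @param events Event table carrying `series` list column (from
#'   [classify_events()]).
#' @param bin Time bin width in s.
#' @param t_max Longest time since binding to report, s.
#' @return Data frame with `role`, `time`, `mean_force`, `sem`, `n`.
#' @export
force_vs_time <- function(events, bin = 0.2, t_max = 8) {
  if (!nrow(events)) return(data.frame())
  long <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    s <- events$series[[i]]
    data.frame(role = events$role[i], t = s$time - events$start[i],
               force = s$force)
  }))
  long <- long[long$t >= 0 & long$t <= t_max, ]
  long$bin <- floor(long$t / bin) * bin + bin / 2
  agg <- do.call(rbind, lapply(split(long, list(long$role, long$bin), drop = TRUE),
    function(g) data.frame(role = g$role[1], time = g$bin[1],
                           mean_force = mean(g$force),
                           sem = stats::sd(g$force) / sqrt(nrow(g)),
                           n = nrow(g))))
  agg <- agg[order(agg$role, agg$time), ]
  rownames(agg) <- NULL
  agg
}

#' Per-frame engagement table from an event table
#'
#' Expands events into per-frame engaged roles, the input to
#' [fraction_driving()] and the motor-number stratification of velocity
#' mixtures.
#'
#' @param events Event table with `kinesin`, `mt`, `role`, `start`, `end`.
#' @param frame_interval Frame interval in s.
#' @param duration Total trace duration in s.
#' @return Data frame with `mt`, `frame`, `kinesin`, `role`.
#' @export
engagement_table <- function(events, frame_interval = 0.2, duration = NULL) {
  if (!nrow(events)) return(data.frame(mt = integer(0), frame = integer(0),
                                       kinesin = integer(0), role = character(0)))
  if (is.null(duration)) duration <- max(events$end)
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    f0 <- ceiling(events$start[i] / frame_interval)
    f1 <- floor(events$end[i] / frame_interval)
    f1 <- min(f1, floor(duration / frame_interval))
    if (f1 < f0) return(NULL)
    data.frame(mt = events$mt[i], frame = f0:f1, kinesin = events$kinesin[i],
               role = events$role[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of engaged motors that are driving, by team size
#'
#' Pools engaged motor-frames by the number of simultaneously engaged motors
#' N on the same microtubule and reports the driving fraction per N with a
#' Wilson binomial confidence interval. Bins with fewer than `min_frames`
#' motor-frames are flagged low-confidence.
#'
#' @param engagement Per-frame engagement table from [engagement_table()].
#' @param max_n Largest team size reported.
#' @param min_frames Minimum motor-frames for a confident bin.
#' @param conf Confidence level.
#' @return Data frame with `n_motors`, `frames`, `fraction`, `lower`,
#'   `upper`, `low_confidence`; the pooled fraction across bins is attached
#'   as attribute `pooled`.
#' @export
fraction_driving <- function(engagement, max_n = 8, min_frames = 50,
                             conf = 0.95) {
  if (!nrow(engagement)) stop("empty engagement table")
  key <- paste(engagement$mt, engagement$frame)
  nmap <- table(key)
  engagement$n_motors <- as.integer(nmap[key])
  engagement <- engagement[engagement$n_motors <= max_n, ]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(sort(unique(engagement$n_motors)), function(N) {
    g <- engagement[engagement$n_motors == N, ]
    k <- sum(g$role == "drive"); n <- nrow(g)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    data.frame(n_motors = N, frames = n, fraction = p,
               lower = max(0, ctr - hw), upper = min(1, ctr + hw),
               low_confidence = n < min_frames)
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- mean(engagement$role == "drive")
  out
}

#' Role-aligned relative velocity of motors versus the microtubule
#'
#' The relative velocity is the microtubule velocity minus the motor velocity
#' (a smoothed Savitzky-Golay derivative of the on-axis displacement),
#' aligned at event start and averaged per role. Driving motors start fast
#' relative to the cargo and resisting motors slow, and both converge to the
#' cargo speed once the tether is taut.
#'
#' @param events Event table with `series` list column.
#' @param mt Microtubule table (`mt`, `time`, `velocity`).
#' @param frame_interval Frame interval in s.
#' @param window Savitzky-Golay window (frames) for the motor velocity.
#' @param t_max Longest time since binding reported, s.
#' @return Data frame with `role`, `time`, `mean_vrel`, `sem`, `n`.
#' @export
relative_velocity_curves <- function(events, mt, frame_interval = 0.2,
                                     window = 5, t_max = 6) {
  if (!nrow(events)) return(data.frame())
  long <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    s <- events$series[[i]]
    if (nrow(s) < window) return(NULL)
    vk <- sg_derivative(s$displacement, frame_interval, window)
    vm_tab <- mt[mt$mt == events$mt[i], ]
    g <- sign(mean(vm_tab$velocity, na.rm = TRUE)); if (g == 0) g <- 1
    vm <- g * vm_tab$velocity[match(round(s$time / frame_interval),
                                    round(vm_tab$time / frame_interval))]
    data.frame(role = events$role[i], t = s$time - events$start[i],
               vrel = vm - vk)
  }))
  long <- long[is.finite(long$vrel) & long$t >= 0 & long$t <= t_max, ]
  long$bin <- floor(long$t / frame_interval) * frame_interval + frame_interval / 2
  agg <- do.call(rbind, lapply(split(long, list(long$role, long$bin), drop = TRUE),
    function(g) data.frame(role = g$role[1], time = g$bin[1],
                           mean_vrel = mean(g$vrel),
                           sem = stats::sd(g$vrel) / sqrt(nrow(g)),
                           n = nrow(g))))
  agg <- agg[order(agg$role, agg$time), ]
  rownames(agg) <- NULL
  agg
}

#' Per-role kinetics across motor surface densities
#'
#' Summarizes per-role mean duration and run length, and the mean number of
#' simultaneously engaged motors, for datasets acquired at different motor
#' surface densities.
#'
#' @param datasets Named list: one event table per density; names are the
#'   densities (motors/um^2).
#' @param frame_interval Frame interval in s (for engagement counts).
#' @return Data frame with one row per density and role.
#' @export
density_sweep <- function(datasets, frame_interval = 0.2) {
  dens <- as.numeric(names(datasets))
  if (any(is.na(dens))) stop("datasets must be named by numeric density")
  rows <- lapply(seq_along(datasets), function(i) {
    ev <- datasets[[i]]
    kin <- event_kinetics(ev)$summary
    if (is.null(kin)) return(NULL)
    eng <- engagement_table(ev, frame_interval)
    n_eng <- if (nrow(eng)) mean(table(paste(eng$mt, eng$frame))) else 0
    kin$density <- dens[i]
    kin$mean_engaged <- n_eng
    kin
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$density, out$role), ]
}
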