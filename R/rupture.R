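#' Bell-Evans bond model
#'
#' Exponential force dependence of the rupture rate of the weakest link in
#' the tether assembly (the digoxigenin:anti-digoxigenin antibody bond),
#' \eqn{k(F) = k_0 \exp(F/F_b)}. Default parameters are calibrated so that a
#' 10 nm/s constant-speed pull of the default dsDNA tether has its median
#' rupture force near 30 pN (and a 100 nm/s pull near 45 pN); they are a
#' calibration, not a measurement.
#'
#' @param k0_bond Zero-force off rate, 1/s.
#' @param fb_bond Force scale, pN.
#' @return Object of class `bond_model`.
#' @export
bond_model <- function(k0_bond = 0.01, fb_bond = 6.5) {
  stopifnot(k0_bond > 0, fb_bond > 0)
  structure(list(k0_bond = k0_bond, fb_bond = fb_bond), class = "bond_model")
}

#' @export
print.bond_model <- function(x, ...) {
  cat(sprintf("Bell-Evans bond: k0 = %g /s, Fb = %g pN\n", x$k0_bond, x$fb_bond))
  invisible(x)
}

bond_rate <- function(force, bond) bond$k0_bond * exp(force / bond$fb_bond)

#' Per-step anchor rupture draw
#'
#' Probability that a Bell-Evans bond held at the given tension ruptures
#' within one time step is \eqn{1 - \exp(-k(F)\,dt)}.
#'
#' @param tension Tension on the bond, pN (>= 0).
#' @param dt Time step, s.
#' @param bond A [bond_model()].
#' @return Logical: did the bond rupture in this step?
#' @export
anchor_rupture_step <- function(tension, dt, bond = bond_model()) {
  stopifnot(tension >= 0, dt > 0)
  stats::runif(length(tension)) < 1 - exp(-bond_rate(tension, bond) * dt)
}

#' Closed-form Bell-Evans survival under a constant force ramp
#'
#' For a constant force-loading rate \eqn{\dot F}, the survival probability is
#' \deqn{S(F) = \exp\left[-\frac{k_0 F_b}{\dot F}\left(e^{F/F_b}-1\right)\right]}
#' with median rupture force
#' \eqn{F_{1/2} = F_b \ln(1 + \ln 2\,\dot F/(k_0 F_b))}.
#'
#' @param bond A [bond_model()].
#' @param force_rate Loading rate, pN/s (> 0).
#' @return List with `survival` (a function of force) and `median` (pN).
#' @export
analytic_survival <- function(bond = bond_model(), force_rate) {
  stopifnot(force_rate > 0)
  a <- bond$k0_bond * bond$fb_bond / force_rate
  list(
    survival = function(force) exp(-a * (exp(force / bond$fb_bond) - 1)),
    median = bond$fb_bond * log(1 + log(2) / a)
  )
}

#' Simulate a constant-speed tether pull to rupture
#'
#' Ramps the tether extension at the pull rate (stiff-trap approximation:
#' the extension follows the trap separation), computes the force from the
#' high-force extensible WLC, and draws the rupture stochastically from the
#' Bell-Evans hazard. The curve is truncated at rupture; pulls surviving to
#' the preset maximum force are right-censored.
#'
#' @param bond A [bond_model()].
#' @param tether A [tether_model()].
#' @param rate Pull rate, nm/s (10 or 100 in the assay).
#' @param dt Time step, s.
#' @param seed Integer seed (NULL to use the current RNG state).
#' @param start_force Force at the start of the recorded ramp, pN.
#' @param max_force Preset ramp maximum, pN.
#' @return List of class `pull_curve`: `curve` (data.frame time, extension,
#'   force), `rupture_force` (pN), `censored`, `rate`.
#' @export
simulate_pull <- function(bond = bond_model(), tether = tether_model(),
                          rate = 10, dt = 0.01, seed = NULL,
                          start_force = 0.5, max_force = 60) {
  stopifnot(rate > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  x0 <- ewlc_extension(start_force, tether)
  x1 <- ewlc_extension(max_force, tether)
  xs <- unique(c(seq(x0, x1, by = rate * dt), x1))
  fs <- ewlc_force(xs, tether)
  # cumulative hazard on the discrete ramp; inverse-CDF rupture draw
  haz <- cumsum(bond_rate(fs, bond) * dt)
  u <- stats::rexp(1)
  idx <- which(haz >= u)
  if (length(idx)) {
    k <- idx[1]
    censored <- FALSE
  } else {
    k <- length(xs)
    censored <- TRUE
  }
  curve <- data.frame(time = (seq_len(k) - 1) * dt,
                      extension = xs[seq_len(k)], force = fs[seq_len(k)])
  structure(list(curve = curve, rupture_force = fs[k], censored = censored,
                 rate = rate), class = "pull_curve")
}

#' @export
print.pull_curve <- function(x, ...) {
  cat(sprintf("pull at %g nm/s: %s at %.1f pN (%d points)\n", x$rate,
              if (x$censored) "censored" else "ruptured",
              x$rupture_force, nrow(x$curve)))
  invisible(x)
}

#' Detect the rupture force in a force-extension/force-time curve
#'
#' The rupture force is the maximum force immediately preceding a drop of
#' more than `drop_fraction` of the current force within `within` samples.
#' Curves without such a drop are right-censored at their final force.
#'
#' @param curve Data frame with a `force` column (or a `pull_curve`).
#' @param drop_fraction Minimum fractional force drop scored as rupture.
#' @param within Number of samples within which the drop must occur.
#' @return List with `rupture_force` (pN) and `censored`.
#' @export
detect_rupture <- function(curve, drop_fraction = 0.5, within = 3) {
  if (inherits(curve, "pull_curve")) curve <- curve$curve
  f <- curve$force
  n <- length(f)
  for (i in seq_len(max(n - 1, 0))) {
    j <- (i + 1):min(i + within, n)
    hit <- which(f[j] < (1 - drop_fraction) * f[i])
    if (length(hit)) {
      jdrop <- i + hit[1]
      return(list(rupture_force = max(f[i:(jdrop - 1)]), censored = FALSE))
    }
  }
  list(rupture_force = f[n], censored = TRUE)
}

#' Fit the extensible WLC to a force-extension curve
#'
#' Least-squares fit of the high-force extensible WLC extension to a
#' measured (force, extension) curve, with any subset of persistence length,
#' contour length and stretch modulus free. Curves whose residual spread
#' exceeds `multi_threshold` are flagged as likely multi-tether (a second
#' molecule halves the apparent compliance).
#'
#' @param curve Data frame with `force` (pN) and `extension` (nm), or a
#'   `pull_curve`.
#' @param free Character vector among `"persistence_length"`,
#'   `"contour_length"`, `"stretch_modulus"`.
#' @param start A [tether_model()] supplying fixed values and starting
#'   points.
#' @param multi_threshold Residual standard deviation (nm) above which a
#'   curve is flagged.
#' @param min_points,min_span Minimal data requirements (points, pN span).
#' @return List with `model` (fitted [tether_model()]), `residual_sd` (nm),
#'   `flagged`, `fit`.
#' @export
fit_fec <- function(curve,
                    free = c("persistence_length", "contour_length"),
                    start = tether_model(), multi_threshold = 5,
                    min_points = 50, min_span = 2) {
  if (inherits(curve, "pull_curve")) curve <- curve$curve
  ok <- is.finite(curve$force) & is.finite(curve$extension) & curve$force > 0
  curve <- curve[ok, ]
  if (nrow(curve) < min_points) stop("need at least ", min_points, " points")
  if (diff(range(curve$force)) < min_span) {
    stop("force range must span at least ", min_span, " pN")
  }
  all_par <- c(persistence_length = start$persistence_length,
               contour_length = start$contour_length,
               stretch_modulus = start$stretch_modulus)
  free <- match.arg(free, names(all_par), several.ok = TRUE)
  lower <- c(persistence_length = 1, contour_length = 10, stretch_modulus = 100)
  upper <- c(persistence_length = 500, contour_length = 5000,
             stretch_modulus = 1e4)
  fit <- minpack.lm::nls.lm(
    par = all_par[free], lower = lower[free], upper = upper[free],
    fn = function(p) {
      pars <- all_par; pars[free] <- p
      m <- tether_model(persistence_length = pars[["persistence_length"]],
                        contour_length = pars[["contour_length"]],
                        stretch_modulus = pars[["stretch_modulus"]],
                        thermal_energy = start$thermal_energy,
                        distance_offset = start$distance_offset)
      curve$extension - ewlc_extension(curve$force, m)
    })
  pars <- all_par; pars[free] <- stats::coef(fit)
  model <- tether_model(persistence_length = pars[["persistence_length"]],
                        contour_length = pars[["contour_length"]],
                        stretch_modulus = pars[["stretch_modulus"]],
                        thermal_energy = start$thermal_energy,
                        distance_offset = start$distance_offset)
  rsd <- sqrt(mean(fit$fvec^2))
  # a second parallel tether halves the apparent compliance, which the fit
  # absorbs as a collapsed persistence length; flag that alongside residuals
  lp_collapse <- "persistence_length" %in% free &&
    model$persistence_length < 0.6 * start$persistence_length
  list(model = model, residual_sd = rsd,
       flagged = rsd > multi_threshold || lp_collapse, fit = fit)
}

#' Kaplan-Meier style survival of rupture forces
#'
#' Empirical survival probability over force with right-censoring of pulls
#' that reached the ramp maximum intact. The median uses the midpoint
#' convention on the force interval where the survival curve crosses one
#' half; if the curve never reaches 0.5 the reported median is a lower
#' bound.
#'
#' @param rupture_forces Rupture (or censoring) forces, pN.
#' @param censored Logical vector (TRUE = censored at that force).
#' @return List with `survival` (data.frame force, surv), `median`,
#'   `median_is_lower_bound`, `fit` (the [survival::survfit] object).
#' @export
survival_curve <- function(rupture_forces, censored = rep(FALSE, length(rupture_forces))) {
  stopifnot(length(rupture_forces) >= 2,
            length(censored) == length(rupture_forces),
            all(rupture_forces > 0))
  if (length(rupture_forces) < 10) {
    warning("fewer than 10 rupture records; survival estimate is crude")
  }
  fit <- survival::survfit(
    survival::Surv(rupture_forces, !censored) ~ 1)
  s <- data.frame(force = fit$time, surv = fit$surv)
  below <- which(s$surv <= 0.5)
  if (!length(below)) {
    med <- max(rupture_forces); lb <- TRUE
  } else {
    i <- below[1]
    lb <- FALSE
    med <- if (s$surv[i] == 0.5 && i < nrow(s)) {
      (s$force[i] + s$force[i + 1]) / 2  # midpoint of the flat at 0.5
    } else {
      s$force[i]
    }
  }
  list(survival = s, median = med, median_is_lower_bound = lb, fit = fit)
}
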