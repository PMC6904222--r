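#' Extensible worm-like-chain tether model
#'
#' Container for the elastic parameters of the dsDNA tether that anchors each
#' kinesin-QD to the coverslip. Forces are inferred from how far the motor is
#' displaced from its anchor, using worm-like-chain (WLC) polymer elasticity.
#' Defaults describe the 1565-bp dsDNA linker used in the force-gliding assay:
#' persistence length 50 nm, contour length 532 nm, and a 20 nm distance
#' offset that absorbs the physical size of the quantum dot, the motor and the
#' attachment chemistry. The stretch modulus (1200 pN) is the standard
#' enthalpic value for dsDNA and the thermal energy corresponds to ~300 K.
#'
#' @param persistence_length Persistence length Lp in nm.
#' @param contour_length Contour length Lc in nm.
#' @param stretch_modulus Enthalpic stretch modulus K0 in pN.
#' @param thermal_energy kBT in pN nm.
#' @param distance_offset Offset in nm subtracted from the measured
#'   anchor-to-motor displacement before converting to DNA extension.
#'
#' @return An object of class `tether_model`.
#' @examples
#' tm <- tether_model()
#' ms_force(266, tm)          # force at half the contour length
#' ms_stiffness(246, tm)      # analytic stiffness, ~6.6e-4 pN/nm
#' @export
tether_model <- function(persistence_length = 50,
                         contour_length = 532,
                         stretch_modulus = 1200,
                         thermal_energy = 4.14,
                         distance_offset = 20) {
  m <- list(
    persistence_length = persistence_length,
    contour_length = contour_length,
    stretch_modulus = stretch_modulus,
    thermal_energy = thermal_energy,
    distance_offset = distance_offset
  )
  vals <- unlist(m)
  if (any(!is.finite(vals)) || any(vals <= 0 & names(vals) != "distance_offset") ||
      distance_offset < 0) {
    stop("all tether_model parameters must be finite and positive (offset >= 0)")
  }
  if (distance_offset >= contour_length) {
    stop("distance_offset must be smaller than contour_length")
  }
  structure(m, class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat("Extensible worm-like-chain tether model\n")
  cat(sprintf("  Lp = %g nm, Lc = %g nm, K0 = %g pN, kBT = %g pN nm, offset = %g nm\n",
              x$persistence_length, x$contour_length, x$stretch_modulus,
              x$thermal_energy, x$distance_offset))
  invisible(x)
}

check_extension <- function(extension, model) {
  if (any(extension < 0)) stop("extension must be non-negative")
  if (any(extension >= model$contour_length)) {
    stop("extension must be below the contour length (inextensible WLC domain)")
  }
}

#' Marko-Siggia worm-like-chain force
#'
#' Inextensible Marko-Siggia interpolation
#' \deqn{F(x) = (k_BT/L_p)\left[\frac{1}{4(1-x/L_c)^2} - \frac14 + \frac{x}{L_c}\right].}
#' Valid for extensions strictly below the contour length; accurate at the low
#' forces (<~0.5 pN) where enthalpic stretching is negligible.
#'
#' @param extension DNA extension in nm (vectorized).
#' @param model A [tether_model()].
#' @return Force in pN.
#' @export
ms_force <- function(extension, model = tether_model()) {
  check_extension(extension, model)
  z <- extension / model$contour_length
  (model$thermal_energy / model$persistence_length) *
    (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Marko-Siggia stiffness (analytic derivative)
#'
#' \deqn{dF/dx = (k_BT/L_p)\left[\frac{1}{2L_c(1-x/L_c)^3} + \frac{1}{L_c}\right].}
#'
#' @inheritParams ms_force
#' @return Stiffness in pN/nm.
#' @export
ms_stiffness <- function(extension, model = tether_model()) {
  check_extension(extension, model)
  z <- extension / model$contour_length
  (model$thermal_energy / model$persistence_length) *
    (1 / (2 * model$contour_length * (1 - z)^3) + 1 / model$contour_length)
}

#' High-force extensible WLC extension
#'
#' Closed-form extension of the extensible worm-like chain in the high-force
#' regime,
#' \deqn{x(F) = L_c\left(1 - \tfrac12\sqrt{k_BT/(F L_p)} + F/K_0\right),}
#' appropriate above ~0.5 pN where the chain is nearly straight and enthalpic
#' stretching matters.
#'
#' @param force Force in pN (vectorized, must be positive).
#' @param model A [tether_model()].
#' @return Extension in nm.
#' @export
ewlc_extension <- function(force, model = tether_model()) {
  if (any(force <= 0)) stop("force must be positive")
  model$contour_length *
    (1 - 0.5 * sqrt(model$thermal_energy / (force * model$persistence_length)) +
       force / model$stretch_modulus)
}

#' Numeric inverse of the high-force extensible WLC
#'
#' Solves `ewlc_extension(F) = extension` for F by bracketed root-finding over
#' F in \[0.05, 100\] pN.
#'
#' @param extension Extension in nm (vectorized).
#' @param model A [tether_model()].
#' @return Force in pN.
#' @export
ewlc_force <- function(extension, model = tether_model()) {
  lo <- 0.05
  hi <- 100
  xlo <- ewlc_extension(lo, model)
  xhi <- ewlc_extension(hi, model)
  if (any(extension < xlo) || any(extension > xhi)) {
    stop(sprintf(
      "extension outside the invertible range [%.1f, %.1f] nm (F in [0.05, 100] pN)",
      xlo, xhi))
  }
  vapply(extension, function(x) {
    stats::uniroot(function(f) ewlc_extension(f, model) - x,
                   lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' High-force extensible WLC stiffness
#'
#' Stiffness dF/dx = 1/(dx/dF) with
#' \deqn{dx/dF = L_c\left[\tfrac14\sqrt{k_BT/L_p}\,F^{-3/2} + 1/K_0\right]}
#' evaluated at the force balancing the given extension.
#'
#' @inheritParams ewlc_force
#' @return Stiffness in pN/nm.
#' @export
ewlc_stiffness <- function(extension, model = tether_model()) {
  f <- ewlc_force(extension, model)
  dxdf <- model$contour_length *
    (0.25 * sqrt(model$thermal_energy / model$persistence_length) * f^(-1.5) +
       1 / model$stretch_modulus)
  1 / dxdf
}

# Full extensible Marko-Siggia interpolation: F = (kBT/Lp)[1/(4(1-l)^2) - 1/4 + l]
# with l = x/Lc - F/K0, solved for F by bracketed root-finding. Valid over the
# whole force range; reduces to ms_force as K0 -> Inf.
ems_force_one <- function(extension, model) {
  if (extension <= 0) return(0)
  c0 <- model$thermal_energy / model$persistence_length
  g <- function(f) {
    l <- extension / model$contour_length - f / model$stretch_modulus
    if (l >= 1) return(-Inf)  # force too low to pull l below 1
    f - c0 * (1 / (4 * (1 - l)^2) - 0.25 + l)
  }
  # expand upper bracket until g > 0
  hi <- 1
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 4
  if (g(hi) < 0) stop("effective extension unreachable for this tether model")
  lo <- 0
  if (extension / model$contour_length >= 1) {
    # need F/K0 large enough that l < 1; start bracket above that force
    lo <- model$stretch_modulus * (extension / model$contour_length - 1) + 1e-9
    if (g(lo) > 0) return(lo)
  }
  stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
}

#' Full extensible Marko-Siggia force
#'
#' The full extensible interpolation formula, with the fractional extension
#' corrected for enthalpic stretching (l = x/Lc - F/K0) and solved
#' self-consistently for the force. This is the relation used for pipeline
#' force traces.
#'
#' @param extension DNA extension in nm (vectorized, >= 0).
#' @param model A [tether_model()].
#' @return Force in pN.
#' @export
ems_force <- function(extension, model = tether_model()) {
  if (any(extension < 0)) stop("extension must be non-negative")
  vapply(extension, ems_force_one, numeric(1), model = model)
}

#' Convert motor displacement from its anchor into tether force
#'
#' Subtracts the distance offset from the displacement magnitude to obtain the
#' DNA extension and evaluates the full extensible Marko-Siggia relation.
#' Displacements at or below the offset carry no tension. Signs (drive vs
#' resist) are handled by the state-classification layer; this function takes
#' the displacement magnitude.
#'
#' @param displacement Displacement magnitude from the equilibrium position,
#'   in nm (vectorized, >= 0).
#' @param model A [tether_model()].
#' @return Force in pN.
#' @examples
#' displacement_to_force(286)  # ~0.103 pN: extensibility negligible here
#' displacement_to_force(10)   # 0: inside the distance offset
#' @export
displacement_to_force <- function(displacement, model = tether_model()) {
  if (any(displacement < 0)) {
    stop("displacement must be a non-negative magnitude; apply sign conventions upstream")
  }
  ext <- pmax(0, displacement - model$distance_offset)
  ems_force(ext, model)
}
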