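#' Sample microtubule velocities from a stuck/fast two-Gaussian mixture
#'
#' Convenience generator of synthetic per-window microtubule velocities:
#' a stuck population centered near 0 nm/s and a fast gliding population.
#' Defaults are the zero-roadblock operating point (7% stuck, fast mean
#' 926 nm/s).
#'
#' @param n Number of samples.
#' @param stuck_fraction Weight of the stuck component.
#' @param stuck_mean,stuck_sd Stuck component mean and sd, nm/s.
#' @param fast_mean,fast_sd Fast component mean and sd, nm/s.
#' @param seed Integer seed.
#' @return Numeric vector of velocities (nm/s).
#' @export
sample_velocity_mixture <- function(n, stuck_fraction = 0.07,
                                    stuck_mean = 0, stuck_sd = 50,
                                    fast_mean = 926, fast_sd = 150,
                                    seed = 1) {
  stopifnot(n > 0, stuck_fraction >= 0, stuck_fraction <= 1)
  set.seed(seed)
  stuck <- stats::runif(n) < stuck_fraction
  ifelse(stuck, stats::rnorm(n, stuck_mean, stuck_sd),
         stats::rnorm(n, fast_mean, fast_sd))
}

#' Two-Gaussian stuck/fast decomposition of a velocity histogram
#'
#' Fits the sum of two Gaussians to a binned velocity histogram by
#' least squares, under the physical constraints that the stuck component is
#' centered near zero (|mean| <= 50 nm/s) and the fast component above
#' 400 nm/s. Initial values come from the histogram itself: the mass near
#' zero seeds the stuck weight and the mode above 400 nm/s the fast mean.
#'
#' @param velocities Velocity samples in nm/s (>= 200 required).
#' @param bin_width Histogram bin width in nm/s.
#' @return A list of class `velocity_mixture`: `stuck_weight`, `stuck_mean`,
#'   `stuck_sd`, `fast_weight`, `fast_mean`, `fast_sd`, `flag`
#'   (`"ok"` or `"degenerate"`), plus fit diagnostics (`rss`, `n`, `fit`).
#' @examples
#' v <- sample_velocity_mixture(2000, seed = 42)
#' fit_two_gaussians(v)
#' @export
fit_two_gaussians <- function(velocities, bin_width = 50) {
  v <- velocities[is.finite(velocities)]
  if (length(v) < 200) stop("need at least 200 velocity samples")
  br <- seq(floor(min(v, -100) / bin_width) * bin_width,
            ceiling(max(v) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  x <- h$mids
  y <- h$counts
  n <- length(v)
  w0 <- min(max(mean(abs(v) < 200), 0.01), 0.95)
  fast0 <- x[x > 400][which.max(y[x > 400])]
  if (!length(fast0) || !is.finite(fast0)) fast0 <- max(500, stats::median(v))
  model <- function(p, x) {
    n * bin_width * (p[1] * stats::dnorm(x, p[2], p[3]) +
                     (1 - p[1]) * stats::dnorm(x, p[4], p[5]))
  }
  fit <- minpack.lm::nls.lm(
    par = c(w = w0, m1 = 0, s1 = 50, m2 = fast0, s2 = max(stats::mad(v[v > 400]), 50)),
    lower = c(0, -50, 5, 400, 10),
    upper = c(1, 50, 150, max(2000, fast0 * 1.5), 1000),
    fn = function(p) y - model(p, x))
  p <- stats::coef(fit)
  flag <- if (p[["w"]] < 0.005 || p[["w"]] > 0.995) "degenerate" else "ok"
  structure(list(stuck_weight = unname(p["w"]), stuck_mean = unname(p["m1"]),
                 stuck_sd = unname(p["s1"]), fast_weight = unname(1 - p["w"]),
                 fast_mean = unname(p["m2"]), fast_sd = unname(p["s2"]),
                 flag = flag, rss = sum(fit$fvec^2), n = n, fit = fit),
            class = "velocity_mixture")
}

#' @export
print.velocity_mixture <- function(x, ...) {
  cat(sprintf("stuck %.1f%% (mean %.0f, sd %.0f nm/s) | fast %.1f%% (mean %.0f, sd %.0f nm/s) [%s]\n",
              100 * x$stuck_weight, x$stuck_mean, x$stuck_sd,
              100 * x$fast_weight, x$fast_mean, x$fast_sd, x$flag))
  invisible(x)
}

#' Constrained EM fit of the stuck/fast mixture (cross-check)
#'
#' Maximum-likelihood two-Gaussian fit on the raw samples by
#' expectation-maximization, with the stuck mean clamped to \[-50, 50\] nm/s
#' and the fast mean to >= 400 nm/s. Kept as an independent route to the
#' same decomposition as [fit_two_gaussians()].
#'
#' @inheritParams fit_two_gaussians
#' @param max_iter,tol EM stopping controls.
#' @return A `velocity_mixture` list (without histogram diagnostics).
#' @export
em_two_gaussians <- function(velocities, max_iter = 500, tol = 1e-8) {
  v <- velocities[is.finite(velocities)]
  if (length(v) < 200) stop("need at least 200 velocity samples")
  w <- min(max(mean(abs(v) < 200), 0.02), 0.9)
  m1 <- 0; s1 <- 50
  m2 <- stats::median(v[abs(v) >= 200]); if (!is.finite(m2)) m2 <- 800
  s2 <- max(stats::mad(v[abs(v) >= 200]), 50)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(v, m1, s1)
    d2 <- (1 - w) * stats::dnorm(v, m2, s2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    w <- mean(r)
    m1 <- min(max(sum(r * v) / sum(r), -50), 50)
    s1 <- max(sqrt(sum(r * (v - m1)^2) / sum(r)), 5)
    m2 <- max(sum((1 - r) * v) / sum(1 - r), 400)
    s2 <- max(sqrt(sum((1 - r) * (v - m2)^2) / sum(1 - r)), 10)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  flag <- if (w < 0.005 || w > 0.995) "degenerate" else "ok"
  structure(list(stuck_weight = w, stuck_mean = m1, stuck_sd = s1,
                 fast_weight = 1 - w, fast_mean = m2, fast_sd = s2,
                 flag = flag, loglik = ll, n = length(v)),
            class = "velocity_mixture")
}

#' Stuck fraction and fast mean across roadblock densities
#'
#' Fits the two-Gaussian decomposition per roadblock density and reports the
#' stuck fraction and fast-population mean with bootstrap confidence
#' intervals.
#'
#' @param samples Named list of velocity vectors; names are roadblock
#'   densities (per um).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param bin_width Histogram bin width passed to [fit_two_gaussians()].
#' @param seed Seed for the bootstrap.
#' @return Data frame with one row per density: stuck fraction and fast mean
#'   with confidence bounds.
#' @export
roadblock_series <- function(samples, n_boot = 100, conf = 0.95,
                             bin_width = 50, seed = 1) {
  dens <- as.numeric(names(samples))
  if (any(is.na(dens))) stop("samples must be named by numeric roadblock density")
  set.seed(seed)
  a <- (1 - conf) / 2
  rows <- lapply(seq_along(samples), function(i) {
    v <- samples[[i]]
    fit <- fit_two_gaussians(v, bin_width)
    boot <- replicate(n_boot, {
      b <- fit_two_gaussians(sample(v, replace = TRUE), bin_width)
      c(b$stuck_weight, b$fast_mean)
    })
    data.frame(density = dens[i], n = length(v),
               stuck_fraction = fit$stuck_weight,
               stuck_lower = stats::quantile(boot[1, ], a, names = FALSE),
               stuck_upper = stats::quantile(boot[1, ], 1 - a, names = FALSE),
               fast_mean = fit$fast_mean,
               fast_lower = stats::quantile(boot[2, ], a, names = FALSE),
               fast_upper = stats::quantile(boot[2, ], 1 - a, names = FALSE))
  })
  out <- do.call(rbind, rows)
  out[order(out$density), ]
}

#' Velocity mixtures stratified by engaged-motor number
#'
#' Fits the stuck/fast decomposition separately for velocity samples grouped
#' by how many motors were engaged with the microtubule, using the standard
#' team-size bins 1, 2-3, 4-5 and 6-8.
#'
#' @param velocities Velocity samples, nm/s.
#' @param n_motors Engaged-motor count per sample.
#' @param bins List of integer vectors defining the team-size bins.
#' @param min_samples Bins with fewer samples are flagged.
#' @param bin_width Histogram bin width.
#' @return Data frame with one row per team-size bin.
#' @export
by_motor_number <- function(velocities, n_motors,
                            bins = list(1, 2:3, 4:5, 6:8),
                            min_samples = 200, bin_width = 50) {
  stopifnot(length(velocities) == length(n_motors))
  rows <- lapply(bins, function(b) {
    v <- velocities[n_motors %in% b]
    label <- if (length(b) == 1) as.character(b) else paste0(min(b), "-", max(b))
    if (length(v) < max(min_samples, 200)) {
      if (length(v) < 200) {
        return(data.frame(bin = label, n = length(v), stuck_fraction = NA,
                          fast_mean = NA, low_confidence = TRUE))
      }
    }
    fit <- fit_two_gaussians(v, bin_width)
    data.frame(bin = label, n = length(v),
               stuck_fraction = if (fit$flag == "degenerate" && fit$stuck_weight < 0.005) 0
                                else fit$stuck_weight,
               fast_mean = fit$fast_mean,
               low_confidence = length(v) < min_samples)
  })
  do.call(rbind, rows)
}
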