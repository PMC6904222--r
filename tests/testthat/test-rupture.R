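test_that("analytic Bell-Evans survival has the closed-form median", {
  b <- bond_model(k0_bond = 1e-4, fb_bond = 5)
  s <- analytic_survival(b, force_rate = 1)
  expect_equal(s$survival(0), 1)
  expect_equal(s$median, 5 * log(1 + log(2) / (1e-4 * 5)), tolerance = 1e-12)
  expect_equal(s$median, 36.2, tolerance = 1e-2)
  expect_equal(s$survival(s$median), 0.5, tolerance = 1e-9)
  f <- seq(0, 60, by = 1)
  expect_true(all(diff(s$survival(f)) < 0))
  # median increases with loading rate
  meds <- vapply(c(0.5, 1, 5, 20), function(r) analytic_survival(b, r)$median,
                 numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("Monte-Carlo rupture under a constant force ramp sits in the DKW band", {
  b <- bond_model(k0_bond = 1e-3, fb_bond = 5)
  rate <- 2            # pN/s
  dt <- 0.01
  n <- 1000
  set.seed(6)
  # per-step hazard simulation using the package's rupture draw
  ruptures <- vapply(seq_len(n), function(i) {
    f <- 0
    repeat {
      f <- f + rate * dt
      if (anchor_rupture_step(f, dt, b)) return(f)
      if (f > 200) return(NA_real_)
    }
  }, numeric(1))
  expect_true(all(is.finite(ruptures)))
  s <- analytic_survival(b, rate)
  grid <- seq(1, max(ruptures), length.out = 200)
  emp <- vapply(grid, function(g) mean(ruptures > g), numeric(1))
  dkw <- sqrt(log(2 / 0.05) / (2 * n))
  expect_lt(max(abs(emp - s$survival(grid))), dkw + rate * dt / b$fb_bond)
})

test_that("pull simulation: no rupture limit, loading-rate ordering", {
  tm <- tether_model()
  # vanishing off-rate: the ramp completes, censored at the preset maximum
  p0 <- simulate_pull(bond_model(k0_bond = 1e-12), tm, rate = 100, dt = 0.02,
                      seed = 1, max_force = 40)
  expect_true(p0$censored)
  expect_equal(p0$rupture_force, 40, tolerance = 1e-6)
  # median rupture force grows with pull speed
  set.seed(7)
  med <- vapply(c(10, 100), function(r) {
    stats::median(vapply(seq_len(250), function(i)
      simulate_pull(rate = r, dt = 0.05)$rupture_force, numeric(1)))
  }, numeric(1))
  expect_gt(med[2], med[1])
  # calibration target of the default bond: ~30 pN at 10 nm/s
  expect_equal(med[1], 30, tolerance = 0.15)
  # force increases along the recorded curve
  p <- simulate_pull(rate = 10, dt = 0.02, seed = 2)
  expect_true(all(diff(p$curve$force) > 0))
  expect_true(all(diff(p$curve$extension) > 0))
})

test_that("eWLC fitting recovers tether parameters from pull curves", {
  tm <- tether_model()
  f <- seq(1, 25, length.out = 120)
  curve <- data.frame(force = f, extension = ewlc_extension(f, tm))
  fit <- fit_fec(curve)
  expect_lt(abs(fit$model$contour_length - 532), 0.5)
  expect_lt(abs(fit$model$persistence_length - 50), 1)
  expect_false(fit$flagged)
  # altered contour length is recovered
  tm400 <- tether_model(contour_length = 400)
  curve400 <- data.frame(force = f, extension = ewlc_extension(f, tm400))
  fit400 <- fit_fec(curve400)
  expect_equal(fit400$model$contour_length, 400, tolerance = 0.01)
  # two parallel tethers halve the compliance: flagged (the fit absorbs the
  # doubled stiffness into a collapsed persistence length)
  x2 <- ewlc_extension(f / 2, tm)
  fit2 <- fit_fec(data.frame(force = f, extension = x2))
  expect_true(fit2$flagged)
  expect_lt(fit2$model$persistence_length, 30)
  expect_error(fit_fec(curve[1:10, ]))
  expect_error(fit_fec(data.frame(force = rep(2, 60),
                                  extension = rep(470, 60))))
})

test_that("parameter recovery from noisy curves is unbiased within 2 SE", {
  tm <- tether_model()
  set.seed(9)
  f <- seq(2, 25, length.out = 80)
  ests <- t(vapply(1:60, function(i) {
    fn <- f + rnorm(length(f), 0, 0.2)
    fn <- sort(pmax(fn, 0.5))
    curve <- data.frame(force = fn, extension = ewlc_extension(f, tm))
    m <- fit_fec(curve)$model
    c(m$persistence_length, m$contour_length)
  }, numeric(2)))
  for (j in 1:2) {
    truth <- c(50, 532)[j]
    se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j]) - truth), 2 * se + 0.01 * truth)
  }
})

test_that("rupture detection uses the 50% drop rule", {
  up <- data.frame(force = seq(1, 15, by = 0.5))
  expect_true(detect_rupture(up)$censored)
  expect_equal(detect_rupture(up)$rupture_force, 15)
  drop <- data.frame(force = c(seq(1, 15, by = 0.5), 0.5))
  d <- detect_rupture(drop)
  expect_false(d$censored)
  expect_equal(d$rupture_force, 15)
  # a 10% dip is not a rupture
  dip <- data.frame(force = c(seq(1, 15, by = 0.5), 13.5, 14, 15))
  expect_true(detect_rupture(dip)$censored)
})

test_that("survival curve handles censoring and the midpoint median", {
  s <- suppressWarnings(survival_curve(c(10, 20, 30, 40)))
  expect_equal(s$median, 25)
  expect_true(all(diff(s$survival$surv) <= 0))
  allc <- suppressWarnings(survival_curve(c(10, 20, 30, 40),
                                          censored = rep(TRUE, 4)))
  expect_true(all(allc$survival$surv == 1))
  expect_true(allc$median_is_lower_bound)
})

test_that("generate -> detect -> survival round trip matches the analytic median", {
  # constant-force-rate pulls so the Bell-Evans closed form is the exact
  # reference; the detection + Kaplan-Meier chain must not distort the median
  b <- bond_model(k0_bond = 5e-3, fb_bond = 6)
  rate <- 3; dt <- 0.02
  set.seed(11)
  forces <- lapply(seq_len(400), function(i) {
    f <- seq(dt, 80, by = dt) * rate
    haz <- cumsum(b$k0_bond * exp(f / b$fb_bond) * dt)
    k <- which(haz >= stats::rexp(1))[1]
    if (is.na(k)) f else c(f[seq_len(k)], 0.01)  # append the rupture drop
  })
  det <- lapply(forces, function(f) detect_rupture(data.frame(force = f)))
  sc <- survival_curve(vapply(det, `[[`, numeric(1), "rupture_force"),
                       vapply(det, `[[`, logical(1), "censored"))
  expect_lt(abs(sc$median / analytic_survival(b, rate)$median - 1), 0.05)
})
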