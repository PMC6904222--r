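tm <- tether_model()

test_that("Marko-Siggia force matches direct evaluation of the interpolation", {
  # hand evaluation at half the contour length: (4.14/50)*(1 - 1/4 + 1/2)
  expect_equal(ms_force(266, tm), (4.14 / 50) * (1 - 0.25 + 0.5), tolerance = 1e-12)
  expect_equal(ms_force(266, tm), 0.1035, tolerance = 1e-4)
  expect_equal(ms_force(246, tm), 0.0892, tolerance = 1e-3)
  expect_identical(ms_force(0, tm), 0)
  expect_error(ms_force(-1, tm))
  expect_error(ms_force(532, tm))
})

test_that("Marko-Siggia stiffness is analytic and matches finite differences", {
  # printed tether elasticity at displacement 266 nm (extension 246 nm)
  expect_equal(signif(ms_stiffness(246, tm), 2), 0.00066)
  expect_equal(ms_stiffness(0, tm),
               (4.14 / 50) * 3 / (2 * 532), tolerance = 1e-12)
  for (x in c(50, 150, 246, 350, 450)) {
    h <- 1e-3
    fd <- (ms_force(x + h, tm) - ms_force(x - h, tm)) / (2 * h)
    expect_equal(ms_stiffness(x, tm), fd, tolerance = 1e-4)
  }
  expect_gt(ms_stiffness(300, tm), ms_stiffness(100, tm))
})

test_that("high-force eWLC extension reproduces printed force-extension points", {
  expect_equal(ewlc_extension(15, tm), 518.9, tolerance = 2e-4)
  expect_equal(ewlc_extension(4.1, tm), 496.0, tolerance = 2e-4)
  expect_lt(ewlc_extension(10, tm), ewlc_extension(20, tm))
  expect_error(ewlc_extension(0, tm))
  expect_error(ewlc_extension(-2, tm))
  # extension never exceeds the enthalpic bound Lc (1 + F/K0)
  f <- c(0.5, 1, 5, 20, 60)
  expect_true(all(ewlc_extension(f, tm) < 532 * (1 + f / 1200)))
})

test_that("ewlc_force inverts ewlc_extension to tight tolerance", {
  expect_equal(ewlc_force(496.0, tm), 4.10, tolerance = 1e-3)
  expect_equal(ewlc_force(518.9, tm), 15.0, tolerance = 1e-3)
  for (f in c(1, 5, 20)) {
    expect_equal(ewlc_force(ewlc_extension(f, tm), tm), f, tolerance = 1e-6)
  }
  x <- ewlc_extension(c(0.1, 2, 40), tm)
  expect_equal(ewlc_extension(ewlc_force(x, tm), tm), x, tolerance = 1e-6)
  expect_error(ewlc_force(1e4, tm))
  expect_error(ewlc_force(-5, tm))
})

test_that("high-force eWLC stiffness reproduces the printed large-extension value", {
  # printed 0.19 pN/nm at displacement 516 nm (extension 496 nm)
  expect_equal(ewlc_stiffness(496, tm), 0.19, tolerance = 0.05)
  # frozen from the finite-difference oracle on ewlc_force at x = 519 nm
  # (F = 15.1 pN there; dx/dF = 532 [0.25 sqrt(kBT/Lp) F^-1.5 + 1/K0])
  expect_equal(ewlc_stiffness(519, tm), 0.9129, tolerance = 1e-3)
  expect_lt(ewlc_stiffness(450, tm), ewlc_stiffness(500, tm))
  # matches finite difference of the inverse map
  h <- 1e-3
  fd <- (ewlc_force(496 + h, tm) - ewlc_force(496 - h, tm)) / (2 * h)
  expect_equal(ewlc_stiffness(496, tm), fd, tolerance = 1e-6)
})

test_that("full extensible Marko-Siggia bridges the two closed forms", {
  # low force: extensibility negligible, agrees with inextensible MS
  for (f in c(0.05, 0.1, 0.3, 0.5)) {
    x <- stats::uniroot(function(x) ms_force(x, tm) - f, c(0, 531.9), tol = 1e-10)$root
    x_ems <- stats::uniroot(function(x) ems_force(x, tm) - f, c(0, 600), tol = 1e-10)$root
    expect_equal(x_ems, x, tolerance = 5e-3)
  }
  # high force: agrees with the high-force series within 1 nm
  for (f in c(2, 5, 10, 20)) {
    x_hi <- ewlc_extension(f, tm)
    x_ems <- stats::uniroot(function(x) ems_force(x, tm) - f, c(0, 600), tol = 1e-10)$root
    expect_lt(abs(x_hi - x_ems), 1)
  }
  # strictly monotone
  xs <- seq(0, 540, by = 20)
  expect_true(all(diff(ems_force(xs, tm)) > 0))
})

test_that("displacement_to_force applies the offset and full extensible relation", {
  expect_identical(displacement_to_force(20, tm), 0)
  expect_identical(displacement_to_force(10, tm), 0)
  expect_equal(displacement_to_force(286, tm), 0.103, tolerance = 5e-3)
  expect_error(displacement_to_force(-5, tm))
  # vectorized and monotone beyond the offset
  d <- c(20, 100, 300, 500, 552)
  expect_true(all(diff(displacement_to_force(d, tm)) >= 0))
})

test_that("tether_model validates its invariants", {
  expect_error(tether_model(persistence_length = -1))
  expect_error(tether_model(distance_offset = 600))
  expect_error(tether_model(contour_length = 0))
})
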