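test_that("quasi-static force balance holds to machine-level residuals", {
  s <- test_glide_sim()
  expect_lt(s$max_residual, 1e-6)
})

test_that("a single motor settles driving at its loaded walking speed", {
  mo <- motor_config(unbind_rate_drive_0 = 1e-6, unbind_rate_resist_0 = 1e-6,
                     unloaded_speed_sd = 0)
  s <- simulate_gliding(assay_config(motor_count = 1, duration = 20, seed = 5),
                        motor = mo, localization_noise_sd = 0)
  late <- s$mt$time > 5
  tension <- mean(s$motors$tension[s$motors$time > 5])
  v <- mean(s$mt$velocity[late])
  expect_equal(v, force_velocity(-tension, 830, mo), tolerance = 0.01)
  # drag force balances the single tether force: F = gamma * V
  expect_equal(tension, 1e-3 * v, tolerance = 0.02)
  # the motor is displaced behind its anchor: driving
  m <- s$motors[s$motors$time > 5, ]
  expect_true(all(m$position_true < s$anchors[1]))
  expect_true(all(m$role == "drive"))
})

test_that("sign conventions: drive labels mean displacement opposite gliding", {
  s <- test_glide_sim()
  m <- s$motors[s$motors$bound & s$motors$role %in% c("drive", "resist"), ]
  expect_true(all((m$displacement < 0) == (m$role == "drive")))
  expect_true(all(m$displacement == m$position_true - m$anchor))
})

test_that("engaged tensions stay in the low-piconewton regime", {
  s <- test_glide_sim()
  m <- s$motors[s$motors$bound, ]
  expect_lt(mean(m$tension), 4)
  # early-binding tension: first 0.8 s of every bound spell averages < 0.4 pN
  early <- unlist(lapply(split(m, m$kinesin), function(g) {
    g <- g[order(g$time), ]
    spell <- cumsum(c(TRUE, diff(g$frame) > 1))
    unlist(lapply(split(g$tension, spell), function(tt) tt[seq_len(min(4, length(tt)))]))
  }))
  expect_lt(mean(early), 0.4)
})

test_that("three calibrated motors keep roughly two thirds driving", {
  fr <- vapply(1:6, function(sd) {
    s <- simulate_gliding(assay_config(motor_count = 3, duration = 60, seed = sd))
    m <- s$motors[s$motors$bound & s$motors$role %in% c("drive", "resist"), ]
    mean(m$role == "drive")
  }, numeric(1))
  expect_gt(mean(fr), 0.55)
  expect_lt(mean(fr), 0.75)
})

test_that("roadblocks generate stuck episodes that more motors rescue", {
  stuck_frac <- vapply(c(2, 6), function(nmot) {
    v <- unlist(lapply(1:3, function(sd) {
      s <- simulate_gliding(
        assay_config(motor_count = nmot, roadblock_density = 2.5,
                     duration = 60, seed = 100 + sd))
      mt_velocity_windows(s, 1)$velocity
    }))
    mean(abs(v) < 200)
  }, numeric(1))
  expect_gt(stuck_frac[1], 0.02)        # stuck population exists
  expect_lte(stuck_frac[2], stuck_frac[1])  # larger teams get stuck less
})

test_that("roadblock placement is Poisson with the requested density", {
  expect_identical(place_roadblocks(0, 10, seed = 1), numeric(0))
  counts <- vapply(1:200, function(i) length(place_roadblocks(2.5, 10)), numeric(1))
  expect_equal(mean(counts), 25, tolerance = 0.05)
  counts2 <- vapply(1:200, function(i) length(place_roadblocks(0.75, 8)), numeric(1))
  expect_equal(mean(counts2), 6, tolerance = 0.1)
})

test_that("force-velocity relation has plateau, stall and assisted branches", {
  mo <- motor_config()
  expect_equal(force_velocity(0, 830, mo), 830)
  expect_equal(force_velocity(2, 830, mo), 830)     # inside the +/-2 pN plateau
  expect_equal(force_velocity(-2, 830, mo), 830)
  expect_equal(force_velocity(-6, 830, mo), 0)      # stall
  expect_equal(force_velocity(-8, 500, mo), 0)      # beyond stall clamps
  expect_gt(force_velocity(4, 500, mo), 500)        # assisting speeds up
  expect_equal(force_velocity(6, 500, mo), force_velocity(9, 500, mo))
  # continuity at the plateau edges
  expect_equal(force_velocity(-2.0001, 830, mo), 830, tolerance = 1e-2)
  expect_equal(force_velocity(2.0001, 830, mo), 830, tolerance = 1e-2)
})

test_that("unbinding obeys the Bell law with resisting asymmetry", {
  mo <- motor_config()
  expect_equal(unbinding_rate(0, "drive", mo), mo$unbind_rate_drive_0)
  expect_equal(unbinding_rate(0, "resist", mo), mo$unbind_rate_resist_0)
  expect_gt(unbinding_rate(2, "resist", mo), unbinding_rate(2, "drive", mo))
  expect_equal(unbinding_rate(4, "drive", mo) / unbinding_rate(0, "drive", mo),
               exp(4 / mo$detach_force_drive), tolerance = 1e-12)
})

test_that("anchor rupture hazard is Bell-Evans", {
  b <- bond_model(k0_bond = 1e-4, fb_bond = 5)
  set.seed(4)
  hits <- mean(replicate(2000, anchor_rupture_step(0, 0.1, b)))
  expect_lt(hits, 1e-3)  # ~1e-5 probability at zero force
  p5 <- 1 - exp(-bond_rate(5, b) * 0.1)
  p10 <- 1 - exp(-bond_rate(10, b) * 0.1)
  expect_gt(p10, p5)
  expect_equal(bond_rate(10, b) / bond_rate(5, b), exp(5 / 5), tolerance = 1e-12)
})

test_that("simulation with a bond model produces rupture records", {
  s <- simulate_gliding(assay_config(motor_count = 3, duration = 40, seed = 8),
                        bond = bond_model(k0_bond = 0.05, fb_bond = 2))
  expect_false(is.null(s$ruptures))
  expect_true(all(s$ruptures$force >= 0))
})
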