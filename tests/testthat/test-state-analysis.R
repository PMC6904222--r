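test_that("equilibrium estimation resists excursion plateaus", {
  set.seed(10)
  base <- rnorm(1000, 0, 20)
  eq <- find_equilibrium(base)
  expect_lt(abs(eq$position), 3)
  expect_lt(abs(eq$noise_sd - 20), 4)
  # 30% of frames on a -300 nm plateau must not shift the estimate
  x <- base
  x[300:599] <- -300 + rnorm(300, 0, 20)
  # plateau entered/exited gradually so only the plateau is quiescent
  eq2 <- find_equilibrium(x)
  expect_lt(abs(eq2$position), 10)
  eq3 <- find_equilibrium(rep(5, 100))
  expect_equal(eq3$position, 5)
  expect_identical(eq3$flag, "constant")
  expect_error(find_equilibrium(rnorm(10)))
})

test_that("classification honours the two-point displacement criteria", {
  fi <- 0.2
  vmt <- rep(800, 200)
  # two samples at +150 nm with noise sd ~20: one resisting event
  set.seed(2)
  x <- rnorm(200, 0, 20)
  x[100:101] <- 150
  eq <- list(position = 0, noise_sd = 20)
  ev <- classify_events(x, vmt, eq = eq, frame_interval = fi)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$role, "resist")
  # peak 90 nm with noise sd 30 qualifies through the 2-sd branch
  set.seed(3)
  x2 <- rnorm(200, 0, 30)
  x2[100:102] <- c(70, 90, 75)
  ev2 <- classify_events(x2, vmt, eq = list(position = 0, noise_sd = 30),
                         frame_interval = fi)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$role, "resist")
  # the same excursion against a reversed gliding direction is driving
  ev3 <- classify_events(x2, -vmt, eq = list(position = 0, noise_sd = 30),
                         frame_interval = fi)
  expect_identical(ev3$role, "drive")
  # a track with a 6 s hole is discarded entirely
  x3 <- x; x3[50:80] <- NA
  ev4 <- classify_events(x3, vmt, eq = eq, frame_interval = fi)
  expect_identical(nrow(ev4), 0L)
  expect_identical(attr(ev4, "removed"), "missing-data")
  expect_error(classify_events(x, vmt, eq = eq, frame_interval = NULL))
})

test_that("frame-level role accuracy and event counts match ground truth", {
  s <- test_event_sim()
  ev <- test_event_analysis()
  expect_lt(abs(nrow(ev) / nrow(s$events) - 1), 0.05)
  eng <- engagement_table(ev, 0.2, 240)
  key <- paste(eng$kinesin, eng$frame)
  pred <- stats::setNames(eng$role, key)
  tt <- s$tracks
  pr <- pred[paste(tt$kinesin, tt$frame)]
  pr[is.na(pr)] <- "none"
  expect_gte(mean(pr == tt$true_role), 0.95)
  # sign consistency: drive events have negative peak displacement
  expect_true(all(ev$peak_displacement[ev$role == "drive"] < 0))
  expect_true(all(ev$peak_displacement[ev$role == "resist"] > 0))
})

test_that("recovered kinetics match the generator within sampling error", {
  ev <- test_event_analysis()
  k <- event_kinetics(ev)
  s <- k$summary
  d <- s[s$role == "drive", ]; r <- s[s$role == "resist", ]
  expect_lt(abs(d$mean_duration - 3.0), 3 * d$sem_duration + 0.1)
  expect_lt(abs(r$mean_duration - 2.15), 3 * r$sem_duration + 0.1)
  expect_lt(abs(d$mean_runlength - 2.31), 3 * d$sem_runlength + 0.08)
  expect_lt(abs(r$mean_runlength - 1.42), 3 * r$sem_runlength + 0.08)
  expect_lt(abs(k$runlength_asymmetry - 0.62), 0.15)
})

test_that("transition counting types consecutive event pairs", {
  ev <- data.frame(kinesin = 1,
                   role = c("drive", "drive", "resist"),
                   start = c(0, 5, 9), end = c(3, 8, 10))
  tr <- count_transitions(ev, observation_min = 1)
  expect_equal(tr$rate_per_min, 2)
  expect_equal(unname(tr$mix[c("dd", "dr")]), c(0.5, 0.5))
  expect_equal(sum(tr$mix), 1)
  single <- count_transitions(ev[1, ], observation_min = 1)
  expect_equal(single$n_transitions, 0L)
})

test_that("recovered transition statistics match the calibration", {
  ev <- test_event_analysis()
  tr <- count_transitions(ev, observation_min = 30 * 240 / 60)
  expect_lt(abs(tr$rate_per_min - 4.9), 0.5)
})

test_that("run length integrates relative velocity", {
  # one event: cargo at 830 nm/s, motor stationary for 2 s -> 1.66 um
  fi <- 0.2
  n <- 300
  x <- c(rep(0, 50), seq(0, 137, length.out = 3), rep(137, 97), rep(0, 150))
  vmt <- rep(830, n)
  ev <- classify_events(x, vmt, eq = list(position = 0, noise_sd = 10),
                        frame_interval = fi)
  expect_identical(nrow(ev), 1L)
  plateau_s <- 97 * fi
  expect_equal(ev$run_length, 0.830 * ev$duration - 0.000137,
               tolerance = 0.05)
})

test_that("force builds slowly early in an event and saturates below full extension", {
  fi <- 0.2
  # ramp at 800 nm/s to a 400 nm plateau: tension < 0.4 pN before 0.8 s,
  # since the tether is slack over the first ~0.5 s of stretching
  x <- c(rep(0, 20), pmin((1:100) * fi * 800, 400), rep(0, 30))
  vmt <- rep(800, length(x))
  ev <- classify_events(x, vmt, eq = list(position = 0, noise_sd = 15),
                        frame_interval = fi)
  fv <- force_vs_time(ev, bin = 0.2)
  expect_true(all(fv$mean_force[fv$time < 0.8] < 0.4))
  # plateau at 520 nm displacement: constant force near the eWLC value,
  # below the force at full extension
  x2 <- c(rep(0, 20), pmin((1:100) * fi * 800, 520), rep(0, 30))
  ev2 <- classify_events(x2, vmt, eq = list(position = 0, noise_sd = 15),
                         frame_interval = fi)
  fv2 <- force_vs_time(ev2, bin = 0.2)
  late <- fv2$mean_force[fv2$time > 2 & fv2$time < 10]
  expect_equal(mean(late), ems_force(500), tolerance = 0.05)
  expect_lt(max(fv2$mean_force), ems_force(531.9))
  # all-zero displacement gives a zero curve
  ev0 <- ev
  ev0$series[[1]]$force <- 0 * ev0$series[[1]]$force
  expect_true(all(force_vs_time(ev0)$mean_force == 0))
})

test_that("fraction driving pools per-frame engaged roles by team size", {
  eng <- data.frame(mt = 1, frame = rep(1:100, each = 3),
                    kinesin = rep(1:3, 100),
                    role = rep(c("drive", "drive", "resist"), 100))
  fd <- fraction_driving(eng)
  expect_identical(fd$n_motors, 3L)
  expect_equal(fd$fraction, 2 / 3)
  all_drive <- within(eng, role <- "drive")
  expect_equal(fraction_driving(all_drive)$fraction, 1)
  # recovery across team sizes on generated data
  s <- generate_event_traces(n_kinesins = 36, duration = 120, seed = 31,
                             motors_per_mt = c(1, 2, 3, 6))
  ev <- extract_events(s$tracks, s$mt, frame_interval = 0.2)
  fd2 <- fraction_driving(engagement_table(ev, 0.2, 120))
  expect_lt(abs(attr(fd2, "pooled") - 0.65), 0.05)
  ok <- fd2$frames >= 200
  expect_true(all(fd2$lower[ok] < 0.80 & fd2$upper[ok] > 0.50))
})

test_that("relative velocity starts role-split and converges to cargo speed", {
  s <- test_event_sim()
  ev <- test_event_analysis()
  rv <- relative_velocity_curves(ev, s$mt, t_max = 4)
  cal <- s$calibration
  early_d <- rv$mean_vrel[rv$role == "drive" & rv$time < 0.2]
  late <- rv[rv$time > 2.5, ]
  gap <- abs(mean(late$mean_vrel[late$role == "drive"]) -
             mean(late$mean_vrel[late$role == "resist"]))
  expect_gt(early_d[1], cal$cargo_speed + 100)  # drivers start fast
  expect_lt(gap, 0.1 * cal$mt_speed_mean)       # roles converge
  # stationary motor relative to an 830 nm/s cargo moves at 830 nm/s
  ev1 <- data.frame(role = "resist", start = 1, end = 3, duration = 2,
                    run_length = 1.66, peak_displacement = 150,
                    mean_force = 0, kinesin = 1, mt = 1)
  ev1$series <- list(data.frame(time = seq(1, 3, by = 0.2),
                                displacement = 150,
                                force = 0))
  mt1 <- data.frame(mt = 1, time = seq(0, 4, by = 0.2), velocity = 830)
  rv1 <- relative_velocity_curves(ev1, mt1)
  expect_equal(mean(rv1$mean_vrel), 830, tolerance = 1e-6)
})

test_that("density sweep tabulates per-role kinetics and engagement", {
  ev <- test_event_analysis()
  tab <- density_sweep(list("0.11" = ev))
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("density", "mean_engaged") %in% names(tab)))
  tab2 <- density_sweep(list("0.03" = ev[ev$duration > 2, ],
                             "0.46" = ev[ev$duration <= 2, ]))
  long <- tab2[tab2$density == 0.03, ]
  short <- tab2[tab2$density == 0.46, ]
  expect_true(all(long$mean_duration > short$mean_duration))
  expect_error(suppressWarnings(density_sweep(list(a = ev))))
})
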