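test_that("linear assignment solver matches brute force on random costs", {
  perm <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perm(v[-i]), function(p) c(v[i], p))
    }))
  }
  set.seed(17)
  for (k in 1:20) {
    n <- sample(2:5, 1); m <- n + sample(0:3, 1)
    C <- matrix(runif(n * m), n, m)
    a <- forceglide:::lap_solve(C)
    best <- Inf
    for (cs in utils::combn(m, n, simplify = FALSE)) {
      for (p in perm(cs)) best <- min(best, sum(C[cbind(1:n, p)]))
    }
    expect_equal(sum(C[cbind(1:n, a)]), best, tolerance = 1e-12)
  }
})

test_that("LoG detection finds isolated spots and nothing on blank frames", {
  set.seed(2)
  blank <- matrix(rpois(96 * 96, 5) + rnorm(96 * 96, 0, 2), 96, 96)
  expect_identical(nrow(detect_spots(blank, 4, threshold = 30)), 0L)
  # two emitters 2 um apart (12.5 px): two detections near truth
  pos <- data.frame(frame = 0, id = 1:2, x = c(4000, 6000), y = c(5000, 5000))
  st <- render_frames(pos, fov = c(96, 96), photons = 3000, seed = 3)
  d <- detect_spots(st$stack[, , 1], 4)
  expect_identical(nrow(d), 2L)
  got <- sort(d$x * 160)
  expect_lt(max(abs(got - c(4000, 6000))), 160)  # within 1 px
  expect_true(all(abs(d$y * 160 - 5000) < 160))
})

test_that("sub-pixel localization is accurate and improves with photons", {
  pos <- data.frame(frame = 0, id = 1, x = 100.3 * 160, y = 57.8 * 160)
  st <- render_frames(pos, fov = c(128, 96), photons = 2e5, background = 1,
                      read_noise = 0.2, seed = 4)
  d <- detect_spots(st$stack[, , 1], 4)
  l <- localize_subpixel(st$stack[, , 1], d[1, ], pixel_nm = 160)
  expect_lt(abs(l$x / 160 - 100.3), 0.02)
  expect_lt(abs(l$y / 160 - 57.8), 0.02)
  # localization error shrinks roughly as 1/sqrt(photons)
  rms <- vapply(c(500, 5000, 50000), function(ph) {
    errs <- vapply(1:8, function(i) {
      sti <- render_frames(pos, fov = c(128, 96), photons = ph, background = 5,
                           seed = 100 + i)
      di <- detect_spots(sti$stack[, , 1], 4)
      li <- localize_subpixel(sti$stack[, , 1], di[1, , drop = FALSE],
                              pixel_nm = 160)
      sqrt((li$x - pos$x)^2 + (li$y - pos$y)^2)
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 5)  # high-photon regime: < 5 nm RMS
})

test_that("linking follows drift, closes small gaps, splits long ones", {
  # steady 1 px/frame drift: one track
  sp <- data.frame(frame = 0:19, x = 1000 + (0:19) * 160, y = 800)
  expect_identical(length(unique(link_tracks(sp)$track)), 1L)
  # 10-frame gap, reappearing within 4 px: stitched
  sp2 <- data.frame(frame = c(0:9, 20:29), x = c(rep(1000, 10), rep(1400, 10)),
                    y = 800)
  expect_identical(length(unique(link_tracks(sp2)$track)), 1L)
  # 25-frame gap exceeds the limit: two tracks
  sp3 <- data.frame(frame = c(0:4, 30:34), x = rep(1000, 10), y = 800)
  expect_identical(length(unique(link_tracks(sp3)$track)), 2L)
  # displacement beyond max_link is not followed
  sp4 <- data.frame(frame = 0:1, x = c(1000, 1000 + 5 * 160), y = 800)
  expect_identical(length(unique(link_tracks(sp4)$track)), 2L)
})

test_that("stack tracking recovers well-separated emitter tracks end-to-end", {
  nf <- 15
  truth <- rbind(
    data.frame(frame = 0:(nf - 1), id = 1, x = 3000 + (0:(nf - 1)) * 120, y = 2400),
    data.frame(frame = 0:(nf - 1), id = 2, x = 9000 - (0:(nf - 1)) * 100, y = 4600))
  st <- render_frames(truth, fov = c(96, 48), photons = 4000, seed = 6)
  spots <- track_stack_spots(st)
  tracks <- link_tracks(spots)
  expect_identical(length(unique(tracks$track)), 2L)
  # match recovered to truth per frame: >= 99% of frames within 60 nm
  err <- vapply(seq_len(nrow(tracks)), function(i) {
    tr <- truth[truth$frame == tracks$frame[i], ]
    min(sqrt((tr$x - tracks$x[i])^2 + (tr$y - tracks$y[i])^2))
  }, numeric(1))
  expect_gte(mean(err < 60), 0.99)
  expect_identical(nrow(tracks), nrow(truth))
})

test_that("spot CSV round-trips through the tracker-export dialect", {
  tr <- data.frame(track = c(1, 1, 2), frame = c(0, 1, 0),
                   x = c(100.5, 120.25, 4000), y = c(50, 51, 2000))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spot_csv(tr, path)
  back <- read_spot_csv(path)
  expect_equal(back, tr)
  expect_error(read_spot_csv(withr::local_tempfile(lines = "a,b\n1,2",
                                                   fileext = ".csv")))
})
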