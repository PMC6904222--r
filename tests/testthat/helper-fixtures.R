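# Shared fixtures built once per test run (small, deterministic).

fg_test_env <- new.env(parent = emptyenv())

test_event_sim <- function() {
  if (is.null(fg_test_env$esim)) {
    fg_test_env$esim <- generate_event_traces(event_calibration(),
                                              n_kinesins = 30,
                                              duration = 240, seed = 71)
  }
  fg_test_env$esim
}

test_event_analysis <- function() {
  if (is.null(fg_test_env$ev)) {
    s <- test_event_sim()
    fg_test_env$ev <- extract_events(s$tracks, s$mt, frame_interval = 0.2)
  }
  fg_test_env$ev
}

test_glide_sim <- function() {
  if (is.null(fg_test_env$glide)) {
    fg_test_env$glide <- simulate_gliding(
      assay_config(motor_count = 3, duration = 90, seed = 5))
  }
  fg_test_env$glide
}

# a synthetic single-motor trace with known events: returns list(onaxis, vmt,
# events truth) on a 0.2 s grid
toy_trace <- function(events, n_frames = 600, noise_sd = 20, v_mt = 724,
                      ramp = list(drive = 576, resist = 224),
                      amplitude = 137, seed = 1, frame_interval = 0.2) {
  set.seed(seed)
  times <- (seq_len(n_frames) - 1) * frame_interval
  disp <- numeric(n_frames)
  for (e in events) {
    sgn <- if (e$role == "drive") -1 else 1
    rate <- ramp[[e$role]]
    idx <- which(times >= e$start & times < e$end)
    disp[idx] <- sgn * pmin((times[idx] - e$start) * rate, amplitude)
  }
  list(onaxis = disp + rnorm(n_frames, 0, noise_sd),
       vmt = rep(v_mt, n_frames) + rnorm(n_frames, 0, 30),
       times = times)
}
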