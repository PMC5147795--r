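test_that("version and vergence decomposition follows the binocular rules", {
  rec <- make_recording(rep(0, 4))
  rec$samples$lx_deg <- c(1, 1, 0, 2); rec$samples$ly_deg <- c(2, 2, 0, 2)
  rec$samples$rx_deg <- c(3, 3, 0, 2); rec$samples$ry_deg <- c(4, 4, 0, 2)
  rec$samples$valid_l[3] <- 0L
  sig <- binocular_signals(rec)
  expect_equal(sig$version_x[1], 2)   # (1+3)/2
  expect_equal(sig$version_y[1], 3)   # (2+4)/2
  expect_equal(sig$vergence_x[1], -2) # 1-3
  expect_equal(sig$vergence_y[1], -2) # 2-4
  ## one invalid eye poisons all four series at that sample
  expect_false(sig$usable[3])
  expect_true(all(is.na(c(sig$version_x[3], sig$version_y[3],
                          sig$vergence_x[3], sig$vergence_y[3]))))
  ## identical eyes: vergence identically zero, version equals either eye
  expect_equal(sig$vergence_x[4], 0)
  expect_equal(sig$version_x[4], 2)
})

test_that("rms_noise matches closed forms and bootstrap rules", {
  expect_equal(rms_noise(rep(3.2, 100), 50), 0)          # constant
  alt <- rep(c(0.7, -0.7), 20)
  expect_equal(rms_noise(alt, 40, window = 24), 0.7)     # +/- a around 0
  expect_equal(rms_noise(alt, 1), 0)                     # idx = 1
  ## NA (unusable) samples are skipped, not counted
  v <- c(rep(NA_real_, 5), rep(c(1, -1), 10))
  expect_equal(rms_noise(v, length(v), window = 20), 1)
})

test_that("a constant signal yields exactly one fixation spanning all samples", {
  rec <- make_recording(rep(1.5, 100))
  ev <- segment_events(rec)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "fixation")
  expect_identical(c(ev$start_idx, ev$end_idx), c(1L, 100L))
})

test_that("an all-invalid recording is one distortion event", {
  rec <- make_recording(rep(0, 80), valid = 0L)
  ev <- segment_events(rec)
  expect_identical(ev$kind, "distortion")
  expect_identical(c(ev$start_idx, ev$end_idx), c(1L, 80L))
})

test_that("a recording shorter than the minimum fixation warns and is empty", {
  rec <- make_recording(rep(0, 4))
  expect_warning(ev <- segment_events(rec), "shorter")
  expect_identical(nrow(ev), 0L)
})

test_that("a sample exactly at threshold distance counts as within", {
  ## constant at 0, then a step of exactly 0.5 deg (the base threshold,
  ## with zero estimated noise): must remain one stable run
  vx <- c(rep(0, 11), 0.5)  # run mean stays 0 until the step sample
  ev <- segment_events(make_recording(vx))
  expect_identical(ev$kind, "fixation")
  expect_identical(nrow(ev), 1L)
  ## just beyond threshold: a saccade opens
  vx2 <- c(rep(0, 11), 0.5 + 1e-9, 2, 2, 2, 2, 2, 2)
  ev2 <- segment_events(make_recording(vx2))
  expect_true("saccade" %in% ev2$kind)
})

test_that("noiseless synthetic recordings are segmented exactly as generated", {
  for (s in c(2, 21, 303)) {
    for (grp in list(hr_gaze_params(), lr_gaze_params())) {
      rec <- simulate_recording(noiseless(grp), seed = s)
      gt <- attr(rec, "ground_truth")
      ev <- detect_events(rec)
      expect_identical(ev$kind, gt$kind)
      expect_identical(ev$start_idx, gt$start_idx)
      expect_identical(ev$end_idx, gt$end_idx)
      expect_identical(ev$direction, gt$direction)
    }
  }
})

test_that("with moderate noise the fixation count stays within one per line", {
  layout <- text_layout()
  for (s in 1:5) {
    p <- hr_gaze_params(measurement_noise_sd = 0.1, dropout_prob = 0,
                        transient_rate = 0)
    rec <- simulate_recording(p, layout, seed = s)
    gt <- attr(rec, "ground_truth")
    ev <- detect_events(rec)
    expect_lte(abs(sum(ev$kind == "fixation") - sum(gt$kind == "fixation")),
               layout$n_lines)
  }
})

test_that("events tile the recording and are mutually exclusive", {
  for (s in 1:10) {
    rec <- simulate_recording(hr_gaze_params(), seed = 1000 + s)
    ev <- detect_events(rec)
    expect_identical(ev$start_idx, c(1L, head(ev$end_idx, -1) + 1L))
    expect_identical(tail(ev$end_idx, 1), nrow(rec$samples))
    expect_true(all(ev$end_idx >= ev$start_idx))
    expect_true(all(ev$kind %in% c("fixation", "saccade", "sweep",
                                   "transient", "distortion")))
  }
})

test_that("raising the dispersion threshold never adds saccades", {
  ## holds from the default threshold upward; below the noise floor a
  ## dispersion state machine merges consecutive movement samples into
  ## fewer, longer saccade runs instead
  rec <- simulate_recording(hr_gaze_params(), seed = 77)
  n_sacc <- vapply(c(0.5, 0.8, 1.2, 2.0), function(b) {
    ev <- segment_events(rec, detector_config(dispersion_base = b))
    sum(ev$kind == "saccade")
  }, numeric(1))
  expect_true(all(diff(n_sacc) <= 0))
})

test_that("direction classes follow the sign and sweep rules", {
  ## fixation, +2.5 deg saccade, fixation: both progressive
  vx <- c(rep(0, 10), 1.2, rep(2.5, 10))
  ev <- detect_events(make_recording(vx))
  expect_identical(ev$kind, c("fixation", "saccade", "fixation"))
  expect_identical(ev$direction, c("none", "progressive", "progressive"))

  ## -12 deg leftward movement becomes a sweep; the following fixation is
  ## progressive
  vx <- c(rep(12, 10), 8, 4, 1, rep(0.4, 10))
  ev <- detect_events(make_recording(vx))
  expect_identical(ev$kind, c("fixation", "sweep", "fixation"))
  expect_identical(ev$direction, c("none", "none", "progressive"))

  ## small leftward movement is regressive, inherited by the fixation
  vx <- c(rep(3, 10), 1.6, rep(1, 10))
  ev <- detect_events(make_recording(vx))
  expect_identical(ev$kind, c("fixation", "saccade", "fixation"))
  expect_identical(ev$direction, c("none", "regressive", "regressive"))

  ## alternating +2 deg saccades: every fixation progressive
  vx <- c(rep(0, 10), 1, rep(2, 10), 3, rep(4, 10), 5, rep(6, 10))
  ev <- detect_events(make_recording(vx))
  fx <- ev$direction[ev$kind == "fixation"]
  expect_identical(fx, c("none", rep("progressive", 3)))
})

test_that("a transient is a stable run too short to be a fixation", {
  ## 3-sample stable plateau between two movements
  vx <- c(rep(0, 10), 1.2, rep(2.5, 3), 3.7, rep(5, 10))
  ev <- segment_events(make_recording(vx))
  expect_identical(ev$kind,
                   c("fixation", "saccade", "transient", "saccade",
                     "fixation"))
})

test_that("distortions interrupt runs without merging across them", {
  vx <- rep(1, 30); valid <- rep(1L, 30); valid[15:16] <- 0L
  ev <- segment_events(make_recording(vx, valid = valid))
  expect_identical(ev$kind, c("fixation", "distortion", "fixation"))
  expect_identical(ev$start_idx, c(1L, 15L, 17L))
})
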