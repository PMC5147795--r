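## Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## a recording constructed directly from a version trajectory (both eyes
## identical, so version == the trajectory and vergence == 0)
make_recording <- function(vx, vy = rep(0, length(vx)), valid = 1L,
                           rate = 100, subject_id = "T1",
                           label = "unknown") {
  n <- length(vx)
  valid <- rep_len(valid, n)
  vx[valid == 0L] <- NA_real_; vy[valid == 0L] <- NA_real_
  structure(list(subject_id = subject_id, label = label,
                 sampling_rate = rate,
                 samples = data.frame(time_ms = (seq_len(n) - 1) * 1000 / rate,
                                      lx_deg = vx, ly_deg = vy,
                                      rx_deg = vx, ry_deg = vy,
                                      valid_l = valid, valid_r = valid)),
            class = "gaze_recording")
}

## noiseless group parameters (clean limit of the generator)
noiseless <- function(params) {
  params$measurement_noise_sd <- 0
  params$dropout_prob <- 0
  params$transient_rate <- 0
  params$vergence_noise_sd <- 0
  params
}

## gaze_events built directly (bypassing detection) for feature tests
make_events <- function(kind, direction, start_idx, end_idx, vx,
                        vy = rep(0, length(vx)), rate = 100) {
  rec <- make_recording(vx, vy, rate = rate)
  sig <- binocular_signals(rec)
  ev <- data.frame(kind = kind, direction = direction,
                   start_idx = start_idx, end_idx = end_idx,
                   start_ms = sig$time_ms[start_idx],
                   end_ms = sig$time_ms[end_idx],
                   stringsAsFactors = FALSE)
  gazescreen:::as_gaze_events(ev, rec, sig)
}

## two-class Gaussian feature set: `informative` columns shifted by
## `delta` in the HR group, the rest pure noise
gaussian_features <- function(n_hr, n_lr, p, informative, delta, seed) {
  set.seed(seed)
  x <- matrix(rnorm((n_hr + n_lr) * p), n_hr + n_lr, p)
  colnames(x) <- paste0("f", seq_len(p))
  x[seq_len(n_hr), informative] <- x[seq_len(n_hr), informative] + delta
  list(x = x, y = factor(rep(c("HR", "LR"), c(n_hr, n_lr))))
}

## small synthetic cohort feature matrix shared across files
small_cohort_features <- function() {
  fixture("small_cohort_features", function() {
    spec <- cohort_spec(n_hr = 14, n_lr = 14, seed = 301, duration_cap = 20)
    cohort_features(generate_cohort(spec))
  })
}
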