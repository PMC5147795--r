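#' Stimulus text layout
#'
#' Geometry of the reading stimulus, abstracted to lines of text on a page:
#' the lexical content is not modelled, only the horizontal extent of a line
#' and the vertical spacing between lines, in degrees of visual angle.
#' Coordinates: x increases rightward, y increases downward (lines progress
#' to larger y); the origin is at the start of the first line.
#'
#' Defaults describe a short passage of 10 sentences averaging 4.6 words,
#' set over 8 lines on a single page read at 45 cm (about 20 degrees of
#' horizontal extent and 1.5 degrees of line spacing).
#'
#' @param n_lines number of text lines (>= 1).
#' @param sentences number of sentences in the passage.
#' @param mean_sentence_len mean sentence length in words.
#' @param line_extent_deg horizontal extent of a line, degrees (> 0).
#' @param line_spacing_deg vertical spacing between lines, degrees (> 0).
#' @return an object of class `text_layout`.
#' @export
text_layout <- function(n_lines = 8, sentences = 10, mean_sentence_len = 4.6,
                        line_extent_deg = 20, line_spacing_deg = 1.5) {
  stopifnot(n_lines >= 1, line_extent_deg > 0, line_spacing_deg > 0,
            sentences >= 1, mean_sentence_len > 0)
  structure(list(n_lines = n_lines, sentences = sentences,
                 mean_sentence_len = mean_sentence_len,
                 line_extent_deg = line_extent_deg,
                 line_spacing_deg = line_spacing_deg),
            class = "text_layout")
}

#' Group-conditional gaze generation parameters
#'
#' Parameters of the generative reading model for one subject group.
#' Fixation durations are drawn from a log-normal with the given mean/SD
#' (ms); progressive saccade amplitudes from a gamma with the given mean/SD
#' (degrees, truncated below at 1 degree so every movement is resolvable at
#' a 0.5-degree dispersion threshold); a regression (leftward saccade of
#' about 60% the progressive amplitude) is taken with probability
#' `regression_prob` whenever there is room on the line. Vergence noise is
#' an AR(1) process applied antisymmetrically to the two eyes; measurement
#' noise is white and per-eye. `between_subject_cv` is the coefficient of
#' variation of multiplicative per-subject jitter applied to the duration
#' and amplitude means (and, on the logit scale, to `regression_prob`),
#' giving subjects within a group distinct oculomotor profiles.
#'
#' @param fixation_dur_mean,fixation_dur_sd fixation duration moments, ms.
#' @param prog_saccade_amp_mean,prog_saccade_amp_sd progressive saccade
#'   amplitude moments, degrees.
#' @param regression_prob probability of a regressive saccade, in `[0, 1]`.
#' @param vergence_noise_sd stationary SD of the AR(1) vergence offset,
#'   degrees.
#' @param measurement_noise_sd white per-eye measurement noise SD, degrees.
#' @param dropout_prob per-sample probability that both eyes' signal drops
#'   out (validity 0).
#' @param transient_rate rate of short high-amplitude signal artifacts,
#'   events per second.
#' @param between_subject_cv coefficient of variation of per-subject
#'   parameter jitter.
#' @return an object of class `group_gaze_params`.
#' @export
group_gaze_params <- function(fixation_dur_mean = 240, fixation_dur_sd = 60,
                              prog_saccade_amp_mean = 2.5,
                              prog_saccade_amp_sd = 0.85,
                              regression_prob = 0.25,
                              vergence_noise_sd = 0.15,
                              measurement_noise_sd = 0.05,
                              dropout_prob = 0.002,
                              transient_rate = 0.1,
                              between_subject_cv = 0.12) {
  p <- list(fixation_dur_mean = fixation_dur_mean,
            fixation_dur_sd = fixation_dur_sd,
            prog_saccade_amp_mean = prog_saccade_amp_mean,
            prog_saccade_amp_sd = prog_saccade_amp_sd,
            regression_prob = regression_prob,
            vergence_noise_sd = vergence_noise_sd,
            measurement_noise_sd = measurement_noise_sd,
            dropout_prob = dropout_prob,
            transient_rate = transient_rate,
            between_subject_cv = between_subject_cv)
  stopifnot(p$fixation_dur_mean > 0, p$fixation_dur_sd > 0,
            p$prog_saccade_amp_mean > 0, p$prog_saccade_amp_sd > 0,
            p$regression_prob >= 0, p$regression_prob <= 1,
            p$vergence_noise_sd >= 0, p$measurement_noise_sd >= 0,
            p$dropout_prob >= 0, p$dropout_prob <= 1,
            p$transient_rate >= 0, p$between_subject_cv >= 0)
  structure(p, class = "group_gaze_params")
}

#' @rdname group_gaze_params
#' @details `hr_gaze_params()` and `lr_gaze_params()` are the default
#'   parameter sets for the high-risk (HR) and low-risk (LR) reader groups:
#'   HR readers fixate longer (280 +/- 70 ms vs 210 +/- 50 ms), make
#'   shorter progressive saccades (2.0 +/- 0.8 vs 3.0 +/- 0.9 degrees),
#'   regress more often (0.35 vs 0.15) and show slightly noisier vergence.
#' @export
hr_gaze_params <- function(...) {
  do.call(group_gaze_params,
          utils::modifyList(list(fixation_dur_mean = 280, fixation_dur_sd = 70,
                                 prog_saccade_amp_mean = 2.0,
                                 prog_saccade_amp_sd = 0.8,
                                 regression_prob = 0.35,
                                 vergence_noise_sd = 0.20),
                            list(...)))
}

#' @rdname group_gaze_params
#' @param ... overrides of the group defaults.
#' @export
lr_gaze_params <- function(...) {
  do.call(group_gaze_params,
          utils::modifyList(list(fixation_dur_mean = 210, fixation_dur_sd = 50,
                                 prog_saccade_amp_mean = 3.0,
                                 prog_saccade_amp_sd = 0.9,
                                 regression_prob = 0.15,
                                 vergence_noise_sd = 0.15),
                            list(...)))
}

#' Synthetic cohort specification
#'
#' Generative parameters of a two-group (HR/LR) synthetic reading cohort.
#' Defaults mirror a screening study cohort of 97 high-risk and 88 low-risk
#' readers recorded at 100 Hz while silently reading an 8-line passage.
#'
#' @param n_hr,n_lr group sizes (`n_hr + n_lr >= 2`).
#' @param hr_params,lr_params [group_gaze_params()] for each group.
#' @param layout [text_layout()] of the stimulus.
#' @param sampling_rate sampling rate, Hz.
#' @param duration_cap soft cap on recording duration, seconds.
#' @param seed integer seed; per-subject seeds are derived from it with
#'   [child_seed()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hr = 97, n_lr = 88,
                        hr_params = hr_gaze_params(),
                        lr_params = lr_gaze_params(),
                        layout = text_layout(),
                        sampling_rate = 100, duration_cap = 60, seed = 1) {
  stopifnot(n_hr >= 0, n_lr >= 0, n_hr + n_lr >= 2,
            sampling_rate > 0, duration_cap > 0,
            inherits(hr_params, "group_gaze_params"),
            inherits(lr_params, "group_gaze_params"),
            inherits(layout, "text_layout"))
  structure(list(n_hr = n_hr, n_lr = n_lr, hr_params = hr_params,
                 lr_params = lr_params, layout = layout,
                 sampling_rate = sampling_rate, duration_cap = duration_cap,
                 seed = seed),
            class = "cohort_spec")
}

## gamma draw with target mean/sd, truncated below (clamped) at `lo`
rgamma_ms <- function(n, mean, sd, lo = 1) {
  shape <- (mean / sd)^2
  pmax(stats::rgamma(n, shape = shape, rate = mean / sd^2), lo)
}

rlnorm_ms <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

## AR(1) series with stationary SD `sd` and autocorrelation `phi`
ar1_series <- function(n, sd, phi = 0.95) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  e[1] <- stats::rnorm(1, 0, sd)
  stats::filter(e, phi, method = "recursive")[seq_len(n)]
}

## Fraction of the saccade vector at which each in-flight sample is
## rendered: a constant-velocity ramp of k interior samples that stops a
## fixed gap short of the landing point, so that every in-flight step on
## the dominant axis exceeds the detector's base dispersion threshold and
## the landing step falls below it.
saccade_ramp_fractions <- function(dx, dy, ramp_gap = 0.4, min_step = 0.55) {
  m <- max(abs(dx), abs(dy))
  stopifnot(m > ramp_gap + min_step - 1e-9)
  k <- max(1L, min(4L, as.integer(floor((m - ramp_gap) / min_step))))
  (seq_len(k) / k) * (1 - ramp_gap / m)
}

#' Simulate one binocular reading recording
#'
#' Generates a piecewise gaze trajectory over the text layout: fixations
#' (log-normal durations, rendered as constant position), progressive
#' saccades (gamma amplitudes, rightward), regressions (leftward, smaller)
#' and return sweeps at line ends (leftward by about a line extent, down by
#' one line spacing). Saccades are rendered over 1-4 in-flight samples with
#' a short deceleration gap before landing. Per-eye signals are the
#' cyclopean trajectory plus/minus half an AR(1) vergence offset (so the
#' version signal equals the cyclopean trajectory exactly), plus white
#' measurement noise; samples drop out (both eyes invalid) with
#' `dropout_prob`, and short high-amplitude transient artifacts are
#' injected at `transient_rate` per second. The ground-truth event list is
#' retained alongside the samples.
#'
#' @param params a [group_gaze_params()] object.
#' @param layout a [text_layout()] object.
#' @param sampling_rate sampling rate in Hz.
#' @param duration_cap soft cap on recording duration in seconds; the
#'   recording ends at the first fixation that reaches the cap.
#' @param seed integer seed (identical seed and parameters reproduce the
#'   recording bit for bit); `NULL` uses the current RNG stream.
#' @param subject_id,label metadata carried on the recording.
#' @return an object of class `gaze_recording`: a list with `subject_id`,
#'   `label`, `sampling_rate` and `samples` (a data frame with columns
#'   `time_ms, lx_deg, ly_deg, rx_deg, ry_deg, valid_l, valid_r`), with the
#'   ground-truth events in `attr(, "ground_truth")` (columns `kind`,
#'   `direction`, `start_idx`, `end_idx`; indices 1-based and inclusive,
#'   tiling the samples) and injected artifact spans in
#'   `attr(, "artifacts")`.
#' @export
simulate_recording <- function(params, layout = text_layout(),
                               sampling_rate = 100, duration_cap = 60,
                               seed = NULL, subject_id = "S1",
                               label = "unknown") {
  stopifnot(inherits(params, "group_gaze_params"),
            inherits(layout, "text_layout"),
            sampling_rate > 0, duration_cap > 0)
  with_seed(seed, {
    dt <- 1000 / sampling_rate
    cap_n <- duration_cap * sampling_rate
    px <- list(); py <- list()
    kind <- character(0); dir <- character(0); seg_n <- integer(0)
    x <- 0; y <- 0; line <- 1L
    dir_prev <- "none"
    total_n <- 0L
    clipped <- 0L
    repeat {
      ## fixation at (x, y)
      n_f <- max(6L, as.integer(round(rlnorm_ms(1, params$fixation_dur_mean,
                                                params$fixation_dur_sd) / dt)))
      px[[length(px) + 1L]] <- rep(x, n_f)
      py[[length(py) + 1L]] <- rep(y, n_f)
      kind <- c(kind, "fixation"); dir <- c(dir, dir_prev)
      seg_n <- c(seg_n, n_f)
      total_n <- total_n + n_f
      if (total_n >= cap_n) break
      ## next movement
      regress <- stats::runif(1) < params$regression_prob && x >= 2
      if (regress) {
        amp <- min(rgamma_ms(1, 0.6 * params$prog_saccade_amp_mean,
                             0.6 * params$prog_saccade_amp_sd), x)
        tx <- x - amp; ty <- y; k_kind <- "saccade"; k_dir <- "regressive"
      } else {
        amp <- rgamma_ms(1, params$prog_saccade_amp_mean,
                         params$prog_saccade_amp_sd)
        if (x + amp > layout$line_extent_deg) {
          if (line == layout$n_lines) break
          tx <- 0; ty <- y + layout$line_spacing_deg
          k_kind <- "sweep"; k_dir <- "none"
          line <- line + 1L
        } else {
          tx <- x + amp; ty <- y; k_kind <- "saccade"; k_dir <- "progressive"
        }
      }
      if (tx < 0 || tx > layout$line_extent_deg) {
        clipped <- clipped + 1L
        tx <- min(max(tx, 0), layout$line_extent_deg)
      }
      fr <- saccade_ramp_fractions(tx - x, ty - y)
      px[[length(px) + 1L]] <- x + fr * (tx - x)
      py[[length(py) + 1L]] <- y + fr * (ty - y)
      kind <- c(kind, k_kind); dir <- c(dir, k_dir)
      seg_n <- c(seg_n, length(fr))
      total_n <- total_n + length(fr)
      x <- tx; y <- ty
      dir_prev <- if (k_kind == "sweep") "progressive" else k_dir
    }
    cx <- unlist(px); cy <- unlist(py)
    n <- length(cx)
    end_idx <- cumsum(seg_n)
    gt <- data.frame(kind = kind, direction = dir,
                     start_idx = c(1L, utils::head(end_idx, -1) + 1L),
                     end_idx = end_idx, stringsAsFactors = FALSE)

    ## binocular rendering: version == cyclopean by construction
    vgx <- ar1_series(n, params$vergence_noise_sd)
    vgy <- ar1_series(n, params$vergence_noise_sd)
    ms <- params$measurement_noise_sd
    noise <- function() if (ms > 0) stats::rnorm(n, 0, ms) else numeric(n)
    lx <- cx + vgx / 2 + noise(); rx <- cx - vgx / 2 + noise()
    ly <- cy + vgy / 2 + noise(); ry <- cy - vgy / 2 + noise()

    ## transient artifacts: short common-mode excursions of both eyes
    dur_s <- n / sampling_rate
    n_tr <- if (params$transient_rate > 0)
      stats::rpois(1, params$transient_rate * dur_s) else 0L
    artifacts <- data.frame(start_idx = integer(0), end_idx = integer(0),
                            offset_deg = numeric(0))
    if (n_tr > 0) {
      for (i in seq_len(n_tr)) {
        s <- sample.int(n, 1)
        e <- min(n, s + sample(0:1, 1))
        off <- sample(c(-1, 1), 1) * stats::runif(1, 2, 5)
        lx[s:e] <- lx[s:e] + off
        rx[s:e] <- rx[s:e] + off
        artifacts <- rbind(artifacts,
                           data.frame(start_idx = s, end_idx = e,
                                      offset_deg = off))
      }
    }

    valid <- rep(1L, n)
    if (params$dropout_prob > 0)
      valid[stats::runif(n) < params$dropout_prob] <- 0L
    lx[valid == 0L] <- NA_real_; ly[valid == 0L] <- NA_real_
    rx[valid == 0L] <- NA_real_; ry[valid == 0L] <- NA_real_

    samples <- data.frame(time_ms = (seq_len(n) - 1) * dt,
                          lx_deg = lx, ly_deg = ly,
                          rx_deg = rx, ry_deg = ry,
                          valid_l = valid, valid_r = valid)
    rec <- structure(list(subject_id = subject_id, label = label,
                          sampling_rate = sampling_rate, samples = samples),
                     class = "gaze_recording")
    attr(rec, "ground_truth") <- gt
    attr(rec, "artifacts") <- artifacts
    attr(rec, "n_clipped") <- clipped
    rec
  })
}

## per-subject parameter jitter (uses current RNG stream)
jitter_params <- function(params) {
  cv <- params$between_subject_cv
  if (cv <= 0) return(params)
  f1 <- exp(stats::rnorm(1, -cv^2 / 2, cv))
  f2 <- exp(stats::rnorm(1, -cv^2 / 2, cv))
  params$fixation_dur_mean <- params$fixation_dur_mean * f1
  params$fixation_dur_sd <- params$fixation_dur_sd * f1
  params$prog_saccade_amp_mean <- params$prog_saccade_amp_mean * f2
  params$prog_saccade_amp_sd <- params$prog_saccade_amp_sd * f2
  p <- params$regression_prob
  if (p > 0 && p < 1)
    params$regression_prob <- stats::plogis(stats::qlogis(p) +
                                              stats::rnorm(1, 0, 0.25))
  params
}

#' Generate a labelled synthetic cohort
#'
#' Simulates `n_hr` recordings under the HR parameters and `n_lr` under the
#' LR parameters. Each subject gets two child seeds derived
#' deterministically from `spec$seed` (one for between-subject parameter
#' jitter, one for the recording), so any single subject can be regenerated
#' in isolation.
#'
#' @param spec a [cohort_spec()] object.
#' @return an object of class `gaze_cohort`: list with `recordings` (a list
#'   of [simulate_recording()] outputs, HR subjects first) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_hr + spec$n_lr
  labels <- c(rep("HR", spec$n_hr), rep("LR", spec$n_lr))
  ids <- sprintf("%s%03d", labels, c(seq_len(spec$n_hr), seq_len(spec$n_lr)))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (labels[i] == "HR") spec$hr_params else spec$lr_params
    p_i <- with_seed(child_seed(spec$seed, 2 * i), jitter_params(base))
    recs[[i]] <- simulate_recording(p_i, spec$layout, spec$sampling_rate,
                                    spec$duration_cap,
                                    seed = child_seed(spec$seed, 2 * i + 1),
                                    subject_id = ids[i], label = labels[i])
  }
  structure(list(recordings = recs, spec = spec), class = "gaze_cohort")
}

#' @export
print.gaze_recording <- function(x, ...) {
  gt <- attr(x, "ground_truth")
  cat(sprintf("Gaze recording '%s' (%s): %d samples at %g Hz (%.1f s)\n",
              x$subject_id, x$label, nrow(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  if (!is.null(gt))
    cat("  ground truth:",
        paste(sprintf("%d %s", table(gt$kind)[unique(gt$kind)],
                      unique(gt$kind)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gaze_cohort <- function(x, ...) {
  labs <- vapply(x$recordings, `[[`, "", "label")
  cat(sprintf("Synthetic gaze cohort: %d subjects (%d HR, %d LR), seed %s\n",
              length(labs), sum(labs == "HR"), sum(labs == "LR"),
              format(x$spec$seed)))
  invisible(x)
}

#' Subject labels of a cohort
#' @param cohort a `gaze_cohort` object.
#' @return character vector of HR/LR labels, one per recording.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$recordings, `[[`, "", "label")
}
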