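#' Detector configuration
#'
#' Parameters of the dynamic dispersion-threshold state machine. The
#' stability threshold at any moment is
#' `dispersion_base + noise_multiplier * rms_noise`, where the RMS noise is
#' estimated over the last `noise_window` samples of the current stable
#' run (and held at the last stable run's value while a saccade is in
#' flight). A stable run is promoted from transient to fixation once its
#' inclusive time span reaches `min_fixation` ms (6 samples at 100 Hz).
#' Leftward saccades of at least `sweep_min_amplitude` degrees are
#' classified as sweeps (most commonly return sweeps) by
#' [classify_directions()].
#'
#' @param dispersion_base base dispersion threshold, degrees.
#' @param noise_multiplier multiplier on the RMS noise estimate.
#' @param noise_window noise estimation window, samples.
#' @param min_fixation minimum fixation span, ms.
#' @param sweep_min_amplitude minimum leftward amplitude for a sweep,
#'   degrees.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(dispersion_base = 0.5, noise_multiplier = 2.5,
                            noise_window = 25, min_fixation = 50,
                            sweep_min_amplitude = 5) {
  stopifnot(dispersion_base > 0, noise_multiplier > 0, noise_window > 0,
            min_fixation > 0, sweep_min_amplitude > 0)
  structure(list(dispersion_base = dispersion_base,
                 noise_multiplier = noise_multiplier,
                 noise_window = as.integer(noise_window),
                 min_fixation = min_fixation,
                 sweep_min_amplitude = sweep_min_amplitude),
            class = "detector_config")
}

#' Version and vergence signals of a binocular recording
#'
#' Decomposes the two eyes' positions into the conjugate (version) and
#' disconjugate (vergence) components per axis: version = (left + right)/2,
#' vergence = left - right. Samples where either eye is invalid are
#' unusable in all four series (`NA`).
#'
#' @param rec a `gaze_recording`.
#' @return a list with numeric per-sample series `version_x`, `version_y`,
#'   `vergence_x`, `vergence_y`, logical `usable`, and the sample times
#'   `time_ms`.
#' @export
binocular_signals <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  usable <- s$valid_l == 1L & s$valid_r == 1L &
    !is.na(s$lx_deg) & !is.na(s$rx_deg) &
    !is.na(s$ly_deg) & !is.na(s$ry_deg)
  mask <- function(v) { v[!usable] <- NA_real_; v }
  list(version_x = mask((s$lx_deg + s$rx_deg) / 2),
       version_y = mask((s$ly_deg + s$ry_deg) / 2),
       vergence_x = mask(s$lx_deg - s$rx_deg),
       vergence_y = mask(s$ly_deg - s$ry_deg),
       usable = usable,
       time_ms = s$time_ms)
}

#' RMS noise of a position series
#'
#' Root-mean-square deviation of the last `window` usable samples (ending
#' at `idx`, inclusive) from their mean. If fewer than `window` usable
#' samples are available the available ones are used; with fewer than two,
#' the estimate is 0.
#'
#' @param series numeric position series (`NA` marks unusable samples).
#' @param idx sample index at which the window ends (1-based).
#' @param window window length in samples.
#' @return RMS deviation in the units of `series`.
#' @export
rms_noise <- function(series, idx, window = 25) {
  stopifnot(idx >= 1, idx <= length(series), window >= 1)
  v <- series[seq_len(idx)]
  v <- v[!is.na(v)]
  if (length(v) > window) v <- v[(length(v) - window + 1):length(v)]
  if (length(v) < 2) return(0)
  sqrt(mean((v - mean(v))^2))
}

#' Segment a recording into events with the dispersion-threshold state
#' machine
#'
#' Runs the four-state machine (distortion, transient, fixation, saccade)
#' sample by sample over the version signal. A sample with the binocular
#' signal missing is a distortion; a usable sample whose horizontal and
#' vertical version positions are both within the dynamic threshold of the
#' running mean of the current stable run extends that run, which is
#' promoted from transient to fixation once it spans `min_fixation` ms; a
#' sample beyond the threshold on either axis opens or continues a
#' saccade. While a saccade is in flight the threshold is held at the last
#' stable run's value and each sample is compared to the saccade's most
#' recent position, so the first sample that lands within threshold of the
#' previous one closes the saccade and starts a new stable run. On every
#' state change the previous run is emitted as one event; a sample exactly
#' at threshold distance counts as within.
#'
#' @param rec a `gaze_recording`.
#' @param cfg a [detector_config()].
#' @return an object of class `gaze_events`: a data frame with columns
#'   `kind` (fixation/saccade/transient/distortion), `direction` (filled by
#'   [classify_directions()]), `start_idx`, `end_idx` (1-based, inclusive,
#'   tiling the recording), `start_ms`, `end_ms`; the binocular signals are
#'   attached as `attr(, "signals")`.
#' @export
segment_events <- function(rec, cfg = detector_config()) {
  stopifnot(inherits(rec, "gaze_recording"))
  sig <- binocular_signals(rec)
  n <- length(sig$usable)
  t <- sig$time_ms
  if (n < 2 || (t[n] - t[1]) < cfg$min_fixation) {
    warning("recording shorter than the minimum fixation span; no events")
    return(empty_events(rec, sig))
  }
  vx <- sig$version_x; vy <- sig$version_y; us <- sig$usable
  ## cumulative sums (NA as 0; windows never span unusable samples)
  zx <- ifelse(us, vx, 0); zy <- ifelse(us, vy, 0)
  cs_x <- c(0, cumsum(zx)); cs_x2 <- c(0, cumsum(zx^2))
  cs_y <- c(0, cumsum(zy)); cs_y2 <- c(0, cumsum(zy^2))
  w <- cfg$noise_window
  run_rms <- function(cs, cs2, a, b) {
    a <- max(a, b - w + 1L)
    nw <- b - a + 1L
    if (nw < 2L) return(0)
    s1 <- cs[b + 1L] - cs[a]
    s2 <- cs2[b + 1L] - cs2[a]
    sqrt(max(s2 / nw - (s1 / nw)^2, 0))
  }

  kind_out <- character(0); s_out <- integer(0); e_out <- integer(0)
  emit <- function(state, s, e) {
    k <- switch(state,
                distortion = "distortion",
                saccade = "saccade",
                stable = if ((t[e] - t[s]) >= cfg$min_fixation) "fixation"
                         else "transient")
    kind_out[[length(kind_out) + 1L]] <<- k
    s_out[[length(s_out) + 1L]] <<- s
    e_out[[length(e_out) + 1L]] <<- e
  }

  base <- cfg$dispersion_base; mult <- cfg$noise_multiplier
  state <- if (us[1]) "stable" else "distortion"
  run_start <- 1L
  sum_x <- if (us[1]) vx[1] else 0; sum_y <- if (us[1]) vy[1] else 0
  n_run <- 1L
  tf_x <- base; tf_y <- base  # frozen thresholds while in saccade

  for (i in 2:n) {
    if (!us[i]) {
      if (state != "distortion") {
        if (state == "stable") {
          tf_x <- base + mult * run_rms(cs_x, cs_x2, run_start, i - 1L)
          tf_y <- base + mult * run_rms(cs_y, cs_y2, run_start, i - 1L)
        }
        emit(state, run_start, i - 1L)
        state <- "distortion"; run_start <- i
      }
      next
    }
    if (state == "distortion") {
      emit(state, run_start, i - 1L)
      state <- "stable"; run_start <- i
      sum_x <- vx[i]; sum_y <- vy[i]; n_run <- 1L
    } else if (state == "stable") {
      T_x <- base + mult * run_rms(cs_x, cs_x2, run_start, i - 1L)
      T_y <- base + mult * run_rms(cs_y, cs_y2, run_start, i - 1L)
      if (abs(vx[i] - sum_x / n_run) <= T_x &&
          abs(vy[i] - sum_y / n_run) <= T_y) {
        sum_x <- sum_x + vx[i]; sum_y <- sum_y + vy[i]; n_run <- n_run + 1L
      } else {
        emit(state, run_start, i - 1L)
        tf_x <- T_x; tf_y <- T_y
        state <- "saccade"; run_start <- i
      }
    } else {  # saccade in flight
      if (abs(vx[i] - vx[i - 1L]) <= tf_x &&
          abs(vy[i] - vy[i - 1L]) <= tf_y) {
        emit(state, run_start, i - 1L)
        state <- "stable"; run_start <- i
        sum_x <- vx[i]; sum_y <- vy[i]; n_run <- 1L
      }
    }
  }
  emit(state, run_start, n)

  ev <- data.frame(kind = kind_out, direction = "none",
                   start_idx = s_out, end_idx = e_out,
                   start_ms = t[s_out], end_ms = t[e_out],
                   stringsAsFactors = FALSE)
  as_gaze_events(ev, rec, sig)
}

empty_events <- function(rec, sig) {
  ev <- data.frame(kind = character(0), direction = character(0),
                   start_idx = integer(0), end_idx = integer(0),
                   start_ms = numeric(0), end_ms = numeric(0),
                   stringsAsFactors = FALSE)
  as_gaze_events(ev, rec, sig)
}

as_gaze_events <- function(ev, rec, sig) {
  structure(ev, class = c("gaze_events", "data.frame"),
            signals = sig, subject_id = rec$subject_id,
            label = rec$label, sampling_rate = rec$sampling_rate)
}

#' Assign progressive/regressive direction classes
#'
#' Saccades with positive horizontal version displacement are progressive
#' (left-to-right); negative, regressive -- except leftward saccades of at
#' least `sweep_min_amplitude` degrees, which become sweeps with no
#' direction. Displacement is measured from the last usable position
#' before the movement began (the preceding stable sample, falling back to
#' the event's first sample at the start of a recording) to the movement's
#' final sample, so that single-sample saccades carry their true
#' direction. Each fixation inherits the direction of the nearest
#' preceding saccade; fixations preceded by a sweep are progressive (the
#' eyes resume forward reading at the new line); fixations with no
#' preceding saccade or sweep keep direction `none` and are excluded from
#' the directional feature pools. Transients and distortions carry no
#' direction.
#'
#' @param events a `gaze_events` object from [segment_events()].
#' @param cfg a [detector_config()] (only `sweep_min_amplitude` is used).
#' @return the event list with `kind` and `direction` updated.
#' @export
classify_directions <- function(events, cfg = detector_config()) {
  stopifnot(inherits(events, "gaze_events"))
  sig <- attr(events, "signals")
  vx <- sig$version_x
  last_dir <- "none"
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k == "saccade") {
      from <- events$start_idx[i] - 1L
      while (from >= 1L && is.na(vx[from])) from <- from - 1L
      if (from < 1L) from <- events$start_idx[i]
      disp <- vx[events$end_idx[i]] - vx[from]
      if (disp > 0) {
        events$direction[i] <- "progressive"; last_dir <- "progressive"
      } else if (disp < 0 && -disp >= cfg$sweep_min_amplitude) {
        events$kind[i] <- "sweep"; events$direction[i] <- "none"
        last_dir <- "progressive"
      } else if (disp < 0) {
        events$direction[i] <- "regressive"; last_dir <- "regressive"
      } else {
        events$direction[i] <- "none"
      }
    } else if (k == "fixation") {
      events$direction[i] <- last_dir
    }
  }
  events
}

#' Detect and classify eye-movement events
#'
#' Convenience wrapper: [segment_events()] followed by
#' [classify_directions()].
#'
#' @inheritParams segment_events
#' @return a `gaze_events` object with direction classes assigned.
#' @export
detect_events <- function(rec, cfg = detector_config()) {
  classify_directions(segment_events(rec, cfg), cfg)
}

#' @export
print.gaze_events <- function(x, ...) {
  cat(sprintf("Gaze events for '%s' (%s): %d events\n",
              attr(x, "subject_id"), attr(x, "label"), nrow(x)))
  if (nrow(x)) print(table(kind = x$kind, direction = x$direction))
  invisible(x)
}

#' @export
summary.gaze_events <- function(object, ...) {
  dur <- object$end_ms - object$start_ms
  out <- stats::aggregate(dur, list(kind = object$kind), function(d)
    c(n = length(d), mean_ms = mean(d), total_ms = sum(d)))
  cat(sprintf("Event summary for '%s':\n", attr(object, "subject_id")))
  print(do.call(data.frame, out))
  invisible(out)
}

#' Debug plot of a segmented recording
#'
#' Horizontal and vertical version signal over time with events shaded by
#' kind (fixation grey, saccade green, sweep blue, transient red,
#' distortion dark grey).
#'
#' @param x a `gaze_events` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gaze_events <- function(x, ...) {
  sig <- attr(x, "signals")
  cols <- c(fixation = "grey85", saccade = "palegreen", sweep = "lightblue",
            transient = "lightcoral", distortion = "grey40")
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (axis in c("version_x", "version_y")) {
    graphics::plot(sig$time_ms, sig[[axis]], type = "n",
                   xlab = "time (ms)", ylab = paste(axis, "(deg)"), ...)
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(x)))
      graphics::rect(x$start_ms[i], usr[3], x$end_ms[i], usr[4],
                     col = cols[[x$kind[i]]], border = NA)
    graphics::lines(sig$time_ms, sig[[axis]])
  }
  invisible(x)
}
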