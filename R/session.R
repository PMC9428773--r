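# Paced-breathing session machinery: BPM-scaled guidance pattern,
# biofeedback (sailboat) dynamics, session trace and score.

#' BPM-scaled breathing pattern
#'
#' Patterns follow inhalation - pause - exhalation - pause. The base
#' pattern is 4-1-5-0 at 6 breaths per minute; for other rates the
#' pauses stay fixed at (1, 0) s and the remaining `60/bpm - 1` seconds
#' are split 4:5 between inhalation and exhalation. This is the unique
#' linear scaling consistent with the published 6 BPM (4-1-5-0) and
#' 7 BPM (3.37-1-4.21-0) patterns.
#'
#' @param bpm breaths per minute; must satisfy `60/bpm > 1` so the
#'   1-second pause fits.
#' @return A `breathing_pattern` with `inhale_s`, `pause1_s`,
#'   `exhale_s`, `pause2_s`, `bpm`.
#' @export
pattern_for_bpm <- function(bpm) {
  stopifnot(bpm > 0)
  cycle <- 60 / bpm
  if (cycle <= 1) {
    stop("pattern_for_bpm: cycle must exceed the 1 s pause (need bpm < 60)",
         call. = FALSE)
  }
  rest <- cycle - 1
  structure(list(inhale_s = rest * 4 / 9, pause1_s = 1,
                 exhale_s = rest * 5 / 9, pause2_s = 0, bpm = bpm),
            class = "breathing_pattern")
}

#' @export
print.breathing_pattern <- function(x, ...) {
  cat(sprintf("<breathing_pattern %g BPM: %.2f-%g-%.2f-%g s>\n",
              x$bpm, x$inhale_s, x$pause1_s, x$exhale_s, x$pause2_s))
  invisible(x)
}

#' Guided phase at time t
#'
#' Reduces t modulo the cycle length and maps it onto the
#' inhalation/pause/exhalation/pause intervals.
#'
#' @param pattern a [pattern_for_bpm()] result.
#' @param t time(s) in seconds, >= 0.
#' @param collapse_pauses if TRUE (default) pauses are reported as
#'   `"nonbreathing"` for comparison with detector output; otherwise
#'   `"pause"`.
#' @return Character vector of guided phases.
#' @export
guided_phase <- function(pattern, t, collapse_pauses = TRUE) {
  stopifnot(inherits(pattern, "breathing_pattern"), all(t >= 0))
  cycle <- with(pattern, inhale_s + pause1_s + exhale_s + pause2_s)
  tm <- t %% cycle
  cuts <- cumsum(c(pattern$inhale_s, pattern$pause1_s, pattern$exhale_s))
  pause_lab <- if (collapse_pauses) "nonbreathing" else "pause"
  ifelse(tm < cuts[1], "inhalation",
         ifelse(tm < cuts[2], pause_lab,
                ifelse(tm < cuts[3], "exhalation", pause_lab)))
}

#' Session configuration
#'
#' Duration presets mirror the 2 (beginner), 3 (intermediate) and
#' 5 (expert) minute training levels. Boat dynamics constants are
#' qualitative design parameters of the feedback loop (units/s): the
#' boat accelerates during correctly detected guided exhalations and
#' otherwise relaxes exponentially to its base speed.
#'
#' @param duration_s session length in seconds (default 180).
#' @param bpm guidance rate (default 6).
#' @param base_speed,accel,max_speed,decay_rate boat dynamics constants.
#' @param tick_hz simulation tick rate (default 30).
#' @return A `session_config` list.
#' @export
session_config <- function(duration_s = 180, bpm = 6, base_speed = 1,
                           accel = 2, max_speed = 4, decay_rate = 1,
                           tick_hz = 30) {
  stopifnot(duration_s > 0, bpm > 0, tick_hz > 0, max_speed >= base_speed)
  structure(list(duration_s = duration_s, bpm = bpm, base_speed = base_speed,
                 accel = accel, max_speed = max_speed,
                 decay_rate = decay_rate, tick_hz = tick_hz),
            class = "session_config")
}

#' One Euler step of the boat speed dynamics
#'
#' During a guided exhalation that the detector also calls exhalation
#' the boat accelerates linearly (clamped at `max_speed`); otherwise the
#' speed decays exponentially toward `base_speed`.
#'
#' @param speed current speed.
#' @param guided guided phase at this tick.
#' @param detected detected (smoothed) phase at this tick.
#' @param dt tick length in seconds, > 0.
#' @param cfg a [session_config()].
#' @return Updated speed.
#' @export
feedback_step <- function(speed, guided, detected, dt, cfg = session_config()) {
  stopifnot(dt > 0)
  if (guided == "exhalation" && detected == "exhalation") {
    min(speed + cfg$accel * dt, cfg$max_speed)
  } else {
    cfg$base_speed + (speed - cfg$base_speed) * exp(-cfg$decay_rate * dt)
  }
}

#' Run a paced-breathing session against a detected phase stream
#'
#' Folds [feedback_step()] over the session at `tick_hz`, applying the
#' exhalation-hold heuristic to the raw detections, and scores the
#' session: `distance` is the Euler integral of the speed and
#' `exhalation_accuracy` is the fraction of guided-exhalation ticks the
#' (smoothed) detector also called exhalation — the guided-exhalation
#' coverage.
#'
#' @param times,raw tick times and raw detected phases covering the
#'   session (times strictly increasing).
#' @param cfg a [session_config()].
#' @param use_heuristic apply the exhalation hold (default TRUE).
#' @param heuristic_cfg a [heuristic_config()].
#' @return List with `trace` (data.frame: t, guided, raw, smoothed,
#'   speed, distance) and `score` (`distance`, `exhalation_accuracy`).
#' @export
run_session <- function(times, raw, cfg = session_config(),
                        use_heuristic = TRUE,
                        heuristic_cfg = heuristic_config()) {
  if (length(times) == 0L) stop("run_session: empty detection stream", call. = FALSE)
  stopifnot(length(times) == length(raw))
  keep <- times <= cfg$duration_s
  times <- times[keep]; raw <- as.character(raw)[keep]
  pattern <- pattern_for_bpm(cfg$bpm)
  guided <- guided_phase(pattern, times)
  smoothed <- if (use_heuristic) apply_heuristic(times, raw, heuristic_cfg) else raw
  n <- length(times)
  dt <- diff(c(0, times))
  speed <- numeric(n); dist <- numeric(n)
  s <- cfg$base_speed; d <- 0
  for (i in seq_len(n)) {
    s <- feedback_step(s, guided[i], smoothed[i], dt[i], cfg)
    d <- d + s * dt[i]
    speed[i] <- s; dist[i] <- d
  }
  exh_ticks <- guided == "exhalation"
  acc <- if (any(exh_ticks)) mean(smoothed[exh_ticks] == "exhalation") else NA_real_
  list(trace = data.frame(t = times, guided = guided, raw = raw,
                          smoothed = smoothed, speed = speed,
                          distance = dist),
       score = list(distance = d, exhalation_accuracy = acc))
}
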