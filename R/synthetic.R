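# Seeded synthetic breathing audio. The archetypes are deliberately
# exaggerated spectrally (relative to real breathing) so that they are
# separable by construction: the generator exists to verify the
# pipeline, not to model psychoacoustics.

# All randomness flows from one config seed through this derivation
# scheme: stream k of seed s uses set.seed((s * 10007 + k) mod (2^31-1)).
.derived_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k) %% (2^31 - 1))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Synthetic session configuration
#'
#' Defaults mirror the study conditions: 3-minute sessions at 6 breaths
#' per minute, and an acoustic/airflow exhalation mix matching the
#' training-data composition (airflow share 418/(4574+418) ~ 8.4%).
#' Amplitudes are RMS targets for each sound class.
#'
#' @param duration_s session length (default 180).
#' @param bpm guidance rate (default 6).
#' @param airflow_prob probability an exhalation is the airflow subtype.
#' @param amp_inhalation,amp_exhalation_acoustic,amp_exhalation_airflow
#'   RMS amplitudes of the breathing archetypes.
#' @param amp_ambient ambient noise RMS during pauses and under all
#'   segments.
#' @param amp_event RMS of inserted nonbreathing events.
#' @param event_prob probability a pause of at least 0.4 s receives a
#'   nonbreathing event (tone/chirp/burst).
#' @param jitter_sd Gaussian SD of phase-boundary jitter in seconds.
#' @param seed integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 180, bpm = 6, airflow_prob = 0.084,
                         amp_inhalation = 0.05,
                         amp_exhalation_acoustic = 0.15,
                         amp_exhalation_airflow = 0.4,
                         amp_ambient = 0.002, amp_event = 0.1,
                         event_prob = 0.3, jitter_sd = 0.05, seed = 1L) {
  stopifnot(airflow_prob >= 0, airflow_prob <= 1, event_prob >= 0,
            event_prob <= 1, duration_s > 0, bpm > 0, jitter_sd >= 0)
  structure(list(duration_s = duration_s, bpm = bpm,
                 airflow_prob = airflow_prob,
                 amp_inhalation = amp_inhalation,
                 amp_exhalation_acoustic = amp_exhalation_acoustic,
                 amp_exhalation_airflow = amp_exhalation_airflow,
                 amp_ambient = amp_ambient, amp_event = amp_event,
                 event_prob = event_prob, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.butter_cache <- new.env(parent = emptyenv())
.butter <- function(type, cutoffs) {
  key <- paste(type, paste(cutoffs, collapse = "-"))
  if (is.null(.butter_cache[[key]])) {
    .butter_cache[[key]] <- signal::butter(4, cutoffs / (TARGET_RATE / 2), type)
  }
  .butter_cache[[key]]
}

.rms_scale <- function(x, target_rms) {
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x * (target_rms / r)
}

# Archetype generators (consume the current RNG stream)
.gen_inhalation <- function(n, amp) {
  filt <- .butter("pass", c(300, 2000))
  .rms_scale(as.numeric(signal::filter(filt, stats::rnorm(n))), amp)
}

.gen_exh_acoustic <- function(n, amp) {
  filt <- .butter("pass", c(100, 6000))
  x <- as.numeric(signal::filter(filt, stats::rnorm(n)))
  ramp <- max(1L, min(n %/% 5L, round(0.1 * TARGET_RATE)))
  env <- rep(1, n)
  env[seq_len(ramp)] <- (1 - cos(pi * seq_len(ramp) / ramp)) / 2
  env[n + 1 - seq_len(ramp)] <- env[seq_len(ramp)]
  .rms_scale(x * env, amp)
}

.gen_exh_airflow <- function(n, amp) {
  filt <- .butter("low", 250)
  .rms_scale(as.numeric(signal::filter(filt, stats::rnorm(n))), amp)
}

.gen_event <- function(n, amp) {
  kind <- sample(c("tone", "chirp", "burst"), 1)
  t <- (seq_len(n) - 1) / TARGET_RATE
  x <- switch(kind,
    tone = sin(2 * pi * stats::runif(1, 500, 4000) * t),
    chirp = {
      f0 <- stats::runif(1, 300, 1500); f1 <- stats::runif(1, 2000, 6000)
      sin(2 * pi * (f0 * t + (f1 - f0) / (2 * max(t[n], 1e-9)) * t^2))
    },
    burst = stats::rnorm(n) * exp(-t / 0.05))
  .rms_scale(x, amp)
}

#' Generate a seeded synthetic breathing session
#'
#' Breathing cycles follow [pattern_for_bpm()] with Gaussian jitter on
#' the phase durations. Inhalations are quiet 300-2000 Hz noise;
#' acoustic exhalations louder 100-6000 Hz noise with an onset/offset
#' envelope; airflow exhalations high-amplitude low-passed (<250 Hz)
#' noise with >= 80% of spectral energy below 500 Hz; pauses carry only
#' ambient noise, optionally with a short nonbreathing event (tone,
#' chirp or noise burst). The ground-truth track records every segment
#' with subtype labels.
#'
#' @param cfg a [synth_config()].
#' @return List with `clip` (an `audio_clip` at 16 kHz), `track`
#'   (a `label_track`) and `config`.
#' @export
synth_session <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  pattern <- pattern_for_bpm(cfg$bpm)
  cycle_s <- 60 / cfg$bpm
  if (cfg$duration_s < cycle_s) {
    stop("synth_session: duration must cover at least one breathing cycle",
         call. = FALSE)
  }
  .with_seed(.derived_seed(cfg$seed, 1L), {
    n_total <- round(cfg$duration_s * TARGET_RATE)
    samples <- stats::rnorm(n_total) * cfg$amp_ambient
    starts <- numeric(0); ends <- numeric(0); labs <- character(0)
    t <- 0
    while (t < cfg$duration_s - 1e-9) {
      durs <- c(pattern$inhale_s, pattern$pause1_s, pattern$exhale_s,
                pattern$pause2_s)
      if (cfg$jitter_sd > 0) {
        j <- stats::rnorm(4, 0, cfg$jitter_sd)
        durs <- pmax(ifelse(durs > 0, 0.1, 0), durs + ifelse(durs > 0, j, 0))
      }
      subtype <- if (stats::runif(1) < cfg$airflow_prob) "airflow" else "acoustic"
      segs <- list(
        list(lab = "inhalation", dur = durs[1]),
        list(lab = "nonbreathing", dur = durs[2]),
        list(lab = paste0("exhalation_", subtype), dur = durs[3]),
        list(lab = "nonbreathing", dur = durs[4])
      )
      for (sg in segs) {
        if (sg$dur <= 0) next
        s0 <- t; s1 <- min(t + sg$dur, cfg$duration_s)
        i0 <- floor(s0 * TARGET_RATE) + 1L
        i1 <- min(floor(s1 * TARGET_RATE), n_total)
        n <- i1 - i0 + 1L
        if (n > 0) {
          x <- switch(sg$lab,
            inhalation = .gen_inhalation(n, cfg$amp_inhalation),
            exhalation_acoustic = .gen_exh_acoustic(n, cfg$amp_exhalation_acoustic),
            exhalation_airflow = .gen_exh_airflow(n, cfg$amp_exhalation_airflow),
            nonbreathing = {
              ev <- NULL
              if (sg$dur >= 0.4 && stats::runif(1) < cfg$event_prob) {
                n_ev <- min(n, round(stats::runif(1, 0.2, 0.9) * n))
                ev <- .gen_event(n_ev, cfg$amp_event)
              }
              base <- numeric(n)
              if (!is.null(ev)) {
                off <- sample.int(n - length(ev) + 1L, 1L) - 1L
                base[off + seq_along(ev)] <- ev
              }
              base
            })
          samples[i0:i1] <- samples[i0:i1] + x
        }
        starts <- c(starts, s0); ends <- c(ends, s1); labs <- c(labs, sg$lab)
        t <- t + sg$dur
        if (t >= cfg$duration_s) break
      }
    }
    samples <- pmin(1, pmax(-1, samples))
    list(clip = audio_clip(samples, TARGET_RATE),
         track = label_track(starts, ends, labs,
                             duration_s = cfg$duration_s),
         config = cfg)
  })
}

#' Training-composition preset frame counts
#'
#' The per-class frame counts of the detector's training composition:
#' 4574 acoustic exhalations, 418 airflow exhalations, 2470 inhalations
#' and 11,752 nonbreathing frames (environmental + laboratory).
#'
#' @return Named integer vector.
#' @export
training_preset_counts <- function() {
  c(exhalation_acoustic = 4574L, exhalation_airflow = 418L,
    inhalation = 2470L, nonbreathing = 9800L + 1952L)
}

#' Generate a framed single-class labeled dataset
#'
#' Generates independent 0.195 s (3120-sample) single-class frames per
#' the requested counts. Nonbreathing frames are a mix of ambient noise
#' and event sounds (tones/chirps/bursts).
#'
#' @param class_counts named vector of requested frame counts over
#'   `exhalation_acoustic`, `exhalation_airflow`, `inhalation`,
#'   `nonbreathing` (missing names = 0).
#' @param cfg a [synth_config()] supplying amplitudes and the seed.
#' @return List with `frames` (list of 3120-sample vectors), `subtype`
#'   (generation label) and `label` (collapsed 3-class phase label).
#' @export
synth_dataset <- function(class_counts, cfg = synth_config()) {
  counts <- c(exhalation_acoustic = 0L, exhalation_airflow = 0L,
              inhalation = 0L, nonbreathing = 0L)
  counts[names(class_counts)] <- as.integer(class_counts)
  if (any(counts < 0)) stop("synth_dataset: counts must be >= 0", call. = FALSE)
  .with_seed(.derived_seed(cfg$seed, 2L), {
    gen_one <- function(subtype) {
      n <- FRAME_SAMPLES
      amb <- stats::rnorm(n) * cfg$amp_ambient
      x <- switch(subtype,
        exhalation_acoustic = .gen_exh_acoustic(n, cfg$amp_exhalation_acoustic),
        exhalation_airflow = .gen_exh_airflow(n, cfg$amp_exhalation_airflow),
        inhalation = .gen_inhalation(n, cfg$amp_inhalation),
        nonbreathing = if (stats::runif(1) < 0.5) {
          .gen_event(n, cfg$amp_event)
        } else numeric(n))
      pmin(1, pmax(-1, amb + x))
    }
    subtype <- rep(names(counts), counts)
    frames <- lapply(subtype, gen_one)
    label <- ifelse(startsWith(subtype, "exhalation"), "exhalation", subtype)
    list(frames = frames, subtype = subtype, label = label)
  })
}

#' Simulate a raw detection stream without audio
#'
#' Ticks through a guided session and corrupts the true guided phase
#' with a per-class confusion model, for driving the heuristic and
#' session machinery independently of the audio pipeline.
#'
#' @param duration_s,bpm,tick_hz session shape.
#' @param error_model 3x3 row-stochastic matrix (rows = true phase,
#'   columns = emitted phase, phase order exhalation/inhalation/
#'   nonbreathing). Default: identity (perfect detector).
#' @param seed integer seed.
#' @return data.frame with `t`, `guided` and `raw`.
#' @export
synth_detection_stream <- function(duration_s = 180, bpm = 6, tick_hz = 30,
                                   error_model = diag(3), seed = 1L) {
  error_model <- as.matrix(error_model)
  if (any(error_model < 0) || any(error_model > 1) ||
      any(abs(rowSums(error_model) - 1) > 1e-9)) {
    stop("synth_detection_stream: error_model rows must be probabilities summing to 1",
         call. = FALSE)
  }
  pattern <- pattern_for_bpm(bpm)
  times <- seq(1 / tick_hz, duration_s, by = 1 / tick_hz)
  guided <- guided_phase(pattern, times)
  .with_seed(.derived_seed(seed, 3L), {
    raw <- vapply(guided, function(g) {
      sample(PHASES, 1, prob = error_model[match(g, PHASES), ])
    }, character(1))
    data.frame(t = times, guided = guided, raw = unname(raw))
  })
}
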