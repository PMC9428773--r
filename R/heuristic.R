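# Exhalation-hold heuristic: after every raw exhalation call the output
# is forced to exhalation for hold_duration_s (default 0.3 s), with the
# hold reset by each new raw exhalation.

#' Heuristic configuration
#' @param hold_duration_s hold length in seconds (default 0.3).
#' @return A `heuristic_config` list.
#' @export
heuristic_config <- function(hold_duration_s = 0.3) {
  stopifnot(hold_duration_s >= 0)
  structure(list(hold_duration_s = hold_duration_s), class = "heuristic_config")
}

#' Initial heuristic state
#' @return A `heuristic_state` with no active hold.
#' @export
heuristic_init <- function() {
  structure(list(hold_until_s = -Inf, last_input_time_s = -Inf),
            class = "heuristic_state")
}

#' One step of the exhalation-hold heuristic
#'
#' A raw exhalation call passes through and (re)arms the hold timer to
#' `t + hold_duration_s`; any other raw call inside an active hold is
#' overridden to exhalation. The hold comparison is strict (`t <
#' hold_until`): a call exactly at expiry uses the raw phase.
#'
#' @param state a `heuristic_state`.
#' @param raw raw phase call (character).
#' @param t time of the call in seconds; must exceed the previous call's
#'   time.
#' @param cfg a [heuristic_config()].
#' @return List with `phase` (smoothed call) and `state` (updated).
#' @export
heuristic_step <- function(state, raw, t, cfg = heuristic_config()) {
  stopifnot(inherits(state, "heuristic_state"))
  if (t <= state$last_input_time_s) {
    stop("heuristic_step: time must advance", call. = FALSE)
  }
  state$last_input_time_s <- t
  if (raw == "exhalation") {
    state$hold_until_s <- t + cfg$hold_duration_s
    phase <- "exhalation"
  } else if (t < state$hold_until_s) {
    phase <- "exhalation"
  } else {
    phase <- raw
  }
  list(phase = phase, state = state)
}

#' Apply the heuristic to a whole stream of raw calls
#'
#' @param times strictly increasing timestamps (seconds).
#' @param raw raw phase calls (same length).
#' @param cfg a [heuristic_config()].
#' @return Character vector of smoothed phase calls.
#' @export
apply_heuristic <- function(times, raw, cfg = heuristic_config()) {
  stopifnot(length(times) == length(raw))
  state <- heuristic_init()
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    step <- heuristic_step(state, raw[i], times[i], cfg)
    out[i] <- step$phase
    state <- step$state
  }
  out
}
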