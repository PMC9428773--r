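# End-to-end detection over a clip: frontend -> embedding -> ensemble ->
# threshold policy -> optional exhalation-hold heuristic.

#' Detect breathing phases over a 16 kHz clip
#'
#' Slices the clip into non-overlapping 0.195 s frames (or sliding
#' most-recent windows at `tick_hz`), embeds each, applies the ensemble
#' and the threshold policy, and optionally smooths the calls with the
#' exhalation-hold heuristic. Heuristic time is the window end time.
#'
#' @param clip an `audio_clip` at 16 kHz (use [resample_to_16k()] first
#'   otherwise).
#' @param ens a trained `ensemble`.
#' @param backend the `embedding_backend` the ensemble was trained on.
#' @param policy a [threshold_policy()].
#' @param use_heuristic apply the 300 ms exhalation hold (default TRUE).
#' @param heuristic_cfg a [heuristic_config()].
#' @param mode `"frames"` (gapless 0.195 s frames) or `"sliding"`
#'   (most-recent window at `tick_hz`).
#' @param tick_hz tick rate for sliding mode (default 30).
#' @return data.frame with t_start, t_end, p_exhalation, p_inhalation,
#'   p_nonbreathing, raw_phase, heuristic_phase.
#' @export
detect_clip <- function(clip, ens, backend = surrogate_backend(),
                        policy = threshold_policy(),
                        use_heuristic = TRUE,
                        heuristic_cfg = heuristic_config(),
                        mode = c("frames", "sliding"), tick_hz = 30) {
  mode <- match.arg(mode)
  if (mode == "frames") {
    frames <- frame_clip(clip)
    if (length(frames) == 0L) stop("detect_clip: clip shorter than one frame", call. = FALSE)
    t_start <- vapply(frames, `[[`, numeric(1), "start_s")
    t_end <- t_start + FRAME_SECONDS
    X <- embed_frames(frames, backend)
  } else {
    wins <- sliding_window(clip, tick_hz)
    if (length(wins) == 0L) stop("detect_clip: clip shorter than one frame", call. = FALSE)
    t_end <- vapply(wins, `[[`, numeric(1), "time_s")
    t_start <- t_end - FRAME_SECONDS
    X <- t(vapply(wins, function(w) embed(tile_frame(w$samples), backend),
                  numeric(EMBED_DIM)))
  }
  P <- ensemble_predict(ens, X)
  raw <- apply_policy(P, policy)
  smoothed <- if (use_heuristic) apply_heuristic(t_end, raw, heuristic_cfg) else raw
  data.frame(t_start = t_start, t_end = t_end,
             p_exhalation = P[, 1], p_inhalation = P[, 2],
             p_nonbreathing = P[, 3],
             raw_phase = raw, heuristic_phase = smoothed)
}

#' Train an ensemble on a framed labeled dataset
#'
#' Embeds the frames with the given backend, splits off a validation
#' fraction (deterministic, seeded), trains candidate heads and keeps
#' the best k by validation loss.
#'
#' @param dataset output of [synth_dataset()], or any list with
#'   `frames` and `label`.
#' @param backend an `embedding_backend`.
#' @param n_candidates,k candidate pool size and ensemble size.
#' @param val_fraction validation split fraction (default 0.2).
#' @param seed split/training base seed.
#' @param cfg a [training_config()].
#' @return A trained `ensemble`.
#' @export
train_on_dataset <- function(dataset, backend = surrogate_backend(),
                             n_candidates = 20L, k = 3L,
                             val_fraction = 0.2, seed = 1L,
                             cfg = training_config()) {
  X <- embed_frames(dataset$frames, backend)
  y <- dataset$label
  n <- nrow(X)
  idx_val <- .with_seed(.derived_seed(seed, 4L),
                        sample.int(n, size = max(1L, round(val_fraction * n))))
  train <- setdiff(seq_len(n), idx_val)
  train_ensemble(X[train, , drop = FALSE], y[train],
                 X[idx_val, , drop = FALSE], y[idx_val],
                 n_candidates = n_candidates, k = k, base_seed = seed,
                 cfg = cfg)
}

#' Score detections against a label track
#'
#' Projects the truth onto the frame grid, drops masked frames, and
#' returns the confusion matrix and metric report for both the raw and
#' heuristic calls.
#'
#' @param detections output of [detect_clip()] in `"frames"` mode.
#' @param track the ground-truth `label_track`.
#' @return List with `truth`, and per mode (`raw`, `heuristic`) the
#'   confusion matrix and [per_class_metrics()] report.
#' @export
evaluate_detection <- function(detections, track) {
  fl <- frame_labels(track, nrow(detections))
  keep <- fl$mask
  truth <- fl$labels[keep]
  score_mode <- function(pred) {
    cm <- confusion(truth, pred[keep])
    list(confusion = cm, metrics = per_class_metrics(cm))
  }
  list(truth = truth,
       raw = score_mode(detections$raw_phase),
       heuristic = score_mode(detections$heuristic_phase))
}
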