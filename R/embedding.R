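# Embedding backends: map a tiled 15,600-sample waveform to a fixed
# 1024-dimensional feature vector for the classifier head.

EMBED_DIM <- 1024L
SURROGATE_SEED_DEFAULT <- 190141L

#' Create the deterministic surrogate embedding backend
#'
#' The surrogate backend makes the whole pipeline run offline with no
#' external model assets. It computes the log-mel patch of the input,
#' summarises each of the 64 mel bands by four statistics over time
#' (mean, standard deviation, maximum, mean absolute first difference;
#' 256 features total), then expands to 1024 dimensions through a fixed
#' seeded Gaussian random projection followed by tanh. Identical inputs
#' give bit-identical embeddings; the projection seed is recorded on the
#' backend object and in any saved model metadata.
#'
#' @param projection_seed integer seed fixing the random projection.
#' @return An `embedding_backend` object.
#' @export
surrogate_backend <- function(projection_seed = SURROGATE_SEED_DEFAULT) {
  n_feat <- 4L * MEL_BANDS
  proj <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(projection_seed)
    matrix(stats::rnorm(n_feat * EMBED_DIM) / sqrt(n_feat),
           nrow = n_feat, ncol = EMBED_DIM)
  })
  structure(
    list(
      name = "surrogate",
      deterministic = TRUE,
      projection_seed = projection_seed,
      embed = function(waveform) {
        patch <- log_mel(waveform)
        feat <- c(rowMeans(patch),
                  apply(patch, 1, stats::sd),
                  apply(patch, 1, max),
                  rowMeans(abs(patch[, -1, drop = FALSE] -
                               patch[, -ncol(patch), drop = FALSE])))
        tanh(as.numeric(feat %*% proj))
      }
    ),
    class = "embedding_backend"
  )
}

#' Adapter stub for a pretrained audio-event embedding network
#'
#' The detector was designed around the 1024-dimensional embeddings of a
#' pretrained audio-event network. Running that network requires an
#' external model asset that is not shipped with this package; this
#' constructor fails loudly rather than silently falling back, so the
#' surrogate backend is never substituted without the caller knowing.
#'
#' @param model_path path to the external saved model assets.
#' @return Never returns unless the asset and runtime are available.
#' @export
yamnet_backend <- function(model_path = NULL) {
  stop(paste0("yamnet backend not installed: the pretrained audio-event ",
              "network requires an external model download",
              if (!is.null(model_path)) sprintf(" (looked at '%s')", model_path),
              "; use surrogate_backend() for offline work"),
       call. = FALSE)
}

#' Resolve a backend by name
#' @param name `"surrogate"` or `"yamnet"`.
#' @param ... passed to the backend constructor.
#' @return An `embedding_backend`.
#' @export
get_backend <- function(name = c("surrogate", "yamnet"), ...) {
  name <- match.arg(name)
  switch(name, surrogate = surrogate_backend(...), yamnet = yamnet_backend(...))
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend '%s'%s>\n", x$name,
              if (isTRUE(x$deterministic)) " (deterministic)" else ""))
  invisible(x)
}

#' Embed a tiled waveform
#'
#' @param waveform numeric vector of exactly 15,600 samples at 16 kHz.
#' @param backend an `embedding_backend` (default: surrogate).
#' @return Numeric vector of length 1024.
#' @export
embed <- function(waveform, backend = surrogate_backend()) {
  stopifnot(inherits(backend, "embedding_backend"))
  if (length(waveform) != TILE_SAMPLES) {
    stop(sprintf("embed: waveform must have exactly %d samples, got %d",
                 TILE_SAMPLES, length(waveform)), call. = FALSE)
  }
  e <- backend$embed(waveform)
  stopifnot(length(e) == EMBED_DIM, all(is.finite(e)))
  e
}

#' Embed every frame of a clip
#'
#' Convenience over [frame_clip()], [tile_frame()] and [embed()].
#'
#' @param frames list of frames from [frame_clip()].
#' @param backend an `embedding_backend`.
#' @return Matrix with one row per frame, 1024 columns.
#' @export
embed_frames <- function(frames, backend = surrogate_backend()) {
  t(vapply(frames, function(f) embed(tile_frame(f), backend),
           numeric(EMBED_DIM)))
}
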