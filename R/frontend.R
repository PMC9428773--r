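# Log-mel front end: STFT 25 ms window / 10 ms hop at 16 kHz, 64 HTK mel
# bands over 125-7500 Hz, log compression with a 0.001 floor.

MEL_BANDS <- 64L
MEL_FMIN <- 125
MEL_FMAX <- 7500
STFT_WIN <- 400L   # 25 ms at 16 kHz
STFT_HOP <- 160L   # 10 ms
STFT_NFFT <- 512L
LOG_FLOOR <- 0.001
TILE_SAMPLES <- 15600L

#' Tile a 0.195 s frame to the embedding input length
#'
#' The embedding backend expects 15,600 samples (0.975 s); one detector
#' frame is 3120 samples, so the frame is concatenated with itself five
#' times. Tiling (rather than constant padding) keeps inputs holding a
#' distinct sound source maximally different from silence.
#'
#' @param frame numeric vector of exactly 3120 samples, or a frame from
#'   [frame_clip()].
#' @return Numeric vector of length 15,600 with `out[i] = frame[i mod 3120]`.
#' @export
tile_frame <- function(frame) {
  if (is.list(frame)) frame <- frame$samples
  if (length(frame) != FRAME_SAMPLES) {
    stop(sprintf("tile_frame: frame must have exactly %d samples, got %d",
                 FRAME_SAMPLES, length(frame)), call. = FALSE)
  }
  rep(frame, TILE_SAMPLES %/% FRAME_SAMPLES)
}

# HTK mel scale
.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# 64 triangular mel filters on the 512-point FFT bin centres (cached)
.mel_fb_cache <- new.env(parent = emptyenv())
.mel_filterbank <- function() {
  if (!is.null(.mel_fb_cache$fb)) return(.mel_fb_cache$fb)
  n_bins <- STFT_NFFT %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1) * TARGET_RATE / STFT_NFFT
  edges <- .mel_to_hz(seq(.hz_to_mel(MEL_FMIN), .hz_to_mel(MEL_FMAX),
                          length.out = MEL_BANDS + 2L))
  fb <- matrix(0, nrow = MEL_BANDS, ncol = n_bins)
  for (b in seq_len(MEL_BANDS)) {
    lo <- edges[b]; ctr <- edges[b + 1L]; hi <- edges[b + 2L]
    up <- (bin_hz - lo) / (ctr - lo)
    down <- (hi - bin_hz) / (hi - ctr)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  .mel_fb_cache$fb <- fb
  fb
}

#' Log-mel spectrogram of a 16 kHz waveform
#'
#' Short-time Fourier transform with a 400-sample periodic Hann window,
#' 160-sample hop and no edge padding ("valid" framing, so T is a pure
#' function of the input length), magnitude spectrum pooled through 64
#' triangular mel filters spanning 125-7500 Hz, then `log(S + 0.001)`.
#' For the tiled 15,600-sample input T = 96.
#'
#' @param waveform numeric vector at 16 kHz, length >= 400.
#' @return 64 x T matrix of log-mel energies; every cell >= `log(0.001)`.
#' @export
log_mel <- function(waveform) {
  n <- length(waveform)
  if (n < STFT_WIN) {
    stop(sprintf("log_mel: waveform must have at least %d samples, got %d",
                 STFT_WIN, n), call. = FALSE)
  }
  n_frames <- (n - STFT_WIN) %/% STFT_HOP + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(STFT_WIN - 1L)) / STFT_WIN) # periodic Hann
  starts <- (seq_len(n_frames) - 1L) * STFT_HOP
  seg <- matrix(0, nrow = STFT_NFFT, ncol = n_frames)
  idx <- seq_len(STFT_WIN)
  for (j in seq_len(n_frames)) {
    seg[idx, j] <- waveform[starts[j] + idx] * win
  }
  spec <- Mod(stats::mvfft(seg))[seq_len(STFT_NFFT %/% 2L + 1L), , drop = FALSE]
  S <- .mel_filterbank() %*% spec
  log(S + LOG_FLOOR)
}
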