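FRAME_SAMPLES <- 3120L
TARGET_RATE <- 16000L
FRAME_SECONDS <- FRAME_SAMPLES / TARGET_RATE # 0.195 s

#' Construct an audio clip
#'
#' An `audio_clip` is the package's container for mono audio: a numeric
#' vector of samples in `[-1, 1]` plus a sample rate in Hz.
#'
#' @param samples numeric vector of finite samples.
#' @param sample_rate positive integer sample rate in Hz.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("audio_clip: samples must be finite", call. = FALSE)
  }
  sample_rate <- as.integer(sample_rate)
  if (length(sample_rate) != 1L || is.na(sample_rate) || sample_rate <= 0L) {
    stop("audio_clip: sample_rate must be a positive integer", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples @ %d Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

#' Duration of an audio clip in seconds
#' @param clip an `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

# Read n bytes as little-endian unsigned integer
.le_uint <- function(raw) sum(as.numeric(raw) * 256^(seq_along(raw) - 1))

#' Read a WAV file
#'
#' Reads RIFF/WAVE audio (PCM 8/16/24/32-bit or IEEE float 32/64-bit,
#' including WAVE_FORMAT_EXTENSIBLE wrappers). Multi-channel audio is
#' collapsed to mono by averaging the channels; samples are scaled to
#' `[-1, 1]`. The original sample rate is preserved.
#'
#' @param path path to a WAV file.
#' @return An `audio_clip` at the file's native rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_wav: cannot read '%s': no such file", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 12L)
  if (length(hdr) < 12L || rawToChar(hdr[1:4]) != "RIFF" ||
      rawToChar(hdr[9:12]) != "WAVE") {
    stop(sprintf("read_wav: '%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    chunk_hdr <- readBin(con, "raw", 8L)
    if (length(chunk_hdr) < 8L) break
    cid <- rawToChar(chunk_hdr[1:4])
    csize <- .le_uint(chunk_hdr[5:8])
    if (cid == "fmt ") {
      body <- readBin(con, "raw", csize)
      fmt <- list(
        format = .le_uint(body[1:2]),
        channels = .le_uint(body[3:4]),
        rate = .le_uint(body[5:8]),
        bits = .le_uint(body[15:16])
      )
      # WAVE_FORMAT_EXTENSIBLE: actual format is in the sub-format GUID
      if (fmt$format == 65534 && csize >= 40) {
        fmt$format <- .le_uint(body[25:26])
      }
    } else if (cid == "data") {
      data_raw <- readBin(con, "raw", csize)
    } else {
      readBin(con, "raw", csize + csize %% 2)
      next
    }
    if (csize %% 2 == 1) readBin(con, "raw", 1L)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("read_wav: '%s' is missing fmt or data chunk", path), call. = FALSE)
  }
  bytes_per <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% bytes_per
  x <- if (fmt$format == 1) {
    if (fmt$bits == 8) {
      (as.numeric(data_raw[seq_len(n_total)]) - 128) / 128
    } else if (fmt$bits == 16) {
      readBin(data_raw, "integer", n_total, size = 2L, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.numeric(data_raw[seq_len(n_total * 3)]), nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n_total, size = 4L, endian = "little") / 2147483648
    } else {
      stop(sprintf("read_wav: unsupported PCM bit depth %d", fmt$bits), call. = FALSE)
    }
  } else if (fmt$format == 3) {
    readBin(data_raw, "double", n_total, size = bytes_per, endian = "little")
  } else {
    stop(sprintf("read_wav: unsupported WAV format code %d", fmt$format), call. = FALSE)
  }
  if (fmt$channels > 1) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  audio_clip(x, fmt$rate)
}

#' Write a WAV file
#'
#' Writes mono PCM audio. Samples are clamped to `[-1, 1]` before
#' quantisation.
#'
#' @param clip an `audio_clip`.
#' @param path output path.
#' @param bits bit depth, 16 (default) or 32-bit float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bits = 16L) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16L, 32L))
  x <- pmin(1, pmax(-1, clip$samples))
  fmt_code <- if (bits == 16L) 1L else 3L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wle(36L + data_size, 4L)
  writeChar("WAVEfmt ", con, eos = NULL)
  wle(16L, 4L); wle(fmt_code, 2L); wle(1L, 2L)
  wle(clip$sample_rate, 4L)
  wle(clip$sample_rate * bytes_per, 4L)
  wle(bytes_per, 2L); wle(bits, 2L)
  writeChar("data", con, eos = NULL)
  wle(data_size, 4L)
  if (bits == 16L) {
    q <- as.integer(pmin(32767, round(x * 32768)))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Resample a clip to 16 kHz
#'
#' Band-limited polyphase resampling to the detector's 16 kHz working
#' rate. A clip already at 16 kHz is returned unchanged. The output
#' length is `round(n * 16000 / rate)`.
#'
#' @param clip an `audio_clip`.
#' @return An `audio_clip` at 16000 Hz.
#' @export
resample_to_16k <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate == TARGET_RATE) return(clip)
  n_out <- round(length(clip$samples) * TARGET_RATE / clip$sample_rate)
  if (length(clip$samples) == 0L) return(audio_clip(numeric(0), TARGET_RATE))
  g <- .gcd(TARGET_RATE, clip$sample_rate)
  p <- TARGET_RATE %/% g
  q <- clip$sample_rate %/% g
  y <- signal::resample(clip$samples, p = p, q = q)
  # polyphase output length may differ by a sample from the exact ratio
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, rep(0, n_out - length(y)))
  y <- pmin(1, pmax(-1, y))
  audio_clip(y, TARGET_RATE)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Cut a 16 kHz clip into non-overlapping 0.195 s frames
#'
#' Frame i covers samples `[3120*i, 3120*(i+1))` (0-based). A trailing
#' remainder shorter than one frame is dropped, not padded.
#'
#' @param clip an `audio_clip` at 16 kHz.
#' @return A list of frames; each frame is a list with `samples`
#'   (length 3120), `index` (0-based) and `start_s`.
#' @export
frame_clip <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate != TARGET_RATE) {
    stop("frame_clip: clip must be at 16 kHz; call resample_to_16k() first",
         call. = FALSE)
  }
  n <- length(clip$samples) %/% FRAME_SAMPLES
  lapply(seq_len(n) - 1L, function(i) {
    list(samples = clip$samples[(i * FRAME_SAMPLES + 1L):((i + 1L) * FRAME_SAMPLES)],
         index = i,
         start_s = i * FRAME_SECONDS)
  })
}

#' Sliding most-recent-window frames at a tick rate
#'
#' Emulates streamed detection: at each tick time t (starting at
#' t = 0.195 s, the first instant a full frame exists) the most recent
#' 3120 samples ending at t are emitted. Ticks are spaced `1/tick_hz`
#' seconds; the last tick does not exceed the clip duration.
#'
#' @param clip an `audio_clip` at 16 kHz, at least one frame long.
#' @param tick_hz tick rate in Hz (default 30).
#' @return A list of `(time_s, samples)` pairs; empty if the clip is
#'   shorter than one frame.
#' @export
sliding_window <- function(clip, tick_hz = 30) {
  stopifnot(inherits(clip, "audio_clip"), tick_hz > 0)
  if (clip$sample_rate != TARGET_RATE) {
    stop("sliding_window: clip must be at 16 kHz", call. = FALSE)
  }
  dur <- clip_duration(clip)
  if (length(clip$samples) < FRAME_SAMPLES) return(list())
  n_ticks <- floor((dur - FRAME_SECONDS) * tick_hz) + 1L
  lapply(seq_len(n_ticks) - 1L, function(k) {
    t <- FRAME_SECONDS + k / tick_hz
    end_idx <- min(length(clip$samples), floor(t * TARGET_RATE))
    list(time_s = t,
         samples = clip$samples[(end_idx - FRAME_SAMPLES + 1L):end_idx])
  })
}

#' Dump per-frame RMS to a TSV (debugging aid)
#' @param frames output of [frame_clip()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_frame_tsv <- function(frames, path) {
  df <- data.frame(
    index = vapply(frames, `[[`, integer(1), "index"),
    start_s = vapply(frames, `[[`, numeric(1), "start_s"),
    rms = vapply(frames, function(f) sqrt(mean(f$samples^2)), numeric(1))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
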