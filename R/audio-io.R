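#' Construct an audio clip
#'
#' An `audio_clip` is the package's in-memory representation of one mono
#' recording: a numeric sample vector (amplitudes nominally in \[-1, 1\]),
#' its sample rate in Hz, an identifier of the originating recording, and a
#' lineage of augmentation descriptors applied so far.
#'
#' @param samples numeric vector of at least one sample.
#' @param sample_rate samples per second (Hz), positive.
#' @param source_id identifier of the originating recording.
#' @param lineage character vector of augmentation descriptors (may be empty).
#' @return an object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, source_id = "clip",
                       lineage = character()) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_clip: 'samples' must be non-empty")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("audio_clip: 'sample_rate' must be a positive scalar")
  if (any(!is.finite(samples))) stop("audio_clip: non-finite samples")
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id), lineage = as.character(lineage)),
    class = "audio_clip")
}

#' Duration of a clip in seconds
#'
#' Derived as `length(samples) / sample_rate`; never stored independently.
#'
#' @param clip an [audio_clip].
#' @return duration in seconds.
#' @export
duration_seconds <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.3f s @ %g Hz (%d samples)%s\n",
              x$source_id, duration_seconds(x), x$sample_rate,
              length(x$samples),
              if (length(x$lineage)) paste0(" [", paste(x$lineage, collapse = " > "), "]")
              else ""))
  invisible(x)
}

# ---- WAV container ---------------------------------------------------------
# Minimal RIFF/WAVE codec for PCM 16/24-bit and IEEE float 32. No audio
# package ships with this R stack, and the container is simple enough that a
# direct reader keeps the package dependency-free here.

read_wav_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("corrupt WAV (missing fmt/data chunk): ", path)
  fmt_code <- fmt$audio_format
  if (fmt_code == 65534L) fmt_code <- 1L  # WAVE_FORMAT_EXTENSIBLE, assume PCM
  x <- if (fmt_code == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
            endian = "little", signed = TRUE) / 32768  # symmetric with writer
  } else if (fmt_code == 1L && fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw), nrow = 3L, ncol = n)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt_code == 3L && fmt$bits == 32L) {
    readBin(data_raw, "numeric", length(data_raw) / 4L, size = 4,
            endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                 fmt$audio_format, fmt$bits, path))
  }
  if (fmt$n_channels > 1L)
    x <- matrix(x, nrow = fmt$n_channels)  # channels in rows, interleaved
  list(samples = x, sample_rate = fmt$sample_rate)
}

write_wav_file <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmin(pmax(round(samples * 32768), -32768), 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Sample-rate conversion by linear interpolation, preceded by a Butterworth
# low-pass (signal::filtfilt, zero phase) when downsampling to limit aliasing.
resample_samples <- function(x, from_rate, to_rate) {
  if (from_rate == to_rate) return(x)
  if (to_rate < from_rate && length(x) > 24L) {
    bf <- signal::butter(6, 0.9 * to_rate / from_rate)
    x <- signal::filtfilt(bf, x)
  }
  n_out <- max(1L, round(length(x) * to_rate / from_rate))
  t_in <- seq(0, length(x) - 1) / from_rate
  t_out <- seq(0, n_out - 1) / to_rate
  approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
}

#' Read an audio file as a mono clip
#'
#' Decodes a PCM WAV file (16/24-bit integer or 32-bit float), averages
#' channels to mono, and resamples to `target_rate`.
#'
#' @param path path to a WAV file.
#' @param target_rate desired sample rate in Hz (default 22050).
#' @return an [audio_clip] with empty lineage; `source_id` is the file name
#'   without extension.
#' @export
read_audio <- function(path, target_rate = 22050) {
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("read_audio: 'target_rate' must be positive")
  if (!file.exists(path)) stop("read_audio: no such file: ", path)
  w <- tryCatch(read_wav_file(path),
                error = function(e) stop("read_audio: cannot decode '", path,
                                         "': ", conditionMessage(e)))
  x <- w$samples
  if (is.matrix(x)) x <- colMeans(x)
  if (length(x) == 0L) stop("read_audio: zero-length audio: ", path)
  x <- resample_samples(x, w$sample_rate, target_rate)
  audio_clip(x, target_rate,
             source_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a clip to a 16-bit PCM WAV file
#'
#' @param clip an [audio_clip].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_audio <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  write_wav_file(clip$samples, clip$sample_rate, path)
  invisible(path)
}
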