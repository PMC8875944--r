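#' Feature matrix
#'
#' A non-negative (after magnitude) 2-D grid of feature values, feature bins
#' in rows and time frames in columns, produced by one of the three feature
#' transforms before conversion to an image.
#'
#' @param values numeric matrix (bins x frames), finite.
#' @param feature_kind one of `"spectrogram"`, `"mfcc"`, `"chromagram"`.
#' @param bin_axis_meaning description of the row axis.
#' @param frame_hop_seconds hop between successive frames, in seconds.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values,
                           feature_kind = c("spectrogram", "mfcc", "chromagram"),
                           bin_axis_meaning = "linear-frequency",
                           frame_hop_seconds = 0.023) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature_matrix: non-finite values")
  if (ncol(values) < 1L) stop("feature_matrix: need at least one frame")
  if (feature_kind == "chromagram" && nrow(values) != 12L)
    stop("feature_matrix: a chromagram has exactly 12 pitch-class rows")
  structure(list(values = values, feature_kind = feature_kind,
                 bin_axis_meaning = bin_axis_meaning,
                 frame_hop_seconds = frame_hop_seconds),
            class = "feature_matrix")
}

#' Segment a clip into fixed-length analysis windows
#'
#' Slides a `window_seconds` window by `hop_seconds` over the clip. A final
#' partial window is zero-padded to full length when it covers at least half
#' the window, and dropped otherwise; a clip shorter than half a window
#' yields an empty list. Each window inherits the source id and lineage and
#' records its offset.
#'
#' @param clip an [audio_clip].
#' @param window_seconds window length in seconds (default 3).
#' @param hop_seconds hop between window starts (default 3: non-overlapping).
#' @return list of [audio_clip] windows with an `offset_seconds` attribute.
#' @export
window_clip <- function(clip, window_seconds = 3.0, hop_seconds = 3.0) {
  stopifnot(inherits(clip, "audio_clip"))
  if (window_seconds <= 0 || hop_seconds <= 0)
    stop("window_clip: window and hop must be positive")
  win <- round(window_seconds * clip$sample_rate)
  hop <- round(hop_seconds * clip$sample_rate)
  n <- length(clip$samples)
  out <- list()
  offset <- 0L
  while (n - offset >= ceiling(win / 2)) {
    avail <- min(win, n - offset)
    x <- clip$samples[offset + seq_len(avail)]
    if (avail < win) x <- c(x, numeric(win - avail))
    w <- audio_clip(x, clip$sample_rate, clip$source_id, clip$lineage)
    attr(w, "offset_seconds") <- offset / clip$sample_rate
    out[[length(out) + 1L]] <- w
    offset <- offset + hop
  }
  out
}

#' Magnitude spectrogram of a window
#'
#' Short-time Fourier transform with a periodic Hann analysis window of
#' `round(frame_seconds * sample_rate)` samples, hop
#' `frame_seconds * hop_fraction`, and FFT size the next power of two at or
#' above the frame length. Values are STFT magnitudes (non-negative), linear
#' frequency in rows.
#'
#' @param window an [audio_clip] (typically a 3-s window from [window_clip]).
#' @param frame_seconds STFT frame length in seconds (default 0.023 = 23 ms).
#' @param hop_fraction hop as a fraction of the frame (default 1: abutting
#'   frames).
#' @return a [feature_matrix] of kind `"spectrogram"`.
#' @export
compute_spectrogram <- function(window, frame_seconds = 0.023,
                                hop_fraction = 1.0) {
  stopifnot(inherits(window, "audio_clip"))
  frame <- round(frame_seconds * window$sample_rate)
  if (frame > length(window$samples))
    stop("compute_spectrogram: frame (", frame,
         " samples) longer than the window")
  hop <- max(1L, round(frame * hop_fraction))
  S <- Mod(stft(window$samples, frame, hop))
  feature_matrix(S, "spectrogram", "linear-frequency",
                 frame_hop_seconds = hop / window$sample_rate)
}

#' Mel scale
#'
#' `mel(f) = 2595 * log10(1 + f / 700)`, the perceptual frequency warping
#' used to place the MFCC filter bank.
#'
#' @param f frequency in Hz.
#' @return mel value(s).
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filter bank: n_mels filters over [0, sample_rate/2] with
# centers equally spaced on the mel scale; rows are filters, columns FFT bins.
mel_filterbank <- function(n_mels, n_fft, sample_rate) {
  freqs <- stft_bin_frequencies(sample_rate, n_fft)
  edges <- mel_to_hz(seq(0, hz_to_mel(sample_rate / 2), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / max(mid - lo, 1e-12)
    down <- (hi - freqs) / max(hi - mid, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
    # a triangle narrower than the FFT bin spacing covers no bin center;
    # sample the nearest bin instead so no band is silently empty
    if (sum(fb[m, ]) == 0) fb[m, which.min(abs(freqs - mid))] <- 1
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in), applied to the log-mel spectrum.
dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1L), 0:(n_in - 1L),
             function(k, n) cos(pi * k * (2 * n + 1) / (2 * n_in)))
  m * sqrt(2 / n_in)
  # note: row 0 keeps the sqrt(2/N) scale; only relative magnitudes matter
  # downstream because the imaging step normalizes by the global maximum.
}

#' Mel-frequency cepstral coefficients of a window
#'
#' Magnitude STFT, mel filter bank ([hz_to_mel] spacing), log, DCT-II;
#' the first `n_coefficients` rows are retained. Frame geometry matches
#' [compute_spectrogram].
#'
#' @inheritParams compute_spectrogram
#' @param n_mels number of mel filters (default 128).
#' @param n_coefficients number of cepstral coefficients kept (default 40).
#' @return a [feature_matrix] of kind `"mfcc"` (signed values).
#' @export
compute_mfcc <- function(window, n_mels = 128L, n_coefficients = 40L,
                         frame_seconds = 0.023) {
  if (n_coefficients > n_mels)
    stop("compute_mfcc: n_coefficients cannot exceed n_mels")
  S <- compute_spectrogram(window, frame_seconds)$values
  n_fft <- 2^ceiling(log2(round(frame_seconds * window$sample_rate)))
  fb <- mel_filterbank(n_mels, n_fft, window$sample_rate)
  logmel <- log(fb %*% S + 1e-10)
  cc <- dct_matrix(n_coefficients, n_mels) %*% logmel
  feature_matrix(cc, "mfcc", "mel-cepstral",
                 frame_hop_seconds = frame_seconds)
}

#' Chromagram (pitch-class profile) of a window
#'
#' STFT magnitudes folded onto the 12 semitone pitch classes with A440 as
#' reference: each frequency bin above the DC bin contributes its magnitude
#' to the class `round(12 * log2(f / 440)) mod 12`. Rows are ordered
#' C, C#, ..., B, so class A is row 10.
#'
#' @inheritParams compute_spectrogram
#' @return a 12-row [feature_matrix] of kind `"chromagram"`.
#' @export
compute_chromagram <- function(window, frame_seconds = 0.023) {
  S <- compute_spectrogram(window, frame_seconds)$values
  n_fft <- 2^ceiling(log2(round(frame_seconds * window$sample_rate)))
  freqs <- stft_bin_frequencies(window$sample_rate, n_fft)
  # semitone class relative to A440; +9 maps A to the 10th of C-ordered rows
  cls <- ((round(12 * log2(freqs / 440)) + 9) %% 12) + 1L
  cls[1L] <- NA  # DC carries no pitch
  agg <- rowsum(S[!is.na(cls), , drop = FALSE], cls[!is.na(cls)])
  chroma <- matrix(0, 12L, ncol(S))
  chroma[as.integer(rownames(agg)), ] <- agg
  feature_matrix(chroma, "chromagram", "pitch-class",
                 frame_hop_seconds = frame_seconds)
}

#' Feature image
#'
#' A 128 x 128 single-channel image of integers in `[0, 255]`, the unit fed
#' to the classifiers.
#'
#' @param pixels integer matrix, exactly 128 x 128, values in `[0, 255]`.
#' @param feature_kind the producing transform.
#' @param source_window identifier of the originating window.
#' @return an object of class `feature_image`.
#' @export
feature_image <- function(pixels, feature_kind = "spectrogram",
                          source_window = "") {
  pixels <- as.matrix(pixels)
  if (!all(dim(pixels) == c(128L, 128L)))
    stop("feature_image: pixels must be 128 x 128")
  if (any(pixels < 0 | pixels > 255) || any(pixels != round(pixels)))
    stop("feature_image: pixels must be integers in [0, 255]")
  structure(list(pixels = pixels, feature_kind = feature_kind,
                 source_window = source_window),
            class = "feature_image")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a feature matrix to a 128 x 128 image
#'
#' Linear scaling to 8-bit range: each value maps to
#' `|v| / max|v| * 255`, rounded half-away-from-zero, so the global maximum
#' maps to 255 and the map is invariant to positive rescaling of the input.
#' The scaled matrix is then resized to 128 x 128 by bilinear interpolation.
#' An all-zero matrix yields an all-zero image.
#'
#' @param matrix a [feature_matrix] (or plain numeric matrix).
#' @param source_window identifier stored on the image.
#' @return a [feature_image].
#' @export
scale_to_image <- function(matrix, source_window = "") {
  kind <- "spectrogram"
  if (inherits(matrix, "feature_matrix")) {
    kind <- matrix$feature_kind
    matrix <- matrix$values
  }
  m <- abs(matrix)
  mx <- max(m)
  scaled <- if (mx > 0) round_half_away(m / mx * 255) else m * 0
  resized <- if (all(dim(scaled) == c(128L, 128L))) scaled else
    matrix(EBImage::resize(scaled, w = 128L, h = 128L, filter = "bilinear"),
           128L, 128L)
  pix <- matrix(pmin(pmax(round_half_away(resized), 0), 255), 128L, 128L)
  feature_image(pix, kind, source_window)
}

#' Write a feature image as an 8-bit grayscale PNG
#' @param image a [feature_image].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_feature_image <- function(image, path) {
  stopifnot(inherits(image, "feature_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read a feature image written by [write_feature_image]
#' @param path PNG path.
#' @param feature_kind kind recorded on the returned object.
#' @return a [feature_image].
#' @export
read_feature_image <- function(path, feature_kind = "spectrogram") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  feature_image(round(px * 255), feature_kind,
                tools::file_path_sans_ext(basename(path)))
}

feature_fun <- function(kind) {
  switch(kind,
         spectrogram = compute_spectrogram,
         mfcc = compute_mfcc,
         chromagram = compute_chromagram,
         stop("unknown feature kind: ", kind))
}

#' Extract feature images for a whole manifest
#'
#' For every manifest record and every requested feature kind, segments the
#' recording into 3-s windows and writes one 128 x 128 PNG per window under
#' `out_dir/<kind>/`. Returns the feature index: one row per image with its
#' path, source record, window offset, kind, label and split. Read failures
#' are collected and reported as a warning, not an error.
#'
#' @param manifest a [dataset_manifest].
#' @param kinds subset of `c("spectrogram", "mfcc", "chromagram")`.
#' @param out_dir output directory.
#' @param target_rate processing sample rate (Hz).
#' @param window_seconds,hop_seconds window geometry, see [window_clip].
#' @return a `data.frame` feature index.
#' @export
extract_features <- function(manifest,
                             kinds = c("spectrogram", "mfcc", "chromagram"),
                             out_dir = tempfile("features"),
                             target_rate = 22050,
                             window_seconds = 3.0, hop_seconds = 3.0) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  kinds <- unique(match.arg(kinds, c("spectrogram", "mfcc", "chromagram"),
                            several.ok = TRUE))
  index <- list()
  failures <- character()
  for (kind in kinds)
    dir.create(file.path(out_dir, kind), showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    clip <- tryCatch(read_audio(rec$clip_path, target_rate),
                     error = function(e) conditionMessage(e))
    if (is.character(clip)) { failures <- c(failures, clip); next }
    windows <- window_clip(clip, window_seconds, hop_seconds)
    stem <- tools::file_path_sans_ext(basename(rec$clip_path))
    for (kind in kinds) {
      f <- feature_fun(kind)
      for (w in windows) {
        off <- attr(w, "offset_seconds")
        img_path <- file.path(out_dir, kind,
                              sprintf("%s__w%07.3f.png", stem, off))
        if (!file.exists(img_path))  # idempotent for unchanged inputs
          write_feature_image(scale_to_image(f(w), basename(img_path)),
                              img_path)
        index[[length(index) + 1L]] <- data.frame(
          image_path = img_path, source_id = rec$clip_path,
          offset_s = off, kind = kind, label = rec$label, split = rec$split,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(failures))
    warning("extract_features: ", length(failures), " file(s) failed: ",
            paste(head(failures, 3L), collapse = "; "))
  if (length(index)) do.call(rbind, index) else
    data.frame(image_path = character(), source_id = character(),
               offset_s = numeric(), kind = character(),
               label = character(), split = character())
}
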