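# Short-time Fourier analysis shared by the feature and augmentation code.
# Frames are contiguous slices (no centering); each frame is multiplied by a
# periodic Hann window and zero-padded to n_fft before the FFT.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)  # periodic form
}

# Returns the complex STFT as a (n_fft/2 + 1) x n_frames matrix.
stft <- function(x, frame_length, hop_length, n_fft = NULL) {
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(frame_length))
  stopifnot(n_fft >= frame_length)
  n <- length(x)
  if (n < frame_length) x <- c(x, numeric(frame_length - n))
  n_frames <- max(1L, floor((length(x) - frame_length) / hop_length) + 1L)
  win <- hann_window(frame_length)
  frames <- matrix(0, nrow = n_fft, ncol = n_frames)
  for (t in seq_len(n_frames)) {
    i0 <- (t - 1L) * hop_length
    frames[seq_len(frame_length), t] <- x[i0 + seq_len(frame_length)] * win
  }
  sp <- stats::mvfft(frames)
  sp[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
}

# Overlap-add inverse with squared-window normalization (standard weighted
# overlap-add; exact for any hop that covers the signal).
istft <- function(S, frame_length, hop_length, n_fft = NULL) {
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(frame_length))
  n_frames <- ncol(S)
  full <- matrix(0+0i, nrow = n_fft, ncol = n_frames)
  full[seq_len(nrow(S)), ] <- S
  if (n_fft > nrow(S))
    full[seq(nrow(S) + 1L, n_fft), ] <- Conj(S[rev(seq(2L, n_fft - nrow(S) + 1L)), , drop = FALSE])
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  win <- hann_window(frame_length)
  n_out <- (n_frames - 1L) * hop_length + frame_length
  y <- numeric(n_out)
  norm <- numeric(n_out)
  for (t in seq_len(n_frames)) {
    idx <- (t - 1L) * hop_length + seq_len(frame_length)
    y[idx] <- y[idx] + frames[seq_len(frame_length), t] * win
    norm[idx] <- norm[idx] + win^2
  }
  y[norm > 1e-8] <- y[norm > 1e-8] / norm[norm > 1e-8]
  y
}

# frequency (Hz) of each retained STFT bin
stft_bin_frequencies <- function(sample_rate, n_fft) {
  (0:(n_fft %/% 2L)) * sample_rate / n_fft
}
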