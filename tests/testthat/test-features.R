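test_that("window counts follow the half-window retention rule", {
  sr <- 22050
  mk <- function(dur) audio_clip(rep(0.1, round(dur * sr)), sr)
  expect_length(window_clip(mk(9)), 3L)    # exact tiling at 0, 3, 6
  w10 <- window_clip(mk(10))               # 1.0 s remainder dropped
  expect_length(w10, 3L)
  expect_equal(vapply(w10, attr, 0, "offset_seconds"), c(0, 3, 6))
  expect_length(window_clip(mk(90)), 30L)
  expect_length(window_clip(mk(11)), 4L)   # 2.0 s >= 50% kept, zero-padded
  w11 <- window_clip(mk(11))[[4]]
  expect_equal(length(w11$samples), 3 * sr)
  expect_true(all(w11$samples[(2 * sr + 1):(3 * sr)] == 0))
  expect_length(window_clip(mk(1)), 0L)    # shorter than half a window
  expect_error(window_clip(mk(9), window_seconds = 0), "positive")
})

test_that("windows number floor(T/3) plus one when the remainder >= 1.5 s", {
  sr <- 4000
  for (dur in c(3, 4.4, 4.6, 6, 7.4, 7.5, 12, 13.7)) {
    n <- length(window_clip(audio_clip(rep(0.1, round(dur * sr)), sr)))
    rem <- dur - 3 * floor(dur / 3)
    expect_equal(n, floor(dur / 3) + (rem >= 1.5), label = paste("dur", dur))
  }
})

test_that("spectrogram geometry and tone localization", {
  tone <- make_tone(440, 3, 22050)
  S <- compute_spectrogram(tone)
  expect_s3_class(S, "feature_matrix")
  expect_true(all(S$values >= 0))
  expect_equal(nrow(S$values), 257L)       # 512-point FFT, one-sided
  expect_equal(ncol(S$values), 130L)       # 3 s / 23 ms abutting frames
  freqs <- (0:256) * 22050 / 512
  peak_bins <- apply(S$values, 2, which.max)
  expect_true(all(peak_bins == which.min(abs(freqs - 440))))

  zero <- audio_clip(numeric(3 * 22050), 22050)
  expect_true(all(compute_spectrogram(zero)$values == 0))

  short <- audio_clip(numeric(100), 22050)
  expect_error(compute_spectrogram(short), "longer than the window")
})

test_that("mel scale matches its closed form", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_equal(hz_to_mel(700), 781.17, tolerance = 1e-4)
  # monotone increasing
  f <- seq(0, 11025, by = 25)
  expect_true(all(diff(hz_to_mel(f)) > 0))
})

test_that("MFCC of white noise concentrates energy in coefficient zero", {
  set.seed(42)
  noise <- audio_clip(rnorm(3 * 22050, sd = 0.2), 22050)
  M <- compute_mfcc(noise)
  expect_equal(dim(M$values), c(40L, 130L))
  c0 <- mean(abs(M$values[1, ]))
  rest <- mean(abs(M$values[-1, ]))
  expect_gt(c0, 5 * rest)
  expect_error(compute_mfcc(noise, n_mels = 20, n_coefficients = 40),
               "exceed")
})

test_that("chromagram folds octaves onto the A pitch class", {
  a4 <- make_tone(440, 3, 22050)
  a5 <- make_tone(880, 3, 22050)
  C4 <- compute_chromagram(a4)
  C5 <- compute_chromagram(a5)
  expect_equal(nrow(C4$values), 12L)
  a_row <- 10L  # C, C#, ..., B ordering
  expect_true(all(apply(C4$values, 2, which.max) == a_row))
  expect_true(all(apply(C5$values, 2, which.max) == a_row))
  zero <- audio_clip(numeric(3 * 22050), 22050)
  expect_true(all(compute_chromagram(zero)$values == 0))
})

test_that("image scaling reproduces the 0/128/255 worked example", {
  m <- matrix(c(0, 5, 10, 10), 2, 2)
  scaled <- fdcnet:::round_half_away(abs(m) / max(abs(m)) * 255)
  expect_equal(sort(unique(as.vector(scaled))), c(0, 128, 255))
  img <- scale_to_image(m)
  expect_s3_class(img, "feature_image")
  expect_equal(dim(img$pixels), c(128L, 128L))
})

test_that("scaling maps the maximum to 255 and ignores positive rescaling", {
  set.seed(1)
  m <- matrix(runif(257 * 130), 257, 130)
  img <- scale_to_image(m)
  expect_equal(dim(img$pixels), c(128L, 128L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  pre <- fdcnet:::round_half_away(abs(m) / max(abs(m)) * 255)
  expect_equal(max(pre), 255)
  for (c_ in c(0.01, 3, 1e6))
    expect_identical(scale_to_image(c_ * m)$pixels, img$pixels)
  # a matrix already spanning [0, 255] is a fixed point up to rounding
  m2 <- matrix(c(0, 17, 128, 255), 2, 2)
  expect_equal(sort(unique(as.vector(
    fdcnet:::round_half_away(abs(m2) / 255 * 255)))), c(0, 17, 128, 255))
  # all-zero input stays all-zero
  expect_true(all(scale_to_image(matrix(0, 10, 10))$pixels == 0))
})

test_that("feature images survive the PNG round trip bit-exactly", {
  img <- scale_to_image(compute_spectrogram(make_tone(500, 3, 22050)))
  f <- tempfile(fileext = ".png")
  write_feature_image(img, f)
  back <- read_feature_image(f)
  expect_equal(back$pixels, img$pixels)
})

test_that("extract_features indexes one image per window and kind", {
  man <- make_wav_dataset(c(healthy = 1), duration_s = 9, sample_rate = 8000)
  idx <- extract_features(man, c("spectrogram", "mfcc", "chromagram"),
                          out_dir = tempfile(), target_rate = 8000)
  expect_equal(nrow(idx), 9L)  # 3 windows x 3 kinds
  expect_true(all(file.exists(idx$image_path)))
  expect_setequal(unique(idx$kind), c("spectrogram", "mfcc", "chromagram"))
  for (p in idx$image_path[c(1, 5, 9)]) {
    px <- read_feature_image(p)$pixels
    expect_equal(dim(px), c(128L, 128L))
    expect_true(all(px >= 0 & px <= 255))
  }
  # unreadable file: failure summarised, remaining records processed
  man2 <- dataset_manifest(c(man$clip_path, "missing.wav"),
                           c("healthy", "healthy"))
  expect_warning(idx2 <- extract_features(man2, "spectrogram",
                                          out_dir = tempfile(),
                                          target_rate = 8000),
                 "failed")
  expect_equal(nrow(idx2), 3L)
})

test_that("pitch-shift covariance: shifted tones move the spectrogram peak", {
  clip <- make_tone(300, 3, 22050)
  for (s in c(-2.5, 3.5)) {
    shifted <- pitch_shift(clip, s)
    ratio <- stft_peak_hz(shifted) / stft_peak_hz(clip)
    expect_equal(ratio, 2^(s / 12), tolerance = 0.1)
  }
})
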