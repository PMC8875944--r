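#' Synthetic class profile
#'
#' Describes one class of synthetic auscultation-like audio: a harmonic
#' stack on a class-specific fundamental, amplitude-modulated at a slow
#' cyclic rate (mimicking respiratory or cardiac cycles), plus additive
#' gaussian noise. These signals exercise the pipeline end to end; they do
#' not emulate the spectral statistics of real lung or heart recordings.
#'
#' @param class_name label.
#' @param fundamental_hz base frequency (> 0).
#' @param n_harmonics number of harmonics (amplitudes 1/h).
#' @param am_rate_hz amplitude-modulation rate in Hz.
#' @param noise_level additive noise standard deviation (>= 0).
#' @param duration_range_s `(min, max)` clip duration in seconds.
#' @return an object of class `synthetic_class_profile`.
#' @export
synthetic_class_profile <- function(class_name, fundamental_hz,
                                    n_harmonics = 3L, am_rate_hz = 0.25,
                                    noise_level = 0.05,
                                    duration_range_s = c(9, 12)) {
  if (fundamental_hz <= 0) stop("fundamental_hz must be positive")
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (duration_range_s[1] > duration_range_s[2])
    stop("duration_range_s must be (min, max)")
  structure(list(class_name = as.character(class_name),
                 fundamental_hz = fundamental_hz,
                 n_harmonics = as.integer(n_harmonics),
                 am_rate_hz = am_rate_hz, noise_level = noise_level,
                 duration_range_s = duration_range_s),
            class = "synthetic_class_profile")
}

#' Default six-class profile set
#'
#' Six classes with fundamentals log-spaced over 80-1000 Hz. The two
#' lowest-pitched classes use a ~1 Hz amplitude modulation (cardiac-cycle
#' regime), the rest ~0.25 Hz (respiratory regime), so both dataset shapes
#' of the auscultation problem are exercised.
#'
#' @param class_names six class labels.
#' @param noise_level shared additive-noise level.
#' @return list of six [synthetic_class_profile] objects.
#' @export
default_synthetic_profiles <- function(class_names = paste0("class", 1:6),
                                       noise_level = 0.05) {
  stopifnot(length(class_names) == 6L)
  f0 <- exp(seq(log(80), log(1000), length.out = 6L))
  lapply(seq_len(6L), function(i)
    synthetic_class_profile(class_names[i], f0[i],
                            n_harmonics = 3L,
                            am_rate_hz = if (f0[i] < 200) 1.0 else 0.25,
                            noise_level = noise_level))
}

#' Generate one synthetic clip
#'
#' `sum_h (1/h) sin(2 pi h f0 t + phi_h)` modulated by
#' `1 + 0.5 sin(2 pi am t)`, plus gaussian noise, peak-normalized to
#' `[-1, 1]`. Deterministic per seed.
#'
#' @param profile a [synthetic_class_profile].
#' @param duration_s clip duration (within the profile's range).
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return an [audio_clip].
#' @export
generate_clip <- function(profile, duration_s = NULL, sample_rate = 22050,
                          seed = 1L) {
  stopifnot(inherits(profile, "synthetic_class_profile"))
  res <- with_seed(seed, {
    d <- duration_s %||% runif(1, profile$duration_range_s[1],
                               profile$duration_range_s[2])
    if (d < profile$duration_range_s[1] - 1e-9 ||
        d > profile$duration_range_s[2] + 1e-9)
      stop("generate_clip: duration outside the profile range")
    n <- round(d * sample_rate)
    t <- (0:(n - 1)) / sample_rate
    phases <- runif(profile$n_harmonics, 0, 2 * pi)
    x <- numeric(n)
    for (h in seq_len(profile$n_harmonics))
      x <- x + sin(2 * pi * h * profile$fundamental_hz * t + phases[h]) / h
    x <- x * (1 + 0.5 * sin(2 * pi * profile$am_rate_hz * t))
    if (profile$noise_level > 0)
      x <- x + rnorm(n, sd = profile$noise_level)
    x / max(abs(x))
  })
  audio_clip(res, sample_rate,
             source_id = sprintf("%s_seed%d", profile$class_name,
                                 as.integer(seed)))
}

#' Generate a synthetic dataset
#'
#' Writes one WAV per requested clip (durations drawn within each profile's
#' range) plus a `manifest.csv`, and returns the manifest. Per-class counts
#' are exact; the whole dataset is deterministic per seed.
#'
#' @param profiles list of [synthetic_class_profile] objects.
#' @param counts_per_class integer count per profile (same length).
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return a [dataset_manifest].
#' @export
generate_dataset <- function(profiles, counts_per_class,
                             sample_rate = 22050, seed = 1L,
                             out_dir = tempfile("synth")) {
  if (length(profiles) != length(counts_per_class))
    stop("generate_dataset: profiles and counts_per_class lengths differ")
  if (any(counts_per_class < 0)) stop("generate_dataset: negative count")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(profiles, function(p) p$class_name, "")
  paths <- character(0); labs <- character(0)
  clip_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(profiles) * max(1L, max(counts_per_class)),
                      replace = TRUE),
           nrow = length(profiles)))
  for (i in seq_along(profiles)) {
    for (j in seq_len(counts_per_class[i])) {
      clip <- generate_clip(profiles[[i]], duration_s = NULL,
                            sample_rate = sample_rate,
                            seed = clip_seeds[i, j])
      path <- file.path(out_dir, sprintf("%s_%03d.wav", labels[i], j))
      write_audio(clip, path)
      paths <- c(paths, path); labs <- c(labs, labels[i])
    }
  }
  if (length(paths) == 0L)
    return(dataset_manifest(character(), character(), character(),
                            character(), label_set = sort(labels)))
  manifest <- dataset_manifest(paths, labs, label_set = sort(labels))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
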