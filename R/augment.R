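#' Noise-mixing specification
#'
#' Configures the background-noise augmentation: a mixing weight alpha is
#' drawn uniformly from `[alpha_low, alpha_high]` and the output is
#' `(1 - alpha) * y + alpha * y_noise`. The noise source is either
#' unit-variance white gaussian noise or a random crop from a pool of
#' background-noise clips.
#'
#' @param alpha_low,alpha_high bounds of the uniform mixing weight;
#'   `0 <= alpha_low <= alpha_high < 1`. Defaults 0.001 and 0.005.
#' @param noise_source `"gaussian"` or `"clip_pool"`.
#' @param clip_pool list of [audio_clip] objects when
#'   `noise_source = "clip_pool"`.
#' @return an object of class `noise_mix_spec`.
#' @export
noise_mix_spec <- function(alpha_low = 0.001, alpha_high = 0.005,
                           noise_source = c("gaussian", "clip_pool"),
                           clip_pool = list()) {
  noise_source <- match.arg(noise_source)
  if (!(alpha_low >= 0 && alpha_low <= alpha_high && alpha_high < 1))
    stop("noise_mix_spec: need 0 <= alpha_low <= alpha_high < 1")
  structure(list(alpha_low = alpha_low, alpha_high = alpha_high,
                 noise_source = noise_source, clip_pool = clip_pool),
            class = "noise_mix_spec")
}

#' Mix background noise into a clip
#'
#' Draws `alpha ~ U[alpha_low, alpha_high]` (one draw per clip) and a noise
#' signal of identical length, and returns
#' `(1 - alpha) * y + alpha * y_noise`. Duration and sample rate are
#' unchanged; the lineage records the operator, alpha and the RNG state.
#'
#' @param clip an [audio_clip].
#' @param spec a [noise_mix_spec].
#' @param rng_state integer seed controlling the alpha and noise draws.
#' @return the noise-mixed [audio_clip].
#' @export
add_noise <- function(clip, spec = noise_mix_spec(), rng_state = 1L) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "noise_mix_spec"))
  n <- length(clip$samples)
  res <- with_seed(rng_state, {
    alpha <- runif(1, spec$alpha_low, spec$alpha_high)
    y_noise <- if (spec$noise_source == "gaussian") {
      rnorm(n)
    } else {
      if (length(spec$clip_pool) == 0L)
        stop("add_noise: noise_source = 'clip_pool' but the pool is empty")
      src <- spec$clip_pool[[sample.int(length(spec$clip_pool), 1L)]]$samples
      if (length(src) < n) src <- rep_len(src, n)
      start <- sample.int(length(src) - n + 1L, 1L)
      src[start:(start + n - 1L)]
    }
    list(alpha = alpha, y_noise = y_noise)
  })
  audio_clip((1 - res$alpha) * clip$samples + res$alpha * res$y_noise,
             clip$sample_rate, clip$source_id,
             c(clip$lineage, sprintf("noise-a%.6f-s%d", res$alpha,
                                     as.integer(rng_state))))
}

# Phase vocoder: time-scale modification at constant pitch. Output length is
# approximately length(x) / rate. Classic magnitude-interpolation /
# phase-accumulation formulation over a 4x-overlapping Hann STFT.
phase_vocoder <- function(x, rate, n_fft = 2048L) {
  n_fft <- min(n_fft, max(64L, 2^floor(log2(length(x)))))
  hop <- n_fft %/% 4L
  n_out <- max(1L, round(length(x) / rate))
  # center-pad so analysis frames cover the signal ends
  S <- stft(c(numeric(n_fft %/% 2L), x, numeric(n_fft %/% 2L)),
            n_fft, hop, n_fft)
  n_bins <- nrow(S)
  steps <- seq(0, ncol(S) - 1L, by = rate)
  phi_advance <- hop * 2 * pi * (0:(n_bins - 1L)) / n_fft
  out <- matrix(0+0i, n_bins, length(steps))
  phase <- Arg(S[, 1L])
  for (j in seq_along(steps)) {
    t0 <- floor(steps[j])
    frac <- steps[j] - t0
    c1 <- S[, t0 + 1L]
    c2 <- if (t0 + 2L <= ncol(S)) S[, t0 + 2L] else c1
    mag <- (1 - frac) * Mod(c1) + frac * Mod(c2)
    out[, j] <- mag * exp(1i * phase)
    dphi <- Arg(c2) - Arg(c1) - phi_advance
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + phi_advance + dphi
  }
  y <- istft(out, n_fft, hop, n_fft)[-seq_len(n_fft %/% 2L)]
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, numeric(n_out - length(y)))
}

#' Time-stretch a clip at constant pitch
#'
#' Phase-vocoder stretching: the output duration is `duration / factor`
#' (within one STFT hop), the pitch is preserved, and the sample rate is
#' unchanged. `factor > 1` shortens, `factor < 1` lengthens.
#'
#' @param clip an [audio_clip].
#' @param factor positive stretch factor.
#' @return the stretched [audio_clip].
#' @export
time_stretch <- function(clip, factor) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("time_stretch: 'factor' must be a positive number")
  y <- if (factor == 1) clip$samples else phase_vocoder(clip$samples, factor)
  audio_clip(y, clip$sample_rate, clip$source_id,
             c(clip$lineage, sprintf("stretch-%g", factor)))
}

#' Pitch-shift a clip at constant duration
#'
#' Shifts all spectral content by `2^(semitones/12)` while keeping the
#' duration constant (within one STFT hop): the clip is phase-vocoder
#' stretched by the inverse factor and then resampled back to the original
#' length, which scales every frequency by the shift factor.
#'
#' @param clip an [audio_clip].
#' @param semitones shift in semitones; positive raises the pitch.
#' @return the shifted [audio_clip].
#' @export
pitch_shift <- function(clip, semitones) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(semitones) || length(semitones) != 1L || !is.finite(semitones))
    stop("pitch_shift: 'semitones' must be a finite number")
  if (semitones == 0) {
    y <- clip$samples
  } else {
    r <- 2^(semitones / 12)
    y1 <- phase_vocoder(clip$samples, 1 / r)
    y <- resample_samples(y1, clip$sample_rate, clip$sample_rate / r)
  }
  audio_clip(y, clip$sample_rate, clip$source_id,
             c(clip$lineage, sprintf("shift-%g", semitones)))
}

#' Dataset-level augmentation policy
#'
#' The default policy emits ten augmented copies per original recording:
#' four time-stretched (factors 0.5, 0.7, 1.2, 1.5), four pitch-shifted
#' (-3.5, -2.5, 2.5, 3.5 semitones) and two independent noise mixes, so an
#' augmented dataset holds eleven files per original (originals retained).
#'
#' @param stretch_factors positive stretch factors (may be empty).
#' @param shift_semitones pitch shifts in semitones (may be empty).
#' @param noise_copies number of independent noise-mix variants (>= 0).
#' @param noise_spec a [noise_mix_spec] used for the noise copies.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(stretch_factors = c(0.5, 0.7, 1.2, 1.5),
                                shift_semitones = c(-3.5, -2.5, 2.5, 3.5),
                                noise_copies = 2L,
                                noise_spec = noise_mix_spec()) {
  if (any(stretch_factors <= 0))
    stop("augmentation_policy: stretch factors must be positive")
  if (noise_copies < 0) stop("augmentation_policy: noise_copies must be >= 0")
  structure(list(stretch_factors = as.numeric(stretch_factors),
                 shift_semitones = as.numeric(shift_semitones),
                 noise_copies = as.integer(noise_copies),
                 noise_spec = noise_spec),
            class = "augmentation_policy")
}

policy_tags <- function(policy) {
  c(sprintf("stretch-%g", policy$stretch_factors),
    sprintf("shift-%g", policy$shift_semitones),
    if (policy$noise_copies > 0) sprintf("noise-%d", seq_len(policy$noise_copies)))
}

#' Augment every recording in a manifest
#'
#' Applies the policy's operators to each original record and returns a
#' manifest holding, per original, the original plus one record per policy
#' tag (`1 + length(stretch) + length(shift) + noise_copies` records; 11 with
#' the default tenfold policy). Labels and split assignments are inherited,
#' so augmented copies can never straddle the split of their original.
#' Augmented files are written as `<source_id>__<tag>.wav` under `out_dir`.
#'
#' @param manifest a [dataset_manifest] of original recordings.
#' @param policy an [augmentation_policy].
#' @param seed integer seed driving all noise draws.
#' @param out_dir directory for the augmented WAV files.
#' @param target_rate sample rate at which clips are read and processed.
#' @param render if `FALSE`, only the augmented manifest is computed (no
#'   audio is read or written) — useful to audit the bookkeeping of a policy
#'   on a large manifest.
#' @return the augmented [dataset_manifest].
#' @export
augment_dataset <- function(manifest, policy = augmentation_policy(),
                            seed = 1L, out_dir = tempfile("aug"),
                            target_rate = 22050, render = TRUE) {
  stopifnot(inherits(manifest, "dataset_manifest"),
            inherits(policy, "augmentation_policy"))
  tags <- policy_tags(policy)
  if (render) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
      stop("augment_dataset: out_dir not writable: ", out_dir)
  }
  src <- manifest_source_id(manifest)
  rng_states <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L,
               nrow(manifest) * max(1L, policy$noise_copies), replace = TRUE),
    nrow = nrow(manifest)))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    out_paths <- file.path(out_dir, sprintf("%s__%s.wav", src[i], tags))
    if (render && length(tags)) {
      clip <- read_audio(rec$clip_path, target_rate)
      k <- 0L
      for (f in policy$stretch_factors) {
        k <- k + 1L; write_audio(time_stretch(clip, f), out_paths[k])
      }
      for (s in policy$shift_semitones) {
        k <- k + 1L; write_audio(pitch_shift(clip, s), out_paths[k])
      }
      for (j in seq_len(policy$noise_copies)) {
        k <- k + 1L
        write_audio(add_noise(clip, policy$noise_spec, rng_states[i, j]),
                    out_paths[k])
      }
    }
    rows[[i]] <- data.frame(
      clip_path = c(rec$clip_path, out_paths),
      label = rec$label,
      split = rec$split,
      augmentation_tag = c(rec$augmentation_tag, tags),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  dataset_manifest(out$clip_path, out$label, out$split, out$augmentation_tag,
                   label_set = label_set(manifest))
}
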