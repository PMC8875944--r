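# Shared fixtures: tones, tiny WAV datasets, manifests with prescribed
# class counts, and an independent parameter-counting oracle.

make_tone <- function(freq, duration_s = 3, sample_rate = 22050,
                      amplitude = 0.8, id = sprintf("tone%g", freq)) {
  t <- (0:(round(duration_s * sample_rate) - 1)) / sample_rate
  audio_clip(amplitude * sin(2 * pi * freq * t), sample_rate, source_id = id)
}

# write n tiny wav files per label and return a manifest
make_wav_dataset <- function(labels_counts, dir = tempfile("wavs"),
                             duration_s = 0.6, sample_rate = 8000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0); labs <- character(0)
  freqs <- seq(200, 900, length.out = length(labels_counts))
  for (i in seq_along(labels_counts)) {
    lab <- names(labels_counts)[i]
    for (j in seq_len(labels_counts[[i]])) {
      p <- file.path(dir, sprintf("%s_%02d.wav", lab, j))
      write_audio(make_tone(freqs[i] + j, duration_s, sample_rate), p)
      paths <- c(paths, p); labs <- c(labs, lab)
    }
  }
  dataset_manifest(paths, labs)
}

# a manifest of the given per-class counts with fake paths (no audio);
# enough for split/augmentation bookkeeping checks
make_count_manifest <- function(counts, labels = names(counts)) {
  paths <- unlist(lapply(seq_along(counts), function(i)
    sprintf("%s_%04d.wav", labels[i], seq_len(counts[i]))))
  dataset_manifest(paths, rep(labels, counts))
}

# Independent parameter-count oracle: allocates every weight tensor a layer
# would hold and counts elements, with its own shape bookkeeping.
oracle_count_params <- function(spec) {
  trainable <- 0; non_trainable <- 0
  walk <- function(layers, shape) {
    for (l in layers) {
      if (l$kind == "conv2d") {
        w <- array(0, c(l$kernel[1], l$kernel[2], shape[3], l$filters))
        trainable <<- trainable + length(w) + l$filters
        hw <- if (l$padding == "same") shape[1:2]
              else shape[1:2] - l$kernel + 1
        shape <- c(hw, l$filters)
      } else if (l$kind == "batchnorm") {
        ch <- shape[length(shape)]
        trainable <<- trainable + length(numeric(ch)) * 2       # scale, shift
        non_trainable <<- non_trainable + length(numeric(ch)) * 2  # run stats
      } else if (l$kind == "dense") {
        w <- matrix(0, l$units, shape[1])
        trainable <<- trainable + length(w) + l$units
        shape <- l$units
      } else if (l$kind == "maxpool2d") {
        hw <- if (l$padding == "same") ceiling(shape[1:2] / l$pool)
              else floor((shape[1:2] - l$pool) / l$pool) + 1
        shape <- c(hw, shape[3])
      } else if (l$kind == "flatten") {
        shape <- prod(shape)
      } else if (l$kind == "global_avg_pool") {
        shape <- shape[3]
      }
    }
    shape
  }
  widths <- vapply(spec$branches, function(b) walk(b, spec$input_shape)[1], 0)
  if (!is.null(spec$fusion_head)) walk(spec$fusion_head[-1], sum(widths))
  list(total = trainable + non_trainable, trainable = trainable,
       non_trainable = non_trainable)
}

# random small single-branch architecture on a small input, for
# property-style cross-checks of the parameter accounting
random_small_arch <- function() {
  layers <- list()
  shape <- c(16L, 16L, 1L)
  for (i in seq_len(sample(1:3, 1))) {
    pad <- sample(c("valid", "same"), 1)
    k <- sample(1:3, 1)
    layers <- c(layers, list(
      layer_spec("conv2d", filters = sample(1:8, 1), kernel = c(k, k),
                 padding = pad,
                 activation = sample(c("relu", "none"), 1))))
    if (runif(1) < 0.5) layers <- c(layers, list(layer_spec("batchnorm")))
    if (runif(1) < 0.5)
      layers <- c(layers, list(
        layer_spec("maxpool2d", pool = c(2L, 2L),
                   padding = sample(c("valid", "same"), 1))))
  }
  n_classes <- sample(2:5, 1)
  tail <- if (runif(1) < 0.5) {
    list(layer_spec("flatten"),
         layer_spec("dense", units = sample(2:10, 1)),
         layer_spec("activation", activation = "relu"),
         layer_spec("dense", units = n_classes),
         layer_spec("activation", activation = "softmax"))
  } else {
    list(layer_spec("global_avg_pool"),
         layer_spec("dense", units = n_classes),
         layer_spec("activation", activation = "softmax"))
  }
  tryCatch(
    architecture_spec(sprintf("rand%d", sample.int(1e6, 1)), c(16L, 16L, 1L),
                      list(c(layers, tail)), n_classes = n_classes),
    error = function(e) random_small_arch())  # reroll infeasible geometries
}

stft_peak_hz <- function(clip) {
  S <- compute_spectrogram(if (duration_seconds(clip) >= 3)
    window_clip(clip)[[1]] else clip)
  n_fft <- 2^ceiling(log2(round(0.023 * clip$sample_rate)))
  freqs <- (0:(n_fft %/% 2)) * clip$sample_rate / n_fft
  freqs[which.max(rowMeans(S$values))]
}
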