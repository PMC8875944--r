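test_that("WAV round trip preserves samples to 16-bit precision", {
  clip <- make_tone(440, duration_s = 0.5)
  f <- tempfile(fileext = ".wav")
  write_audio(clip, f)
  back <- read_audio(f, target_rate = clip$sample_rate)
  expect_equal(length(back$samples), length(clip$samples))
  expect_lt(max(abs(back$samples - clip$samples)), 1 / 32000)
  expect_identical(back$lineage, character(0))
})

test_that("read_audio resamples and the length follows the rate ratio", {
  t <- (0:44099) / 44100
  f <- tempfile(fileext = ".wav")
  write_audio(audio_clip(0.5 * sin(2 * pi * 300 * t), 44100), f)
  clip <- read_audio(f, target_rate = 22050)
  expect_lte(abs(length(clip$samples) - 22050), 1)
  # dominant frequency survives resampling
  expect_lt(abs(stft_peak_hz(clip) - 300), 22050 / 512 + 1)
})

test_that("stereo input is averaged to mono", {
  # hand-build a 2-channel PCM16 WAV with c1 = 0.5, c2 = -0.25 constants
  f <- tempfile(fileext = ".wav")
  n <- 1000L
  c1 <- as.integer(round(0.5 * 32767))
  c2 <- as.integer(round(-0.25 * 32767))
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * 4L), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(8000L, 32000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n * 4L, con, size = 4, endian = "little")
  writeBin(rep(c(c1, c2), n), con, size = 2, endian = "little")
  close(con)
  clip <- read_audio(f, 8000)
  expect_equal(length(clip$samples), n)
  expect_equal(unique(round(clip$samples, 4)), round((0.5 - 0.25) / 2, 4),
               tolerance = 1e-3)
})

test_that("read_audio rejects missing and corrupt files", {
  expect_error(read_audio(tempfile()), "no such file")
  bad <- tempfile(fileext = ".wav")
  writeLines("not audio at all", bad)
  expect_error(read_audio(bad), "decode")
})

test_that("manifest load/save round trip with defaults and validation", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("clip_path,label", "a.wav,COPD", "b.wav,URTI"), f)
  m <- load_manifest(f)
  expect_s3_class(m, "dataset_manifest")
  expect_equal(nrow(m), 2L)
  expect_identical(label_set(m), c("COPD", "URTI"))
  expect_identical(unique(m$split), "unassigned")
  expect_identical(unique(m$augmentation_tag), "original")

  f2 <- tempfile(fileext = ".csv")
  write_manifest(m, f2)
  expect_identical(as.data.frame(load_manifest(f2)), as.data.frame(m))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("clip_path,label", "a.wav,COPD", "b.wav,"), bad)
  expect_error(load_manifest(bad), "row 2")
  expect_error(load_manifest(tempfile()), "no such file")
  hdr <- tempfile(fileext = ".csv")
  writeLines(c("path,class", "a.wav,COPD"), hdr)
  expect_error(load_manifest(hdr), "header")
})

test_that("a manifest with the lung-dataset class imbalance loads intact", {
  counts <- c(Bronchiectasis = 29, COPD = 785, Health = 35, LRTI = 2,
              Pneumonia = 37, URTI = 31)
  m <- make_count_manifest(counts)
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- load_manifest(f)
  expect_equal(nrow(m2), 919L)
  expect_equal(as.vector(table(m2$label)[names(counts)]),
               unname(counts))
})

test_that("split_dataset hits exact fractions and is deterministic", {
  m <- make_count_manifest(c(a = 100))
  s <- split_dataset(m, c(0.64, 0.16, 0.20), seed = 7, stratified = FALSE,
                     group_by_source = FALSE)
  expect_equal(as.vector(table(s$split)[c("train", "val", "test")]),
               c(64L, 16L, 20L))
  # partition: every record in exactly one split
  expect_true(all(s$split %in% c("train", "val", "test")))
  s2 <- split_dataset(m, c(0.64, 0.16, 0.20), seed = 7, stratified = FALSE,
                      group_by_source = FALSE)
  expect_identical(s$split, s2$split)
  s3 <- split_dataset(m, c(0.64, 0.16, 0.20), seed = 8, stratified = FALSE,
                      group_by_source = FALSE)
  expect_false(identical(s$split, s3$split))
})

test_that("stratified splitting gives each label its own 64/16/20", {
  m <- make_count_manifest(c(x = 50, y = 50))
  s <- split_dataset(m, c(0.64, 0.16, 0.20), seed = 1, stratified = TRUE,
                     group_by_source = FALSE)
  for (lab in c("x", "y")) {
    tab <- table(s$split[s$label == lab])
    expect_equal(as.vector(tab[c("train", "val", "test")]), c(32L, 8L, 10L))
  }
})

test_that("a single record lands in train (largest fraction wins)", {
  m <- make_count_manifest(c(only = 1))
  s <- suppressWarnings(split_dataset(m, seed = 1))
  expect_identical(s$split, "train")
  expect_warning(split_dataset(m, seed = 1), "fewer records")
})

test_that("group_by_source keeps augmented copies with their original", {
  paths <- c("rec1.wav", "rec1__stretch-0.5.wav", "rec1__noise-1.wav",
             "rec2.wav", "rec2__stretch-0.5.wav", "rec2__noise-1.wav",
             "rec3.wav", "rec4.wav", "rec5.wav", "rec6.wav")
  m <- dataset_manifest(paths, rep("a", 10),
                        augmentation_tag = ifelse(grepl("__", paths),
                                                  "aug", "original"))
  s <- split_dataset(m, seed = 3, stratified = FALSE, group_by_source = TRUE)
  for (src in c("rec1", "rec2")) {
    grp <- s$split[startsWith(basename(s$clip_path), src)]
    expect_length(unique(grp), 1L)
  }
  # no source appears in more than one split
  tab <- table(sub("__.*$", "", basename(s$clip_path)), s$split)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("split fractions are validated", {
  m <- make_count_manifest(c(a = 10))
  expect_error(split_dataset(m, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(split_dataset(m, c(1, -0.5, 0.5)), "positive")
})
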