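#' Construct a dataset manifest
#'
#' A manifest is an ordered table of recordings with columns `clip_path`,
#' `label`, `split` (one of `train`, `val`, `test`, `unassigned`) and
#' `augmentation_tag` (`original` or an operator tag such as `stretch-0.5`).
#' The ordered set of class names is carried in the `label_set` attribute.
#'
#' @param clip_path character vector of audio file paths.
#' @param label class label per record.
#' @param split split assignment per record (default `unassigned`).
#' @param augmentation_tag augmentation tag per record (default `original`).
#' @param label_set optional ordered class names; defaults to the sorted set
#'   of distinct labels.
#' @return a `data.frame` of class `dataset_manifest`.
#' @export
dataset_manifest <- function(clip_path, label,
                             split = "unassigned",
                             augmentation_tag = "original",
                             label_set = NULL) {
  df <- data.frame(clip_path = as.character(clip_path),
                   label = as.character(label),
                   split = as.character(split),
                   augmentation_tag = as.character(augmentation_tag),
                   stringsAsFactors = FALSE)
  bad_split <- setdiff(unique(df$split), c("train", "val", "test", "unassigned"))
  if (length(bad_split))
    stop("dataset_manifest: invalid split value(s): ",
         paste(bad_split, collapse = ", "))
  if (any(!nzchar(df$label)))
    stop("dataset_manifest: empty label at row ",
         paste(which(!nzchar(df$label)), collapse = ", "))
  if (is.null(label_set)) label_set <- sort(unique(df$label))
  if (!all(df$label %in% label_set))
    stop("dataset_manifest: label(s) outside label_set: ",
         paste(setdiff(unique(df$label), label_set), collapse = ", "))
  attr(df, "label_set") <- as.character(label_set)
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d records, %d classes\n",
              nrow(x), length(attr(x, "label_set"))))
  print(table(label = x$label, split = x$split))
  invisible(x)
}

#' Ordered class names of a manifest
#' @param manifest a [dataset_manifest].
#' @return character vector of class names.
#' @export
label_set <- function(manifest) attr(manifest, "label_set")

#' Load a manifest from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming at least
#' `clip_path` and `label`; optional `split` and `augmentation_tag` columns
#' default to `unassigned` / `original`.
#'
#' @param path CSV file path.
#' @param label_set optional explicit ordered class names.
#' @return a [dataset_manifest].
#' @export
load_manifest <- function(path, label_set = NULL) {
  if (!file.exists(path)) stop("load_manifest: no such file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
                 error = function(e) stop("load_manifest: cannot parse '",
                                          path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("load_manifest: empty manifest: ", path)
  if (!all(c("clip_path", "label") %in% names(df)))
    stop("load_manifest: header must contain clip_path,label (got: ",
         paste(names(df), collapse = ","), ")")
  if (any(is.na(df$label) | !nzchar(df$label)))
    stop("load_manifest: empty label at data row ",
         paste(which(is.na(df$label) | !nzchar(df$label)), collapse = ", "))
  dataset_manifest(df$clip_path, df$label,
                   split = if ("split" %in% names(df)) df$split else "unassigned",
                   augmentation_tag = if ("augmentation_tag" %in% names(df))
                     df$augmentation_tag else "original",
                   label_set = label_set)
}

#' Write a manifest to CSV
#'
#' Serializes back into the schema read by [load_manifest]; the row order is
#' preserved so equal manifests produce byte-identical files.
#'
#' @param manifest a [dataset_manifest].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  write.csv(as.data.frame(manifest)[, c("clip_path", "label", "split",
                                        "augmentation_tag")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# A recording identity that survives augmentation: augmented files are named
# <source>__<op>-<param>.wav, so stripping the "__..." suffix recovers the
# original recording for leak-free grouping.
manifest_source_id <- function(manifest) {
  sub("__[^_].*$", "", tools::file_path_sans_ext(basename(manifest$clip_path)))
}

#' Assign train/validation/test splits
#'
#' Deterministically partitions a manifest into train/val/test. With
#' `stratified`, per-label counts follow the target fractions by
#' largest-remainder allocation (within one record per label). With
#' `group_by_source`, all records sharing an originating recording (clips and
#' their augmented copies) are kept in the same split, so the test material is
#' never derived from training recordings.
#'
#' @param manifest a [dataset_manifest].
#' @param fractions numeric `(train, val, test)`; positive, summing to 1.
#' @param seed integer seed; identical inputs yield identical assignments.
#' @param stratified stratify by label (default TRUE).
#' @param group_by_source keep augmented copies with their original
#'   (default TRUE).
#' @return the manifest with the `split` column filled in.
#' @export
split_dataset <- function(manifest, fractions = c(0.64, 0.16, 0.20),
                          seed = 1L, stratified = TRUE,
                          group_by_source = TRUE) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (nrow(manifest) == 0L) stop("split_dataset: empty manifest")
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("split_dataset: 'fractions' must be three positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split_dataset: 'fractions' must sum to 1")
  splits <- c("train", "val", "test")

  unit <- if (group_by_source) manifest_source_id(manifest)
          else as.character(seq_len(nrow(manifest)))
  # one label per unit (augmented copies inherit their original's label)
  unit_label <- tapply(manifest$label, unit, function(x) x[[1]])
  strata <- if (stratified) split(names(unit_label), unname(unit_label))
            else list(all = names(unit_label))

  assignment <- character(0)
  with_seed(seed, {
    for (stratum in strata) {
      n <- length(stratum)
      if (stratified && n < 3L)
        warning("split_dataset: a label has fewer records (", n,
                ") than splits; best-effort assignment")
      base <- floor(fractions * n)
      rem <- fractions * n - base
      # largest remainder; ties broken by split order via stable sort
      extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
      counts <- base
      counts[extra] <- counts[extra] + 1L
      shuffled <- if (n > 1L) sample(stratum) else stratum
      lab <- rep(splits, counts)
      names(lab) <- shuffled
      assignment <- c(assignment, lab)
    }
  })
  manifest$split <- unname(assignment[unit])
  manifest
}
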