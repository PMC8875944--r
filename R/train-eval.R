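#' Training configuration
#'
#' @param epochs number of training epochs (>= 1). Reference regimes: 50
#'   epochs at batch 64 for original-size datasets, 30 epochs at batch 128
#'   for tenfold-augmented ones.
#' @param batch_size mini-batch size (>= 1).
#' @param loss only `"categorical_cross_entropy"`.
#' @param optimizer only `"adam"`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param balance `"none"` or `"oversample"` (see [balance_training_set]).
#' @param early_stop optional patience (epochs without validation-loss
#'   improvement before stopping; best weights are restored).
#' @param stop_at_val_accuracy optional accuracy plateau: stop once the
#'   validation accuracy has held at or above this level for three
#'   consecutive epochs.
#' @param reduce_lr_patience optional: halve the learning rate (down to
#'   1/16 of the initial value) whenever the validation loss has not
#'   improved for this many epochs.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 128L,
                         loss = "categorical_cross_entropy",
                         optimizer = "adam", learning_rate = 1e-3,
                         seed = 1L, balance = c("none", "oversample"),
                         early_stop = NULL, stop_at_val_accuracy = NULL,
                         reduce_lr_patience = NULL) {
  if (!is.numeric(epochs) || epochs < 1) stop("train_config: epochs >= 1")
  if (!is.numeric(batch_size) || batch_size < 1)
    stop("train_config: batch_size >= 1")
  stopifnot(loss == "categorical_cross_entropy", optimizer == "adam")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 optimizer = optimizer, learning_rate = learning_rate,
                 seed = as.integer(seed), balance = match.arg(balance),
                 early_stop = if (!is.null(early_stop)) as.integer(early_stop),
                 stop_at_val_accuracy = stop_at_val_accuracy,
                 reduce_lr_patience = if (!is.null(reduce_lr_patience))
                   as.integer(reduce_lr_patience)),
            class = "train_config")
}

#' Oversample minority classes in the training split
#'
#' Duplicates minority-class rows of a feature index (drawn with
#' replacement, seeded) until every class matches the majority count —
#' sample replication, not feature interpolation. Only rows with
#' `split == "train"` are touched; validation and test rows pass through
#' unchanged.
#'
#' @param index feature index (from [extract_features]).
#' @param mode `"none"` (identity) or `"oversample"`.
#' @param seed integer seed.
#' @return the balanced feature index.
#' @export
balance_training_set <- function(index, mode = c("oversample", "none"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "none") return(index)
  train <- index[index$split == "train", , drop = FALSE]
  rest <- index[index$split != "train", , drop = FALSE]
  counts <- table(train$label)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    warning("balance_training_set: no training rows")
    return(index)
  }
  target <- max(counts)
  extra <- list()
  with_seed(seed, {
    for (lab in names(counts)) {
      rows <- which(train$label == lab)
      need <- target - length(rows)
      if (need > 0)
        extra[[lab]] <- train[sample(rows, need, replace = TRUE), ,
                              drop = FALSE]
    }
  })
  out <- rbind(train, do.call(rbind, extra), rest)
  rownames(out) <- NULL
  out
}

# Load the images of one index split as an (H, W, 1, N) array in [0, 1].
load_image_array <- function(index_rows) {
  n <- nrow(index_rows)
  if (n == 0L) stop("no images in the requested split")
  x <- array(0, c(128L, 128L, 1L, n))
  for (i in seq_len(n))
    x[, , 1L, i] <- read_feature_image(index_rows$image_path[i])$pixels / 255
  x
}

#' Train an architecture on a feature index
#'
#' Compiles the architecture, loads the train/val images of the index, and
#' optimizes the categorical cross-entropy with Adam. The history records
#' per-epoch training and validation loss and accuracy. Runs are
#' reproducible for a given config seed.
#'
#' @param spec an [architecture_spec].
#' @param index feature index restricted to one feature kind, with `train`
#'   and `val` rows.
#' @param config a [train_config].
#' @param class_levels optional explicit label ordering; defaults to the
#'   sorted labels of the index.
#' @param verbose print per-epoch progress.
#' @return an object of class `fdc_model` with elements `compiled`,
#'   `history`, `classes`, `config`.
#' @export
train_model <- function(spec, index, config = train_config(),
                        class_levels = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(config, "train_config"))
  if (length(unique(index$kind)) > 1L)
    stop("train_model: index mixes feature kinds; filter to one")
  classes <- class_levels %||% sort(unique(index$label))
  if (spec$n_classes != length(classes))
    stop("train_model: spec has ", spec$n_classes, " classes but the index ",
         length(classes))
  tr <- index[index$split == "train", , drop = FALSE]
  va <- index[index$split == "val", , drop = FALSE]
  if (nrow(tr) == 0L || nrow(va) == 0L)
    stop("train_model: index needs train and val rows")
  x_tr <- load_image_array(tr)
  if (!all(dim(x_tr)[1:3] == spec$input_shape))
    stop("train_model: image shape does not match the architecture input")
  y_tr <- match(tr$label, classes)
  x_va <- load_image_array(va)
  y_va <- match(va$label, classes)

  model <- compile_model(spec, seed = config$seed)
  opt <- adam_init(model$params)
  n <- length(y_tr)
  history <- data.frame()
  best <- list(loss = Inf, params = NULL, state = NULL, epoch = 0L)
  wait <- 0L
  plateau <- 0L
  lr <- config$learning_rate
  lr_wait <- 0L
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      tr_loss <- 0; tr_correct <- 0
      for (i0 in seq(1L, n, by = config$batch_size)) {
        idx <- perm[i0:min(i0 + config$batch_size - 1L, n)]
        xb <- x_tr[, , , idx, drop = FALSE]
        yb <- y_tr[idx]
        fwd <- engine_forward(model, xb, training = TRUE)
        model$state <- fwd$state
        loss <- engine_loss(model, fwd$probs, yb)
        grads <- engine_backward(model, fwd, yb)
        step <- adam_step(model$params, grads, opt, lr = lr)
        model$params <- step$params
        opt <- step$opt
        tr_loss <- tr_loss + loss * length(idx)
        tr_correct <- tr_correct +
          sum(apply(fwd$probs, 2, which.max) == yb)
      }
      model <- engine_recalibrate_bn(model, x_tr,
                                     chunk = max(32L, config$batch_size))
      pv <- engine_predict_probs(model, x_va)
      val_loss <- engine_loss(model, pv, y_va)
      val_acc <- mean(apply(pv, 2, which.max) == y_va)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = tr_loss / n, accuracy = tr_correct / n,
        val_loss = val_loss, val_accuracy = val_acc))
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
                        epoch, config$epochs, tr_loss / n, tr_correct / n,
                        val_loss, val_acc))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = model$params,
                     state = model$state, epoch = epoch)
        wait <- 0L
        lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
      }
      if (!is.null(config$reduce_lr_patience) &&
          lr_wait >= config$reduce_lr_patience &&
          lr > config$learning_rate / 16) {
        lr <- lr / 2
        lr_wait <- 0L
      }
      if (!is.null(config$early_stop) && wait >= config$early_stop) break
      plateau <- if (!is.null(config$stop_at_val_accuracy) &&
                     val_acc >= config$stop_at_val_accuracy)
        plateau + 1L else 0L
      if (plateau >= 3L) break
    }
  })
  if (!is.null(config$early_stop) && !is.null(best$params)) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(list(compiled = model, history = history, classes = classes,
                 config = config),
            class = "fdc_model")
}

#' @export
print.fdc_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<fdc_model> %s, %d classes, %d epochs (final val_acc %.3f)\n",
              x$compiled$arch$name, length(x$classes), nrow(x$history),
              h$val_accuracy))
  invisible(x)
}

#' Predict class labels for feature images
#'
#' @param object a trained [train_model] result.
#' @param index feature index rows to predict.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return character labels, or a classes x n probability matrix.
#' @export
predict.fdc_model <- function(object, index, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- load_image_array(index)
  p <- engine_predict_probs(object$compiled, x)
  rownames(p) <- object$classes
  if (type == "prob") p else object$classes[apply(p, 2, which.max)]
}

#' Evaluate a trained model on one split
#'
#' Reports per-class accuracy (`correct / support`) with supports and the
#' support-weighted average accuracy
#' `sum(support_i * acc_i) / sum(support_i)`, the primary figure for
#' imbalanced test sets; the unweighted (macro) mean over present classes is
#' reported alongside. Classes absent from the split appear with support 0
#' and accuracy `NA` and are excluded from both averages.
#'
#' @param model a trained [train_model] result.
#' @param index feature index.
#' @param split which split to evaluate (default `"test"`).
#' @return an object of class `evaluation_report`.
#' @export
evaluate_model <- function(model, index, split = "test") {
  rows <- index[index$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("evaluate_model: split '", split, "' is empty")
  pred <- predict(model, rows)
  per_class <- data.frame(class = model$classes,
                          support = 0L, accuracy = NA_real_)
  for (i in seq_along(model$classes)) {
    sel <- rows$label == model$classes[i]
    per_class$support[i] <- sum(sel)
    if (any(sel))
      per_class$accuracy[i] <- mean(pred[sel] == model$classes[i])
  }
  present <- per_class$support > 0
  weighted <- sum(per_class$support[present] * per_class$accuracy[present]) /
    sum(per_class$support[present])
  structure(list(per_class = per_class, weighted_average = weighted,
                 macro_average = mean(per_class$accuracy[present]),
                 split = split, feature_kind = unique(rows$kind),
                 model = model$compiled$arch$name),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s on %s (%s)\n", x$model, x$split,
              paste(x$feature_kind, collapse = "+")))
  df <- x$per_class
  df$accuracy <- sprintf("%.3f", df$accuracy)
  print(df, row.names = FALSE)
  cat(sprintf("W. AVG: %.4f (macro %.4f)\n", x$weighted_average,
              x$macro_average))
  invisible(x)
}

#' Serialize an evaluation report
#' @param report an `evaluation_report`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(
    list(model = report$model, split = report$split,
         feature_kind = report$feature_kind,
         per_class = report$per_class,
         weighted_average = report$weighted_average,
         macro_average = report$macro_average),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run one cell of the model-by-feature experiment grid
#'
#' Orchestrates split (if unassigned), optional training-set balancing,
#' training, and test evaluation of one architecture on one feature kind.
#'
#' @param index feature index covering the requested kind (all splits).
#' @param feature_kind `"spectrogram"`, `"mfcc"` or `"chromagram"`.
#' @param model_name `"fdc1"`, `"fdc2"`, `"fdc3"` or `"fdcfs"`.
#' @param config a [train_config].
#' @param out_dir optional directory to persist the history and report.
#' @return list with `model` ([train_model] result) and `report`
#'   ([evaluate_model] result).
#' @export
run_experiment <- function(index, feature_kind, model_name,
                           config = train_config(), out_dir = NULL) {
  idx <- index[index$kind == feature_kind, , drop = FALSE]
  if (nrow(idx) == 0L)
    stop("run_experiment: no '", feature_kind, "' rows in the index")
  if (config$balance == "oversample")
    idx <- balance_training_set(idx, "oversample", seed = config$seed)
  classes <- sort(unique(idx$label))
  spec <- build_architecture(model_name, n_classes = length(classes))
  model <- train_model(spec, idx, config, class_levels = classes)
  report <- evaluate_model(model, idx, split = "test")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(model$history,
              file.path(out_dir, sprintf("%s_%s_history.csv", model_name,
                                         feature_kind)), row.names = FALSE)
    write_evaluation_report(report,
                            file.path(out_dir, sprintf("%s_%s_report.json",
                                                       model_name,
                                                       feature_kind)))
  }
  list(model = model, report = report)
}
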