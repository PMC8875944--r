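#' Declarative layer specification
#'
#' One entry of an architecture: a layer kind plus the hyper-parameters that
#' determine its output shape and parameter count. Builders assemble these
#' into an [architecture_spec]; nothing is allocated until a model is
#' compiled for training.
#'
#' @param kind one of `conv2d`, `maxpool2d`, `batchnorm`, `activation`,
#'   `dropout`, `flatten`, `dense`, `global_avg_pool`, `concatenate`, `input`.
#' @param filters number of convolution filters (conv2d only).
#' @param units number of output units (dense only).
#' @param kernel `(h, w)` receptive field (conv2d).
#' @param pool `(h, w)` pool size; the pool stride equals the pool size.
#' @param padding `"valid"` or `"same"`. For conv2d, `same` preserves the
#'   spatial size (stride 1); for maxpool2d, `same` uses ceiling semantics
#'   (`ceil(in/pool)`, edge windows padded) while `valid` drops incomplete
#'   windows (`floor((in - pool)/pool) + 1`).
#' @param activation `"relu"`, `"softmax"` or `"none"`. Convolutions may
#'   carry an inline ReLU; dense layers are linear, with explicit
#'   `activation` layers following them.
#' @param rate dropout rate in `[0, 1)` (dropout only).
#' @param l2 L2 weight-penalty coefficient (0 = none).
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(kind, filters = NULL, units = NULL, kernel = NULL,
                       pool = NULL, padding = "valid", activation = "none",
                       rate = 0, l2 = 0) {
  kinds <- c("conv2d", "maxpool2d", "batchnorm", "activation", "dropout",
             "flatten", "dense", "global_avg_pool", "concatenate", "input")
  if (!kind %in% kinds) stop("layer_spec: unknown kind: ", kind)
  if (kind == "conv2d" && (is.null(filters) || is.null(kernel) ||
                           any(kernel < 1)))
    stop("layer_spec: conv2d needs filters and a positive kernel")
  if (kind == "dense" && is.null(units))
    stop("layer_spec: dense needs units")
  if (kind == "maxpool2d" && (is.null(pool) || any(pool < 1)))
    stop("layer_spec: maxpool2d needs a positive pool size")
  if (kind == "dropout" && (rate < 0 || rate >= 1))
    stop("layer_spec: dropout rate must be in [0, 1)")
  structure(list(kind = kind, filters = filters, units = units,
                 kernel = kernel, pool = pool, padding = padding,
                 activation = activation, rate = rate, l2 = l2),
            class = "layer_spec")
}

#' Declarative architecture
#'
#' One or more ordered branches of [layer_spec] entries applied to a shared
#' input, optionally followed by a fusion head (concatenate + dense +
#' softmax). Every architecture must end in a dense layer with
#' `units = n_classes` followed by a softmax activation.
#'
#' @param name model name.
#' @param input_shape `(height, width, channels)`; default `c(128, 128, 1)`.
#' @param branches list of layer lists.
#' @param fusion_head optional layer list applied to the concatenated branch
#'   outputs (multi-branch models only).
#' @param n_classes number of output classes.
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(name, input_shape = c(128, 128, 1),
                              branches, fusion_head = NULL, n_classes) {
  spec <- structure(list(name = name, input_shape = input_shape,
                         branches = branches, fusion_head = fusion_head,
                         n_classes = as.integer(n_classes)),
                    class = "architecture_spec")
  tail_layers <- fusion_head %||% branches[[length(branches)]]
  k <- length(tail_layers)
  if (k < 2L ||
      tail_layers[[k]]$kind != "activation" ||
      tail_layers[[k]]$activation != "softmax" ||
      tail_layers[[k - 1L]]$kind != "dense" ||
      tail_layers[[k - 1L]]$units != n_classes)
    stop("architecture_spec: must end in dense(n_classes) + softmax")
  invisible(infer_shapes(spec))  # validates shape feasibility
  spec
}

conv_pad <- function(layer) {
  if (layer$padding == "same") (layer$kernel - 1L) %/% 2L else c(0L, 0L)
}

layer_out_shape <- function(layer, shape) {
  if (layer$kind %in% c("dense", "flatten", "global_avg_pool") ||
      length(shape) == 1L) {
    switch(layer$kind,
           dense = layer$units,
           flatten = prod(shape),
           global_avg_pool = shape[3],
           activation = shape, dropout = shape,
           stop("layer '", layer$kind, "' cannot follow a flat vector"))
  } else {
    switch(layer$kind,
           input = shape,
           conv2d = {
             hw <- if (layer$padding == "same") shape[1:2]
                   else shape[1:2] - layer$kernel + 1L
             if (any(hw < 1))
               stop("infer_shapes: conv kernel ", paste(layer$kernel, collapse = "x"),
                    " larger than its input ", paste(shape[1:2], collapse = "x"))
             c(hw, layer$filters)
           },
           maxpool2d = {
             hw <- if (layer$padding == "same") ceiling(shape[1:2] / layer$pool)
                   else (shape[1:2] - layer$pool) %/% layer$pool + 1L
             if (any(hw < 1))
               stop("infer_shapes: pool ", paste(layer$pool, collapse = "x"),
                    " larger than its input")
             c(hw, shape[3])
           },
           batchnorm = shape, activation = shape, dropout = shape,
           stop("unexpected layer kind in spatial position: ", layer$kind))
  }
}

#' Infer per-layer output shapes
#'
#' Walks each branch (and the fusion head) of an architecture, propagating
#' the input shape through every layer exactly as the builders' tables print
#' them: `valid` convolutions shrink by `kernel - 1`, `same` convolutions
#' preserve size, `valid` pooling floors and `same` pooling ceils, the
#' concatenate width is the sum of the branch output widths.
#'
#' @param spec an [architecture_spec].
#' @return list with `branches` (per-branch list of `(kind, shape)`) and
#'   `head`.
#' @export
infer_shapes <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  walk <- function(layers, shape) {
    out <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      shape <- layer_out_shape(layers[[i]], shape)
      out[[i]] <- list(kind = layers[[i]]$kind, shape = shape)
    }
    out
  }
  branch_shapes <- lapply(spec$branches, walk, shape = spec$input_shape)
  head_shapes <- NULL
  if (!is.null(spec$fusion_head)) {
    widths <- vapply(branch_shapes,
                     function(b) as.numeric(b[[length(b)]]$shape[1]), 0)
    shape <- sum(widths)
    head_shapes <- list(list(kind = "concatenate", shape = shape))
    for (layer in spec$fusion_head[-1L]) {
      shape <- layer_out_shape(layer, shape)
      head_shapes[[length(head_shapes) + 1L]] <-
        list(kind = layer$kind, shape = shape)
    }
  }
  list(branches = branch_shapes, head = head_shapes)
}

layer_param_count <- function(layer, in_shape) {
  switch(layer$kind,
         conv2d = {
           in_c <- in_shape[3]
           c(trainable = layer$filters * (prod(layer$kernel) * in_c + 1),
             non_trainable = 0)
         },
         batchnorm = {
           ch <- if (length(in_shape) == 1L) in_shape else in_shape[3]
           c(trainable = 2 * ch, non_trainable = 2 * ch)
         },
         dense = c(trainable = layer$units * (in_shape[1] + 1),
                   non_trainable = 0),
         c(trainable = 0, non_trainable = 0))
}

#' Count trainable and non-trainable parameters
#'
#' Exact accounting from the declarative spec: a convolution holds
#' `filters * (kh*kw*in_channels + 1)` weights, a dense layer
#' `units * (in_width + 1)`, batch normalization `4 * channels` (scale and
#' shift trainable; running mean and variance not); pooling, activation,
#' dropout, flatten, global average pooling and concatenation hold none.
#'
#' @param spec an [architecture_spec].
#' @return list of class `parameter_count` with `total`, `trainable` and
#'   `non_trainable`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  trainable <- 0; non_trainable <- 0
  add_layers <- function(layers, shape) {
    for (layer in layers) {
      pc <- layer_param_count(layer, shape)
      trainable <<- trainable + pc[["trainable"]]
      non_trainable <<- non_trainable + pc[["non_trainable"]]
      shape <- layer_out_shape(layer, shape)
    }
    shape
  }
  widths <- vapply(spec$branches,
                   function(b) as.numeric(add_layers(b, spec$input_shape)[1]), 0)
  if (!is.null(spec$fusion_head))
    add_layers(spec$fusion_head[-1L], sum(widths))
  structure(list(total = trainable + non_trainable, trainable = trainable,
                 non_trainable = non_trainable),
            class = "parameter_count")
}

#' @export
print.parameter_count <- function(x, ...) {
  cat(sprintf("Total Parameters: %s\nTrainable Parameters: %s\nNon-Trainable Parameters: %s\n",
              format(x$total, big.mark = ","),
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ",")))
  invisible(x)
}

# ---- FDC builders ----------------------------------------------------------

fdc1_layers <- function(n_classes) list(
  layer_spec("conv2d", filters = 24, kernel = c(5L, 5L)),
  layer_spec("maxpool2d", pool = c(4L, 2L)),
  layer_spec("activation", activation = "relu"),
  layer_spec("conv2d", filters = 48, kernel = c(5L, 5L)),
  layer_spec("maxpool2d", pool = c(4L, 2L)),
  layer_spec("activation", activation = "relu"),
  layer_spec("conv2d", filters = 48, kernel = c(5L, 5L)),
  layer_spec("activation", activation = "relu"),
  layer_spec("flatten"),
  layer_spec("dropout", rate = 0.5),
  layer_spec("dense", units = 64L),
  layer_spec("activation", activation = "relu"),
  layer_spec("dropout", rate = 0.5),
  layer_spec("dense", units = as.integer(n_classes)),
  layer_spec("activation", activation = "softmax"))

fdc2_layers <- function(n_classes) list(
  layer_spec("conv2d", filters = 32, kernel = c(3L, 3L), l2 = 5e-4),
  layer_spec("activation", activation = "relu"),
  layer_spec("maxpool2d", pool = c(4L, 2L)),
  layer_spec("conv2d", filters = 64, kernel = c(3L, 3L)),
  layer_spec("activation", activation = "relu"),
  layer_spec("maxpool2d", pool = c(4L, 2L)),
  layer_spec("flatten"),
  layer_spec("dropout", rate = 0.5),
  layer_spec("dense", units = 64L),
  layer_spec("activation", activation = "relu"),
  layer_spec("dropout", rate = 0.5),
  layer_spec("dense", units = as.integer(n_classes)),
  layer_spec("activation", activation = "softmax"))

fdc3_block <- function(filters) list(
  layer_spec("conv2d", filters = filters, kernel = c(3L, 3L),
             padding = "same", activation = "relu"),
  layer_spec("batchnorm"),
  layer_spec("conv2d", filters = filters, kernel = c(3L, 3L),
             activation = "relu"),
  layer_spec("batchnorm"),
  layer_spec("maxpool2d", pool = c(2L, 2L), padding = "same"),
  layer_spec("dropout", rate = 0.25))

fdc3_layers <- function(n_classes) c(
  fdc3_block(32), fdc3_block(64), fdc3_block(64), fdc3_block(128),
  list(layer_spec("global_avg_pool"),
       layer_spec("dense", units = as.integer(n_classes)),
       layer_spec("activation", activation = "softmax")))

check_n_classes <- function(n_classes) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2)
    stop("n_classes must be a single number >= 2")
}

#' Build the FDC-1 architecture
#'
#' Three valid-padded convolutions (24, 48, 48 filters, 5x5 receptive
#' fields) with 4x2 max pooling after the first two, a 64-unit hidden dense
#' layer, 0.5 dropout around it, and a softmax output. On a 128x128x1 input
#' the flattened width is 2,400 and the trainable parameter total at six
#' classes is 241,174.
#'
#' @param n_classes number of output classes (>= 2).
#' @param input_shape input image shape.
#' @return an [architecture_spec].
#' @export
build_fdc1 <- function(n_classes = 6L, input_shape = c(128L, 128L, 1L)) {
  check_n_classes(n_classes)
  architecture_spec("FDC-1", input_shape, list(fdc1_layers(n_classes)),
                    n_classes = n_classes)
}

#' Build the FDC-2 architecture
#'
#' Two valid-padded convolutions (32 filters with an L2 penalty of 0.0005,
#' then 64 filters; 3x3 receptive fields) each followed by 4x2 max pooling,
#' a 64-unit hidden dense layer on the 13,440-wide flattened features, 0.5
#' dropout, and a softmax output (879,430 trainable parameters at six
#' classes).
#'
#' @inheritParams build_fdc1
#' @return an [architecture_spec].
#' @export
build_fdc2 <- function(n_classes = 6L, input_shape = c(128L, 128L, 1L)) {
  check_n_classes(n_classes)
  architecture_spec("FDC-2", input_shape, list(fdc2_layers(n_classes)),
                    n_classes = n_classes)
}

#' Build the FDC-3 architecture
#'
#' Four blocks of paired 3x3 convolutions (32, 64, 64, 128 filters; the
#' first of each pair same-padded, the second valid), each convolution
#' followed by batch normalization, with ceiling-mode 2x2 max pooling and
#' 0.25 dropout closing every block; global average pooling and a softmax
#' dense output. Batch normalization contributes 2 trainable and 2
#' non-trainable parameters per channel (362,214 trainable and 1,152
#' non-trainable at six classes).
#'
#' @inheritParams build_fdc1
#' @return an [architecture_spec].
#' @export
build_fdc3 <- function(n_classes = 6L, input_shape = c(128L, 128L, 1L)) {
  check_n_classes(n_classes)
  architecture_spec("FDC-3", input_shape, list(fdc3_layers(n_classes)),
                    n_classes = n_classes)
}

#' Build the FDC-FS fusion architecture
#'
#' Late fusion of the three FDC branches on one shared 128x128x1 input:
#' FDC-1 and FDC-2 truncated after the dropout following their 64-unit
#' dense layers, FDC-3 truncated after global average pooling, concatenated
#' to a 256-wide feature vector (64 + 64 + 128) and classified by a single
#' softmax dense head (1,483,958 total parameters at six classes).
#'
#' @inheritParams build_fdc1
#' @return an [architecture_spec].
#' @export
build_fdcfs <- function(n_classes = 6L, input_shape = c(128L, 128L, 1L)) {
  check_n_classes(n_classes)
  drop_tail <- function(layers, n) layers[seq_len(length(layers) - n)]
  branches <- list(
    drop_tail(fdc1_layers(n_classes), 2L),   # ends after dropout(0.5)
    drop_tail(fdc2_layers(n_classes), 2L),   # ends after dropout(0.5)
    drop_tail(fdc3_layers(n_classes), 2L))   # ends after global_avg_pool
  head <- list(layer_spec("concatenate"),
               layer_spec("dense", units = as.integer(n_classes)),
               layer_spec("activation", activation = "softmax"))
  architecture_spec("FDC-FS", input_shape, branches, fusion_head = head,
                    n_classes = n_classes)
}

#' Build any FDC architecture by name
#' @param name one of `"fdc1"`, `"fdc2"`, `"fdc3"`, `"fdcfs"`.
#' @inheritParams build_fdc1
#' @return an [architecture_spec].
#' @export
build_architecture <- function(name = c("fdc1", "fdc2", "fdc3", "fdcfs"),
                               n_classes = 6L,
                               input_shape = c(128L, 128L, 1L)) {
  switch(match.arg(name),
         fdc1 = build_fdc1(n_classes, input_shape),
         fdc2 = build_fdc2(n_classes, input_shape),
         fdc3 = build_fdc3(n_classes, input_shape),
         fdcfs = build_fdcfs(n_classes, input_shape))
}

# ---- rendering and serialization ------------------------------------------

layer_type_name <- function(layer) {
  switch(layer$kind,
         conv2d = "Conv2D", maxpool2d = "MaxPooling2D",
         batchnorm = "BatchNormalization", activation = "Activation",
         dropout = "DropOut", flatten = "Flatten", dense = "Dense",
         global_avg_pool = "GlobalAveragePooling2D",
         concatenate = "Concatenate", input = "Input")
}

format_shape <- function(shape) {
  if (length(shape) == 1L)
    sprintf("(None, %s)", format(shape, big.mark = ","))
  else sprintf("(None, %s)", paste(shape, collapse = ", "))
}

#' Render an architecture as a layer table
#'
#' One row per layer with its output shape and parameter count, plus the
#' total/trainable/non-trainable footer — the layout used to audit an
#' architecture against a reference summary.
#'
#' @param x an [architecture_spec].
#' @param ... unused.
#' @return the formatted character vector, invisibly printed by `print`.
#' @export
format.architecture_spec <- function(x, ...) {
  lines <- c(sprintf("Model: %s  (input %s)", x$name,
                     paste(x$input_shape, collapse = "x")),
             sprintf("%-28s %-22s %s", "Layer (Type)", "Output Shape", "Param #"))
  emit <- function(layers, shape) {
    for (layer in layers) {
      pc <- layer_param_count(layer, shape)
      shape <- layer_out_shape(layer, shape)
      lines <<- c(lines, sprintf("%-28s %-22s %s", layer_type_name(layer),
                                 format_shape(shape),
                                 format(unname(pc[["trainable"]] + pc[["non_trainable"]]),
                                        big.mark = ",")))
    }
    shape
  }
  widths <- numeric(0)
  for (b in seq_along(x$branches)) {
    if (length(x$branches) > 1L) lines <- c(lines, sprintf("-- branch %d --", b))
    widths[b] <- emit(x$branches[[b]], x$input_shape)[1]
  }
  if (!is.null(x$fusion_head)) {
    lines <- c(lines, sprintf("%-28s %-22s %s", "Concatenate",
                              format_shape(sum(widths)), "0"))
    emit(x$fusion_head[-1L], sum(widths))
  }
  pc <- count_parameters(x)
  c(lines,
    sprintf("Total Parameters: %s", format(pc$total, big.mark = ",")),
    sprintf("Trainable Parameters: %s", format(pc$trainable, big.mark = ",")),
    sprintf("Non-Trainable Parameters: %s",
            format(pc$non_trainable, big.mark = ",")))
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

layer_to_list <- function(layer) Filter(Negate(is.null), unclass(layer))

list_to_layer <- function(lst) do.call(layer_spec, lst)

#' Serialize an architecture to YAML
#'
#' The document round-trips through [read_architecture] to an identical
#' spec.
#'
#' @param spec an [architecture_spec].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_architecture <- function(spec, path) {
  stopifnot(inherits(spec, "architecture_spec"))
  doc <- list(name = spec$name, input_shape = spec$input_shape,
              n_classes = spec$n_classes,
              branches = lapply(spec$branches,
                                function(b) lapply(b, layer_to_list)),
              fusion_head = if (!is.null(spec$fusion_head))
                lapply(spec$fusion_head, layer_to_list))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read an architecture written by [write_architecture]
#' @param path YAML file.
#' @return an [architecture_spec].
#' @export
read_architecture <- function(path) {
  doc <- yaml::read_yaml(path)
  architecture_spec(doc$name, as.integer(doc$input_shape),
                    lapply(doc$branches,
                           function(b) lapply(b, list_to_layer)),
                    fusion_head = if (!is.null(doc$fusion_head))
                      lapply(doc$fusion_head, list_to_layer),
                    n_classes = doc$n_classes)
}
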