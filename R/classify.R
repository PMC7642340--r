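#' Classifier configuration
#'
#' Architecture and training settings for the raw-signal molbit
#' classifier: five convolution blocks (1-D convolution, ReLU, average
#' pooling, batch normalization), two fully connected layers with
#' dropout, and a softmax output over `n_classes`. A prediction whose
#' softmax maximum falls below `confidence_threshold` is reported
#' unclassified. The exact per-layer shapes are tunable; the defaults
#' (channels 16/32/64/128/256, kernel 9, pool 3) suit 3000-sample inputs,
#' while shorter inputs need proportionally smaller kernels/pools.
#'
#' @param n_classes number of molbit classes (default 96).
#' @param input_length fixed input length in samples; shorter signals are
#'   zero-padded after normalization, longer ones truncated (default 3000).
#' @param conv_blocks integer matrix with one row per block and columns
#'   (channels, kernel, pool).
#' @param fc_sizes sizes of the two fully connected layers.
#' @param dropout dropout fraction on the fully connected layers
#'   (default 0.5).
#' @param confidence_threshold softmax confidence below which a read is
#'   unclassified (default 0.9).
#' @param epochs,batch_size,learning_rate,seed training settings.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes = 96, input_length = 3000,
                              conv_blocks = cbind(
                                channels = c(16L, 32L, 64L, 128L, 256L),
                                kernel = rep(9L, 5),
                                pool = rep(3L, 5)),
                              fc_sizes = c(512L, 256L),
                              dropout = 0.5,
                              confidence_threshold = 0.9,
                              epochs = 10, batch_size = 32,
                              learning_rate = 1e-3, seed = 1) {
  conv_blocks <- as.matrix(conv_blocks)
  storage.mode(conv_blocks) <- "integer"
  if (ncol(conv_blocks) != 3) stop("conv_blocks needs columns (channels, kernel, pool)")
  if (!(dropout > 0 && dropout < 1)) stop("dropout must be in (0, 1)")
  if (!(confidence_threshold > 0 && confidence_threshold <= 1))
    stop("confidence_threshold must be in (0, 1]")
  if (length(fc_sizes) != 2) stop("fc_sizes must give two layer sizes")
  structure(list(n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 conv_blocks = conv_blocks,
                 fc_sizes = as.integer(fc_sizes),
                 dropout = dropout,
                 confidence_threshold = confidence_threshold,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = seed),
            class = "classifier_config")
}

#' Label a basecalled read by barcode alignment
#'
#' Aligns every barcode (and its reverse complement, since strands are
#' sensed from either direction) semilocally against the read and
#' returns the best-scoring barcode when its score reaches `threshold`;
#' exact ties between distinct barcodes are treated as unlabelable.
#'
#' @param basecall read sequence (DNA string).
#' @param barcodes character vector of barcode sequences (names used as
#'   labels if present).
#' @param threshold minimum well-aligned SW score (default 15).
#' @param match,mismatch,gap SW scoring (defaults +1/-1/-8).
#' @return The winning barcode's name (or index as character) or
#'   `NA_character_`.
#' @export
label_read_by_alignment <- function(basecall, barcodes, threshold = 15,
                                    match = 1L, mismatch = -1L, gap = -8L) {
  if (length(barcodes) == 0) stop("empty barcode set")
  check_dna(basecall, "read")
  scores <- vapply(barcodes, function(bc) {
    max(cpp_sw_semilocal(bc, basecall, match, mismatch, gap),
        cpp_sw_semilocal(reverse_complement(bc), basecall, match, mismatch,
                         gap))
  }, numeric(1))
  top <- max(scores)
  if (top < threshold) return(NA_character_)
  winners <- which(scores == top)
  if (length(winners) > 1) return(NA_character_)
  lbl <- names(barcodes)[winners]
  if (is.null(lbl) || is.na(lbl) || !nzchar(lbl)) as.character(winners)
  else lbl
}

prepare_input <- function(x, input_length) {
  if (inherits(x, "squiggle")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) >= input_length) x[seq_len(input_length)]
  else c(x, numeric(input_length - length(x)))
}

#' Assemble a balanced, split training dataset
#'
#' Downsamples each class to at most `per_class_cap` reads (the cap the
#' labeling pipeline uses to balance classes), applies signal
#' preprocessing, zero-pads or truncates every signal to the classifier
#' input length, and splits stratified by class into training and
#' validation subsets.
#'
#' @param signals list of [squiggle()] objects or numeric vectors.
#' @param labels class label per signal.
#' @param config a [classifier_config()].
#' @param per_class_cap maximum reads kept per class (default 6000).
#' @param split_fraction train/validation fractions (default 0.85/0.15).
#' @param preprocess apply [preprocess_signal()] to raw signals; signals
#'   already flagged normalized are passed through.
#' @param pre_config a [preprocess_config()].
#' @param seed optional seed for downsampling and the split.
#' @return An object of class `training_dataset`: input matrix `x`
#'   (`input_length` rows, one column per read), 0-based labels `y`,
#'   class levels, and a logical `train` split indicator.
#' @export
build_training_dataset <- function(signals, labels, config,
                                   per_class_cap = 6000,
                                   split_fraction = c(0.85, 0.15),
                                   preprocess = TRUE,
                                   pre_config = preprocess_config(),
                                   seed = NULL) {
  stopifnot(length(signals) == length(labels))
  if (abs(sum(split_fraction) - 1) > 1e-8)
    stop("split_fraction must sum to 1")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < config$n_classes)
    warning(config$n_classes - length(classes),
            " of ", config$n_classes,
            " classes have no reads and are masked from training")
  with_seed(seed, {
    keep <- unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > per_class_cap) sort(sample(idx, per_class_cap))
      else idx
    }))
    keep <- sort(keep)
    signals <- signals[keep]
    labels <- labels[keep]
    x <- vapply(signals, function(s) {
      if (preprocess) {
        already <- inherits(s, "squiggle") && isTRUE(s$normalized)
        if (!already) s <- preprocess_signal(s, pre_config)
      }
      prepare_input(s, config$input_length)
    }, numeric(config$input_length))
    y <- match(labels, classes) - 1L
    train <- logical(length(labels))
    for (cl in seq_along(classes) - 1L) {
      idx <- which(y == cl)
      n_tr <- round(split_fraction[1] * length(idx))
      train[sample(idx, n_tr)] <- TRUE
    }
    structure(list(x = x, y = y, classes = classes, train = train,
                   input_length = config$input_length),
              class = "training_dataset")
  })
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("training dataset: %d reads, %d classes, %d train / %d validation\n",
              length(x$y), length(x$classes), sum(x$train), sum(!x$train)))
  invisible(x)
}

#' Train the raw-signal molbit classifier
#'
#' Fits the convolutional network described in [classifier_config()] by
#' mini-batch Adam on the training split, tracking training loss and
#' accuracy and validation accuracy per epoch. Training is reproducible
#' given `config$seed`.
#'
#' @param dataset a [build_training_dataset()] result.
#' @param config a [classifier_config()].
#' @param verbose print per-epoch progress.
#' @return An object of class `molbit_classifier` with the fitted
#'   parameters, the class map, the config and a per-epoch `history`
#'   data.frame.
#' @export
train_classifier <- function(dataset, config, verbose = FALSE) {
  stopifnot(inherits(dataset, "training_dataset"))
  n_classes_present <- length(dataset$classes)
  if (n_classes_present < 2)
    stop("training requires at least 2 classes, got ", n_classes_present)
  if (length(dataset$y) == 0) stop("empty training dataset")
  xtr <- dataset$x[, dataset$train, drop = FALSE]
  ytr <- dataset$y[dataset$train]
  xva <- dataset$x[, !dataset$train, drop = FALSE]
  yva <- dataset$y[!dataset$train]
  # the softmax covers the classes present in the data; absent classes
  # (already warned about at dataset assembly) are masked
  fit <- with_seed(config$seed,
    cpp_cnn_train(xtr, ytr, n_classes_present, config$conv_blocks,
                  config$fc_sizes, config$dropout, config$epochs,
                  config$batch_size, config$learning_rate,
                  xva, yva, verbose))
  structure(list(params = fit$params,
                 config = config,
                 classes = dataset$classes,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_loss = fit$train_loss,
                                      train_accuracy = fit$train_accuracy,
                                      val_accuracy = fit$val_accuracy)),
            class = "molbit_classifier")
}

#' @export
print.molbit_classifier <- function(x, ...) {
  h <- x$history
  cat(sprintf("molbit classifier: %d classes, input length %d, %d epochs\n",
              x$config$n_classes, x$config$input_length, nrow(h)))
  if (nrow(h) > 0)
    cat(sprintf("  final train accuracy %.4f, validation accuracy %.4f\n",
                h$train_accuracy[nrow(h)], h$val_accuracy[nrow(h)]))
  invisible(x)
}

#' Predict molbit classes for signals
#'
#' @param object a [train_classifier()] model.
#' @param newdata matrix (`input_length` rows, one column per read), a
#'   list of signals/squiggles, or a single numeric vector.
#' @param type `"prob"` for the softmax matrix, `"class"` for thresholded
#'   class calls (`NA` below the confidence threshold).
#' @param ... unused.
#' @return Probability matrix (reads x classes) or a character vector of
#'   class calls.
#' @export
predict.molbit_classifier <- function(object, newdata,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  il <- object$config$input_length
  x <- if (is.matrix(newdata)) {
    if (nrow(newdata) != il) stop("input matrix must have ", il, " rows")
    newdata
  } else if (is.list(newdata)) {
    vapply(newdata, prepare_input, numeric(il), input_length = il)
  } else {
    matrix(prepare_input(newdata, il), ncol = 1)
  }
  probs <- cpp_cnn_predict(object$params, x, object$config$batch_size)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  conf <- apply(probs, 1, max)
  calls <- object$classes[apply(probs, 1, which.max)]
  calls[conf < object$config$confidence_threshold] <- NA_character_
  calls
}

#' Classify one preprocessed signal
#'
#' @param model a `molbit_classifier`.
#' @param squiggle a preprocessed [squiggle()] or numeric vector.
#' @return An object of class `classification_result`: `molbit_id` (class
#'   label or `NA` when confidence is below the threshold), `confidence`
#'   and the full probability vector.
#' @export
classify_signal <- function(model, squiggle) {
  if (inherits(squiggle, "squiggle") && length(squiggle$samples) == 0)
    stop("empty signal")
  probs <- predict(model, list(squiggle), type = "prob")[1, ]
  conf <- max(probs)
  id <- if (conf >= model$config$confidence_threshold)
    model$classes[which.max(probs)] else NA_character_
  structure(list(molbit_id = id, confidence = conf, probabilities = probs),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  if (is.na(x$molbit_id))
    cat(sprintf("unclassified (max confidence %.3f)\n", x$confidence))
  else
    cat(sprintf("molbit %s (confidence %.3f)\n", x$molbit_id, x$confidence))
  invisible(x)
}

#' Evaluate a classifier on labeled signals
#'
#' @param model a `molbit_classifier`.
#' @param signals list of signals/squiggles or an input matrix.
#' @param labels true labels.
#' @return List with `accuracy` (trace over total, no confidence
#'   threshold applied) and `confusion` (true x predicted counts; rows
#'   sum to per-class totals).
#' @export
evaluate_classifier <- function(model, signals, labels) {
  probs <- predict(model, signals, type = "prob")
  pred <- model$classes[apply(probs, 1, which.max)]
  labels <- as.character(labels)
  lv <- model$classes
  confusion <- table(factor(labels, levels = lv),
                     factor(pred, levels = lv))
  list(accuracy = mean(pred == labels),
       confusion = unclass(confusion))
}
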