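#' CNN model configuration
#'
#' Hyper-parameters of the two 3D classifiers. `fli_lenet` is a LeNet-style
#' network: two 3x3x3 convolutions each followed by 2x2x2 max pooling, a
#' 64-unit dense layer and a softmax head. `fli_resnet` is a ResNet-style
#' network: one convolution, then two residual blocks (two convolutions with
#' an identity skip each) separated by max pooling, global average pooling
#' over the spatial axes (the temporal axis is kept, since the decay shape
#' carries the class signal), a 64-unit dense feature layer and a softmax
#' head.
#'
#' @param architecture `"fli_lenet"` or `"fli_resnet"`.
#' @param n_classes 2 or 3.
#' @param input_shape Per-cell stack shape `c(x, y, t)`; t is typically 256
#'   or 128.
#' @param conv_filters Filter counts: length 2 for `fli_lenet`
#'   (default 8, 16); a single width for `fli_resnet` blocks (default 8).
#' @param penultimate_units Width of the dense feature layer (both
#'   architectures).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A `flim_model_config`.
#' @export
model_config <- function(architecture = c("fli_lenet", "fli_resnet"),
                         n_classes = 2L, input_shape = c(21L, 21L, 256L),
                         conv_filters = NULL, penultimate_units = 64L,
                         learning_rate = 1e-3, batch_size = 8L,
                         epochs = 50L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (!n_classes %in% 2:3) stop("`n_classes` must be 2 or 3", call. = FALSE)
  conv_filters <- conv_filters %||%
    (if (architecture == "fli_lenet") c(8L, 16L) else 8L)
  if (any(input_shape %/% 4L < 1L))
    stop("input_shape incompatible with two rounds of 2x2x2 pooling",
         call. = FALSE)
  structure(
    list(architecture = architecture, n_classes = as.integer(n_classes),
         input_shape = as.integer(input_shape),
         conv_filters = as.integer(conv_filters),
         penultimate_units = as.integer(penultimate_units),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "flim_model_config")
}

cfg_dims <- function(config) {
  d1 <- config$input_shape
  d2 <- d1 %/% 2L
  d3 <- d2 %/% 2L
  c1 <- config$conv_filters[1]
  c2 <- if (config$architecture == "fli_lenet") config$conv_filters[2] else c1
  list(d1 = d1, d2 = d2, d3 = d3, c1 = c1, c2 = c2,
       flat = if (config$architecture == "fli_lenet") c2 * prod(d3)
              else c1 * d3[3])
}

weight_shapes <- function(config) {
  dm <- cfg_dims(config)
  K <- config$n_classes
  if (config$architecture == "fli_lenet") {
    list(conv1_W = c(dm$c1, 27L), conv1_b = c(dm$c1, 1L),
         conv2_W = c(dm$c2, 27L * dm$c1), conv2_b = c(dm$c2, 1L),
         dense_W = c(config$penultimate_units, dm$flat),
         dense_b = c(config$penultimate_units, 1L),
         out_W = c(K, config$penultimate_units), out_b = c(K, 1L))
  } else {
    cc <- c(dm$c1, 27L * dm$c1)
    list(conv1_W = c(dm$c1, 27L), conv1_b = c(dm$c1, 1L),
         block1a_W = cc, block1a_b = c(dm$c1, 1L),
         block1b_W = cc, block1b_b = c(dm$c1, 1L),
         block2a_W = cc, block2a_b = c(dm$c1, 1L),
         block2b_W = cc, block2b_b = c(dm$c1, 1L),
         dense_W = c(config$penultimate_units, dm$flat),
         dense_b = c(config$penultimate_units, 1L),
         out_W = c(K, config$penultimate_units), out_b = c(K, 1L))
  }
}

#' Build an untrained 3D CNN classifier
#'
#' Initialises the weights (He-scaled Gaussians for kernels, zero biases)
#' deterministically from `config$seed`; the same config and seed always
#' give bit-identical initial weights.
#'
#' @param config A [model_config()].
#' @return A `flim_cnn`: `config`, `weights` (named list of matrices),
#'   `trained` flag, `trace` (NULL until trained).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "flim_model_config"))
  shapes <- weight_shapes(config)
  set.seed(config$seed)
  weights <- purrr::imap(shapes, function(sh, nm) {
    if (grepl("_b$", nm)) return(matrix(0, sh[1], sh[2]))
    # the closing conv of each residual block starts at zero so every block
    # is the identity at initialisation (stabilises small-batch training)
    if (grepl("^block[12]b_W$", nm)) return(matrix(0, sh[1], sh[2]))
    matrix(stats::rnorm(prod(sh), sd = sqrt(2 / sh[2])), sh[1], sh[2])
  })
  structure(list(config = config, weights = weights, trained = FALSE,
                 trace = NULL),
            class = "flim_cnn")
}

#' @export
print.flim_cnn <- function(x, ...) {
  cat(sprintf("<flim_cnn> %s, %d classes, input %s, %d parameters%s\n",
              x$config$architecture, x$config$n_classes,
              paste(x$config$input_shape, collapse = "x"),
              count_parameters(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Total trainable parameter count
#' @param model A `flim_cnn`.
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "flim_cnn"))
  sum(vapply(model$weights, length, integer(1)))
}

#' Flatten cells into the network input matrix
#'
#' Stacks per-cell count arrays into a (voxels x cells) matrix, normalising
#' each cell by its own maximum count so inputs are scale-free in `[0, 1]`.
#'
#' @param cells List of `flim_cell` records with identical dimensions.
#' @return Numeric matrix, one column per cell.
#' @export
cells_to_matrix <- function(cells) {
  stopifnot(length(cells) > 0)
  d <- dim(cells[[1]]$counts)
  X <- vapply(cells, function(cl) {
    if (!identical(dim(cl$counts), d))
      stop(sprintf("cell %s has shape %s; expected %s", cl$cell_id,
                   paste(dim(cl$counts), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
    mx <- max(cl$counts)
    as.vector(cl$counts) / if (mx > 0) mx else 1
  }, numeric(prod(d)))
  X
}

encode_labels <- function(phenotypes, classes) {
  y <- match(phenotypes, classes) - 1L
  if (anyNA(y))
    stop(sprintf("labels outside model classes (%s)",
                 paste(classes, collapse = ", ")), call. = FALSE)
  y
}

#' Train a 3D CNN on a dataset
#'
#' Minimises the softmax cross-entropy with Adam (default learning rate
#' 1e-3, batch size 8) on the `train` split, monitoring loss and accuracy
#' on the `val` split every epoch and checkpointing the weights with the
#' best validation loss. Training is deterministic given the config seed.
#'
#' @param model A `flim_cnn` from [build_model()].
#' @param dataset A `flim_dataset`; its `train` and `val` splits are used.
#' @param classes Class labels in output order (default: the phenotypes
#'   present, in [phenotype_levels()] order).
#' @param epochs Override `config$epochs`.
#' @param stop_val_loss Stop early once the validation loss falls below this
#'   value (0 disables; training never exceeds `epochs`).
#' @param use_best If `TRUE` (default) restore the best-validation-loss
#'   checkpoint into the returned model.
#' @param verbose Print per-epoch losses.
#' @return The trained `flim_cnn`, with `trace` a tibble of per-epoch train/
#'   validation loss and accuracy and `classes` recorded.
#' @export
train_cnn <- function(model, dataset, classes = NULL, epochs = NULL,
                      stop_val_loss = 0, use_best = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "flim_cnn"), inherits(dataset, "flim_dataset"))
  cfg <- model$config
  phen <- dataset$info$phenotype
  classes <- classes %||% intersect(phenotype_levels(), unique(phen))
  if (length(classes) != cfg$n_classes)
    stop(sprintf("model expects %d classes, got %d", cfg$n_classes,
                 length(classes)), call. = FALSE)
  tr <- dataset$info$split == "train"
  va <- dataset$info$split == "val"
  if (!any(tr) || !any(va)) stop("dataset needs train and val splits", call. = FALSE)
  Xtr <- cells_to_matrix(dataset$cells[tr])
  Xva <- cells_to_matrix(dataset$cells[va])
  check_input_shape(model, dim(dataset$cells[[1]]$counts))
  dm <- cfg_dims(cfg)
  res <- .cnn_train(cfg$architecture, dm$d1[1], dm$d1[2], dm$d1[3],
                    cfg$n_classes, dm$c1, dm$c2, cfg$penultimate_units,
                    unname(model$weights), Xtr, encode_labels(phen[tr], classes),
                    Xva, encode_labels(phen[va], classes),
                    epochs %||% cfg$epochs, cfg$learning_rate,
                    cfg$batch_size, cfg$seed, stop_val_loss, verbose)
  w <- if (use_best) res$best_weights else res$weights
  names(w) <- names(model$weights)
  model$weights <- w
  model$trained <- TRUE
  model$classes <- classes
  model$trace <- tibble::as_tibble(res$trace)
  model
}

check_input_shape <- function(model, d) {
  exp <- model$config$input_shape
  if (!identical(as.integer(d), exp))
    stop(sprintf("input shape %s does not match model input %s",
                 paste(d, collapse = "x"), paste(exp, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Predict class probabilities for cells
#'
#' Deterministic forward pass; probabilities are softmax outputs summing to
#' one per cell, labels are the argmax class.
#'
#' @param model A trained `flim_cnn`.
#' @param cells List of `flim_cell` records matching the model input shape.
#' @return Tibble: cell_id, truth (phenotype if present), predicted, one
#'   probability column per class (`p_<class>`).
#' @export
predict_cnn <- function(model, cells) {
  stopifnot(inherits(model, "flim_cnn"))
  if (!isTRUE(model$trained)) warning("model has not been trained")
  check_input_shape(model, dim(cells[[1]]$counts))
  X <- cells_to_matrix(cells)
  cfg <- model$config
  dm <- cfg_dims(cfg)
  res <- .cnn_forward(cfg$architecture, dm$d1[1], dm$d1[2], dm$d1[3],
                      cfg$n_classes, dm$c1, dm$c2, cfg$penultimate_units,
                      unname(model$weights), X)
  classes <- model$classes %||% paste0("class", seq_len(cfg$n_classes))
  probs <- res$probs
  colnames(probs) <- paste0("p_", classes)
  out <- tibble::tibble(
    cell_id = vapply(cells, `[[`, 1L, "cell_id"),
    truth = vapply(cells, function(cl) cl$phenotype %||% NA_character_,
                   character(1)),
    predicted = classes[max.col(probs, ties.method = "first")])
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' Penultimate-layer activations as a feature matrix
#'
#' The 64 dense-layer activations entering the softmax head (the learned
#' features commonly projected with t-SNE). One row per cell.
#'
#' @param model A trained `flim_cnn`.
#' @param cells List of `flim_cell` records.
#' @param layer Only `"penultimate"` is available.
#' @return Numeric matrix, n_cells x n_features.
#' @export
extract_activations <- function(model, cells, layer = "penultimate") {
  if (!identical(layer, "penultimate"))
    stop(sprintf("unknown layer '%s'", layer), call. = FALSE)
  stopifnot(inherits(model, "flim_cnn"))
  check_input_shape(model, dim(cells[[1]]$counts))
  cfg <- model$config
  dm <- cfg_dims(cfg)
  res <- .cnn_forward(cfg$architecture, dm$d1[1], dm$d1[2], dm$d1[3],
                      cfg$n_classes, dm$c1, dm$c2, cfg$penultimate_units,
                      unname(model$weights), cells_to_matrix(cells))
  res$features
}

#' @export
tidy.flim_cnn <- function(x, ...) {
  if (is.null(x$trace)) stop("model has no training trace", call. = FALSE)
  tidyr::pivot_longer(x$trace, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' @export
glance.flim_cnn <- function(x, ...) {
  tibble::tibble(architecture = x$config$architecture,
                 n_classes = x$config$n_classes,
                 parameters = count_parameters(x), trained = x$trained,
                 final_val_loss = if (!is.null(x$trace))
                   utils::tail(x$trace$val_loss, 1) else NA_real_)
}

#' Stratified k-fold cross-validation of a CNN configuration
#'
#' Trains one model per fold on the remaining folds (a stratified tenth of
#' the training cells is held out as the validation split each time),
#' evaluates on the held-out fold, and reports per-fold metrics plus the
#' mean and standard deviation across folds.
#'
#' @param cells List of labelled `flim_cell` records.
#' @param config A [model_config()].
#' @param folds Number of folds.
#' @param seed Seed for fold assignment.
#' @param epochs,stop_val_loss Passed to [train_cnn()].
#' @return List with `fold_metrics` (list of `flim_metrics`), `predictions`
#'   (tibble over all held-out cells), and `summary` (tibble of
#'   mean +/- SD accuracy, precision, recall, F1).
#' @export
cross_validate <- function(cells, config, folds = 5L, seed = 1L,
                           epochs = NULL, stop_val_loss = 0) {
  ds <- build_dataset(cells, folds = folds, seed = seed)
  preds <- list(); reports <- list()
  for (f in seq_len(folds)) {
    hold <- ds$info$fold == f
    train_cells <- cells[!hold]
    # carve a stratified val split out of the training cells
    sub <- build_dataset(train_cells, split = c(0.9, 0.1, 0),
                         folds = max(2L, min(folds, 3L)), seed = seed + f)
    sub$info$split[sub$info$split == "test"] <- "train"
    cfg <- config
    cfg$seed <- config$seed + f
    model <- build_model(cfg)
    model <- train_cnn(model, sub, epochs = epochs,
                       stop_val_loss = stop_val_loss)
    p <- predict_cnn(model, cells[hold])
    p$fold <- f
    preds[[f]] <- p
    reports[[f]] <- if (config$n_classes == 2L)
      binary_metrics(p$truth, p$predicted, p[[paste0("p_", model$classes[1])]],
                     positive = model$classes[1])
    else multiclass_metrics(p$truth, p$predicted)
  }
  gl <- dplyr::select(purrr::map_dfr(reports, glance), -"n")
  summary <- tidyr::pivot_longer(gl, dplyr::everything(), names_to = "metric",
                                 values_drop_na = TRUE) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value))
  list(fold_metrics = reports, predictions = dplyr::bind_rows(preds),
       summary = summary)
}
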