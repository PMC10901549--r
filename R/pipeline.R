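#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: simulation,
#' pre-processing, training and evaluation settings plus a global seed from
#' which every stage's randomness is derived. `pipeline_config()` builds it
#' in code; a YAML document with the same field names can be loaded with
#' [read_pipeline_config()].
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for all artifacts.
#' @param n_fields,n_cells_per_field,field_size,photon_budget Simulation
#'   stage settings.
#' @param k_sigma,downsample Pre-processing stage settings (see
#'   [preprocess_field()]).
#' @param architecture,n_classes,epochs,stop_val_loss Training stage
#'   settings (see [model_config()] and [train_cnn()]).
#' @param fit_cells_stage If `TRUE`, also run the classical bi-exponential
#'   fit over all cells and write `fits.csv`.
#' @return A `flim_pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L, out_dir = "flimclass_run",
                            n_fields = 3L, n_cells_per_field = 20L,
                            field_size = 128L, photon_budget = 2000,
                            k_sigma = 2, downsample = "mean",
                            architecture = "fli_resnet", n_classes = 3L,
                            epochs = 30L, stop_val_loss = 0,
                            fit_cells_stage = FALSE) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         simulate = list(n_fields = as.integer(n_fields),
                         n_cells_per_field = as.integer(n_cells_per_field),
                         field_size = as.integer(field_size),
                         photon_budget = photon_budget),
         preprocess = list(k_sigma = k_sigma, downsample = downsample),
         train = list(architecture = architecture,
                      n_classes = as.integer(n_classes),
                      epochs = as.integer(epochs),
                      stop_val_loss = stop_val_loss),
         fit_cells_stage = isTRUE(fit_cells_stage)),
    class = "flim_pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    y[intersect(names(y), c("seed", "out_dir", "fit_cells_stage"))],
    y$simulate %||% list(), y$preprocess %||% list(), y$train %||% list()))
}

#' Run the full simulate / preprocess / train / evaluate workflow
#'
#' Executes the stages in order, writing every artifact under
#' `config$out_dir` and recording each file with its MD5 checksum in a
#' manifest (`manifest.csv`). Simulation and pre-processing are
#' deterministic given the seed, so re-running the same config reproduces
#' those artifacts checksum-for-checksum. A stage failure raises an error
#' naming the stage; artifacts already written are kept.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return Invisibly, the manifest tibble (stage, path, md5).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "flim_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(stage = character(), path = character(),
                             md5 = character())
  note <- function(stage, ...) {
    for (p in c(...))
      manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
        stage = stage, path = p, md5 = unname(tools::md5sum(p))))
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  op <- function(f) file.path(config$out_dir, f)

  # --- simulate -------------------------------------------------------
  axis <- time_axis()
  fields <- in_stage("simulate", {
    lapply(seq_len(config$simulate$n_fields), function(i) {
      f <- simulate_field(config$simulate$n_cells_per_field,
                          axis = axis,
                          field_size = config$simulate$field_size,
                          photon_budget = config$simulate$photon_budget,
                          seed = config$seed * 1000L + i)
      pre <- op(sprintf("field_%02d", i))
      write_field(f, pre)
      note("simulate", paste0(pre, ".tif"), paste0(pre, "_mask.tif"),
           paste0(pre, ".json"))
      f
    })
  })

  # --- preprocess -----------------------------------------------------
  dataset <- in_stage("preprocess", {
    pp <- lapply(fields, preprocess_field, k_sigma = config$preprocess$k_sigma,
                 downsample = config$preprocess$downsample)
    cells <- unlist(lapply(pp, `[[`, "cells"), recursive = FALSE)
    for (i in seq_along(cells)) cells[[i]]$cell_id <- i  # unique across fields
    qc <- dplyr::bind_rows(lapply(seq_along(pp), function(i)
      dplyr::mutate(pp[[i]]$qc, field = i, .before = 1)))
    utils::write.csv(qc, op("qc.csv"), row.names = FALSE)
    # clamp folds to the smallest class so small smoke runs stay valid
    phen <- vapply(cells, `[[`, character(1), "phenotype")
    folds <- max(2L, min(5L, min(table(phen))))
    ds <- build_dataset(cells, folds = folds, seed = config$seed)
    write_dataset(ds, op("dataset"))
    note("preprocess", op("qc.csv"), op("dataset_cells.tif"),
         op("dataset_masks.tif"), op("dataset.json"))
    ds
  })

  if (config$fit_cells_stage) {
    in_stage("fit", {
      fits <- fit_cells(dataset$cells)
      utils::write.csv(fits, op("fits.csv"), row.names = FALSE)
      note("fit", op("fits.csv"))
    })
  }

  # --- train ----------------------------------------------------------
  model <- in_stage("train", {
    cfg <- model_config(config$train$architecture,
                        n_classes = config$train$n_classes,
                        input_shape = dim(dataset$cells[[1]]$counts),
                        epochs = config$train$epochs, seed = config$seed)
    m <- train_cnn(build_model(cfg), dataset,
                   stop_val_loss = config$train$stop_val_loss)
    utils::write.csv(m$trace, op("trace.csv"), row.names = FALSE)
    saveRDS(m, op("model.rds"))
    note("train", op("trace.csv"), op("model.rds"))
    m
  })

  # --- evaluate -------------------------------------------------------
  in_stage("evaluate", {
    test <- dataset$info$split == "test"
    preds <- predict_cnn(model, dataset$cells[test])
    utils::write.csv(preds, op("predictions.csv"), row.names = FALSE)
    rep <- if (model$config$n_classes == 2L)
      binary_metrics(preds$truth, preds$predicted,
                     preds[[paste0("p_", model$classes[1])]],
                     positive = model$classes[1])
    else multiclass_metrics(preds$truth, preds$predicted)
    report <- list(
      accuracy = rep$accuracy, auc = rep$auc,
      macro = as.list(rep$macro), per_class = rep$per_class,
      confusion = rep$confusion,
      fractions = phenotype_fractions(preds$predicted),
      n_test = sum(test))
    jsonlite::write_json(report, op("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    note("evaluate", op("predictions.csv"), op("report.json"))
  })

  utils::write.csv(manifest, op("manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
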