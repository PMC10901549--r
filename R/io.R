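#' Write / read a field stack
#'
#' A field is stored as three files sharing one path prefix: a multi-frame
#' 16-bit TIFF `<prefix>.tif` holding the photon counts (one page per time
#' bin), a 16-bit label TIFF `<prefix>_mask.tif`, and a JSON sidecar
#' `<prefix>.json` with the time axis, the seed, and the per-cell phenotype
#' labels. Counts, mask, labels and metadata survive the round trip
#' bit-exactly. Counts above 65535 do not fit in the container and raise an
#' error rather than being truncated.
#'
#' @param field A `flim_field`.
#' @param prefix Path prefix (no extension).
#' @return `write_field()` returns the prefix invisibly; `read_field()`
#'   returns the `flim_field`.
#' @export
write_field <- function(field, prefix) {
  stopifnot(inherits(field, "flim_field"))
  check_uint16(field$counts, "counts")
  check_uint16(field$mask, "mask")
  d <- dim(field$counts)
  pages <- lapply(seq_len(d[3]), function(k) field$counts[, , k] / 65535)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L,
                  compression = "none")
  tiff::writeTIFF(field$mask / 65535, paste0(prefix, "_mask.tif"),
                  bits.per.sample = 16L, compression = "none")
  meta <- list(kind = "flim_field",
               n_bins = field$axis$n_bins, window_ns = field$axis$window_ns,
               seed = field$seed, dim = d,
               labels = list(cell_id = field$labels$cell_id,
                             phenotype = field$labels$phenotype))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

check_uint16 <- function(x, what) {
  if (any(x < 0)) stop(sprintf("negative values in %s", what), call. = FALSE)
  if (any(x > 65535))
    stop(sprintf("%s exceed 65535 and cannot be stored losslessly", what),
         call. = FALSE)
  invisible(TRUE)
}

read_sidecar <- function(prefix, kind) {
  path <- paste0(prefix, ".json")
  if (!file.exists(path))
    stop(sprintf("missing metadata sidecar '%s'", path), call. = FALSE)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("kind", "n_bins", "window_ns"))
    if (is.null(meta[[fld]]))
      stop(sprintf("sidecar '%s' lacks required member '%s'", path, fld),
           call. = FALSE)
  if (!identical(meta$kind, kind))
    stop(sprintf("'%s' holds a %s, not a %s", path, meta$kind, kind),
         call. = FALSE)
  meta
}

read_stack_tiff <- function(path) {
  if (!file.exists(path))
    stop(sprintf("missing dataset member '%s'", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' @rdname write_field
#' @export
read_field <- function(prefix) {
  meta <- read_sidecar(prefix, "flim_field")
  pages <- read_stack_tiff(paste0(prefix, ".tif"))
  if (length(pages) != meta$n_bins)
    stop(sprintf("expected %d pages, found %d", meta$n_bins, length(pages)),
         call. = FALSE)
  counts <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  mask_path <- paste0(prefix, "_mask.tif")
  if (!file.exists(mask_path))
    stop(sprintf("missing dataset member '%s'", mask_path), call. = FALSE)
  mask <- tiff::readTIFF(mask_path, as.is = TRUE)
  storage.mode(mask) <- "integer"
  structure(
    list(counts = counts, mask = mask,
         labels = tibble::tibble(cell_id = as.integer(meta$labels$cell_id),
                                 phenotype = as.character(meta$labels$phenotype)),
         truth = NULL,
         axis = time_axis(meta$n_bins, meta$window_ns),
         seed = as.integer(meta$seed)),
    class = "flim_field")
}

#' Write / read a per-cell dataset bundle
#'
#' A `flim_dataset` (see [build_dataset()]) is stored as one multi-frame
#' 16-bit TIFF `<prefix>_cells.tif` with each cell's T pages in sequence,
#' one mask TIFF `<prefix>_masks.tif` with one page per cell, and a JSON
#' sidecar carrying the time axis plus the per-cell id, phenotype, split
#' tag, fold and spatial dimensions. Duplicate cell ids are rejected.
#'
#' @param dataset A `flim_dataset`.
#' @param prefix Path prefix (no extension).
#' @return `write_dataset()` returns the prefix invisibly; `read_dataset()`
#'   the `flim_dataset`.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "flim_dataset"))
  ids <- dataset$info$cell_id
  if (anyDuplicated(ids))
    stop("duplicated cell ids in dataset", call. = FALSE)
  pages <- list(); masks <- list(); dims <- list()
  for (cl in dataset$cells) {
    check_uint16(cl$counts, sprintf("cell %s counts", cl$cell_id))
    d <- dim(cl$counts)
    dims[[length(dims) + 1]] <- d
    for (k in seq_len(d[3]))
      pages[[length(pages) + 1]] <- cl$counts[, , k] / 65535
    masks[[length(masks) + 1]] <- cl$mask_crop / 65535
  }
  tiff::writeTIFF(pages, paste0(prefix, "_cells.tif"), bits.per.sample = 16L,
                  compression = "none")
  tiff::writeTIFF(masks, paste0(prefix, "_masks.tif"), bits.per.sample = 16L,
                  compression = "none")
  meta <- list(kind = "flim_dataset",
               n_bins = dataset$axis$n_bins,
               window_ns = dataset$axis$window_ns,
               seed = dataset$seed,
               cells = list(cell_id = dataset$info$cell_id,
                            phenotype = dataset$info$phenotype,
                            split = dataset$info$split,
                            fold = dataset$info$fold,
                            nx = vapply(dims, `[`, 1L, 1L),
                            ny = vapply(dims, `[`, 1L, 2L)))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  meta <- read_sidecar(prefix, "flim_dataset")
  info <- tibble::tibble(cell_id = as.integer(meta$cells$cell_id),
                         phenotype = as.character(meta$cells$phenotype),
                         split = as.character(meta$cells$split),
                         fold = as.integer(meta$cells$fold))
  if (anyDuplicated(info$cell_id))
    stop("duplicated cell ids in dataset", call. = FALSE)
  pages <- read_stack_tiff(paste0(prefix, "_cells.tif"))
  masks <- read_stack_tiff(paste0(prefix, "_masks.tif"))
  axis <- time_axis(meta$n_bins, meta$window_ns)
  T <- axis$n_bins
  cells <- list(); at <- 0L
  for (i in seq_len(nrow(info))) {
    nx <- meta$cells$nx[i]; ny <- meta$cells$ny[i]
    counts <- array(0L, dim = c(nx, ny, T))
    for (k in seq_len(T)) counts[, , k] <- pages[[at + k]]
    at <- at + T
    cells[[i]] <- structure(
      list(counts = counts, mask_crop = masks[[i]] > 0,
           phenotype = info$phenotype[i], cell_id = info$cell_id[i],
           source_field = NA_character_, true_params = NULL,
           amplitude_map = NULL, axis = axis, qc = NULL),
      class = "flim_cell")
  }
  structure(list(cells = cells, info = info, axis = axis,
                 seed = as.integer(meta$seed)),
            class = "flim_dataset")
}
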