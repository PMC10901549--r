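#' Extract per-cell TPSF stacks from a field
#'
#' Crops each labelled cell to the tight bounding box of its mask and zeroes
#' any pixels of other cells that fall inside the box, so every record
#' contains exactly one cell's photons.
#'
#' @param field A `flim_field` from [simulate_field()] or [read_field()].
#' @return List of `flim_cell` records, one per nonzero mask label (empty
#'   labels are skipped with a warning).
#' @export
extract_cells <- function(field) {
  stopifnot(inherits(field, "flim_field"))
  labels <- sort(unique(as.vector(field$mask)))
  labels <- labels[labels != 0]
  out <- list()
  for (lab in labels) {
    sel <- field$mask == lab
    if (!any(sel)) next
    xs <- range(which(rowSums(sel) > 0))
    ys <- range(which(colSums(sel) > 0))
    m <- sel[xs[1]:xs[2], ys[1]:ys[2], drop = FALSE]
    cr <- field$counts[xs[1]:xs[2], ys[1]:ys[2], , drop = FALSE]
    # zero out pixels belonging to other cells or background inside the box
    other <- field$mask[xs[1]:xs[2], ys[1]:ys[2], drop = FALSE] != lab
    if (any(other)) {
      oi <- which(other)
      for (k in seq_len(dim(cr)[3])) {
        pl <- cr[, , k]; pl[oi] <- 0L; cr[, , k] <- pl
      }
    }
    phen <- field$labels$phenotype[match(lab, field$labels$cell_id)]
    out[[length(out) + 1]] <- structure(
      list(counts = cr, mask_crop = m, phenotype = phen,
           cell_id = as.integer(lab),
           source_field = sprintf("field_seed%d", field$seed),
           true_params = if (!is.null(field$truth)) field$truth[[lab]] else NULL,
           amplitude_map = NULL, axis = field$axis, qc = NULL),
      class = "flim_cell")
  }
  missing <- setdiff(field$labels$cell_id, vapply(out, `[[`, 1L, "cell_id"))
  if (length(missing))
    warning(sprintf("skipped empty mask label(s): %s",
                    paste(missing, collapse = ", ")))
  out
}

#' Time frame with the maximum summed photon count
#'
#' Sums the photon counts of all pixels at each time frame and returns the
#' 1-based index of the maximum (ties broken toward the earlier frame).
#' Under the default axis and IRF, noiseless cells peak at frame 64 or 65.
#'
#' @param cell A `flim_cell` record (or a bare x-y-t array).
#' @return Integer 1-based frame index.
#' @export
peak_frame <- function(cell) {
  counts <- if (inherits(cell, "flim_cell")) cell$counts else cell
  tot <- apply(counts, 3, sum)
  if (all(tot == 0)) stop("all-zero cell: peak frame undefined", call. = FALSE)
  which.max(tot)  # which.max returns the first (earliest) maximum
}

#' Shannon entropy of a 2-D count image, in bits
#'
#' Entropy of the normalised gray-level histogram of the frame, using 256
#' equal-width bins over `[0, max(frame)]`. Empty bins contribute zero; an
#' all-zero frame has entropy 0 by convention. Used as the per-cell quality
#' statistic at the peak frame.
#'
#' @param frame Non-negative numeric matrix.
#' @param n_bins Number of histogram bins.
#' @return Entropy in bits.
#' @export
frame_entropy <- function(frame, n_bins = 256L) {
  if (any(frame < 0)) stop("frame must be non-negative", call. = FALSE)
  mx <- max(frame)
  if (mx == 0) return(0)
  # bin i covers ((i-1)/n, i/n] * mx, with 0 in the first bin
  idx <- pmin(n_bins, floor(as.vector(frame) / mx * n_bins) + 1L)
  p <- tabulate(idx, nbins = n_bins)
  p <- p[p > 0] / length(frame)
  -sum(p * log2(p))
}

#' Entropy-based quality filter over a set of cells
#'
#' Computes the entropy of each cell's peak frame, fits a Gaussian
#' approximation (mean and standard deviation) to the entropy distribution,
#' and retains cells whose entropy falls within `mean +/- k_sigma * sd`.
#' Removes incomplete or poorly segmented cells whose peak-frame texture is
#' atypical.
#'
#' @param cells List of `flim_cell` records (>= 2).
#' @param k_sigma Width of the retention interval in standard deviations.
#' @return List with `cells` (retained records, `qc` field filled in) and
#'   `qc` (tibble: cell_id, phenotype, entropy, retained).
#' @export
entropy_filter <- function(cells, k_sigma = 2) {
  if (length(cells) < 2) stop("need at least 2 cells", call. = FALSE)
  ent <- vapply(cells, function(cl) frame_entropy(cl$counts[, , peak_frame(cl)]),
                numeric(1))
  mu <- mean(ent); sg <- stats::sd(ent)
  if (sg == 0) {
    warning("zero entropy spread: retaining all cells")
    keep <- rep(TRUE, length(cells))
  } else {
    keep <- ent >= mu - k_sigma * sg & ent <= mu + k_sigma * sg
  }
  qc <- tibble::tibble(
    cell_id = vapply(cells, `[[`, 1L, "cell_id"),
    phenotype = vapply(cells, function(cl) cl$phenotype %||% NA_character_,
                       character(1)),
    entropy = ent, retained = keep)
  cells <- purrr::map2(cells, seq_along(cells), function(cl, i) {
    cl$qc <- list(entropy = ent[i], retained = keep[i]); cl
  })
  list(cells = cells[keep], qc = qc)
}

#' Standardise a cell crop to a fixed spatial size
#'
#' Zero-pads the crop symmetrically to `pad_to` x `pad_to` (extra pixel on
#' the bottom/right when the difference is odd), then extracts the centred
#' `crop_to` x `crop_to` square. The time dimension is untouched. Cells
#' larger than `pad_to` in either dimension are rejected.
#'
#' @param cell A `flim_cell` record.
#' @param pad_to Padded spatial size (default 40).
#' @param crop_to Final spatial size (default 21).
#' @return The record with `counts` and `mask_crop` resized to
#'   `crop_to` x `crop_to`.
#' @export
standardize_spatial <- function(cell, pad_to = 40L, crop_to = 21L) {
  stopifnot(inherits(cell, "flim_cell"))
  d <- dim(cell$counts)
  if (d[1] > pad_to || d[2] > pad_to)
    stop(sprintf("cell %s exceeds %d px (%d x %d): excluded",
                 cell$cell_id, pad_to, d[1], d[2]), call. = FALSE)
  off <- function(n) (pad_to - n) %/% 2L        # leading pad (extra goes after)
  ox <- off(d[1]); oy <- off(d[2])
  pad <- array(0, dim = c(pad_to, pad_to, d[3]))
  pad[ox + seq_len(d[1]), oy + seq_len(d[2]), ] <- cell$counts
  pm <- matrix(FALSE, pad_to, pad_to)
  pm[ox + seq_len(d[1]), oy + seq_len(d[2])] <- cell$mask_crop
  s <- (pad_to - crop_to) %/% 2L + 1L           # 1-based crop start
  sel <- s:(s + crop_to - 1L)
  cell$counts <- pad[sel, sel, , drop = FALSE]
  cell$mask_crop <- pm[sel, sel]
  cell
}

#' Temporal down-sampling specification
#'
#' A sliding mean or median filter of odd `window` applied along the time
#' axis (edge frames replicated at the boundaries), followed by extraction
#' of the 1-based odd frames. The mean variant is called MD, the median
#' variant MEDD.
#'
#' @param method `"mean"` or `"median"`.
#' @param window Odd filter window (default 3).
#' @return A `flim_downsample_spec`.
#' @export
downsample_spec <- function(method = c("mean", "median"), window = 3L) {
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be a positive odd integer", call. = FALSE)
  structure(list(method = method, window = window),
            class = "flim_downsample_spec")
}

#' Down-sample a TPSF stack in time
#'
#' Applies the window filter of `spec` along T per pixel (edge replication
#' at the boundaries), keeps the 1-based odd frames (1, 3, ...), and rounds
#' to integers to preserve photon-count semantics. A 256-frame stack becomes
#' 128 frames; in general the output length is `ceil(T / 2)`.
#'
#' @param x A `flim_cell` record or x-y-t array.
#' @param spec A [downsample_spec()].
#' @return Same type as `x`, with the time dimension halved (a `flim_cell`
#'   also gets its `axis` updated to the new bin count/width).
#' @export
downsample_time <- function(x, spec = downsample_spec("mean")) {
  stopifnot(inherits(spec, "flim_downsample_spec"))
  is_cell <- inherits(x, "flim_cell")
  counts <- if (is_cell) x$counts else x
  d <- dim(counts)
  T <- d[3]
  if (T < spec$window) stop("time dimension shorter than filter window", call. = FALSE)
  h <- (spec$window - 1L) %/% 2L
  idx_ext <- pmin(pmax(seq_len(T + 2L * h) - h, 1L), T)  # edge replication
  mat <- matrix(counts, prod(d[1:2]), T)[, idx_ext, drop = FALSE]
  filt <- matrix(0, nrow(mat), T)
  fun <- if (spec$method == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  for (k in seq_len(T))
    filt[, k] <- fun(mat[, k:(k + 2L * h), drop = FALSE])
  keep <- seq(1L, T, by = 2L)
  out <- round(filt[, keep, drop = FALSE])
  out <- array(out, dim = c(d[1], d[2], length(keep)))
  if (!is_cell) return(out)
  x$counts <- out
  x$axis <- time_axis(n_bins = length(keep),
                      window_ns = x$axis$window_ns)
  x
}

#' Mean temporal decay of a cell (per-frame masked mean)
#'
#' Element `t` is the mean photon count over the cell's mask pixels at frame
#' `t`; a 256-frame cell yields 256 temporal features.
#'
#' @param cell A `flim_cell` record.
#' @return Numeric vector of length T.
#' @export
temporal_features <- function(cell) {
  stopifnot(inherits(cell, "flim_cell"))
  if (!any(cell$mask_crop)) stop("empty mask", call. = FALSE)
  idx <- which(cell$mask_crop)
  apply(cell$counts, 3, function(fr) mean(fr[idx]))
}

#' Assemble a labelled dataset with stratified splits and folds
#'
#' Randomly assigns each cell a train/validation/test tag (default 70/10/20)
#' and a cross-validation fold (default 5), both stratified by phenotype,
#' under a fixed seed.
#'
#' @param cells List of labelled `flim_cell` records.
#' @param split Length-3 proportions for train/val/test (sums to 1).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed.
#' @return A `flim_dataset`: `cells` (list), `info` (tibble: cell_id,
#'   phenotype, split, fold), `axis`, `seed`.
#' @export
build_dataset <- function(cells, split = c(0.7, 0.1, 0.2), folds = 5L,
                          seed = 1L) {
  if (!length(cells)) stop("no cells", call. = FALSE)
  phen <- vapply(cells, function(cl) cl$phenotype %||% NA_character_, character(1))
  if (anyNA(phen)) stop("every cell must be labelled", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8) stop("`split` must sum to 1", call. = FALSE)
  tab <- table(phen)
  if (any(tab < folds))
    stop(sprintf("class '%s' has fewer cells than folds",
                 names(tab)[which.min(tab)]), call. = FALSE)
  set.seed(seed)
  n <- length(cells)
  tag <- character(n); fold <- integer(n)
  for (cl in names(tab)) {
    idx <- sample(which(phen == cl))
    k <- length(idx)
    n_tr <- round(split[1] * k); n_va <- round(split[2] * k)
    n_tr <- min(n_tr, k - 2L); n_va <- max(1L, min(n_va, k - n_tr - 1L))
    tag[idx] <- rep(c("train", "val", "test"),
                    c(n_tr, n_va, k - n_tr - n_va))
    fold[idx] <- rep_len(seq_len(folds), k)
  }
  structure(
    list(cells = cells,
         info = tibble::tibble(
           cell_id = vapply(cells, `[[`, 1L, "cell_id"),
           phenotype = phen, split = tag, fold = fold),
         axis = cells[[1]]$axis, seed = as.integer(seed)),
    class = "flim_dataset")
}

#' @export
print.flim_dataset <- function(x, ...) {
  cat(sprintf("<flim_dataset> %d cells, seed %d\n", length(x$cells), x$seed))
  print(dplyr::count(x$info, .data$phenotype, .data$split))
  invisible(x)
}

#' Run the standard pre-processing chain over a simulated or imported field
#'
#' Convenience wrapper: [extract_cells()], [entropy_filter()],
#' [standardize_spatial()] and optional [downsample_time()], returning the
#' retained, standardised cells plus the QC table.
#'
#' @param field A `flim_field`.
#' @param k_sigma Entropy filter width.
#' @param downsample `"none"`, `"mean"` or `"median"`.
#' @param pad_to,crop_to Spatial standardisation sizes.
#' @return List with `cells` and `qc` (as [entropy_filter()], after
#'   standardisation).
#' @export
preprocess_field <- function(field, k_sigma = 2, downsample = "none",
                             pad_to = 40L, crop_to = 21L) {
  cells <- extract_cells(field)
  flt <- entropy_filter(cells, k_sigma = k_sigma)
  std <- list()
  dropped <- character()
  for (cl in flt$cells) {
    std1 <- tryCatch(standardize_spatial(cl, pad_to, crop_to),
                     error = function(e) {dropped <<- c(dropped, conditionMessage(e)); NULL})
    if (!is.null(std1)) std[[length(std) + 1]] <- std1
  }
  if (length(dropped)) warning(paste(dropped, collapse = "; "))
  if (downsample != "none")
    std <- lapply(std, downsample_time, spec = downsample_spec(downsample))
  list(cells = std, qc = flt$qc)
}
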