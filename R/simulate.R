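#' Expected (noiseless) TCSPC decay curve
#'
#' Builds the IRF-convolved bi-exponential model on a discrete time axis:
#' the unit decay `alpha1 exp(-t/tau1) + (1-alpha1) exp(-t/tau2)` is
#' convolved causally (zero-padded, no wrap-around) with the IRF kernel and
#' rescaled so the expected total signal over the window equals `amplitude`;
#' the per-bin `offset` is then added.
#'
#' @param params A [decay_params()].
#' @param irf_kernel Discrete IRF kernel from [make_irf()] (length `n_bins`).
#' @param axis A [time_axis()].
#' @return Numeric vector of expected counts per bin.
#' @export
forward_model <- function(params, irf_kernel = make_irf(axis = axis),
                          axis = time_axis()) {
  stopifnot(inherits(params, "flim_decay_params"),
            inherits(axis, "flim_time_axis"))
  if (length(irf_kernel) != axis$n_bins)
    stop("IRF kernel length must equal `n_bins`", call. = FALSE)
  shape <- decay_shape(params, irf_kernel, axis)
  params$amplitude * shape + params$offset
}

# unit-sum IRF-convolved bi-exponential shape (internal, shared between the
# simulator and the fitter so both sides use the identical model)
decay_shape <- function(params, irf_kernel, axis) {
  T <- axis$n_bins
  t_rel <- (seq_len(T) - 1) * axis$bin_width_ps
  d <- params$alpha1 * exp(-t_rel / params$tau1_ps) +
    (1 - params$alpha1) * exp(-t_rel / params$tau2_ps)
  full <- stats::convolve(irf_kernel, rev(d), type = "open")
  cv <- full[seq_len(T)]
  cv[cv < 0] <- 0  # guard tiny negative FFT round-off
  cv / sum(cv)
}

#' Simulate one TCSPC decay histogram
#'
#' Draws per-bin Poisson photon counts around the [forward_model()]
#' expectation, or returns the expectation itself in noiseless mode. Uses
#' R's global random number generator; seed with `set.seed()` for
#' reproducibility.
#'
#' @inheritParams forward_model
#' @param noiseless If `TRUE`, return the expected curve (no Poisson draw).
#' @return Numeric vector of length `n_bins` (integer counts unless
#'   `noiseless`).
#' @export
simulate_decay <- function(params, irf_kernel = make_irf(axis = axis),
                           axis = time_axis(), noiseless = FALSE) {
  mu <- forward_model(params, irf_kernel, axis)
  if (noiseless) return(mu)
  stats::rpois(length(mu), mu)
}

#' Cell geometry for the synthetic generator
#'
#' An axis-aligned elliptical cell with a concentric elliptical nucleus.
#' Cytoplasm (inside the cell, outside the nucleus) is brighter than the
#' nucleus by `intensity_ratio_nucleus`, reflecting the higher NAD(P)H
#' content of the cytoplasm.
#'
#' @param axes_px Cell ellipse semi-axes (x, y), pixels.
#' @param nucleus_axes_px Nucleus semi-axes (x, y); must be strictly smaller.
#' @param intensity_ratio_nucleus Cytoplasm-to-nucleus mean brightness
#'   ratio (> 1).
#' @param center_xy Optional centre (used when placing into a field).
#' @return A `flim_cell_geometry` object.
#' @export
cell_geometry <- function(axes_px = c(8, 6.5), nucleus_axes_px = c(3.5, 3),
                          intensity_ratio_nucleus = 2.5, center_xy = NULL) {
  if (any(axes_px <= 0) || any(nucleus_axes_px <= 0))
    stop("all ellipse axes must be > 0", call. = FALSE)
  if (any(nucleus_axes_px >= axes_px))
    stop("nucleus must lie strictly inside the cell", call. = FALSE)
  if (intensity_ratio_nucleus <= 1)
    stop("`intensity_ratio_nucleus` must be > 1", call. = FALSE)
  structure(list(axes_px = axes_px, nucleus_axes_px = nucleus_axes_px,
                 intensity_ratio_nucleus = intensity_ratio_nucleus,
                 center_xy = center_xy),
            class = "flim_cell_geometry")
}

# smooth a noise matrix with a separable Gaussian kernel (internal)
smooth2d <- function(z, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m)), , drop = FALSE]
  zz <- apply(pad(z, r), 2, function(col) stats::filter(col, k)[(r + 1):(length(col) - r)])
  zz <- t(apply(pad(t(zz), r), 2, function(col) stats::filter(col, k)[(r + 1):(length(col) - r)]))
  zz
}

# multiplicative intensity texture over cytoplasm pixels, mean 1 (internal).
# punctate: bright blobs from the upper tail of a smooth Gaussian field;
# networked: connected ridges along the zero set of the same kind of field.
texture_field <- function(dim_xy, texture = c("punctate", "networked", "flat")) {
  texture <- match.arg(texture)
  if (texture == "flat") return(matrix(1, dim_xy[1], dim_xy[2]))
  z <- matrix(stats::rnorm(prod(dim_xy)), dim_xy[1], dim_xy[2])
  if (texture == "punctate") {
    # sparse bright puncta: fragmented mitochondria concentrate NAD(P)H
    # into isolated high-contrast spots
    zs <- smooth2d(z, 0.6)
    on <- zs > stats::quantile(zs, 0.85)
    depth <- 2.5
  } else {
    # connected moderate-contrast ridges: fused mitochondrial networks
    zs <- smooth2d(z, 2.2)
    on <- abs(zs - stats::median(zs)) < 0.6 * stats::sd(zs)
    depth <- 1.0
  }
  f <- 1 + depth * as.numeric(on)
  matrix(f, dim_xy[1], dim_xy[2])
}

# ellipse membership on a pixel grid, centre at (cx, cy), 1-based (internal)
ellipse_mask <- function(nx, ny, cx, cy, ax, ay) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
}

# draw per-cell decay parameters around a preset mean (internal)
jitter_params <- function(preset) {
  p <- preset$mean_params
  cv <- preset$cell_cv
  t1 <- p$tau1_ps * (1 + cv * stats::rnorm(1))
  t2 <- p$tau2_ps * (1 + cv * stats::rnorm(1))
  a1 <- p$alpha1 * (1 + cv * stats::rnorm(1))
  t1 <- min(max(t1, 150), 900)
  t2 <- min(max(t2, max(t1 + 200, 1000)), 3200)
  a1 <- min(max(a1, 0.02), 0.98)
  decay_params(tau1_ps = t1, tau2_ps = t2, alpha1 = a1,
               amplitude = 1, offset = p$offset)
}

#' Simulate one cell as an X-Y-T photon-count stack
#'
#' Generates an elliptical cell on a small canvas: every pixel inside the
#' mask receives an IRF-convolved bi-exponential decay whose parameters are
#' drawn once per cell around the preset mean (`cell_cv` jitter); pixel
#' brightness encodes the cytoplasm/nucleus contrast and the preset's
#' cytoplasmic texture. Photon counts are Poisson unless `noiseless`.
#'
#' @param preset A `flim_class_preset` from [class_presets()].
#' @param geometry A [cell_geometry()].
#' @param axis A [time_axis()].
#' @param irf_kernel IRF kernel from [make_irf()].
#' @param photon_budget Expected total photons in an average cytoplasm pixel.
#' @param seed Optional integer seed (deterministic output when supplied).
#' @param canvas_px Canvas side length; default fits the cell with a 2-px
#'   margin.
#' @param cell_id,source_field Provenance fields stored on the record.
#' @param noiseless If `TRUE`, store expected counts instead of Poisson draws.
#' @return A `flim_cell` record: `counts` (x, y, t array), `mask_crop`,
#'   `phenotype`, `cell_id`, `source_field`, `true_params`, `amplitude_map`,
#'   `axis`, `qc`.
#' @export
simulate_cell <- function(preset, geometry = cell_geometry(),
                          axis = time_axis(),
                          irf_kernel = make_irf(axis = axis),
                          photon_budget = 2000, seed = NULL,
                          canvas_px = NULL, cell_id = 1L,
                          source_field = NA_character_, noiseless = FALSE) {
  stopifnot(inherits(preset, "flim_class_preset"),
            inherits(geometry, "flim_cell_geometry"))
  if (!is.null(seed)) set.seed(seed)
  side <- if (is.null(canvas_px)) 2L * ceiling(max(geometry$axes_px)) + 5L else as.integer(canvas_px)
  if (side < 2 * max(geometry$axes_px))
    stop("cell geometry does not fit inside the requested canvas", call. = FALSE)
  c0 <- (side + 1) / 2
  cell <- ellipse_mask(side, side, c0, c0, geometry$axes_px[1], geometry$axes_px[2])
  nuc <- ellipse_mask(side, side, c0, c0, geometry$nucleus_axes_px[1],
                      geometry$nucleus_axes_px[2])
  params <- jitter_params(preset)

  amp <- matrix(0, side, side)
  tex <- texture_field(c(side, side), preset$texture)
  cyto <- cell & !nuc
  amp[cyto] <- photon_budget * tex[cyto] / mean(tex[cyto])
  amp[nuc] <- photon_budget / geometry$intensity_ratio_nucleus

  shape <- decay_shape(params, irf_kernel, axis)
  idx <- which(cell)
  counts <- array(0, dim = c(side, side, axis$n_bins))
  if (photon_budget > 0 && length(idx)) {
    mu <- outer(amp[idx], shape)  # pixels x time
    vals <- if (noiseless) mu else
      matrix(stats::rpois(length(mu), mu), nrow = length(idx))
    for (k in seq_len(axis$n_bins)) {
      pl <- counts[, , k]
      pl[idx] <- vals[, k]
      counts[, , k] <- pl
    }
  }
  structure(
    list(counts = counts, mask_crop = cell, phenotype = preset$phenotype,
         cell_id = as.integer(cell_id), source_field = source_field,
         true_params = params, amplitude_map = amp, axis = axis,
         qc = NULL),
    class = "flim_cell")
}

#' @export
print.flim_cell <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_cell> id %s, %s, %d x %d x %d, %d mask px, %.3g photons\n",
              x$cell_id, x$phenotype %||% "unlabeled", d[1], d[2], d[3],
              sum(x$mask_crop), sum(x$counts)))
  invisible(x)
}

#' Simulate a full imaging field with ground-truth masks
#'
#' Places non-overlapping elliptical cells (rejection sampling with bounded
#' attempts) on a square field and renders each with [simulate_cell()]'s
#' machinery. Returns the photon-count stack, the integer label mask and the
#' per-cell ground truth.
#'
#' @param n_cells Number of cells to place.
#' @param class_mix Named integer vector of cells per phenotype (names from
#'   [phenotype_levels()]); must sum to `n_cells`. Default: as even a split
#'   as possible.
#' @param axis A [time_axis()].
#' @param irf_kernel IRF kernel.
#' @param field_size Field side length in pixels.
#' @param photon_budget Expected photons in an average cytoplasm pixel.
#' @param presets Class presets, see [class_presets()].
#' @param seed Integer seed (stored on the field).
#' @param max_attempts Placement attempts per cell before failing.
#' @return A `flim_field`: `counts` (X, Y, T), `mask` (X, Y integer labels,
#'   0 = background), `labels` tibble (cell_id, phenotype), `truth` list of
#'   per-cell true parameters, `axis`, `seed`.
#' @export
simulate_field <- function(n_cells = 10L, class_mix = NULL,
                           axis = time_axis(),
                           irf_kernel = make_irf(axis = axis),
                           field_size = 256L, photon_budget = 2000,
                           presets = class_presets(), seed = 1L,
                           max_attempts = 200L) {
  set.seed(seed)
  n_cells <- as.integer(n_cells)
  if (is.null(class_mix)) {
    base <- n_cells %/% 3L
    class_mix <- c(glycolysis = base + (n_cells %% 3L > 0),
                   oxphos = base + (n_cells %% 3L > 1),
                   glutaminolysis = base)
  }
  if (sum(class_mix) != n_cells)
    stop("`class_mix` must sum to `n_cells`", call. = FALSE)
  phenos <- rep(names(class_mix), class_mix)
  phenos <- sample(phenos)  # shuffle placement order

  counts <- array(0L, dim = c(field_size, field_size, axis$n_bins))
  mask <- matrix(0L, field_size, field_size)
  truth <- vector("list", n_cells)
  placed <- list()
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ax_c <- stats::runif(1, 6, 9); ay_c <- stats::runif(1, 5, 8)
      cx <- stats::runif(1, ax_c + 2, field_size - ax_c - 1)
      cy <- stats::runif(1, ay_c + 2, field_size - ay_c - 1)
      clash <- any(vapply(placed, function(p)
        (cx - p[1])^2 + (cy - p[2])^2 < (ax_c + p[3] + 2)^2, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("could not place cell %d within %d attempts", i, max_attempts),
           call. = FALSE)
    placed[[length(placed) + 1]] <- c(cx, cy, max(ax_c, ay_c))
    geom <- cell_geometry(axes_px = c(ax_c, ay_c),
                          nucleus_axes_px = c(ax_c, ay_c) * stats::runif(1, 0.35, 0.45),
                          center_xy = c(cx, cy))
    rec <- simulate_cell(presets[[phenos[i]]], geom, axis, irf_kernel,
                         photon_budget, cell_id = i,
                         source_field = sprintf("field_seed%d", seed))
    side <- dim(rec$counts)[1]
    x0 <- round(cx) - (side - 1L) %/% 2L
    y0 <- round(cy) - (side - 1L) %/% 2L
    xs <- x0:(x0 + side - 1L); ys <- y0:(y0 + side - 1L)
    keepx <- xs >= 1 & xs <= field_size; keepy <- ys >= 1 & ys <= field_size
    m <- rec$mask_crop[keepx, keepy, drop = FALSE]
    sub <- mask[xs[keepx], ys[keepy]]
    sub[m] <- i
    mask[xs[keepx], ys[keepy]] <- sub
    counts[xs[keepx], ys[keepy], ] <- counts[xs[keepx], ys[keepy], , drop = FALSE] +
      rec$counts[keepx, keepy, , drop = FALSE]
    truth[[i]] <- rec$true_params
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, mask = mask,
         labels = tibble::tibble(cell_id = seq_len(n_cells), phenotype = phenos),
         truth = truth, axis = axis, seed = as.integer(seed)),
    class = "flim_field")
}

#' @export
print.flim_field <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_field> %d x %d x %d, %d cells, seed %d\n",
              d[1], d[2], d[3], nrow(x$labels), x$seed))
  print(dplyr::count(x$labels, .data$phenotype))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
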