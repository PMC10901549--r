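#' Fit an IRF-convolved bi-exponential decay
#'
#' Weighted least-squares fit of the [forward_model()] to a measured TCSPC
#' histogram, with Poisson-variance weights (`max(counts, 1)`), box bounds
#' on the parameters and Levenberg-Marquardt minimisation. Component order
#' `tau1 < tau2` is enforced after the fit (swapping and replacing `alpha1`
#' by `1 - alpha1` if needed). Non-convergence is reported in the result,
#' never raised.
#'
#' @param counts Numeric vector of photon counts per bin.
#' @param irf_kernel IRF kernel from [make_irf()].
#' @param axis A [time_axis()].
#' @param init Initial [decay_params()] (default tau1 400 ps, tau2 1800 ps,
#'   alpha1 0.7, amplitude = total counts).
#' @param lower,upper Named bound vectors for `tau1_ps`, `tau2_ps`,
#'   `alpha1`, `amplitude`, `offset`.
#' @param fit_offset If `FALSE` (default) the background offset is fixed at
#'   `init$offset`.
#' @param min_photons Minimum total counts required to attempt a fit.
#' @param reweight Number of reweighting passes: after each fit the Poisson
#'   variances are re-estimated from the fitted curve rather than the noisy
#'   counts and the fit repeated. The default (1 extra pass) removes most of
#'   the low-count bias of data-estimated weights.
#' @return A `flim_fit`: `params` (recovered [decay_params()]), `tau_m_ps`,
#'   `reduced_chisq`, `converged`, `n_photons`.
#' @export
fit_biexponential <- function(counts, irf_kernel = make_irf(axis = axis),
                              axis = time_axis(), init = NULL,
                              lower = c(tau1_ps = 100, tau2_ps = 1000,
                                        alpha1 = 0, amplitude = 1, offset = 0),
                              upper = c(tau1_ps = 800, tau2_ps = 3000,
                                        alpha1 = 1, amplitude = Inf, offset = Inf),
                              fit_offset = FALSE, min_photons = 500,
                              reweight = 1L) {
  stopifnot(inherits(axis, "flim_time_axis"))
  n_tot <- sum(counts)
  if (n_tot < min_photons)
    stop(sprintf("total counts %.0f below minimum %.0f", n_tot, min_photons),
         call. = FALSE)
  if (is.null(init))
    init <- decay_params(tau1_ps = 400, tau2_ps = 1800, alpha1 = 0.7,
                         amplitude = n_tot)
  w <- 1 / sqrt(pmax(counts, 1))
  par_names <- c("tau1_ps", "tau2_ps", "alpha1", "amplitude",
                 if (fit_offset) "offset")
  p0 <- unlist(init[par_names])
  as_params <- function(p) {
    pl <- as.list(p)
    pl$offset <- if (fit_offset) pl$offset else init$offset
    # avoid constructor validation inside the optimiser; bounds keep order
    structure(list(tau1_ps = pl$tau1_ps, tau2_ps = pl$tau2_ps,
                   alpha1 = pl$alpha1, amplitude = pl$amplitude,
                   offset = pl$offset), class = "flim_decay_params")
  }
  resid_fun <- function(p) {
    w * (forward_model(as_params(p), irf_kernel, axis) - counts)
  }
  run_fit <- function(start) tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       lower = lower[par_names], upper = upper[par_names],
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  res <- run_fit(p0)
  # re-estimate the Poisson variances from the fitted curve and refit:
  # weights from the noisy counts themselves bias the fit at low counts
  for (pass in seq_len(reweight)) {
    if (is.null(res)) break
    w <- 1 / sqrt(pmax(forward_model(as_params(res$par), irf_kernel, axis), 1))
    res2 <- run_fit(res$par)
    if (!is.null(res2)) res <- res2
  }
  if (is.null(res)) {
    params <- init
    converged <- FALSE
    rss <- sum(resid_fun(p0)^2)
    npar <- length(p0)
  } else {
    p <- res$par
    off <- if (fit_offset) p[["offset"]] else init$offset
    t1 <- p[["tau1_ps"]]; t2 <- p[["tau2_ps"]]; a1 <- p[["alpha1"]]
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; a1 <- 1 - a1 }
    params <- structure(list(tau1_ps = t1, tau2_ps = t2, alpha1 = a1,
                             amplitude = p[["amplitude"]], offset = off),
                        class = "flim_decay_params")
    converged <- res$info %in% 1:4
    rss <- res$deviance
    npar <- length(p0)
  }
  structure(
    list(params = params,
         tau_m_ps = params$alpha1 * params$tau1_ps +
           (1 - params$alpha1) * params$tau2_ps,
         reduced_chisq = rss / max(1L, length(counts) - npar),
         converged = converged, n_photons = n_tot),
    class = "flim_fit")
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_fit> tau1 %.0f ps, tau2 %.0f ps, alpha1 %.3f, tau_m %.0f ps, chisq_r %.3g%s\n",
    x$params$tau1_ps, x$params$tau2_ps, x$params$alpha1, x$tau_m_ps,
    x$reduced_chisq, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.flim_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau1_ps", "tau2_ps", "alpha1", "amplitude", "offset", "tau_m_ps"),
    estimate = c(x$params$tau1_ps, x$params$tau2_ps, x$params$alpha1,
                 x$params$amplitude, x$params$offset, x$tau_m_ps))
}

#' @export
glance.flim_fit <- function(x, ...) {
  tibble::tibble(reduced_chisq = x$reduced_chisq, converged = x$converged,
                 n_photons = x$n_photons, tau_m_ps = x$tau_m_ps)
}

#' Fit every cell of a list and return a tidy table
#'
#' Sums each cell's masked pixels into one decay, fits it with
#' [fit_biexponential()], and returns one row per cell. Cells whose total
#' counts fall below `min_photons` get `NA` estimates.
#'
#' @param cells List of `flim_cell` records.
#' @inheritParams fit_biexponential
#' @return Tibble: cell_id, phenotype, tau1_ps, tau2_ps, alpha1, tau_m_ps,
#'   reduced_chisq, converged, n_photons.
#' @export
fit_cells <- function(cells, irf_kernel = NULL, axis = NULL,
                      min_photons = 500, ...) {
  purrr::map_dfr(cells, function(cl) {
    ax <- axis %||% cl$axis
    irf <- irf_kernel %||% make_irf(axis = ax)
    dec <- apply(cl$counts, 3, sum)
    base <- tibble::tibble(cell_id = cl$cell_id,
                           phenotype = cl$phenotype %||% NA_character_)
    ft <- tryCatch(fit_biexponential(dec, irf, ax, min_photons = min_photons, ...),
                   error = function(e) NULL)
    if (is.null(ft))
      return(dplyr::mutate(base, tau1_ps = NA_real_, tau2_ps = NA_real_,
                           alpha1 = NA_real_, tau_m_ps = NA_real_,
                           reduced_chisq = NA_real_, converged = FALSE,
                           n_photons = sum(dec)))
    dplyr::mutate(base, tau1_ps = ft$params$tau1_ps, tau2_ps = ft$params$tau2_ps,
                  alpha1 = ft$params$alpha1, tau_m_ps = ft$tau_m_ps,
                  reduced_chisq = ft$reduced_chisq, converged = ft$converged,
                  n_photons = ft$n_photons)
  })
}

#' Mean-lifetime image of a field
#'
#' For every pixel, pools the decays of its neighbourhood (spatial binning:
#' `bin = 1` pools the 3x3 square, i.e. 9 pixels), fits the pooled decay
#' and stores the amplitude-weighted mean lifetime. Pixels whose pooled
#' counts fall below `min_photons` are `NA` (missing), never zero.
#'
#' @param field A `flim_field`.
#' @param irf_kernel IRF kernel.
#' @param bin Neighbourhood radius; the pooled square has side `2*bin + 1`.
#' @param min_photons Minimum pooled counts to attempt a fit.
#' @param mask_only If `TRUE` (default) only pixels inside the cell mask are
#'   fitted.
#' @return List with `tau_m` (X x Y matrix, ps, `NA` where not fitted) and
#'   `intensity` (X x Y total counts).
#' @export
tau_m_image <- function(field, irf_kernel = make_irf(axis = field$axis),
                        bin = 1L, min_photons = 500, mask_only = TRUE) {
  stopifnot(inherits(field, "flim_field"))
  d <- dim(field$counts)
  intensity <- apply(field$counts, c(1, 2), sum)
  taum <- matrix(NA_real_, d[1], d[2])
  tod <- if (mask_only) which(field$mask != 0, arr.ind = TRUE)
         else as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2])))
  for (r in seq_len(nrow(tod))) {
    i <- tod[r, 1]; j <- tod[r, 2]
    xs <- max(1, i - bin):min(d[1], i + bin)
    ys <- max(1, j - bin):min(d[2], j + bin)
    dec <- apply(field$counts[xs, ys, , drop = FALSE], 3, sum)
    if (sum(dec) < min_photons) next
    ft <- tryCatch(
      fit_biexponential(dec, irf_kernel, field$axis, min_photons = min_photons),
      error = function(e) NULL)
    if (!is.null(ft)) taum[i, j] <- ft$tau_m_ps
  }
  list(tau_m = taum, intensity = intensity)
}

#' Write a mean-lifetime image pair to TIFF
#'
#' Stores the tau_m map as a 16-bit TIFF in integer picoseconds (lossless
#' for lifetimes below 65.5 ns; unfitted pixels are stored as 0, which is
#' never a valid lifetime) and the total photon-count image alongside it,
#' as `<prefix>_taum.tif` and `<prefix>_intensity.tif`.
#'
#' @param taum Output of [tau_m_image()].
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_tau_m_image <- function(taum, prefix) {
  m <- round(taum$tau_m)
  m[is.na(m)] <- 0
  check_uint16(m, "tau_m (ps)")
  tiff::writeTIFF(m / 65535, paste0(prefix, "_taum.tif"),
                  bits.per.sample = 16L, compression = "none")
  check_uint16(taum$intensity, "intensity")
  tiff::writeTIFF(taum$intensity / 65535, paste0(prefix, "_intensity.tif"),
                  bits.per.sample = 16L, compression = "none")
  invisible(prefix)
}

#' Population-average normalised decay curve
#'
#' Each in-mask pixel's decay is divided by its own maximum, the normalised
#' decays are averaged within each cell, and the per-cell curves are then
#' averaged across cells. All-zero pixels are excluded from the within-cell
#' average. This is the standard way to display class-average TPSF curves.
#'
#' @param cells List of `flim_cell` records sharing one time axis.
#' @return Numeric vector of length T with maximum <= 1.
#' @export
average_decay_curve <- function(cells) {
  if (!length(cells)) stop("need at least one cell", call. = FALSE)
  per_cell <- purrr::map(cells, function(cl) {
    d <- dim(cl$counts)
    m <- matrix(cl$counts, prod(d[1:2]), d[3])[which(cl$mask_crop), , drop = FALSE]
    mx <- apply(m, 1, max)
    m <- m[mx > 0, , drop = FALSE]
    if (!nrow(m)) stop("cell with no nonzero pixels", call. = FALSE)
    colMeans(m / apply(m, 1, max))
  })
  Reduce(`+`, per_cell) / length(per_cell)
}
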