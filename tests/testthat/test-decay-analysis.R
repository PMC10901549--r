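test_that("forward model and the simulator's noiseless mode are one contract", {
  ax <- time_axis()
  irf <- default_irf()
  p <- decay_params(420, 1700, 0.6, amplitude = 5e4, offset = 1)
  expect_identical(forward_model(p, irf, ax),
                   simulate_decay(p, irf, ax, noiseless = TRUE))
  # alpha1 = 0: pure long-lifetime curve
  p0 <- decay_params(400, 1800, 0, amplitude = 1e4)
  p1 <- structure(list(tau1_ps = 1, tau2_ps = 1800, alpha1 = 0,
                       amplitude = 1e4, offset = 0),
                  class = "flim_decay_params")
  expect_equal(forward_model(p0, irf, ax), forward_model(p1, irf, ax),
               tolerance = 1e-12)
  # photon conservation over the window
  expect_equal(sum(forward_model(p, irf, ax)), 5e4 + 1 * 256,
               tolerance = 1e-6)
})

test_that("bi-exponential fits recover noiseless truth to within 1%", {
  ax <- time_axis()
  irf <- default_irf()
  truth <- decay_params(400, 1800, 0.7, amplitude = 1e5)
  mu <- forward_model(truth, irf, ax)
  ft <- fit_biexponential(mu, irf, ax)
  expect_true(ft$converged)
  expect_equal(ft$params$tau1_ps, 400, tolerance = 0.01)
  expect_equal(ft$params$tau2_ps, 1800, tolerance = 0.01)
  expect_equal(ft$params$alpha1, 0.7, tolerance = 0.01)
  # fixed point: fitting a forward curve starting from truth returns truth
  ft2 <- fit_biexponential(mu, irf, ax, init = truth)
  expect_equal(ft2$params$alpha1, 0.7, tolerance = 1e-4)
  expect_equal(ft2$params$tau1_ps, 400, tolerance = 1e-3)
})

test_that("mono-exponential input drives the short fraction to one", {
  ax <- time_axis()
  irf <- default_irf()
  mono <- decay_params(400, 1800, 1, amplitude = 1e5)
  ft <- fit_biexponential(forward_model(mono, irf, ax), irf, ax)
  expect_gte(ft$params$alpha1, 0.99)
})

test_that("fit results satisfy the mean-lifetime identity and bounds", {
  ax <- time_axis()
  irf <- default_irf()
  set.seed(7)
  for (a1 in c(0.3, 0.68, 0.79)) {
    y <- simulate_decay(decay_params(400, 1800, a1, amplitude = 2e4), irf, ax)
    ft <- fit_biexponential(y, irf, ax)
    expect_equal(ft$tau_m_ps,
                 ft$params$alpha1 * ft$params$tau1_ps +
                   (1 - ft$params$alpha1) * ft$params$tau2_ps)
    expect_gte(ft$tau_m_ps, ft$params$tau1_ps)
    expect_lte(ft$tau_m_ps, ft$params$tau2_ps)
    expect_equal(mean_lifetime(ft), ft$tau_m_ps)
  }
  # low-count input is refused, not silently fitted
  expect_error(fit_biexponential(rep(1, 256), default_irf()), "below minimum")
})

test_that("the short-lifetime fraction estimator is nearly unbiased at 1e4 photons", {
  ax <- time_axis()
  irf <- default_irf()
  truth <- decay_params(400, 1800, 0.7, amplitude = 1e4)
  mu <- forward_model(truth, irf, ax)
  set.seed(11)
  est <- replicate(60, fit_biexponential(rpois(256, mu), irf, ax)$params$alpha1)
  expect_lt(abs(mean(est) - 0.7), 0.02)          # bias
  expect_lt(sqrt(mean((est - 0.7)^2)), 0.05)     # RMSE
})

test_that("fitted short fractions separate the metabolic classes", {
  # pixel-averaged decays of simulated cells, fitted per cell: the recovered
  # alpha1 separates glycolysis from OXPHOS almost perfectly
  ax <- toy_axis()
  irf <- make_irf(irf_spec(), ax)
  cells <- toy_cells(n_per_class = 25L, seed0 = 900L)
  fits <- fit_cells(cells, irf_kernel = irf, axis = ax)
  pos <- fits$phenotype == "glycolysis"
  rk <- rank(fits$alpha1)
  auc <- (sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  expect_gt(auc, 0.95)
})

test_that("mean-lifetime images are flat for uniform fields and ordered across classes", {
  ax <- time_axis(64L, 12.5)
  irf <- make_irf(irf_spec(), ax)
  pres <- class_presets(cell_cv = 0)      # uniform parameters
  fg <- simulate_field(3L, class_mix = c(glycolysis = 3L), axis = ax,
                       irf_kernel = irf, field_size = 64L, seed = 5L,
                       presets = pres, photon_budget = 3000)
  img_g <- tau_m_image(fg, irf, min_photons = 800)
  vals_g <- img_g$tau_m[!is.na(img_g$tau_m)]
  expect_gt(length(vals_g), 50)
  expect_lt(stats::sd(vals_g) / mean(vals_g), 0.05)
  # background pixels are missing, not zero
  expect_true(all(is.na(img_g$tau_m[fg$mask == 0])))
  fo <- simulate_field(3L, class_mix = c(oxphos = 3L), axis = ax,
                       irf_kernel = irf, field_size = 64L, seed = 6L,
                       presets = pres, photon_budget = 3000)
  img_o <- tau_m_image(fo, irf, min_photons = 800)
  expect_lt(mean(vals_g), mean(img_o$tau_m, na.rm = TRUE))
})

test_that("average decay curves are normalised and correctly ordered", {
  cells <- small_field_cells()
  phen <- vapply(cells, `[[`, character(1), "phenotype")
  cv <- average_decay_curve(cells)
  expect_lte(max(cv), 1)
  # single cell, single pixel: the curve is that pixel's decay scaled to 1
  cl <- cells[[1]]
  px <- which(cl$mask_crop, arr.ind = TRUE)
  best <- px[which.max(apply(px, 1, function(rc) sum(cl$counts[rc[1], rc[2], ]))), ]
  one <- cl
  one$mask_crop[] <- FALSE
  one$mask_crop[best[1], best[2]] <- TRUE
  dec <- cl$counts[best[1], best[2], ]
  expect_equal(average_decay_curve(list(one)), dec / max(dec))
})

test_that("tidy and glance methods expose fit results as tibbles", {
  ax <- time_axis()
  irf <- default_irf()
  ft <- fit_biexponential(forward_model(decay_params(400, 1800, 0.79,
                                                     amplitude = 1e5),
                                        irf, ax), irf, ax)
  td <- tidy(ft)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "alpha1"], 0.79, tolerance = 0.01)
  gl <- glance(ft)
  expect_true(gl$converged)
  expect_equal(gl$tau_m_ps, 694, tolerance = 0.01)
})
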