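test_that("class presets carry the published short-lifetime fractions", {
  pres <- class_presets()
  expect_named(pres, c("glycolysis", "oxphos", "glutaminolysis"))
  expect_equal(pres$glycolysis$mean_params$alpha1, 0.79)
  expect_equal(pres$oxphos$mean_params$alpha1, 0.68)
  expect_equal(pres$glutaminolysis$mean_params$alpha1, 0.68)
  expect_gt(pres$glycolysis$mean_params$alpha1, pres$oxphos$mean_params$alpha1)
  for (p in pres) {
    expect_gte(p$mean_params$tau1_ps, 300)
    expect_lte(p$mean_params$tau1_ps, 500)
    expect_gte(p$mean_params$tau2_ps, 1500)
    expect_lte(p$mean_params$tau2_ps, 2000)
  }
  # oxphos and glutaminolysis share alpha1 but differ in a surrogate cue
  expect_false(identical(pres$oxphos$texture, pres$glutaminolysis$texture) &&
                 pres$oxphos$mean_params$tau2_ps ==
                   pres$glutaminolysis$mean_params$tau2_ps)
})

test_that("noiseless decays conserve photons and decay monotonically after the peak", {
  ax <- time_axis()
  irf <- default_irf()
  p <- decay_params(400, 1800, 0.79, amplitude = 1e5, offset = 2)
  mu <- simulate_decay(p, irf, ax, noiseless = TRUE)
  expect_equal(sum(mu), 1e5 + 2 * 256, tolerance = 1e-6)
  pk <- which.max(mu)
  expect_true(all(diff(mu[pk:length(mu)]) <= 1e-9))
})

test_that("the mono-exponential limit with a delta IRF is a pure exponential", {
  ax <- time_axis()
  delta <- c(1, numeric(255))
  p <- decay_params(400, 1800, 1, amplitude = 1e4)
  mu <- simulate_decay(p, delta, ax, noiseless = TRUE)
  t_rel <- (seq_len(256) - 1) * ax$bin_width_ps
  expected <- exp(-t_rel / 400)
  expect_equal(mu / mu[1], expected, tolerance = 1e-9)
})

test_that("the default IRF places the noiseless decay peak at frame 64-65", {
  ax <- time_axis()
  irf <- default_irf()
  for (pr in class_presets()) {
    p <- pr$mean_params
    p$amplitude <- 1e5
    mu <- simulate_decay(p, irf, ax, noiseless = TRUE)
    expect_true(which.max(mu) %in% c(64L, 65L))
  }
})

test_that("Poisson totals concentrate around the amplitude", {
  ax <- time_axis()
  irf <- default_irf()
  p <- decay_params(400, 1800, 0.79, amplitude = 1e5, offset = 0)
  set.seed(99)
  totals <- replicate(20, sum(simulate_decay(p, irf, ax)))
  expect_true(all(abs(totals - 1e5) < 4 * sqrt(1e5)))
})

test_that("simulated cells honour geometry, brightness contrast and determinism", {
  pres <- class_presets()
  cl <- simulate_cell(pres$glycolysis, seed = 2L)
  expect_s3_class(cl, "flim_cell")
  # outside-mask pixels all zero
  tot <- apply(cl$counts, c(1, 2), sum)
  expect_true(all(tot[!cl$mask_crop] == 0))
  # cytoplasm / nucleus brightness ratio ~ intensity_ratio_nucleus (10%)
  geom <- cell_geometry()
  nuc <- abs(cl$amplitude_map - 2000 / geom$intensity_ratio_nucleus) < 1e-9
  cyto <- cl$mask_crop & !nuc
  ratio <- mean(tot[cyto]) / mean(tot[nuc])
  expect_equal(ratio, geom$intensity_ratio_nucleus, tolerance = 0.1)
  # determinism: same seed, bit-identical stack
  cl2 <- simulate_cell(pres$glycolysis, seed = 2L)
  expect_identical(cl$counts, cl2$counts)
  # zero photon budget -> all-zero stack
  cl0 <- simulate_cell(pres$oxphos, photon_budget = 0, seed = 5L)
  expect_true(all(cl0$counts == 0))
  # invalid geometry rejected
  expect_error(cell_geometry(axes_px = c(5, 5), nucleus_axes_px = c(6, 2)),
               "nucleus")
})

test_that("simulated fields have the requested cell count and class mix", {
  f <- small_field()
  labs <- sort(unique(as.vector(f$mask)))
  expect_equal(setdiff(labs, 0L), 1:10)
  expect_true(all(f$counts >= 0))
  mix <- c(glycolysis = 4L, oxphos = 3L, glutaminolysis = 3L)
  f2 <- simulate_field(10L, class_mix = mix, field_size = 96L, seed = 4L)
  cnt <- table(f2$labels$phenotype)
  expect_equal(cnt[["glycolysis"]], 4L)
  expect_equal(cnt[["oxphos"]], 3L)
  expect_equal(cnt[["glutaminolysis"]], 3L)
  expect_error(simulate_field(4L, class_mix = c(glycolysis = 3L), seed = 1L),
               "sum")
  # impossible packing fails naming the cell index
  expect_error(simulate_field(20L, field_size = 40L, seed = 1L,
                              max_attempts = 10L),
               "cell")
})

test_that("glycolysis-preset cells decay faster than oxphos cells after the peak", {
  cells <- small_field_cells()
  phen <- vapply(cells, `[[`, character(1), "phenotype")
  cg <- average_decay_curve(cells[phen == "glycolysis"])
  co <- average_decay_curve(cells[phen == "oxphos"])
  ax <- small_field()$axis
  at2ns <- which.max(cg) + round(2000 / ax$bin_width_ps)
  expect_lt(cg[at2ns], co[at2ns])
})

test_that("seeded field simulation is reproducible", {
  f1 <- simulate_field(5L, field_size = 80L, seed = 21L)
  f2 <- simulate_field(5L, field_size = 80L, seed = 21L)
  expect_identical(f1$counts, f2$counts)
  expect_identical(f1$mask, f2$mask)
  expect_identical(f1$labels, f2$labels)
})
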