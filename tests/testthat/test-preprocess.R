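test_that("cell extraction crops tight bounding boxes and preserves photons", {
  field <- small_field()
  cells <- small_field_cells()
  expect_length(cells, 10)
  for (cl in cells[1:3]) {
    # bounding box is tight: mask touches every edge of the crop
    expect_true(any(cl$mask_crop[1, ]) && any(cl$mask_crop[nrow(cl$mask_crop), ]))
    expect_true(any(cl$mask_crop[, 1]) && any(cl$mask_crop[, ncol(cl$mask_crop)]))
    # photon sum inside the mask is preserved by extraction
    sel <- field$mask == cl$cell_id
    orig <- sum(vapply(seq_len(dim(field$counts)[3]),
                       function(k) sum(field$counts[, , k][sel]), numeric(1)))
    expect_equal(sum(cl$counts), orig)
  }
})

test_that("peak_frame matches an exhaustive argmax and the expected NAD(P)H peak", {
  # delta decay at frame 10
  arr <- array(0, dim = c(2, 2, 32))
  arr[, , 10] <- 5
  expect_equal(peak_frame(arr), 10L)
  # brute-force oracle over a noisy cell
  cl <- small_field_cells()[[1]]
  sums <- vapply(seq_len(dim(cl$counts)[3]),
                 function(k) sum(cl$counts[, , k]), numeric(1))
  expect_equal(peak_frame(cl), which(sums == max(sums))[1])
  # noiseless simulated cell with the default IRF peaks at frame 64-65
  nl <- simulate_cell(class_presets()$glycolysis, seed = 1L, noiseless = TRUE)
  expect_true(peak_frame(nl) %in% c(64L, 65L))
  expect_error(peak_frame(array(0, dim = c(2, 2, 4))), "all-zero")
})

test_that("frame entropy follows the histogram definition", {
  expect_equal(frame_entropy(matrix(7, 5, 5)), 0)      # single occupied bin
  expect_equal(frame_entropy(matrix(0, 5, 5)), 0)      # all-zero convention
  # two gray levels, half the pixels each -> 1 bit
  two <- matrix(c(rep(1, 8), rep(255, 8)), 4, 4)
  expect_equal(frame_entropy(two), 1)
  # permutation invariance
  fr <- matrix(rpois(64, 20), 8, 8)
  expect_equal(frame_entropy(fr),
               frame_entropy(matrix(sample(fr), 8, 8)))
  expect_error(frame_entropy(matrix(-1, 2, 2)), "non-negative")
})

test_that("the entropy filter removes outliers and nests with k_sigma", {
  cells <- small_field_cells()
  # a near-empty crop is an entropy outlier among well-formed cells
  junk <- cells[[1]]
  junk$counts[] <- 0L
  junk$counts[1, 1, 1:4] <- 1L
  junk$cell_id <- 99L
  many <- c(rep(cells, 5), list(junk))  # 50 good cells + 1 outlier
  flt <- entropy_filter(many, k_sigma = 2)
  expect_false(flt$qc$retained[flt$qc$cell_id == 99L])
  # direct verification of the rule
  mu <- mean(flt$qc$entropy); sg <- sd(flt$qc$entropy)
  expect_true(all((flt$qc$entropy >= mu - 2 * sg &
                     flt$qc$entropy <= mu + 2 * sg) == flt$qc$retained))
  # k_sigma -> Inf retains everything; retention is monotone in k_sigma
  expect_length(entropy_filter(many, k_sigma = Inf)$cells, length(many))
  n_ret <- vapply(c(0.5, 1, 2, 4, Inf),
                  function(k) length(entropy_filter(many, k)$cells), numeric(1))
  expect_true(all(diff(n_ret) >= 0))
  expect_error(entropy_filter(cells[1]), "at least 2")
})

test_that("spatial standardisation pads then centre-crops to 21 x 21", {
  cells <- small_field_cells()
  for (cl in cells[1:4]) {
    s <- standardize_spatial(cl)
    expect_equal(dim(s$counts)[1:2], c(21L, 21L))
    expect_equal(dim(s$counts)[3], dim(cl$counts)[3])   # T unchanged
    expect_true(all(s$counts >= 0))
    expect_equal(sum(s$counts), sum(cl$counts))          # cell fits the centre
  }
  # a 21 x 21 input comes back unchanged
  cl <- cells[[1]]
  s1 <- standardize_spatial(cl)
  expect_identical(standardize_spatial(s1)$counts, s1$counts)
  # oversized cells are rejected with a clear message
  big <- cl
  big$counts <- array(0L, dim = c(45, 10, 8))
  big$mask_crop <- matrix(TRUE, 45, 10)
  expect_error(standardize_spatial(big), "exceeds 40")
})

test_that("temporal down-sampling halves T and preserves structure", {
  cells <- small_field_cells()
  s <- standardize_spatial(cells[[1]])
  for (method in c("mean", "median")) {
    d <- downsample_time(s, downsample_spec(method))
    expect_equal(dim(d$counts), c(21L, 21L, 128L))
    expect_equal(d$axis$n_bins, 128L)
  }
  # constant-in-time stack is untouched
  const <- array(7L, dim = c(3, 3, 16))
  expect_true(all(downsample_time(const) == 7L))
  expect_equal(dim(downsample_time(const))[3], 8L)
  # odd T: output length is ceil(T/2)
  expect_equal(dim(downsample_time(array(1, dim = c(2, 2, 15))))[3], 8L)
  # window-3 median of a strictly decreasing decay equals the original
  # value at every interior frame (brute-force frame-wise comparison)
  dec <- 1000 * exp(-(0:63) / 10)
  arr <- array(rep(round(dec), each = 1), dim = c(1, 1, 64))
  md <- downsample_time(arr, downsample_spec("median"))
  odd <- seq(1, 63, by = 2)
  interior <- odd > 1  # first frame uses edge replication
  expect_equal(as.vector(md)[interior], round(dec)[odd][interior])
  expect_error(downsample_spec(window = 4), "odd")
})

test_that("temporal features are masked means with T entries", {
  cells <- small_field_cells()
  cl <- cells[[2]]
  tf <- temporal_features(cl)
  expect_length(tf, 256)
  # single-pixel cell: features equal that pixel's decay
  one <- cl
  one$mask_crop <- matrix(FALSE, nrow(cl$mask_crop), ncol(cl$mask_crop))
  px <- which(cl$mask_crop, arr.ind = TRUE)[1, ]
  one$mask_crop[px[1], px[2]] <- TRUE
  expect_equal(temporal_features(one), cl$counts[px[1], px[2], ])
  # linearity
  tripled <- cl
  tripled$counts <- cl$counts * 3L
  expect_equal(temporal_features(tripled), 3 * tf)
})

test_that("down-sampling shifts the peak frame to about half its index", {
  nl <- simulate_cell(class_presets()$oxphos, seed = 9L, noiseless = TRUE)
  pk <- peak_frame(nl)
  for (method in c("mean", "median")) {
    pk2 <- peak_frame(downsample_time(nl, downsample_spec(method)))
    expect_lte(abs(pk2 - ceiling(pk / 2)), 1)
  }
})

test_that("dataset assembly stratifies splits and folds", {
  cells <- toy_cells(n_per_class = 50L)  # 100 cells, 2 classes
  ds <- build_dataset(cells, seed = 42L)
  expect_equal(sum(ds$info$split == "train"), 70L)
  expect_equal(sum(ds$info$split == "val"), 10L)
  expect_equal(sum(ds$info$split == "test"), 20L)
  # folds partition the cells
  expect_setequal(ds$info$fold, 1:5)
  expect_equal(sort(unlist(lapply(1:5, function(f)
    ds$info$cell_id[ds$info$fold == f]))), sort(ds$info$cell_id))
  # per-fold class proportions within 1 cell of global proportions
  tab <- table(ds$info$fold, ds$info$phenotype)
  for (cl in colnames(tab))
    expect_lte(max(tab[, cl]) - min(tab[, cl]), 1)
  expect_error(build_dataset(cells[c(1:3, 51:53)], folds = 5L), "fewer cells")
  # unlabeled cells rejected
  un <- cells
  un[[1]]$phenotype <- NULL
  expect_error(build_dataset(un), "labelled")
})

test_that("the preprocessing chain is deterministic", {
  f <- simulate_field(6L, field_size = 80L, seed = 31L)
  a <- preprocess_field(f, downsample = "mean")
  b <- preprocess_field(f, downsample = "mean")
  expect_identical(lapply(a$cells, `[[`, "counts"),
                   lapply(b$cells, `[[`, "counts"))
  expect_identical(a$qc, b$qc)
})
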