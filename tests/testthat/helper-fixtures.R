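# Shared fixtures, generated in code. Heavier objects are memoised within a
# test run so several test files can reuse them without re-simulating.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

# cells on a short 64-bin axis: fast to simulate and to train on
toy_axis <- function() time_axis(64L, 12.5)

toy_cells <- function(n_per_class = 10L, phenos = c("glycolysis", "oxphos"),
                      seed0 = 500L, photon_budget = 2000) {
  ax <- toy_axis()
  irf <- make_irf(irf_spec(), ax)
  pres <- class_presets()
  cells <- list()
  i <- 0L
  for (ph in phenos) for (j in seq_len(n_per_class)) {
    i <- i + 1L
    cells[[i]] <- standardize_spatial(
      simulate_cell(pres[[ph]], axis = ax, irf_kernel = irf,
                    photon_budget = photon_budget, seed = seed0 + i,
                    cell_id = i))
  }
  cells
}

small_field <- function() {
  memo("small_field",
       simulate_field(10L, field_size = 96L, seed = 3L))
}

small_field_cells <- function() {
  memo("small_field_cells", extract_cells(small_field()))
}

default_irf <- function() memo("default_irf", make_irf(irf_spec(), time_axis()))
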