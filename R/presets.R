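#' Metabolic class presets for the synthetic generator
#'
#' Returns one preset per metabolic phenotype. The temporal signature is the
#' short-lifetime (free NAD(P)H) fraction: 0.79 for glycolysis vs 0.68 for
#' OXPHOS and glutaminolysis, with lifetimes inside the canonical free
#' (300-500 ps) and bound (1.5-2 ns) ranges. Because OXPHOS and
#' glutaminolysis share the same short-lifetime fraction, the generator
#' injects two configurable surrogate cues that keep the three classes
#' distinguishable: a +100 ps long-lifetime offset for glutaminolysis and a
#' cytoplasmic texture difference (networked mitochondria-like intensity for
#' OXPHOS vs punctate for the glycolysis/glutaminolysis presets). Both cues
#' are modelling choices of this package, not measured facts.
#'
#' @param cell_cv Per-cell coefficient of variation applied to lifetimes and
#'   to the short-lifetime fraction when simulating cells.
#' @param glutaminolysis_tau2_offset_ps Surrogate long-lifetime offset added
#'   to the glutaminolysis preset, ps.
#' @return Named list of `flim_class_preset` objects, in the order
#'   glycolysis, oxphos, glutaminolysis.
#' @examples
#' class_presets()$glycolysis$mean_params$alpha1  # 0.79
#' @export
class_presets <- function(cell_cv = 0.04, glutaminolysis_tau2_offset_ps = 100) {
  mk <- function(phenotype, alpha1, tau2, texture) {
    structure(
      list(phenotype = phenotype,
           mean_params = decay_params(tau1_ps = 400, tau2_ps = tau2,
                                      alpha1 = alpha1, amplitude = 1),
           cell_cv = cell_cv,
           texture = texture),
      class = "flim_class_preset")
  }
  list(
    glycolysis     = mk("glycolysis", 0.79, 1800, "punctate"),
    oxphos         = mk("oxphos", 0.68, 1800, "networked"),
    glutaminolysis = mk("glutaminolysis", 0.68,
                        1800 + glutaminolysis_tau2_offset_ps, "punctate"))
}

#' Phenotype levels used throughout the package
#' @return Character vector of the three phenotype names.
#' @export
phenotype_levels <- function() c("glycolysis", "oxphos", "glutaminolysis")

#' @export
print.flim_class_preset <- function(x, ...) {
  cat(sprintf("<class_preset> %s: alpha1 %.2f, tau1 %.0f ps, tau2 %.0f ps, cv %.2f, %s\n",
              x$phenotype, x$mean_params$alpha1, x$mean_params$tau1_ps,
              x$mean_params$tau2_ps, x$cell_cv, x$texture))
  invisible(x)
}

#' Tidy view of the class presets
#'
#' @param presets Output of [class_presets()].
#' @return A tibble with one row per phenotype.
#' @export
preset_table <- function(presets = class_presets()) {
  purrr::map_dfr(presets, function(p)
    tibble::tibble(phenotype = p$phenotype,
                   alpha1 = p$mean_params$alpha1,
                   tau1_ps = p$mean_params$tau1_ps,
                   tau2_ps = p$mean_params$tau2_ps,
                   cell_cv = p$cell_cv,
                   texture = p$texture))
}
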