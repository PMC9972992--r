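#' Named parameter presets for the worked analyses
#'
#' The package ships the parameter sets used throughout its figures and
#' tests as named presets. `fig3A`--`fig3D` are the four interaction
#' scenarios of the baseline analysis (competition, commensal exploits
#' pathogen, pathogen exploits commensal, mutualism) with
#' `r_p = r_c = 0.5`, `k_p = k_c = 1`, `x = 0.1`. `figS1`--`figS4` vary the
#' demographic asymmetries (growth rates, carrying capacities) with
#' competitive interactions. `fig4` and `figS6` are the competition scenario
#' under maximal exposure (`A = 1`); `fig5B`/`fig5C` are the
#' susceptible-commensal (`f = 2`) and resistant-commensal (`f = 0.5`)
#' temporal scenarios.
#'
#' `A` defaults to 0 and `f` to 1 except where the scenario pins them; both
#' are typically swept or overridden via [lv_update()].
#'
#' @param name Preset name; see [lv_presets()] for the registry.
#' @return An [lv_params()] object.
#' @examples
#' lv_preset("fig3A")
#' lv_update(lv_preset("fig3A"), A = 1, f = 2)
#' @export
lv_preset <- function(name) {
  reg <- lv_preset_registry()
  if (!name %in% names(reg)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  do.call(lv_params, reg[[name]]$params)
}

#' List available Lotka-Volterra presets
#'
#' @return A tibble with preset names and a provenance note for each.
#' @export
lv_presets <- function() {
  reg <- lv_preset_registry()
  tibble::tibble(
    name = names(reg),
    note = vapply(reg, function(z) z$note, character(1))
  )
}

lv_preset_registry <- function() {
  base <- list(r_p = 0.5, r_c = 0.5, k_p = 1, k_c = 1, x = 0.1, f = 1, A = 0)
  with_alpha <- function(b, apc, acp, ...) {
    b$alpha_pc <- apc
    b$alpha_cp <- acp
    extra <- list(...)
    b[names(extra)] <- extra
    b
  }
  list(
    fig3A = list(params = with_alpha(base, 0.8, 0.8),
                 note = "competition (symmetric demography)"),
    fig3B = list(params = with_alpha(base, 0.8, -0.8),
                 note = "commensal exploits pathogen"),
    fig3C = list(params = with_alpha(base, -0.8, 0.8),
                 note = "pathogen exploits commensal"),
    fig3D = list(params = with_alpha(base, -0.8, -0.8),
                 note = "mutualism"),
    fig4 = list(params = with_alpha(base, 0.8, 0.8, A = 1),
                note = "competition under maximal exposure (gradient map)"),
    figS1 = list(params = with_alpha(modifyList(base, list(r_p = 0.25, r_c = 0.75)), 0.8, 0.8),
                 note = "commensal grows faster (r_c > r_p), competition"),
    figS2 = list(params = with_alpha(modifyList(base, list(k_p = 0.5, k_c = 1.5)), 0.8, 0.8),
                 note = "commensal higher capacity (k_c > k_p), competition"),
    figS3 = list(params = with_alpha(modifyList(base, list(r_p = 0.75, r_c = 0.25)), 0.8, 0.8),
                 note = "pathogen grows faster (r_p > r_c), competition"),
    figS4 = list(params = with_alpha(modifyList(base, list(k_p = 1.5, k_c = 0.5)), 0.8, 0.8),
                 note = "pathogen higher capacity (k_p > k_c), competition"),
    fig5A = list(params = with_alpha(base, 0.8, 0.8, A = 0),
                 note = "pathogen clonal infection (run with C0 = 0)"),
    fig5B = list(params = with_alpha(base, 0.8, 0.8, f = 2),
                 note = "drug-susceptible commensal (f = 2)"),
    fig5C = list(params = with_alpha(base, 0.8, 0.8, f = 0.5),
                 note = "drug-resistant commensal (f = 0.5)"),
    figS6 = list(params = with_alpha(base, 0.8, 0.8, A = 1),
                 note = "risk optimisation ecology (competition, A = 1)")
  )
}
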