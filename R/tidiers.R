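#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an equilibrium classification
#'
#' One row per equilibrium (candidate or attractor) with densities, outcome
#' kind and stability flags.
#'
#' @param x An `lv_equilibrium` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.lv_equilibrium <- function(x, ...) {
  tibble::as_tibble(unclass(x)[!names(unclass(x)) %in% character(0)])
}

#' @rdname tidy.lv_equilibrium
#' @export
glance.lv_equilibrium <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_states = nrow(x),
    any_stable = any(x$stable),
    A = p$A, f = p$f, alpha_pc = p$alpha_pc, alpha_cp = p$alpha_cp
  )
}

#' Tidy a trajectory into long (species) format
#'
#' @param x An `lv_trajectory` object.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `density`.
#' @export
tidy.lv_trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "density")
}

#' @rdname tidy.lv_trajectory
#' @export
glance.lv_trajectory <- function(x, ...) {
  last <- nrow(x)
  out <- tibble::tibble(
    terminal_P = x$P[last],
    terminal_C = x$C[last],
    converged = attr(x, "converged"),
    residual = attr(x, "residual")
  )
  if ("R" %in% names(x)) out$terminal_R <- x$R[last]
  out
}

#' Summary of a parameter sweep
#'
#' Outcome composition of the grid plus the release threshold when defined.
#'
#' @param x An `lv_scan` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lv_scan <- function(x, ...) {
  base <- attr(x, "base_params")
  thr <- if (base$alpha_pc > 0) release_threshold_f(base) else NA_real_
  prop <- function(kind) mean(x$outcome == kind)
  tibble::tibble(
    n_cells = nrow(x),
    prop_coexistence = prop("coexistence"),
    prop_pathogen_dominance = prop("pathogen_dominance"),
    prop_commensal_dominance = prop("commensal_dominance"),
    release_threshold_f = thr
  )
}

#' Summary of a risk profile
#'
#' @param x A `risk_profile` object.
#' @param ... Unused.
#' @return A one-row tibble with the argmin and any interior peak.
#' @export
glance.risk_profile <- function(x, ...) {
  opt <- optimal_f(x)
  pk <- interior_peak(x)
  tibble::tibble(
    f_opt = opt$f_opt, min_risk = opt$min_risk, n_ties = opt$n_ties,
    f_peak = if (is.null(pk)) NA_real_ else pk$f_peak,
    peak_risk = if (is.null(pk)) NA_real_ else pk$peak_risk
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
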