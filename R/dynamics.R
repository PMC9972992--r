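new_lv_trajectory <- function(df, params, converged, residual) {
  structure(df, class = c("lv_trajectory", class(df)),
            params = params, converged = converged, residual = residual)
}

#' Integrate the model forward in time
#'
#' Numerically integrates the pathogen-commensal equations from
#' `(P0, C0)` with an adaptive (lsoda) solver at relative tolerance `1e-8`.
#' Convergence to a fixed point is declared when the terminal growth rates
#' satisfy `max(|dP/dt|, |dC/dt|) < 1e-8`; the terminal residual is stored
#' on the result either way. Tiny negative densities produced by solver
#' overshoot (more negative than `-1e-9` aborts instead) are clipped to
#' zero with a warning.
#'
#' @param params An [lv_params()] object.
#' @param P0,C0 Non-negative initial densities.
#' @param horizon Integration horizon (time units), default 200 -- long
#'   enough for all bundled presets to reach their attractor.
#' @param n_points Number of evenly spaced samples stored (including t = 0).
#' @return A tibble of class `lv_trajectory` with columns `time`, `P`, `C`;
#'   attributes `params`, `converged`, `residual`.
#' @examples
#' tr <- lv_integrate(lv_update(lv_preset("fig3A"), A = 1), P0 = 1, C0 = 0)
#' tail(tr, 1)  # pathogen-alone equilibrium 0.8 under maximal exposure
#' @export
lv_integrate <- function(params, P0, C0, horizon = 200, n_points = 201) {
  stopifnot(inherits(params, "lv_params"))
  if (P0 < 0 || C0 < 0) stop("initial densities must be >= 0", call. = FALSE)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  times <- seq(0, horizon, length.out = n_points)
  rhs <- function(t, y, parms) {
    d <- lv_rhs_core(parms, max(y[1], 0), max(y[2], 0))
    list(c(d[[1]], d[[2]]))
  }
  sol <- deSolve::ode(y = c(P = P0, C = C0), times = times, func = rhs,
                      parms = params, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("ODE integration failed (istate = ", diagn[1], "); see ",
         "deSolve::diagnostics for details", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  P <- sol$P
  C <- sol$C
  if (any(P < -1e-6) || any(C < -1e-6)) {
    stop("integration produced substantially negative densities", call. = FALSE)
  }
  if (any(P < -1e-9) || any(C < -1e-9)) {
    warning("clipping negative densities (beyond -1e-9) to zero",
            call. = FALSE)
  }
  P <- pmax(P, 0)
  C <- pmax(C, 0)
  nT <- length(P)
  res <- lv_rhs_core(params, P[nT], C[nT])
  residual <- max(abs(res[[1]]), abs(res[[2]]))
  new_lv_trajectory(
    tibble::tibble(time = sol$time, P = P, C = C),
    params = params, converged = residual < 1e-8, residual = residual
  )
}

#' Integrate across a ladder of antibiotic exposures
#'
#' Runs [lv_integrate()] once per exposure level from a shared initial
#' condition. The default initial condition is the exposure-free (`A = 0`)
#' coexistence equilibrium: before treatment both organisms are present and
#' sit at their drug-free steady state. The resulting terminal densities
#' reveal the treatment response regime -- increasing in `A` under
#' competitive release (susceptible commensal), decreasing under beneficial
#' commensal resistance.
#'
#' @param params An [lv_params()] object; its `A` field is masked by the
#'   ladder.
#' @param A_values Exposure levels (default: 6 evenly spaced in `[0, 1]`).
#' @param P0,C0 Shared initial densities; `NULL` (default) uses the `A = 0`
#'   coexistence equilibrium (or the pathogen-alone state when that is the
#'   drug-free attractor).
#' @param horizon,n_points Passed to [lv_integrate()].
#' @return A tibble of class `lv_ladder`: the stacked trajectories with an
#'   `A` column, plus attribute `terminal` -- a tibble of terminal densities
#'   per exposure (see [terminal_states()]).
#' @examples
#' lad <- exposure_ladder(lv_preset("fig5C"))
#' terminal_states(lad)
#' @export
exposure_ladder <- function(params, A_values = seq(0, 1, length.out = 6),
                            P0 = NULL, C0 = NULL,
                            horizon = 200, n_points = 201) {
  stopifnot(inherits(params, "lv_params"))
  if (is.null(P0) || is.null(C0)) {
    eq0 <- classify_core(unclass(lv_update(params, A = 0)))
    if (is.null(P0)) P0 <- eq0$P_star
    if (is.null(C0)) C0 <- eq0$C_star
  }
  runs <- purrr::map(A_values, function(a) {
    tr <- lv_integrate(lv_update(params, A = a), P0 = P0, C0 = C0,
                       horizon = horizon, n_points = n_points)
    df <- tibble::as_tibble(tr)
    df$A <- a
    df$converged <- attr(tr, "converged")
    df
  })
  df <- dplyr::bind_rows(runs)
  terminal <- df |>
    dplyr::group_by(.data$A) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("A", "P", "C", "converged")
  structure(dplyr::select(df, "time", "A", "P", "C"),
            class = c("lv_ladder", class(df)),
            params = params, terminal = terminal,
            initial = c(P0 = P0, C0 = C0))
}

#' Terminal densities of an exposure ladder
#'
#' @param ladder An object returned by [exposure_ladder()] (or the resource
#'   variant).
#' @return A tibble with one row per exposure level: `A`, terminal `P`, `C`
#'   (and `R` for resource runs), and `converged`.
#' @export
terminal_states <- function(ladder) {
  term <- attr(ladder, "terminal")
  if (is.null(term)) stop("not a ladder object", call. = FALSE)
  term
}
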