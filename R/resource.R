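#' Parameters of the resource-explicit (chemostat) competition model
#'
#' A one-nutrient, two-consumer chemostat model used as a structural
#' robustness check on the Lotka-Volterra abstraction. Each consumer takes
#' up the shared nutrient with Monod (saturating) kinetics and converts it
#' to biomass with a fixed yield; nutrient flows in at concentration `R_in`
#' and everything washes out at dilution rate `d`; antibiotic loss terms
#' mirror the baseline model (`x * A` on the pathogen, `x * f * A` on the
#' commensal):
#' \deqn{dP/dt = v_p \frac{R}{K_p + R} P - d P - x A P}
#' \deqn{dC/dt = v_c \frac{R}{K_c + R} C - d C - x f A C}
#' \deqn{dR/dt = d (R_{in} - R) - \frac{1}{y_p} v_p \frac{R}{K_p+R} P
#'               - \frac{1}{y_c} v_c \frac{R}{K_c+R} C}
#'
#' Defaults give two symmetric consumers that share the nutrient equally in
#' the absence of antibiotic, with a partially resistant pathogen (maximal
#' exposure reduces the pathogen-alone steady state by about 20%, matching
#' the baseline-model treatment scenarios), so that the
#' susceptible-commensal (`f = 2`) and resistant-commensal (`f = 0.5`)
#' treatment scenarios can be contrasted directly. Note that a single
#' shared nutrient supports no generically stable two-consumer coexistence
#' (competitive exclusion), so treatment contrasts are statements about
#' finite-horizon dynamics, not equilibria.
#'
#' @param v_p,v_c Maximal per-capita growth rates (per unit time).
#' @param K_p,K_c Half-saturation constants for the nutrient
#'   (concentration units).
#' @param y_p,y_c Biomass yields per unit nutrient.
#' @param d Dilution (washout/turnover) rate (per unit time).
#' @param R_in Inflow nutrient concentration; the supply rate is `d * R_in`.
#' @param x,f,A Antibiotic terms with the same semantics as in
#'   [lv_params()].
#' @param R0 Initial nutrient concentration.
#' @return An object of class `resource_params`.
#' @export
resource_params <- function(v_p = 1, v_c = 1, K_p = 0.5, K_c = 0.5,
                            y_p = 1, y_c = 1, d = 0.1, R_in = 1,
                            x = 0.025, f = 1, A = 0, R0 = R_in) {
  p <- list(v_p = v_p, v_c = v_c, K_p = K_p, K_c = K_c,
            y_p = y_p, y_c = y_c, d = d, R_in = R_in,
            x = x, f = f, A = A, R0 = R0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  if (p$A > 1) stop("antibiotic exposure `A` must lie in [0, 1]",
                    call. = FALSE)
  if (p$y_p <= 0 || p$y_c <= 0) stop("yields must be > 0", call. = FALSE)
  structure(p, class = "resource_params")
}

#' @export
print.resource_params <- function(x, ...) {
  cat("<resource_params>\n")
  cat(sprintf("  uptake:     v_p = %g, v_c = %g; K_p = %g, K_c = %g\n",
              x$v_p, x$v_c, x$K_p, x$K_c))
  cat(sprintf("  yields:     y_p = %g, y_c = %g\n", x$y_p, x$y_c))
  cat(sprintf("  turnover:   d = %g, R_in = %g (supply %g)\n",
              x$d, x$R_in, x$d * x$R_in))
  cat(sprintf("  antibiotic: x = %g, f = %g, A = %g\n", x$x, x$f, x$A))
  invisible(x)
}

#' Update fields of a resource parameter set
#'
#' @param params A [resource_params()] object.
#' @param ... Named fields to replace.
#' @return A new `resource_params` object.
#' @export
resource_update <- function(params, ...) {
  stopifnot(inherits(params, "resource_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params[names(repl)] <- repl
  do.call(resource_params, unclass(params))
}

#' Right-hand side of the chemostat model
#'
#' @param params A [resource_params()] object.
#' @param P,C Consumer densities, >= 0.
#' @param R Nutrient concentration, >= 0.
#' @return A tibble with columns `dP`, `dC`, `dR`.
#' @export
resource_rhs <- function(params, P, C, R) {
  stopifnot(inherits(params, "resource_params"))
  if (any(P < 0) || any(C < 0) || any(R < 0)) {
    stop("state must be non-negative", call. = FALSE)
  }
  d <- resource_rhs_core(params, P, C, R)
  tibble::tibble(dP = d[[1]], dC = d[[2]], dR = d[[3]])
}

resource_rhs_core <- function(p, P, C, R) {
  up <- p$v_p * R / (p$K_p + R)   # per-capita pathogen growth
  uc <- p$v_c * R / (p$K_c + R)
  dP <- (up - p$d - p$x * p$A) * P
  dC <- (uc - p$d - p$x * p$f * p$A) * C
  dR <- p$d * (p$R_in - R) - up * P / p$y_p - uc * C / p$y_c
  list(dP, dC, dR)
}

#' Integrate the chemostat model
#'
#' Monod-uptake chemostat analogue of [lv_integrate()], tracking both
#' consumers and the nutrient. Because both consumers draw on the same
#' nutrient pool they inhibit each other indirectly -- the analogue of
#' mutual inhibition (`alpha_pc > 0`) in the baseline model -- so commensal
#' resistance remains beneficial here: under exposure, a resistant
#' commensal (low `f`) keeps the nutrient drawn down and suppresses the
#' pathogen harder than antibiotic alone, while a susceptible commensal
#' (high `f`) washes out and releases the pathogen.
#'
#' @param params A [resource_params()] object.
#' @param P0,C0 Initial consumer densities (defaults 0.3 each).
#' @param R0 Initial nutrient concentration; default taken from `params`.
#' @param horizon,n_points As in [lv_integrate()]; the default horizon 100
#'   is the treatment-course scale on which the scenario contrasts are
#'   defined.
#' @return A tibble of class `lv_trajectory` (and `resource_trajectory`)
#'   with columns `time`, `P`, `C`, `R`.
#' @examples
#' tr <- integrate_resource(resource_params(A = 1, f = 0.5))
#' tail(tr, 1)
#' @export
integrate_resource <- function(params, P0 = 0.3, C0 = 0.3, R0 = NULL,
                               horizon = 100, n_points = 201) {
  stopifnot(inherits(params, "resource_params"))
  if (is.null(R0)) R0 <- params$R0
  if (P0 < 0 || C0 < 0 || R0 < 0) {
    stop("initial state must be non-negative", call. = FALSE)
  }
  times <- seq(0, horizon, length.out = n_points)
  rhs <- function(t, y, parms) {
    d <- resource_rhs_core(parms, max(y[1], 0), max(y[2], 0), max(y[3], 0))
    list(c(d[[1]], d[[2]], d[[3]]))
  }
  sol <- deSolve::ode(y = c(P = P0, C = C0, R = R0), times = times,
                      func = rhs, parms = params, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop("chemostat integration failed (istate = ", diagn[1], ")",
         call. = FALSE)
  }
  sol <- as.data.frame(sol)
  P <- pmax(sol$P, 0); C <- pmax(sol$C, 0); R <- pmax(sol$R, 0)
  nT <- length(P)
  res <- resource_rhs_core(params, P[nT], C[nT], R[nT])
  residual <- max(abs(unlist(res)))
  df <- tibble::tibble(time = sol$time, P = P, C = C, R = R)
  structure(df, class = c("resource_trajectory", "lv_trajectory", class(df)),
            params = params, converged = residual < 1e-8,
            residual = residual)
}

#' Chemostat exposure ladder
#'
#' Runs [integrate_resource()] across antibiotic exposures from a shared
#' initial condition, mirroring [exposure_ladder()].
#'
#' @param params A [resource_params()] object; `A` is masked by the ladder.
#' @param A_values Exposure levels.
#' @param P0,C0,R0,horizon,n_points Passed to [integrate_resource()].
#' @return A tibble of class `lv_ladder` with columns `time`, `A`, `P`,
#'   `C`, `R`; attribute `terminal` as in [terminal_states()].
#' @export
resource_ladder <- function(params, A_values = seq(0, 1, length.out = 6),
                            P0 = 0.3, C0 = 0.3, R0 = NULL,
                            horizon = 100, n_points = 201) {
  stopifnot(inherits(params, "resource_params"))
  runs <- purrr::map(A_values, function(a) {
    tr <- integrate_resource(resource_update(params, A = a), P0 = P0,
                             C0 = C0, R0 = R0, horizon = horizon,
                             n_points = n_points)
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
    dplyr::select("A", "P", "C", "R", "converged")
  structure(dplyr::select(df, "time", "A", "P", "C", "R"),
            class = c("lv_ladder", class(df)),
            params = params, terminal = terminal,
            initial = c(P0 = P0, C0 = C0))
}
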