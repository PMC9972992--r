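#' Parameters of the antibiotic-perturbed two-species Lotka-Volterra model
#'
#' Constructs and validates the full parameter vector of the
#' pathogen-commensal model
#' \deqn{dP/dt = r_p P (1 - (P + \alpha_{pc} C)/k_p) - x A P}
#' \deqn{dC/dt = r_c C (1 - (C + \alpha_{cp} P)/k_c) - x f A C}
#' where `P` is pathogen density, `C` commensal density, and the antibiotic
#' enters as a density-independent loss term scaled by exposure `A` (pathogen)
#' and `f * A` (commensal).
#'
#' Interaction coefficients are signed: positive values denote inhibition,
#' negative values facilitation (so both competition, exploitation and
#' mutualism are covered). They are restricted to `|alpha| < 1`, which rules
#' out strong interference competition and the bistable equilibria it brings.
#'
#' @param r_p,r_c Maximal per-capita growth rates (per unit time), >= 0.
#' @param k_p,k_c Single-species carrying capacities (scaled density), > 0.
#'   Values above 2 trigger a warning (densities are scaled so that a default
#'   pathogen has unit carrying capacity).
#' @param alpha_pc Per-capita effect of the commensal on the pathogen
#'   (dimensionless, signed; `|alpha_pc| < 1`).
#' @param alpha_cp Per-capita effect of the pathogen on the commensal
#'   (dimensionless, signed; `|alpha_cp| < 1`).
#' @param x Maximal antibiotic clearance rate of the pathogen (per unit
#'   time), >= 0.
#' @param f Commensal susceptibility relative to the pathogen
#'   (dimensionless, >= 0): `f < 1` means the commensal is more resistant,
#'   `f > 1` more susceptible.
#' @param A Antibiotic exposure in `[0, 1]` (0 = none, 1 = maximal).
#'
#' @return An object of class `lv_params`: a named list of the nine
#'   parameters.
#' @examples
#' p <- lv_params(r_p = 0.5, r_c = 0.5, k_p = 1, k_c = 1,
#'                alpha_pc = 0.8, alpha_cp = 0.8, x = 0.1, f = 1, A = 0)
#' growth_rhs(p, P = 0.5, C = 0.5)
#' @seealso [lv_preset()] for parameter sets used in the worked analyses.
#' @export
lv_params <- function(r_p = 0.5, r_c = 0.5, k_p = 1, k_c = 1,
                      alpha_pc = 0.8, alpha_cp = 0.8,
                      x = 0.1, f = 1, A = 0) {
  p <- list(r_p = r_p, r_c = r_c, k_p = k_p, k_c = k_c,
            alpha_pc = alpha_pc, alpha_cp = alpha_cp,
            x = x, f = f, A = A)
  validate_lv_params(p)
  structure(p, class = "lv_params")
}

validate_lv_params <- function(p) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  for (nm in c("r_p", "r_c", "k_p", "k_c", "alpha_pc", "alpha_cp",
               "x", "f", "A")) {
    num1(p[[nm]], nm)
  }
  if (abs(p$alpha_pc) >= 1 || abs(p$alpha_cp) >= 1) {
    stop("interaction coefficients must satisfy |alpha| < 1 ",
         "(strong interference competition is outside the model's scope)",
         call. = FALSE)
  }
  for (nm in c("r_p", "r_c", "x", "f")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$k_p <= 0 || p$k_c <= 0) {
    stop("carrying capacities must be > 0", call. = FALSE)
  }
  if (p$A < 0 || p$A > 1) {
    stop("antibiotic exposure `A` must lie in [0, 1]", call. = FALSE)
  }
  if (p$k_p > 2 || p$k_c > 2) {
    warning("carrying capacities above 2 are outside the scaled convention ",
            "(expected range (0, 2])", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.lv_params <- function(x, ...) {
  cat("<lv_params>\n")
  cat(sprintf("  growth:      r_p = %g, r_c = %g\n", x$r_p, x$r_c))
  cat(sprintf("  capacity:    k_p = %g, k_c = %g\n", x$k_p, x$k_c))
  cat(sprintf("  interaction: alpha_pc = %g, alpha_cp = %g\n",
              x$alpha_pc, x$alpha_cp))
  cat(sprintf("  antibiotic:  x = %g, f = %g, A = %g\n", x$x, x$f, x$A))
  invisible(x)
}

#' Update fields of a parameter set
#'
#' Convenience wrapper returning a revalidated copy with some fields
#' replaced, e.g. `lv_update(lv_preset("fig3A"), A = 1, f = 0.5)`.
#'
#' @param params An [lv_params()] object.
#' @param ... Named fields to replace.
#' @return A new `lv_params` object.
#' @export
lv_update <- function(params, ...) {
  stopifnot(inherits(params, "lv_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params[names(repl)] <- repl
  do.call(lv_params, unclass(params))
}

#' Right-hand side of the model equations
#'
#' Evaluates the instantaneous growth rates (dP/dt, dC/dt) of the pathogen
#' and commensal at densities `P` and `C`.
#'
#' @param params An [lv_params()] object.
#' @param P,C Non-negative densities (vectorised: equal-length vectors are
#'   evaluated elementwise).
#' @return A tibble with columns `dP` and `dC`.
#' @examples
#' p <- lv_preset("fig3A")
#' growth_rhs(p, P = 1, C = 0)  # single-species carrying capacity: (0, 0)
#' @export
growth_rhs <- function(params, P, C) {
  stopifnot(inherits(params, "lv_params"))
  if (any(P < 0) || any(C < 0)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  rhs <- lv_rhs_core(params, P, C)
  tibble::tibble(dP = rhs[[1]], dC = rhs[[2]])
}

# bare arithmetic core shared by the ODE integrator and the equilibria code
lv_rhs_core <- function(p, P, C) {
  dP <- p$r_p * P * (1 - (P + p$alpha_pc * C) / p$k_p) - p$x * p$A * P
  dC <- p$r_c * C * (1 - (C + p$alpha_cp * P) / p$k_c) - p$x * p$f * p$A * C
  list(dP, dC)
}
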