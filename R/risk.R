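#' Infection-risk weights
#'
#' Per-capita weights attached to equilibrium abundances when scoring the
#' community's total infection risk: `w_p` for the (resistant) pathogen,
#' `w_c` for the commensal's opportunistic-infection risk, and `w_h_beta`
#' for the horizontal-gene-transfer (HGT) class -- the product of the HGT
#' rate and the risk posed by an HGT-resistant pathogen, applied to
#' `P* x C*` (transfer requires both populations present). Setting
#' `w_h_beta = 0` disables the HGT class.
#'
#' @param w_p Per-capita pathogen infection risk weight, >= 0.
#' @param w_c Per-capita commensal infection risk weight, >= 0.
#' @param w_h_beta Combined HGT weight (rate x risk), >= 0.
#' @return An object of class `risk_weights`.
#' @export
risk_weights <- function(w_p = 1, w_c = 0.1, w_h_beta = 0) {
  w <- list(w_p = w_p, w_c = w_c, w_h_beta = w_h_beta)
  for (nm in names(w)) {
    v <- w[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  structure(w, class = "risk_weights")
}

#' Total infection risk as a function of commensal susceptibility
#'
#' For each `f`, finds the stable attractor of the model (the boundary
#' equilibria are used where coexistence fails) and scores three risk
#' classes on its abundances: pathogen risk `w_p * P*`, commensal
#' (opportunistic) risk `w_c * C*` and HGT risk `w_h_beta * P* * C*`. The
#' total is their sum. Decreasing `f` (more commensal resistance) lowers
#' the pathogen class but raises the commensal class; the HGT class peaks
#' where both populations persist together -- making the choice of
#' commensal resistance an optimisation rather than a minimisation problem.
#'
#' Per-capita weights are constants by default; `weight_fn` accepts a
#' function `(f, weights) -> risk_weights` for susceptibility-dependent
#' weightings.
#'
#' @param base An [lv_params()] object with `A > 0` (the trade-off is
#'   defined under exposure); the `f` field is masked by the grid.
#' @param weights A [risk_weights()] object.
#' @param f_values Ordered susceptibility grid (default: 301 points over
#'   `[0, 3]`).
#' @param weight_fn Optional hook returning the weights to use at each `f`.
#' @return A tibble of class `risk_profile` with columns `f`, `P_star`,
#'   `C_star`, `outcome`, `pathogen_risk`, `commensal_risk`, `hgt_risk`,
#'   `total_risk`.
#' @examples
#' rp <- risk_profile(lv_preset("figS6"), risk_weights(1, 0.1, 5))
#' optimal_f(rp)
#' @export
risk_profile <- function(base, weights = risk_weights(),
                         f_values = seq(0, 3, length.out = 301),
                         weight_fn = NULL) {
  stopifnot(inherits(base, "lv_params"), inherits(weights, "risk_weights"))
  if (base$A <= 0) {
    stop("risk trade-off requires antibiotic exposure (A > 0)", call. = FALSE)
  }
  if (any(f_values < 0)) stop("f_values must be >= 0", call. = FALSE)
  n <- length(f_values)
  P_star <- C_star <- numeric(n)
  outcome <- character(n)
  p <- unclass(base)
  for (i in seq_len(n)) {
    p$f <- f_values[i]
    out <- classify_core(p)
    P_star[i] <- out$P_star
    C_star[i] <- out$C_star
    outcome[i] <- out$kind
  }
  w <- lapply(f_values, function(fv) {
    if (is.null(weight_fn)) weights else weight_fn(fv, weights)
  })
  w_p <- vapply(w, function(z) z$w_p, double(1))
  w_c <- vapply(w, function(z) z$w_c, double(1))
  w_h <- vapply(w, function(z) z$w_h_beta, double(1))
  df <- tibble::tibble(
    f = f_values, P_star = P_star, C_star = C_star, outcome = outcome,
    pathogen_risk = w_p * P_star,
    commensal_risk = w_c * C_star,
    hgt_risk = w_h * P_star * C_star
  )
  df$total_risk <- df$pathogen_risk + df$commensal_risk + df$hgt_risk
  structure(df, class = c("risk_profile", class(df)),
            base_params = base, weights = weights)
}

#' Susceptibility minimising total infection risk
#'
#' Argmin of the total risk over the profile's grid. Exact ties (within
#' `tol`) are broken towards *larger* `f` -- the least commensal resistance
#' that still achieves minimal risk -- and the full tie set is reported.
#'
#' @param profile A [risk_profile()] tibble.
#' @param tol Absolute tolerance for tie detection.
#' @return A one-row tibble with `f_opt`, `min_risk`, `n_ties`; the tie set
#'   is available as attribute `ties`.
#' @export
optimal_f <- function(profile, tol = 1e-12) {
  stopifnot(inherits(profile, "risk_profile"), nrow(profile) > 0)
  m <- min(profile$total_risk)
  ties <- profile$f[profile$total_risk <= m + tol]
  out <- tibble::tibble(f_opt = max(ties), min_risk = m,
                        n_ties = length(ties))
  attr(out, "ties") <- ties
  out
}

#' Interior maximum of the total-risk curve
#'
#' Locates a strict local maximum of total risk away from the grid ends,
#' the signature of an HGT-driven risk peak at intermediate commensal
#' resistance. Returns `NULL` when the curve has no interior peak.
#'
#' @param profile A [risk_profile()] tibble.
#' @return A one-row tibble with `f_peak` and `peak_risk`, or `NULL`.
#' @export
interior_peak <- function(profile) {
  stopifnot(inherits(profile, "risk_profile"))
  y <- profile$total_risk
  n <- length(y)
  if (n < 3) return(NULL)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (!length(idx)) return(NULL)
  best <- idx[which.max(y[idx])]
  tibble::tibble(f_peak = profile$f[best], peak_risk = y[best])
}
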