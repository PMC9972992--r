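#' Sensitivity of equilibrium pathogen density to antibiotic exposure
#'
#' Closed-form gradient of the coexistence pathogen density with respect to
#' antibiotic exposure,
#' \deqn{\partial P^*/\partial A =
#'   \frac{x(\alpha_{pc} r_p k_c f - r_c k_p)}{r_p r_c (1-\alpha_{pc}\alpha_{cp})}.}
#' A positive value is the definition of *competitive release*: more
#' antibiotic yields more pathogen, because the drug removes an inhibiting
#' competitor faster than it clears the pathogen.
#'
#' The gradient is a statement about the interior (coexistence) branch. By
#' default the parameter set is checked to sit in a feasible, stable
#' coexistence regime; outside it the closed form is still evaluated but
#' returned as `NA` with a warning (set `check_coexistence = FALSE` to get
#' the bare formula value).
#'
#' @param params An [lv_params()] object.
#' @param check_coexistence If `TRUE` (default), return `NA` with a warning
#'   when the attractor at `params` is not stable coexistence.
#' @return A single numeric gradient (density per unit `A`), or `NA_real_`
#'   outside the coexistence regime.
#' @examples
#' dPstar_dA(lv_update(lv_preset("fig3A"), A = 0.5, f = 2))   # > 0: release
#' dPstar_dA(lv_update(lv_preset("fig3A"), A = 0.5, f = 0.5)) # < 0
#' @export
dPstar_dA <- function(params, check_coexistence = TRUE) {
  stopifnot(inherits(params, "lv_params"))
  val <- with(params, x * (alpha_pc * r_p * k_c * f - r_c * k_p) /
                (r_p * r_c * (1 - alpha_pc * alpha_cp)))
  maybe_mask_gradient(val, params, check_coexistence)
}

#' Sensitivity of equilibrium pathogen density to commensal susceptibility
#'
#' Closed-form gradient of the coexistence pathogen density with respect to
#' the commensal's relative susceptibility,
#' \deqn{\partial P^*/\partial f =
#'   \frac{\alpha_{pc} k_c x A}{r_c (1-\alpha_{pc}\alpha_{cp})}.}
#' A positive value defines *beneficial commensal resistance*: making the
#' commensal more resistant (lower `f`) lowers the equilibrium pathogen
#' burden. With `A > 0` and positive demographic parameters the sign equals
#' the sign of `alpha_pc` -- benefit requires that the commensal inhibits
#' the pathogen.
#'
#' @inheritParams dPstar_dA
#' @return A single numeric gradient (density per unit `f`), or `NA_real_`
#'   outside the coexistence regime.
#' @examples
#' dPstar_df(lv_preset("fig4"))  # 0.4444 at the competition point
#' @export
dPstar_df <- function(params, check_coexistence = TRUE) {
  stopifnot(inherits(params, "lv_params"))
  val <- with(params, alpha_pc * k_c * x * A /
                (r_c * (1 - alpha_pc * alpha_cp)))
  maybe_mask_gradient(val, params, check_coexistence)
}

maybe_mask_gradient <- function(val, params, check) {
  if (!check) return(val)
  out <- classify_core(params)
  if (!identical(out$kind, "coexistence") || !out$stable) {
    warning("gradient not applicable: attractor is ", out$kind,
            if (out$marginal) " (marginal)" else "",
            "; returning NA (use check_coexistence = FALSE for the raw ",
            "closed form)", call. = FALSE)
    return(NA_real_)
  }
  val
}

#' Critical commensal susceptibility for competitive release
#'
#' The threshold \eqn{f^* = r_c k_p / (r_p k_c \alpha_{pc})}: within the
#' coexistence regime, competitive release (\eqn{\partial P^*/\partial A > 0})
#' occurs exactly for `f > f*`. The threshold is lowered by stronger
#' commensal inhibition of the pathogen (`alpha_pc`), higher commensal
#' carrying capacity and lower commensal growth rate. It is undefined when
#' `alpha_pc <= 0` (a facilitating commensal can never be competitively
#' released from).
#'
#' @inheritParams dPstar_dA
#' @return The critical susceptibility `f*` (dimensionless).
#' @examples
#' release_threshold_f(lv_preset("fig3A"))  # 1.25
#' @export
release_threshold_f <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  if (params$alpha_pc <= 0) {
    stop("release threshold undefined for alpha_pc <= 0: competitive ",
         "release requires commensal inhibition of the pathogen",
         call. = FALSE)
  }
  with(params, r_c * k_p / (r_p * k_c * alpha_pc))
}

#' Is commensal resistance beneficial?
#'
#' Under antibiotic exposure (`A > 0`) and the model's parameter
#' restrictions, \eqn{\partial P^*/\partial f > 0} reduces to
#' `alpha_pc > 0`: commensal resistance lowers pathogen burden exactly when
#' the commensal inhibits the pathogen (competition or commensal
#' exploitation of the pathogen), and never when the commensal facilitates
#' it (pathogen exploitation or mutualism).
#'
#' @inheritParams dPstar_dA
#' @return `TRUE` or `FALSE`.
#' @export
beneficial_resistance_condition <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  if (params$A <= 0) {
    stop("the beneficial-resistance condition is defined under antibiotic ",
         "exposure (A > 0)", call. = FALSE)
  }
  params$alpha_pc > 0
}

new_lv_scan <- function(df, base_params, axes, contour_increment) {
  structure(df, class = c("lv_scan", class(df)),
            base_params = base_params, axes = axes,
            contour_increment = contour_increment)
}

scan_cells <- function(base, grid) {
  n <- nrow(grid)
  P_star <- C_star <- dP_dA <- dP_df <- numeric(n)
  outcome <- character(n)
  p <- unclass(base)
  nm1 <- names(grid)[1]; nm2 <- names(grid)[2]
  v1 <- grid[[1]]; v2 <- grid[[2]]
  for (i in seq_len(n)) {
    p[[nm1]] <- v1[i]
    p[[nm2]] <- v2[i]
    out <- classify_core(p)
    P_star[i] <- out$P_star
    C_star[i] <- out$C_star
    outcome[i] <- out$kind
    if (identical(out$kind, "coexistence") && out$stable) {
      dP_dA[i] <- p$x * (p$alpha_pc * p$r_p * p$k_c * p$f - p$r_c * p$k_p) /
        (p$r_p * p$r_c * (1 - p$alpha_pc * p$alpha_cp))
      dP_df[i] <- p$alpha_pc * p$k_c * p$x * p$A /
        (p$r_c * (1 - p$alpha_pc * p$alpha_cp))
    } else {
      dP_dA[i] <- NA_real_
      dP_df[i] <- NA_real_
    }
  }
  dplyr::bind_cols(tibble::as_tibble(grid),
                   tibble::tibble(P_star = P_star, C_star = C_star,
                                  outcome = outcome,
                                  dP_dA = dP_dA, dP_df = dP_df))
}

#' Sweep antibiotic exposure against commensal susceptibility
#'
#' Evaluates the stable attractor, equilibrium densities and (on the
#' coexistence branch) both closed-form gradients over a 2-D grid of
#' antibiotic exposure `A` and commensal relative susceptibility `f`. The
#' result is the phase/contour map of the baseline analysis: pathogen
#' density contours with a competitive-release threshold line at
#' `f = release_threshold_f(base)` and outcome-classified regions where
#' coexistence breaks down. Gradients are reported for the coexistence
#' branch only; cells whose attractor is a boundary state carry its
#' densities and `NA` gradients.
#'
#' @param base An [lv_params()] object; its `A` and `f` fields are masked by
#'   the grid.
#' @param A_values,f_values Ordered numeric axis values (defaults: 201
#'   points over `[0, 1]` and `[0, 2]`).
#' @param contour_increment Contour spacing stored as plot metadata
#'   (0.03 for the competition/exploitation panels, 0.06 for mutualism).
#' @return A tibble of class `lv_scan` in long format with columns `A`,
#'   `f`, `P_star`, `C_star`, `outcome`, `dP_dA`, `dP_df`; attributes
#'   `base_params`, `axes`, `contour_increment`.
#' @examples
#' sc <- scan_Af(lv_preset("fig3A"), seq(0, 1, length.out = 21),
#'               seq(0, 2, length.out = 21))
#' dplyr::count(sc, outcome)
#' @export
scan_Af <- function(base, A_values = seq(0, 1, length.out = 201),
                    f_values = seq(0, 2, length.out = 201),
                    contour_increment = 0.03) {
  stopifnot(inherits(base, "lv_params"))
  if (any(A_values < 0 | A_values > 1)) {
    stop("A_values must lie in [0, 1]", call. = FALSE)
  }
  if (any(f_values < 0)) stop("f_values must be >= 0", call. = FALSE)
  grid <- expand.grid(A = A_values, f = f_values, KEEP.OUT.ATTRS = FALSE)
  df <- scan_cells(base, grid)
  new_lv_scan(df, base,
              axes = list(axis1 = list(name = "A", values = A_values),
                          axis2 = list(name = "f", values = f_values)),
              contour_increment = contour_increment)
}

#' Sweep the two interaction coefficients
#'
#' Evaluates the beneficial-resistance gradient \eqn{\partial P^*/\partial f}
#' over a grid of interaction coefficients `(alpha_pc, alpha_cp)`, holding
#' the demographic and antibiotic parameters of `base` fixed. This is the
#' interaction-sign heat map: the sign boundary lies on `alpha_pc = 0`, and
#' the magnitude grows towards the strongly-coupled corners.
#'
#' Here the gradient is reported as the bare closed form for every cell
#' (the map is a statement about the interior branch across interaction
#' structures); the attractor kind is still classified per cell.
#'
#' @param base An [lv_params()] object; its `alpha_pc`, `alpha_cp` fields
#'   are masked by the grid.
#' @param alpha_pc_values,alpha_cp_values Ordered axis values, each within
#'   `(-1, 1)`.
#' @return A tibble of class `lv_scan` with columns `alpha_pc`, `alpha_cp`,
#'   `P_star`, `C_star`, `outcome`, `dP_dA`, `dP_df` (closed-form values).
#' @examples
#' sc <- scan_alpha(lv_preset("fig4"),
#'                  seq(-0.9, 0.9, length.out = 19),
#'                  seq(-0.9, 0.9, length.out = 19))
#' @export
scan_alpha <- function(base,
                       alpha_pc_values = seq(-0.95, 0.95, length.out = 201),
                       alpha_cp_values = seq(-0.95, 0.95, length.out = 201)) {
  stopifnot(inherits(base, "lv_params"))
  if (any(abs(alpha_pc_values) >= 1) || any(abs(alpha_cp_values) >= 1)) {
    stop("interaction axis values must satisfy |alpha| < 1", call. = FALSE)
  }
  grid <- expand.grid(alpha_pc = alpha_pc_values, alpha_cp = alpha_cp_values,
                      KEEP.OUT.ATTRS = FALSE)
  df <- scan_cells(base, grid)
  # the heat map reports the interior-branch gradients for every cell
  p <- unclass(base)
  df$dP_df <- df$alpha_pc * p$k_c * p$x * p$A /
    (p$r_c * (1 - df$alpha_pc * df$alpha_cp))
  df$dP_dA <- p$x * (df$alpha_pc * p$r_p * p$k_c * p$f - p$r_c * p$k_p) /
    (p$r_p * p$r_c * (1 - df$alpha_pc * df$alpha_cp))
  new_lv_scan(df, base,
              axes = list(axis1 = list(name = "alpha_pc",
                                       values = alpha_pc_values),
                          axis2 = list(name = "alpha_cp",
                                       values = alpha_cp_values)),
              contour_increment = NA_real_)
}
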