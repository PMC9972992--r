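#' @keywords internal
"_PACKAGE"

#' @importFrom utils modifyList head tail
#' @importFrom stats setNames
#' @importFrom rlang .data
NULL

# tolerances shared across the equilibrium machinery
.comres_tol <- list(
  feas = 1e-9,   # densities in [-feas, 0) snap to 0; below is infeasible
  eig  = 1e-9,   # |Re(eig)| <= eig  => marginal
  sing = 1e-12   # singular-denominator guard for 1 - a_pc*a_cp
)

# Analytic Jacobian of the model at (P, C); returns the four entries.
lv_jacobian <- function(p, P, C) {
  J11 <- p$r_p * (1 - (2 * P + p$alpha_pc * C) / p$k_p) - p$x * p$A
  J12 <- -p$r_p * p$alpha_pc * P / p$k_p
  J21 <- -p$r_c * p$alpha_cp * C / p$k_c
  J22 <- p$r_c * (1 - (2 * C + p$alpha_cp * P) / p$k_c) - p$x * p$f * p$A
  c(J11 = J11, J12 = J12, J21 = J21, J22 = J22)
}

# Real parts of the eigenvalues of a 2x2 matrix via trace/determinant.
eig_real_parts <- function(J) {
  tr <- J[["J11"]] + J[["J22"]]
  det <- J[["J11"]] * J[["J22"]] - J[["J12"]] * J[["J21"]]
  disc <- tr^2 - 4 * det
  if (disc >= 0) {
    s <- sqrt(disc)
    c((tr + s) / 2, (tr - s) / 2)
  } else {
    c(tr / 2, tr / 2)
  }
}

# Stability labels from eigenvalue real parts.
stability_flags <- function(re, tol = .comres_tol$eig) {
  m <- max(re)
  list(stable = m < -tol, marginal = abs(m) <= tol)
}

# Snap tiny negative closed-form densities to zero; flag feasibility.
snap_density <- function(v, tol = .comres_tol$feas) {
  if (v < 0 && v >= -tol) v <- 0
  v
}

kind_from_zero_pattern <- function(P, C, tol = .comres_tol$feas) {
  if (P > tol && C > tol) "coexistence"
  else if (P > tol) "pathogen_dominance"
  else if (C > tol) "commensal_dominance"
  else "joint_extinction"
}

# One candidate equilibrium as a plain list (fast path for grid scans).
candidate_record <- function(p, P, C, label) {
  P <- snap_density(P)
  C <- snap_density(C)
  feasible <- P >= 0 && C >= 0
  if (!feasible) {
    return(list(label = label, P_star = P, C_star = C, feasible = FALSE,
                kind = NA_character_, stable = FALSE, marginal = FALSE,
                eig1 = NA_real_, eig2 = NA_real_))
  }
  re <- eig_real_parts(lv_jacobian(p, P, C))
  fl <- stability_flags(re)
  list(label = label, P_star = P, C_star = C, feasible = TRUE,
       kind = kind_from_zero_pattern(P, C),
       stable = fl$stable && !fl$marginal, marginal = fl$marginal,
       eig1 = re[1], eig2 = re[2])
}

# All four candidate fixed points of the model as plain lists.
lv_candidates <- function(p) {
  denom <- 1 - p$alpha_pc * p$alpha_cp
  if (abs(denom) < .comres_tol$sing) {
    stop("singular interaction structure: |1 - alpha_pc*alpha_cp| ~ 0",
         call. = FALSE)
  }
  # single-species equilibria; effective growth <= 0 collapses them to 0
  P_alone <- if (p$r_p > 0) max(0, p$k_p * (1 - p$x * p$A / p$r_p)) else 0
  C_alone <- if (p$r_c > 0) max(0, p$k_c * (1 - p$x * p$f * p$A / p$r_c)) else 0
  # interior (coexistence) closed forms
  P_co <- (p$r_c * p$k_p * (p$r_p - p$x * p$A) -
             p$alpha_pc * p$r_p * p$k_c * (p$r_c - p$x * p$f * p$A)) /
    (p$r_p * p$r_c * denom)
  C_co <- (p$r_p * p$k_c * (p$r_c - p$x * p$f * p$A) -
             p$alpha_cp * p$r_c * p$k_p * (p$r_p - p$x * p$A)) /
    (p$r_p * p$r_c * denom)
  list(
    extinction = candidate_record(p, 0, 0, "extinction"),
    pathogen = candidate_record(p, P_alone, 0, "pathogen_alone"),
    commensal = candidate_record(p, 0, C_alone, "commensal_alone"),
    coexistence = candidate_record(p, P_co, C_co, "coexistence")
  )
}

candidates_to_tibble <- function(cands) {
  pull <- function(field, proto) {
    vapply(cands, function(z) z[[field]], proto, USE.NAMES = FALSE)
  }
  tibble::tibble(
    label = pull("label", character(1)),
    P_star = pull("P_star", double(1)),
    C_star = pull("C_star", double(1)),
    kind = pull("kind", character(1)),
    feasible = pull("feasible", logical(1)),
    stable = pull("stable", logical(1)),
    marginal = pull("marginal", logical(1)),
    eig1 = pull("eig1", double(1)),
    eig2 = pull("eig2", double(1))
  )
}

new_lv_equilibrium <- function(df, params) {
  structure(df, class = c("lv_equilibrium", class(df)), params = params)
}

#' Interior (coexistence) equilibrium in closed form
#'
#' Evaluates the closed-form coexistence fixed point
#' \deqn{P^* = \frac{r_c k_p (r_p - x A) - \alpha_{pc} r_p k_c (r_c - x f A)}
#'             {r_p r_c (1 - \alpha_{pc}\alpha_{cp})}}
#' and its commensal counterpart (swap the roles of the two species, with
#' the commensal loss rate `x f A`). Feasibility requires both densities to
#' be non-negative (values within `1e-9` below zero are snapped to zero);
#' local stability is classified from the real parts of the Jacobian
#' eigenvalues at the fixed point.
#'
#' @param params An [lv_params()] object.
#' @return A one-row tibble of class `lv_equilibrium` with columns
#'   `P_star`, `C_star`, `kind`, `feasible`, `stable`, `marginal`,
#'   `eig1`, `eig2`. When infeasible, `kind` is `NA` and the raw (negative)
#'   closed-form densities are reported for diagnostic use.
#' @examples
#' coexistence_equilibrium(lv_preset("fig3A"))  # P* = C* = 0.5556
#' @export
coexistence_equilibrium <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  co <- lv_candidates(params)$coexistence
  new_lv_equilibrium(candidates_to_tibble(list(co))[-1], params)
}

#' Boundary equilibria (extinction and single-species dominance)
#'
#' Returns the three boundary fixed points: joint extinction `(0, 0)`,
#' pathogen dominance `(k_p (1 - x A / r_p), 0)` and commensal dominance
#' `(0, k_c (1 - x f A / r_c))`. Single-species densities whose effective
#' growth rate is non-positive (growth rate minus antibiotic loss less than
#' or equal to zero) collapse to zero rather
#' than going negative. Stability of each boundary state combines its
#' own-dynamics eigenvalue and the invasion growth rate of the absent
#' species; both are the Jacobian eigenvalues at the fixed point.
#'
#' @inheritParams coexistence_equilibrium
#' @return A tibble of class `lv_equilibrium` with one row per boundary
#'   state (same columns as [coexistence_equilibrium()], plus `label`).
#' @examples
#' boundary_equilibria(lv_update(lv_preset("fig3A"), A = 1))
#' @export
boundary_equilibria <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  cands <- lv_candidates(params)[c("extinction", "pathogen", "commensal")]
  new_lv_equilibrium(candidates_to_tibble(cands), params)
}

# Lean classification core returning a plain list (used by grid scans).
classify_core <- function(p) {
  cands <- lv_candidates(p)
  feas <- Filter(function(z) z$feasible, cands)
  # dedupe coincident fixed points (e.g. interior branch colliding with a
  # boundary state at a transcritical point): prefer the boundary labelling
  key <- vapply(feas, function(z) paste(round(z$P_star, 9), round(z$C_star, 9)),
                character(1))
  feas <- feas[!duplicated(key)]
  stable <- Filter(function(z) z$stable, feas)
  if (length(stable) == 1L) {
    out <- stable[[1]]
    out$multistable <- FALSE
    return(out)
  }
  if (length(stable) > 1L) {
    # defensive: unreachable under |alpha| < 1, but reported rather than hidden
    out <- stable[[1]]
    out$multistable <- TRUE
    return(out)
  }
  marg <- Filter(function(z) z$marginal, feas)
  if (length(marg) >= 1L) {
    # prefer the state with the largest total density (the attractor the
    # interior flow approaches along the marginal direction)
    tot <- vapply(marg, function(z) z$P_star + z$C_star, double(1))
    out <- marg[[which.max(tot)]]
    out$multistable <- FALSE
    return(out)
  }
  stop("no stable feasible equilibrium found (numerical tolerance problem?)",
       call. = FALSE)
}

#' Classify the ecological outcome of a parameter set
#'
#' Evaluates all candidate fixed points (extinction, the two single-species
#' boundary states, and the interior coexistence point) and returns the
#' stable feasible one -- the attractor reached from interior initial
#' conditions. Under the model's `|alpha| < 1` restriction this attractor
#' is unique; if several strictly stable states were ever found (possible
#' only outside that regime) the result carries `multistable = TRUE`.
#' Fixed points whose leading eigenvalue real part is within `1e-9` of zero
#' are flagged `marginal = TRUE` rather than silently stable; such points
#' arise exactly on bifurcation boundaries (e.g. threshold curves in
#' exposure-susceptibility sweeps).
#'
#' @inheritParams coexistence_equilibrium
#' @return A one-row tibble of class `lv_equilibrium` with columns `P_star`,
#'   `C_star`, `kind` (one of `joint_extinction`, `pathogen_dominance`,
#'   `commensal_dominance`, `coexistence`), `feasible`, `stable`,
#'   `marginal`, `eig1`, `eig2`, `multistable`.
#' @examples
#' classify_outcome(lv_preset("fig3A"))                      # coexistence
#' classify_outcome(lv_update(lv_preset("fig3A"), A = 1, f = 2))  # release
#' @export
classify_outcome <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  out <- classify_core(params)
  df <- tibble::tibble(
    P_star = out$P_star, C_star = out$C_star, kind = out$kind,
    feasible = out$feasible, stable = out$stable, marginal = out$marginal,
    eig1 = out$eig1, eig2 = out$eig2, multistable = out$multistable
  )
  new_lv_equilibrium(df, params)
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  cat("<lv_equilibrium>\n")
  NextMethod()
}
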