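test_that("beneficial-resistance gradient reproduces the interaction map", {
  # the four marked interaction points under maximal exposure
  base <- lv_preset("fig4")
  pts <- list(
    list(apc = 0.8, acp = 0.8, val = 0.4444),
    list(apc = 0.8, acp = -0.8, val = 0.0976),
    list(apc = -0.8, acp = 0.8, val = -0.0976),
    list(apc = -0.8, acp = -0.8, val = -0.4444)
  )
  for (pt in pts) {
    p <- lv_update(base, alpha_pc = pt$apc, alpha_cp = pt$acp)
    expect_equal(round(dPstar_df(p), 4), pt$val)
  }
})

test_that("no antibiotic means commensal susceptibility is inert", {
  p <- lv_update(lv_preset("fig3A"), A = 0)
  expect_equal(dPstar_df(p), 0)
})

test_that("gradients flag non-coexistence regimes as not applicable", {
  p <- lv_update(lv_preset("fig3A"), A = 1, f = 2)  # pathogen dominance
  expect_warning(v <- dPstar_dA(p), "not applicable")
  expect_true(is.na(v))
  expect_type(dPstar_dA(p, check_coexistence = FALSE), "double")
})

test_that("closed-form gradients match central finite differences", {
  set.seed(21)
  h <- 1e-6
  n_checked <- 0
  while (n_checked < 100) {
    p <- sample_coexistence_params()
    # keep the finite-difference stencil inside the coexistence regime
    if (p$A < 2 * h || p$A > 1 - 2 * h || p$f < 2 * h) next
    kA <- function(a) classify_outcome(lv_update(p, A = a))$kind
    kf <- function(fv) classify_outcome(lv_update(p, f = fv))$kind
    if (kA(p$A + h) != "coexistence" || kA(p$A - h) != "coexistence" ||
        kf(p$f + h) != "coexistence" || kf(p$f - h) != "coexistence") next
    fdA <- (coexistence_equilibrium(lv_update(p, A = p$A + h))$P_star -
              coexistence_equilibrium(lv_update(p, A = p$A - h))$P_star) /
      (2 * h)
    fdf <- (coexistence_equilibrium(lv_update(p, f = p$f + h))$P_star -
              coexistence_equilibrium(lv_update(p, f = p$f - h))$P_star) /
      (2 * h)
    # hybrid tolerance: relative 1e-6, with an absolute floor where the
    # gradient itself is tiny and finite-difference roundoff dominates
    expect_lt(abs(dPstar_dA(p) - fdA), 1e-6 * (1 + abs(fdA)))
    expect_lt(abs(dPstar_df(p) - fdf), 1e-6 * (1 + abs(fdf)))
    n_checked <- n_checked + 1
  }
})

test_that("release threshold values match the documented settings", {
  expect_equal(round(release_threshold_f(lv_preset("figS3")), 3), 0.417)
  expect_equal(release_threshold_f(lv_preset("fig3A")), 1.25)
  # symmetric limit: f* -> 1 as alpha_pc -> 1
  p <- lv_params(alpha_pc = 1 - 1e-9, alpha_cp = 0.5)
  expect_equal(release_threshold_f(p), 1, tolerance = 1e-6)
  expect_error(release_threshold_f(lv_preset("fig3C")), "undefined")
})

test_that("the exposure gradient changes sign exactly at the threshold", {
  # bisection on the sign of dP*/dA over f around f*
  p <- lv_update(lv_preset("fig3A"), A = 0.5)
  fstar <- release_threshold_f(p)
  g <- function(fv) dPstar_dA(lv_update(p, f = fv), check_coexistence = FALSE)
  lo <- 0.5; hi <- 2
  expect_lt(g(lo), 0)
  expect_gt(g(hi), 0)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, fstar, tolerance = 1e-10)
  # consistency at the documented competition setting
  expect_gt(dPstar_dA(lv_update(p, f = 2)), 0)   # release above f*
  expect_lt(dPstar_dA(lv_update(p, f = 0.5)), 0) # suppression below f*
})

test_that("beneficial resistance reduces to the sign of alpha_pc", {
  expect_true(beneficial_resistance_condition(
    lv_update(lv_preset("fig3A"), A = 1)))
  expect_true(beneficial_resistance_condition(
    lv_update(lv_preset("fig3B"), A = 1)))
  expect_false(beneficial_resistance_condition(
    lv_update(lv_preset("fig3C"), A = 1)))
  expect_false(beneficial_resistance_condition(
    lv_update(lv_preset("fig3D"), A = 1)))
  expect_false(beneficial_resistance_condition(
    lv_update(lv_preset("fig3A"), A = 1, alpha_pc = 0)))
  expect_error(beneficial_resistance_condition(lv_preset("fig3A")), "A > 0")
  # sign consistency with the gradient across random sets under exposure
  set.seed(22)
  for (i in 1:30) {
    p <- sample_params()
    if (p$A == 0) p <- lv_update(p, A = 0.5)
    g <- dPstar_df(p, check_coexistence = FALSE)
    expect_equal(g > 0,
                 beneficial_resistance_condition(p) && p$x > 0 && p$A > 0)
  }
})
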