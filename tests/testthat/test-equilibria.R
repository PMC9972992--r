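test_that("coexistence closed form matches hand-derived reference points", {
  p <- lv_preset("fig3A")
  eq <- coexistence_equilibrium(p)
  # (0.25 - 0.2)/0.09 by direct substitution
  expect_equal(eq$P_star, 0.05 / 0.09, tolerance = 1e-12)
  expect_equal(eq$C_star, 0.05 / 0.09, tolerance = 1e-12)
  expect_equal(eq$kind, "coexistence")
  expect_true(eq$stable)

  eq2 <- coexistence_equilibrium(lv_update(p, A = 1, f = 0.5))
  expect_equal(eq2$P_star, 0.02 / 0.09, tolerance = 1e-12)
  expect_gt(eq2$C_star, eq2$P_star)
})

test_that("coexistence equilibrium agrees with long-time ODE integration", {
  for (cfg in list(list(A = 0, f = 1), list(A = 1, f = 0.5))) {
    p <- lv_update(lv_preset("fig3A"), A = cfg$A, f = cfg$f)
    eq <- coexistence_equilibrium(p)
    tr <- lv_integrate(p, 0.1, 0.1, horizon = 500)
    expect_equal(tail(tr$P, 1), eq$P_star, tolerance = 1e-6)
    expect_equal(tail(tr$C, 1), eq$C_star, tolerance = 1e-6)
  }
})

test_that("boundary equilibria carry feasibility and invasion stability", {
  # pathogen-alone density 0.8 under maximal exposure (20% reduction)
  p <- lv_update(lv_preset("fig3A"), A = 1)
  be <- boundary_equilibria(p)
  expect_equal(be$P_star[be$label == "pathogen_alone"], 0.8)
  # extinction unstable whenever a species can grow at the origin
  p0 <- lv_preset("fig3A")
  be0 <- boundary_equilibria(p0)
  expect_false(be0$stable[be0$label == "extinction"])
  # commensal-alone state at A = 1, f = 2 is feasible (x*f*A < r_c)...
  p2 <- lv_update(lv_preset("fig3A"), A = 1, f = 2)
  be2 <- boundary_equilibria(p2)
  com <- be2[be2$label == "commensal_alone", ]
  expect_equal(com$C_star, 0.6)
  expect_true(com$feasible)
  # ...but invadable by the pathogen, so pathogen dominance is the attractor
  expect_false(com$stable)
  expect_equal(classify_outcome(p2)$kind, "pathogen_dominance")
})

test_that("effective-growth extinction collapses boundary densities to zero", {
  p <- lv_params(r_p = 0.1, r_c = 0.5, x = 0.2, A = 1, f = 3,
                 alpha_pc = 0.5, alpha_cp = 0.5)
  be <- boundary_equilibria(p)
  expect_equal(be$P_star[be$label == "pathogen_alone"], 0)  # r_p - xA < 0
  expect_gte(be$C_star[be$label == "commensal_alone"], 0)
})

test_that("classification recovers the documented outcome regimes", {
  p <- lv_preset("fig3A")
  expect_equal(classify_outcome(p)$kind, "coexistence")
  expect_equal(classify_outcome(lv_update(p, A = 1, f = 2))$kind,
               "pathogen_dominance")
  # faster-growing commensal regime: high f*A drives commensal dominance
  # only when the pathogen cannot invade; with r_c > r_p and low pathogen
  # growth the commensal holds the niche at strong pathogen clearance
  pS1 <- lv_update(lv_preset("figS1"), A = 1, f = 0.2)
  expect_equal(classify_outcome(pS1)$kind, "commensal_dominance")
})

test_that("every returned equilibrium is a fixed point of the dynamics", {
  set.seed(11)
  for (i in 1:50) {
    p <- sample_params()
    out <- classify_outcome(p)
    rhs <- growth_rhs(p, out$P_star, out$C_star)
    expect_lt(max(abs(rhs$dP), abs(rhs$dC)), 1e-9)
    be <- boundary_equilibria(p)
    feas <- be[be$feasible, ]
    r2 <- growth_rhs(p, feas$P_star, feas$C_star)
    expect_lt(max(abs(r2$dP), abs(r2$dC)), 1e-9)
  }
})

test_that("analytic stability agrees with eigen() on a numerical Jacobian", {
  set.seed(12)
  for (i in 1:25) {
    p <- sample_params()
    out <- classify_outcome(p)
    if (out$marginal) next
    re <- numeric_jacobian_eigs(p, out$P_star, out$C_star)
    expect_equal(sort(c(out$eig1, out$eig2)), sort(re), tolerance = 1e-4)
    expect_true(max(re) < 1e-5)
  }
})

test_that("swapping species roles swaps the equilibrium densities", {
  set.seed(13)
  for (i in 1:25) {
    p <- sample_params()
    if (p$f < 0.05) next
    q <- lv_params(r_p = p$r_c, r_c = p$r_p, k_p = p$k_c, k_c = p$k_p,
                   alpha_pc = p$alpha_cp, alpha_cp = p$alpha_pc,
                   x = p$x * p$f, f = 1 / p$f, A = p$A)
    eq_p <- coexistence_equilibrium(p)
    eq_q <- coexistence_equilibrium(q)
    expect_equal(eq_p$P_star, eq_q$C_star, tolerance = 1e-12)
    expect_equal(eq_p$C_star, eq_q$P_star, tolerance = 1e-12)
  }
})

test_that("fully symmetric parameters give identical densities", {
  p <- lv_update(lv_preset("fig3A"), A = 0.6, f = 1)
  eq <- coexistence_equilibrium(p)
  expect_equal(eq$P_star, eq$C_star, tolerance = 1e-14)
})

test_that("without interactions the model reduces to logistic loss forms", {
  set.seed(14)
  for (i in 1:10) {
    p <- sample_params()
    p0 <- lv_update(p, alpha_pc = 0, alpha_cp = 0)
    out <- classify_outcome(p0)
    expect_equal(out$P_star, max(0, p0$k_p * (1 - p0$x * p0$A / p0$r_p)),
                 tolerance = 1e-12)
    expect_equal(out$C_star,
                 max(0, p0$k_c * (1 - p0$x * p0$f * p0$A / p0$r_c)),
                 tolerance = 1e-12)
  }
  # and A = 0 removes the antibiotic entirely: classic two-species model
  p <- lv_update(lv_preset("fig3A"), A = 0)
  eqA0 <- classify_outcome(p)
  px0 <- lv_update(p, x = 0, A = 1)
  expect_equal(classify_outcome(px0)$P_star, eqA0$P_star, tolerance = 1e-12)
})

test_that("ODE trajectories converge to the classified attractor", {
  set.seed(15)
  for (i in 1:40) {
    p <- sample_params(min_rate = 0.02)
    out <- classify_outcome(p)
    P0 <- runif(1, 0.05, 1.2)
    C0 <- runif(1, 0.05, 1.2)
    tr <- lv_integrate(p, P0, C0, horizon = 800, n_points = 11)
    expect_equal(tail(tr$P, 1), out$P_star, tolerance = 1e-5)
    expect_equal(tail(tr$C, 1), out$C_star, tolerance = 1e-5)
  }
})
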