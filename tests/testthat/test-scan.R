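test_that("exposure-susceptibility scan has the documented phase structure", {
  A_vals <- seq(0, 1, length.out = 41)
  f_vals <- seq(0, 2, length.out = 41)
  sc <- scan_Af(lv_preset("fig3A"), A_vals, f_vals)
  expect_equal(nrow(sc), 41 * 41)
  expect_true(all(sc$outcome %in% c("joint_extinction", "pathogen_dominance",
                                    "commensal_dominance", "coexistence")))
  fstar <- release_threshold_f(lv_preset("fig3A"))
  dom <- sc[sc$outcome == "pathogen_dominance", ]
  # pathogen dominance confined to the high-exposure, high-susceptibility corner
  expect_gt(nrow(dom), 0)
  expect_true(all(dom$f > fstar))
  expect_true(all(dom$A >= 0.5))
  co <- sc[sc$outcome == "coexistence" & sc$A > 0, ]
  # release exactly above the threshold, suppression below
  expect_true(all(co$dP_dA[co$f > fstar + 1e-9] > 0))
  expect_true(all(co$dP_dA[co$f < fstar - 1e-9] < 0))
  # beneficial resistance everywhere coexistence holds under exposure
  expect_true(all(co$dP_df > 0))
})

test_that("scan cells agree with the closed forms and single classification", {
  sc <- scan_Af(lv_preset("fig3A"), seq(0, 1, length.out = 11),
                seq(0, 2, length.out = 11))
  co <- sc[sc$outcome == "coexistence", ]
  for (i in seq_len(nrow(co))) {
    p <- lv_update(lv_preset("fig3A"), A = co$A[i], f = co$f[i])
    expect_equal(co$P_star[i], coexistence_equilibrium(p)$P_star,
                 tolerance = 1e-12)
  }
  # sampled cells match the scalar classifier
  set.seed(31)
  for (i in sample(nrow(sc), 15)) {
    p <- lv_update(lv_preset("fig3A"), A = sc$A[i], f = sc$f[i])
    out <- classify_outcome(p)
    expect_equal(sc$outcome[i], out$kind)
    expect_equal(sc$P_star[i], out$P_star, tolerance = 1e-12)
  }
})

test_that("susceptibility is inert along the exposure-free row", {
  sc <- scan_Af(lv_preset("fig3A"), c(0, 0.5), seq(0, 2, length.out = 9))
  row0 <- sc[sc$A == 0, ]
  expect_equal(length(unique(row0$P_star)), 1L)
})

test_that("facilitating-commensal scenarios never show release or benefit", {
  for (preset in c("fig3C", "fig3D")) {
    sc <- scan_Af(lv_preset(preset), seq(0, 1, length.out = 21),
                  seq(0, 2, length.out = 21),
                  contour_increment = if (preset == "fig3D") 0.06 else 0.03)
    co <- sc[sc$outcome == "coexistence" & sc$A > 0, ]
    expect_gt(nrow(co), 0)
    expect_true(all(co$dP_dA < 0))
    expect_true(all(co$dP_df < 0))
  }
})

test_that("higher commensal capacity precludes competitive release", {
  # k_c > k_p setting: no release anywhere on the default ranges
  sc <- scan_Af(lv_preset("figS2"), seq(0, 1, length.out = 21),
                seq(0, 2, length.out = 21))
  co <- sc[sc$outcome == "coexistence", ]
  expect_true(all(co$dP_dA <= 0, na.rm = TRUE))
  expect_equal(sum(sc$outcome == "pathogen_dominance"), 0)
})

test_that("interaction sweep reproduces the sign map and marked cells", {
  vals <- c(-0.8, -0.4, 0, 0.4, 0.8)
  sc <- scan_alpha(lv_preset("fig4"), vals, vals)
  expect_equal(nrow(sc), 25)
  cell <- function(a, b) sc$dP_df[sc$alpha_pc == a & sc$alpha_cp == b]
  expect_equal(round(cell(0.8, 0.8), 4), 0.4444)
  expect_equal(round(cell(0.8, -0.8), 4), 0.0976)
  expect_equal(round(cell(-0.8, 0.8), 4), -0.0976)
  expect_equal(round(cell(-0.8, -0.8), 4), -0.4444)
  # sign boundary on alpha_pc = 0 under exposure
  expect_true(all(sign(sc$dP_df) == sign(sc$alpha_pc)))
  expect_true(all(cell(0, vals) == 0))
  # magnitude grows toward the strongly coupled corners along the diagonal
  expect_true(abs(cell(0.8, 0.8)) > abs(cell(0.4, 0.4)))
  expect_true(abs(cell(-0.8, -0.8)) > abs(cell(-0.4, -0.4)))
})

test_that("interaction sweep obeys the reflection identity of the gradient", {
  # from the closed form: g(a, b) = -g(-a, b) * (1 + ab) / (1 - ab)
  sc <- scan_alpha(lv_preset("fig4"), seq(-0.9, 0.9, by = 0.3),
                   seq(-0.9, 0.9, by = 0.3))
  cell <- function(a, b) {
    sc$dP_df[abs(sc$alpha_pc - a) < 1e-9 & abs(sc$alpha_cp - b) < 1e-9]
  }
  set.seed(32)
  as <- c(0.3, 0.6, 0.9); bs <- c(-0.9, -0.3, 0.3, 0.9)
  for (a in as) for (b in bs) {
    expect_equal(cell(a, b), -cell(-a, b) * (1 + a * b) / (1 - a * b),
                 tolerance = 1e-12)
  }
})
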