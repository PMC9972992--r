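# Random valid parameter sets for property-style tests.
#
# `min_rate` rejects parameter sets whose attractor is only weakly
# attracting (leading eigenvalue real part closer to 0 than -min_rate):
# near-bifurcation sets converge too slowly for a fixed-horizon ODE oracle
# and are exercised separately by the threshold tests.
sample_params <- function(min_rate = 0) {
  repeat {
    p <- lv_params(
      r_p = runif(1, 0.2, 1), r_c = runif(1, 0.2, 1),
      k_p = runif(1, 0.3, 2), k_c = runif(1, 0.3, 2),
      alpha_pc = runif(1, -0.9, 0.9), alpha_cp = runif(1, -0.9, 0.9),
      x = runif(1, 0, 0.3), f = runif(1, 0, 2), A = runif(1, 0, 1)
    )
    if (min_rate == 0) return(p)
    out <- classify_outcome(p)
    if (out$stable && max(out$eig1, out$eig2) < -min_rate) return(p)
  }
}

# Random parameter sets whose attractor is stable coexistence.
sample_coexistence_params <- function(min_rate = 1e-4) {
  repeat {
    p <- sample_params()
    out <- classify_outcome(p)
    if (out$kind == "coexistence" && out$stable &&
        max(out$eig1, out$eig2) < -min_rate) {
      return(p)
    }
  }
}

# Independent 2x2 stability check via base R eigen() on a numerically
# differentiated Jacobian (never uses the package's analytic Jacobian).
numeric_jacobian_eigs <- function(params, P, C, h = 1e-7) {
  fun <- function(y) {
    d <- growth_rhs(params, max(y[1], 0), max(y[2], 0))
    c(d$dP, d$dC)
  }
  J <- matrix(0, 2, 2)
  y0 <- c(P, C)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (fun(y0 + e) - fun(pmax(y0 - e, 0))) /
      (y0[j] + h - max(y0[j] - h, 0))
  }
  Re(eigen(J, only.values = TRUE)$values)
}
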