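# Quasi-steady-state algebra: equilibrium constants, gene occupancies
# (against an independent linear-solve oracle and against relaxation of
# the actual fast subsystem), dimer activation, mRNA levels, and the
# reduced right-hand sides.

test_that("equilibrium constants are the forward/backward rate ratios", {
  K <- equilibrium_constants(p_base)
  expect_equal(K$Kalpha, 100 / 0.66, tolerance = 1e-12)
  expect_equal(K$KUJ, 0.1 / 0.0133, tolerance = 1e-12)
  pr <- equilibrium_constants(p_base, orientation = "printed")
  expect_equal(pr$Kalpha, 1 / K$Kalpha, tolerance = 1e-12)
  p_eq <- set_parameters(p_base, kbetaRf = 0.522)  # forward = backward
  expect_equal(equilibrium_constants(p_eq)$KbetaR, 1)
})

test_that("gene occupancies solve the fast gene-state equations", {
  g0 <- gene_qss(0, 0, p_base)
  expect_equal(unlist(g0),
               c(alphaStar = 0, beta = 1, betaR = 0, betaStar = 0,
                 sigma = 1))
  # saturation: strong dimer turns everything on
  g_inf <- gene_qss(1e9, 5, p_base)
  expect_gt(g_inf$alphaStar, 1 - 1e-6)
  expect_gt(g_inf$betaStar, 1 - 1e-6)
  expect_lt(g_inf$sigma, 1e-6)

  # independent oracle: direct linear solve of d(beta)/dt = 0,
  # d(betaR)/dt = 0 from the full model's gene-state kinetics
  S2 <- 0.5; A <- 10
  M <- rbind(c(-p_base[["kbetaf"]] * S2 - p_base[["kbetab"]],
               -p_base[["kbetab"]]),
             c(p_base[["kbetaRf"]] * A, -p_base[["kbetaRb"]]))
  sol <- solve(M, c(-p_base[["kbetab"]], 0))
  g <- gene_qss(S2, A, p_base)
  expect_equal(g$beta, sol[1], tolerance = 1e-10)
  expect_equal(g$betaR, sol[2], tolerance = 1e-10)
})

test_that("the partition identity beta + betaR + betaStar = 1 is exact", {
  set.seed(7)
  for (i in 1:50) {
    g <- gene_qss(stats::rexp(1, 1 / 5), stats::rexp(1, 1 / 50), p_base)
    expect_equal(g$beta + g$betaR + g$betaStar, 1, tolerance = 1e-14)
    expect_true(g$alphaStar >= 0 && g$alphaStar <= 1)
    expect_true(g$sigma >= 0 && g$sigma <= 1)
  }
})

test_that("gene occupancies match relaxation of the frozen fast subsystem", {
  S2 <- 0.3; A <- 20
  rhs <- function(t, y, parms) {
    al <- y[1]; be <- y[2]; beR <- y[3]; si <- y[4]
    list(c(-p_base[["kalphaf"]] * S2 * al + p_base[["kalphab"]] * (1 - al),
           -p_base[["kbetaf"]] * S2 * be +
             p_base[["kbetab"]] * (1 - be - beR),
           p_base[["kbetaRf"]] * A * be - p_base[["kbetaRb"]] * beR,
           -p_base[["ksigmaf"]] * S2 * si + p_base[["ksigmab"]] * (1 - si)))
  }
  out <- deSolve::ode(c(1, 1, 0, 1), c(0, 10), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  fin <- out[nrow(out), -1]
  g <- gene_qss(S2, A, p_base)
  expect_equal(unname(fin[1]), 1 - g$alphaStar, tolerance = 1e-6)
  expect_equal(unname(fin[2]), g$beta, tolerance = 1e-6)
  expect_equal(unname(fin[3]), g$betaR, tolerance = 1e-6)
  expect_equal(unname(fin[4]), g$sigma, tolerance = 1e-6)
})

test_that("JAK activation saturates with half-saturation at KUJ", {
  expect_equal(jak_qss(0, p_base), 0)
  expect_equal(jak_qss(1e9, p_base), 0.15, tolerance = 1e-6)
  KUJ <- equilibrium_constants(p_base)$KUJ
  expect_equal(jak_qss(KUJ, p_base), 0.15 / 2, tolerance = 1e-12)
  U <- seq(0, 30, by = 0.5)
  expect_true(all(diff(jak_qss(U, p_base)) > 0))
})

test_that("dimer activation has the two-substrate Michaelis form", {
  d <- stat_dimer_qss(0, 5, p_base)
  expect_equal(d$S2star, 0)
  # Michaelis constant of the 2-STAT catalytic step, in nM^2
  expect_equal(d$km^2, (0.1 + 100) / 1, tolerance = 1e-12)
  # half saturation at S = km
  dh <- stat_dimer_qss(d$km, 5, p_base)
  expect_equal(dh$S2star, dh$vmax / (2 * p_base[["kS2star"]]),
               tolerance = 1e-12)
  # monotone in S and in U
  expect_gt(stat_dimer_qss(20, 5, p_base)$S2star,
            stat_dimer_qss(10, 5, p_base)$S2star)
  expect_gt(stat_dimer_qss(10, 8, p_base)$S2star,
            stat_dimer_qss(10, 5, p_base)$S2star)
})

test_that("mRNA levels balance transcription against miRNA-boosted decay", {
  m <- mrna_qss(0, 0, 0, 0, p_base)
  expect_equal(m$malpha, 0.52 / 0.086, tolerance = 1e-12)
  expect_equal(m$mbeta, 0.03 / 0.086, tolerance = 1e-12)
  # cooperative SLBO repression: doubling B strictly lowers apt mRNA
  m1 <- mrna_qss(0.5, 0.5, 10, 2, p_base)
  m2 <- mrna_qss(0.5, 0.5, 10, 4, p_base)
  expect_lt(m2$malpha, m1$malpha)
  # APT represses slbo mRNA to zero in the limit
  expect_lt(mrna_qss(0, 0, 1e9, 0, p_base)$mbeta, 1e-8)
})

test_that("two-variable cross-repression model matches direct substitution", {
  d <- two_var_rhs(0, 0, 0, p_base)
  expect_equal(d[["A"]], 0.298 * 0.52 / 0.086, tolerance = 1e-12)
  expect_equal(d[["B"]], 0.312 * 0.03 / 0.086, tolerance = 1e-12)
  # APT represses SLBO: B-nullcline at A = 0 sits above its level at
  # large A for a fixed high dimer level
  b_null <- function(A) {
    stats::uniroot(function(B) two_var_rhs(A, B, 5, p_base)[["B"]],
                   c(0, 500))$root
  }
  expect_gt(b_null(0), b_null(100))
})

test_that("reduced RHS vanishes at steady states and rejects bad input", {
  eq <- cached_equilibria(4)
  for (s in eq) {
    expect_lt(max(abs(three_var_rhs(s$state, 4, p_base))), 1e-8)
  }
  expect_error(three_var_rhs(c(-1, 0, 0), 4, p_base), ">= 0")
  expect_error(three_var_rhs(c(1, NA, 0), 4, p_base), "finite")
})

test_that("finite-difference Jacobian agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:5) {
    x <- stats::runif(3, c(1, 1, 0.1), c(100, 100, 20))
    U <- stats::runif(1, 0.1, 8)
    J <- jacobian_three_var(x, U, p_base)
    J_ref <- pracma::jacobian(function(z) three_var_rhs(z, U, p_base), x)
    expect_equal(unname(J), J_ref, tolerance = 1e-5)
  }
  # stable node: all eigenvalues in the left half plane
  mot <- stable_states(cached_equilibria(4))
  ev <- eigen(jacobian_three_var(mot[[1]]$state, 4, p_base))$values
  expect_true(all(Re(ev) < 0))
  # degradation dominates at large S
  expect_lt(jacobian_three_var(c(500, 10, 1), 4, p_base)["S", "S"], 0)
})

test_that("reduced model projects the full model at small STAT levels", {
  # place the 12 fast variables at their QSS for given (S, A, B, U) and
  # compare the (S, A, B) components of the full RHS with the reduced
  # RHS; valid where S^2 is small against the Michaelis constant
  U <- 4
  km2 <- (p_base[["kc1b"]] + p_base[["kc1"]]) / p_base[["kc1f"]]
  for (S in c(0.5, 1, 2)) for (A in c(1, 10, 50)) for (B in c(0.1, 1, 5)) {
    Jstar <- jak_qss(U, p_base)
    c1 <- p_base[["kc1f"]] * Jstar * S^2 / (p_base[["kc1b"]] + p_base[["kc1"]])
    S2 <- p_base[["kc1"]] * c1 / p_base[["kS2star"]]
    g <- gene_qss(S2, A, p_base)
    m <- mrna_qss(g$alphaStar, g$betaStar, A, B, p_base)
    msig <- (p_base[["kmsigma"]] * (1 - g$sigma) + p_base[["msigma0"]]) /
      (p_base[["deltamsigma"]] + p_base[["deltaAsigma"]] * A)
    st <- c(Jstar = Jstar, J = p_base[["JT"]] - Jstar, S = S, c1 = c1,
            c2 = 0, S2star = S2, A = A, B = B, malpha = m$malpha,
            mbeta = m$mbeta, msigma = msig, alpha = 1 - g$alphaStar,
            beta = g$beta, betaR = g$betaR, sigma = g$sigma)
    d_full <- full_rhs(st, U, p_base)[c("S", "A", "B")]
    d_red <- three_var_rhs(c(S, A, B), U, p_base)
    scale <- pmax(abs(d_full), 0.05)
    expect_lt(max(abs(d_full - d_red) / scale), 0.05)
  }
})
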