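# Quasi-steady-state reduction of the full model.
#
# The gene-state variables equilibrate orders of magnitude faster than
# proteins and mRNAs, so alpha, beta and betaR are solved algebraically
# in terms of the activated STAT dimer S2* and APT. A Michaelis--Menten
# treatment of the JAK-catalyzed dimerization then removes Jstar, c1 and
# S2star, yielding the minimal three-variable model in (S, A, B).

#' Gene-state and JAK equilibrium constants
#'
#' Ratios of the fast binding/dissociation rates that parameterize the
#' quasi-steady-state gene occupancies. The constants are oriented as
#' forward/backward ratios (`Kalpha = kalphaf / kalphab`, etc., units
#' nM^-1), which makes the closed-form gene occupancies the exact
#' stationary solution of the gene-state kinetics; the opposite
#' (backward/forward) orientation is available via
#' `orientation = "printed"` for comparison (see the methods vignette
#' for why the derived orientation is the package default).
#' `KUJ = kUJb / kUJf` (nM) is the half-saturation UPD level of JAK
#' activation.
#'
#' @param p Parameter set.
#' @param orientation `"derived"` (default) or `"printed"`.
#' @return Named list with `Kalpha`, `Kbeta`, `KbetaR`, `Ksigma`, `KUJ`.
#' @export
equilibrium_constants <- function(p, orientation = c("derived", "printed")) {
  orientation <- match.arg(orientation)
  back <- c("kalphab", "kbetab", "kbetaRb", "ksigmab", "kUJf")
  if (any(unclass(p)[back] <= 0)) {
    stop("backward rates (and kUJf) must be > 0 to form equilibrium ",
         "constants", call. = FALSE)
  }
  if (orientation == "derived") {
    list(
      Kalpha = p[["kalphaf"]] / p[["kalphab"]],
      Kbeta  = p[["kbetaf"]]  / p[["kbetab"]],
      KbetaR = p[["kbetaRf"]] / p[["kbetaRb"]],
      Ksigma = p[["ksigmaf"]] / p[["ksigmab"]],
      KUJ    = p[["kUJb"]]    / p[["kUJf"]]
    )
  } else {
    if (any(unclass(p)[c("kalphaf", "kbetaf", "kbetaRf", "ksigmaf")] <= 0)) {
      stop("forward rates must be > 0 for the printed orientation",
           call. = FALSE)
    }
    list(
      Kalpha = p[["kalphab"]] / p[["kalphaf"]],
      Kbeta  = p[["kbetab"]]  / p[["kbetaf"]],
      KbetaR = p[["kbetaRb"]] / p[["kbetaRf"]],
      Ksigma = p[["ksigmab"]] / p[["ksigmaf"]],
      KUJ    = p[["kUJb"]]    / p[["kUJf"]]
    )
  }
}

#' Quasi-steady-state gene occupancies
#'
#' Solves the fast gene-state kinetics at equilibrium for given dimer
#' and APT levels:
#' \deqn{\alpha^* = \frac{K_\alpha S_2^*}{K_\alpha S_2^* + 1}, \quad
#'       \beta = \frac{1}{K_\beta S_2^* + 1 + K_{\beta R} A}, \quad
#'       \beta^R = K_{\beta R} A \beta, \quad
#'       \beta^* = K_\beta S_2^* \beta, \quad
#'       \sigma = \frac{1}{K_\sigma S_2^* + 1}.}
#' `alphaStar` and `betaStar` are the transcribing apt and slbo
#' fractions; `sigma` is the inactive stat fraction. The identity
#' `beta + betaR + betaStar = 1` holds exactly.
#'
#' @param S2star Activated STAT dimer (nM), `>= 0`.
#' @param A APT protein (nM), `>= 0`.
#' @param p Parameter set.
#' @param orientation Passed to [equilibrium_constants()].
#' @return Named list `alphaStar`, `beta`, `betaR`, `betaStar`, `sigma`.
#' @export
gene_qss <- function(S2star, A, p, orientation = "derived") {
  if (any(!is.finite(c(S2star, A))) || S2star < 0 || A < 0) {
    stop("S2star and A must be finite and >= 0", call. = FALSE)
  }
  K <- equilibrium_constants(p, orientation)
  beta <- 1 / (K$Kbeta * S2star + 1 + K$KbetaR * A)
  list(
    alphaStar = K$Kalpha * S2star / (K$Kalpha * S2star + 1),
    beta      = beta,
    betaR     = K$KbetaR * A * beta,
    betaStar  = K$Kbeta * S2star * beta,
    sigma     = 1 / (K$Ksigma * S2star + 1)
  )
}

#' Quasi-steady-state activated JAK
#'
#' Saturating JAK activation by UPD under conservation of the total JAK
#' pool: `Jstar = kUJf * U * JT / (kUJb + kUJf * U)`. Monotone in `U`,
#' bounded by `JT`, half-saturated at `U = KUJ`.
#'
#' @param U UPD level (nM).
#' @param p Parameter set.
#' @return Activated JAK (nM).
#' @export
jak_qss <- function(U, p) {
  if (!all(is.finite(U)) || any(U < 0)) stop("U must be finite and >= 0",
                                             call. = FALSE)
  p[["kUJf"]] * U * p[["JT"]] / (p[["kUJb"]] + p[["kUJf"]] * U)
}

#' Quasi-steady-state activated STAT dimer
#'
#' Michaelis--Menten treatment of JAK-catalyzed STAT dimerization:
#' `S2star = vmax * S^2 / (kS2star * (S^2 + km^2))` with
#' `vmax = kc1 * Jstar`. Because the catalytic step binds one activated
#' JAK with two STAT monomers, the Michaelis constant
#' `(kc1b + kc1) / kc1f` carries units of nM^2; the half-saturation
#' monomer concentration `km` returned here is its square root
#' (about 10.0 nM at baseline), so that `S = km` gives
#' `S2star = vmax / (2 * kS2star)`.
#'
#' @param S STAT monomer (nM).
#' @param U UPD level (nM).
#' @param p Parameter set.
#' @return Named list `Jstar`, `vmax`, `km`, `S2star`.
#' @export
stat_dimer_qss <- function(S, U, p) {
  if (!all(is.finite(c(S, U))) || any(S < 0) || any(U < 0)) {
    stop("S and U must be finite and >= 0", call. = FALSE)
  }
  if (p[["kS2star"]] <= 0) stop("kS2star must be > 0", call. = FALSE)
  Jstar <- jak_qss(U, p)
  vmax <- p[["kc1"]] * Jstar
  km <- sqrt((p[["kc1b"]] + p[["kc1"]]) / p[["kc1f"]])
  list(Jstar = Jstar, vmax = vmax, km = km,
       S2star = vmax * S^2 / (p[["kS2star"]] * (S^2 + km^2)))
}

#' Quasi-steady-state mRNA levels
#'
#' mRNA balances transcription (STAT-activated plus basal) against
#' degradation, including miRNA-mediated degradation: SLBO represses apt
#' mRNA cooperatively (`deltaBalpha * B^2`) and APT represses slbo mRNA
#' linearly (`deltaAbeta * A`).
#'
#' @param alphaStar,betaStar Transcribing apt/slbo gene fractions in
#'   `[0, 1]`.
#' @param A,B APT and SLBO protein levels (nM).
#' @param p Parameter set.
#' @return Named list `malpha`, `mbeta` (nM).
#' @export
mrna_qss <- function(alphaStar, betaStar, A, B, p) {
  vals <- c(alphaStar, betaStar, A, B)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("inputs must be finite and >= 0", call. = FALSE)
  }
  if (alphaStar > 1 || betaStar > 1) {
    stop("gene fractions must be <= 1", call. = FALSE)
  }
  list(
    malpha = (p[["kmalpha"]] * alphaStar + p[["malpha0"]]) /
      (p[["deltamalpha"]] + p[["deltaBalpha"]] * B^2),
    mbeta = (p[["kmbeta"]] * betaStar + p[["mbeta0"]]) /
      (p[["deltambeta"]] + p[["deltaAbeta"]] * A)
  )
}

#' Two-variable cross-repression model (fixed STAT dimer)
#'
#' The APT--SLBO cross-repression core with the activated dimer held at
#' a fixed level, as used to study the switch in isolation:
#' `dA/dt = kA * malpha_qss - deltaA * A` and
#' `dB/dt = kB * mbeta_qss - deltaB * B`.
#'
#' @param A,B APT and SLBO protein levels (nM).
#' @param S2star Fixed activated STAT dimer (nM).
#' @param p Parameter set.
#' @return Named numeric vector `c(A = dA/dt, B = dB/dt)` (nM/min).
#' @export
two_var_rhs <- function(A, B, S2star, p) {
  g <- gene_qss(S2star, A, p)
  m <- mrna_qss(g$alphaStar, g$betaStar, A, B, p)
  c(A = p[["kA"]] * m$malpha - p[["deltaA"]] * A,
    B = p[["kB"]] * m$mbeta - p[["deltaB"]] * B)
}

#' Minimal three-variable model right-hand side
#'
#' The reduced model in STAT (`S`), APT (`A`) and SLBO (`B`): JAK
#' activation, STAT dimerization and the gene states are all at quasi-
#' steady state, leaving
#' \deqn{dS/dt = k_S \frac{k_{m\sigma}(1-\sigma) + m_{\sigma 0}}
#'       {\delta_{m\sigma} + \delta_{A\sigma} A} - \delta_S S,}
#' with analogous rational production terms for APT and SLBO
#' (see [mrna_qss()]). UPD enters only through the dimer level.
#'
#' @param state Numeric vector `(S, A, B)` (nM), optionally named.
#' @param U UPD level (nM).
#' @param p Parameter set.
#' @return Named numeric vector `c(S = , A = , B = )` of derivatives
#'   (nM/min).
#' @export
#' @examples
#' three_var_rhs(c(12, 56, 1.5), U = 4, default_parameters())
three_var_rhs <- function(state, U, p) {
  if (length(state) != 3 || any(!is.finite(state))) {
    stop("state must be a finite numeric vector (S, A, B)", call. = FALSE)
  }
  if (any(state < 0)) stop("state components must be >= 0", call. = FALSE)
  .rhs3_raw(state[[1]], state[[2]], state[[3]], U, p)
}

# Unchecked algebra of the three-variable RHS. Newton iterates and
# finite differences may probe slightly negative values, where all the
# rational terms are still well defined; domain checks live in the
# exported wrapper.
.rhs3_raw <- function(S, A, B, U, p) {
  Jstar <- p[["kUJf"]] * U * p[["JT"]] / (p[["kUJb"]] + p[["kUJf"]] * U)
  vmax <- p[["kc1"]] * Jstar
  km2 <- (p[["kc1b"]] + p[["kc1"]]) / p[["kc1f"]]   # Michaelis constant, nM^2
  S2 <- vmax * S^2 / (p[["kS2star"]] * (S^2 + km2))
  Ka <- p[["kalphaf"]] / p[["kalphab"]]
  Kb <- p[["kbetaf"]] / p[["kbetab"]]
  KbR <- p[["kbetaRf"]] / p[["kbetaRb"]]
  Ks <- p[["ksigmaf"]] / p[["ksigmab"]]
  alphaStar <- Ka * S2 / (Ka * S2 + 1)
  beta <- 1 / (Kb * S2 + 1 + KbR * A)
  betaStar <- Kb * S2 * beta
  sigma <- 1 / (Ks * S2 + 1)
  c(
    S = p[["kS"]] * (p[["kmsigma"]] * (1 - sigma) + p[["msigma0"]]) /
      (p[["deltamsigma"]] + p[["deltaAsigma"]] * A) - p[["deltaS"]] * S,
    A = p[["kA"]] * (p[["kmalpha"]] * alphaStar + p[["malpha0"]]) /
      (p[["deltamalpha"]] + p[["deltaBalpha"]] * B^2) - p[["deltaA"]] * A,
    B = p[["kB"]] * (p[["kmbeta"]] * betaStar + p[["mbeta0"]]) /
      (p[["deltambeta"]] + p[["deltaAbeta"]] * A) - p[["deltaB"]] * B
  )
}

# Closure factory for the reduced RHS: hoists all parameter lookups out
# of the evaluation path. The returned function f(x, U) evaluates the
# same algebra as .rhs3_raw; hot loops (multistart Newton, continuation,
# time stepping over basin grids) use it instead of the checked wrapper.
.rhs3_factory <- function(p) {
  kUJf <- p[["kUJf"]]; kUJb <- p[["kUJb"]]
  vJT <- p[["kc1"]] * p[["JT"]]; ikS2 <- 1 / p[["kS2star"]]
  km2 <- (p[["kc1b"]] + p[["kc1"]]) / p[["kc1f"]]
  Ka <- p[["kalphaf"]] / p[["kalphab"]]
  Kb <- p[["kbetaf"]] / p[["kbetab"]]
  KbR <- p[["kbetaRf"]] / p[["kbetaRb"]]
  Ks <- p[["ksigmaf"]] / p[["ksigmab"]]
  kS <- p[["kS"]]; kms <- p[["kmsigma"]]; ms0 <- p[["msigma0"]]
  dms <- p[["deltamsigma"]]; dAs <- p[["deltaAsigma"]]; dS <- p[["deltaS"]]
  kA <- p[["kA"]]; kma <- p[["kmalpha"]]; ma0 <- p[["malpha0"]]
  dma <- p[["deltamalpha"]]; dBa <- p[["deltaBalpha"]]; dA <- p[["deltaA"]]
  kB <- p[["kB"]]; kmb <- p[["kmbeta"]]; mb0 <- p[["mbeta0"]]
  dmb <- p[["deltambeta"]]; dAb <- p[["deltaAbeta"]]; dB <- p[["deltaB"]]
  function(x, U) {
    S <- x[1]; A <- x[2]; B <- x[3]
    S2 <- vJT * U / (kUJb + kUJf * U) * kUJf * ikS2 * S^2 / (S^2 + km2)
    aS <- Ka * S2 / (Ka * S2 + 1)
    be <- 1 / (Kb * S2 + 1 + KbR * A)
    c(kS * (kms * (1 - 1 / (Ks * S2 + 1)) + ms0) / (dms + dAs * A) -
        dS * S,
      kA * (kma * aS + ma0) / (dma + dBa * B^2) - dA * A,
      kB * (kmb * Kb * S2 * be + mb0) / (dmb + dAb * A) - dB * B)
  }
}

# central-difference Jacobian of .rhs3_raw in (S, A, B), no clipping
.jac3_raw <- function(x, U, p) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- max(1e-6 * abs(x[j]), 1e-9)
    up <- x; up[j] <- x[j] + h
    dn <- x; dn[j] <- x[j] - h
    J[, j] <- (.rhs3_raw(up[1], up[2], up[3], U, p) -
               .rhs3_raw(dn[1], dn[2], dn[3], U, p)) / (2 * h)
  }
  J
}

# central-difference derivative of .rhs3_raw with respect to U
.dFdU_raw <- function(x, U, p) {
  h <- max(1e-6 * abs(U), 1e-9)
  Ud <- max(U - h, 0)
  (.rhs3_raw(x[1], x[2], x[3], U + h, p) -
   .rhs3_raw(x[1], x[2], x[3], Ud, p)) / (U + h - Ud)
}

#' Jacobian of the three-variable model
#'
#' Central finite differences of [three_var_rhs()] with relative step
#' `1e-6` per component (absolute floor `1e-9`). States are clipped at
#' zero from below so the Jacobian is one-sided on the boundary of the
#' positive octant.
#'
#' @param state Numeric vector `(S, A, B)`.
#' @param U UPD level (nM).
#' @param p Parameter set.
#' @return A 3x3 numeric matrix with rows/columns named `S`, `A`, `B`.
#' @export
jacobian_three_var <- function(state, U, p) {
  state <- as.numeric(state)
  J <- matrix(0, 3, 3, dimnames = list(c("S", "A", "B"), c("S", "A", "B")))
  for (j in 1:3) {
    h <- max(1e-6 * abs(state[j]), 1e-9)
    up <- state; up[j] <- state[j] + h
    dn <- state; dn[j] <- max(state[j] - h, 0)
    fu <- three_var_rhs(up, U, p)
    fd <- three_var_rhs(dn, U, p)
    if (any(!is.finite(fu)) || any(!is.finite(fd))) {
      stop("non-finite RHS while differencing the Jacobian", call. = FALSE)
    }
    J[, j] <- (fu - fd) / (up[j] - dn[j])
  }
  J
}
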