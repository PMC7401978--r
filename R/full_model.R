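# The full 15-variable mechanistic model of JAK/STAT-driven border-cell
# fate. State variables (all nM except the dimensionless gene-state
# proportions): activated JAK Jstar, free JAK J, STAT monomer S, the
# JAK--STAT complex c1, the APT--dimer complex c2, the activated STAT
# dimer S2star, APT protein A, SLBO protein B, mRNAs malpha/mbeta/msigma,
# and the proportions of *inactive* apt (alpha), slbo (beta), repressed
# slbo (betaR) and stat (sigma) genes. By that convention 1 - alpha is
# the transcribing apt fraction, and the resting gene state is
# alpha = beta = sigma = 1, betaR = 0.

.full_state_names <- c("Jstar", "J", "S", "c1", "c2", "S2star",
                       "A", "B", "malpha", "mbeta", "msigma",
                       "alpha", "beta", "betaR", "sigma")

#' Names of the 15 state variables of the full model
#' @return Character vector of length 15.
#' @export
full_state_names <- function() .full_state_names

#' Right-hand side of the full 15-variable model
#'
#' Evaluates the time derivatives of all 15 state variables for a given
#' UPD level `U`. The APT--dimer sequestration complex `c2` exchanges
#' with `S2star` and `A` at rates `c2_kf` (binding, nM^-1 min^-1) and
#' `c2_kb` (dissociation, min^-1); both default to 0, which freezes `c2`
#' and decouples it from the rest of the system. Because the binding and
#' dissociation fluxes cancel jointly at any steady state, switching
#' sequestration on changes transients but not the steady-state values
#' of the other 14 variables (this is checked numerically in the test
#' suite rather than assumed).
#'
#' @param state Named or ordered numeric vector of length 15 (see
#'   [full_state_names()]).
#' @param U UPD (Unpaired) ligand concentration, nM, `>= 0`.
#' @param p Parameter set from [default_parameters()] or
#'   [set_parameters()].
#' @param c2_kf,c2_kb Binding/dissociation rates of the APT--dimer
#'   complex; default 0 (sequestration off).
#' @return Named numeric vector of 15 derivatives (nM/min, or 1/min for
#'   gene-state proportions).
#' @export
full_rhs <- function(state, U, p, c2_kf = 0, c2_kb = 0) {
  if (length(state) != 15) stop("full model state must have 15 components",
                                call. = FALSE)
  if (!all(is.finite(state)) || !is.finite(U)) {
    stop("non-finite state or U", call. = FALSE)
  }
  if (U < 0) stop("U must be >= 0", call. = FALSE)
  s <- as.numeric(state)
  names(s) <- .full_state_names
  Jstar <- s[["Jstar"]]; J <- s[["J"]]; S <- s[["S"]]
  c1 <- s[["c1"]]; c2 <- s[["c2"]]; S2 <- s[["S2star"]]
  A <- s[["A"]]; B <- s[["B"]]
  ma <- s[["malpha"]]; mb <- s[["mbeta"]]; ms <- s[["msigma"]]
  al <- s[["alpha"]]; be <- s[["beta"]]; beR <- s[["betaR"]]
  si <- s[["sigma"]]

  seq_flux <- c2_kf * S2 * A - c2_kb * c2   # APT sequestering the dimer

  d <- c(
    Jstar  = p[["kUJf"]] * U * J - p[["kUJb"]] * Jstar -
             p[["kc1f"]] * Jstar * S^2 + p[["kc1b"]] * c1 +
             p[["kc1"]] * c1,
    J      = -p[["kUJf"]] * U * J + p[["kUJb"]] * Jstar,
    S      = -2 * p[["kc1f"]] * Jstar * S^2 + 2 * p[["kc1b"]] * c1 +
             2 * p[["kS2star"]] * S2 + p[["kS"]] * ms - p[["deltaS"]] * S,
    c1     = p[["kc1f"]] * Jstar * S^2 - p[["kc1b"]] * c1 -
             p[["kc1"]] * c1,
    c2     = seq_flux,
    S2star = p[["kc1"]] * c1 - p[["kS2star"]] * S2 - seq_flux,
    A      = p[["kA"]] * ma - p[["deltaA"]] * A - seq_flux,
    B      = p[["kB"]] * mb - p[["deltaB"]] * B,
    malpha = p[["kmalpha"]] * (1 - al) - p[["deltamalpha"]] * ma +
             p[["malpha0"]] - p[["deltaBalpha"]] * B^2 * ma,
    mbeta  = p[["kmbeta"]] * (1 - be - beR) - p[["deltambeta"]] * mb +
             p[["mbeta0"]] - p[["deltaAbeta"]] * A * mb,
    msigma = p[["kmsigma"]] * (1 - si) - p[["deltamsigma"]] * ms +
             p[["msigma0"]] - p[["deltaAsigma"]] * A * ms,
    alpha  = -p[["kalphaf"]] * S2 * al + p[["kalphab"]] * (1 - al),
    beta   = -p[["kbetaf"]] * S2 * be + p[["kbetab"]] * (1 - be - beR),
    betaR  = p[["kbetaRf"]] * A * be - p[["kbetaRb"]] * beR,
    sigma  = -p[["ksigmaf"]] * S2 * si + p[["ksigmab"]] * (1 - si)
  )
  d
}

#' Default initial condition for the full model
#'
#' Only the three slow proteins are specified by a scenario; the fast
#' variables are started at biologically neutral defaults: the whole JAK
#' pool unbound (`J = JT`, `Jstar = c1 = c2 = S2star = 0`), all genes in
#' the inactive state (`alpha = beta = sigma = 1`, `betaR = 0`), and the
#' three mRNAs at their quasi-steady-state level conditioned on the
#' initial proteins (with the genes at rest, transcription is basal
#' only, so e.g. `malpha = malpha0 / (deltamalpha + deltaBalpha * B0^2)`).
#' Every component can be overridden afterwards by plain assignment.
#'
#' @param p Parameter set.
#' @param S0,A0,B0 Initial STAT, APT and SLBO protein levels (nM).
#' @return Named numeric vector of length 15.
#' @export
#' @examples
#' initial_full_state(default_parameters(), 12, 56, 1.5)
initial_full_state <- function(p, S0, A0, B0) {
  if (any(!is.finite(c(S0, A0, B0))) || any(c(S0, A0, B0) < 0)) {
    stop("initial protein levels must be finite and >= 0", call. = FALSE)
  }
  st <- numeric(15)
  names(st) <- .full_state_names
  st[["J"]] <- p[["JT"]]
  st[["S"]] <- S0
  st[["A"]] <- A0
  st[["B"]] <- B0
  st[["alpha"]] <- 1
  st[["beta"]] <- 1
  st[["sigma"]] <- 1
  # mRNA at QSS given resting genes (transcribing fractions are zero)
  st[["malpha"]] <- p[["malpha0"]] /
    (p[["deltamalpha"]] + p[["deltaBalpha"]] * B0^2)
  st[["mbeta"]] <- p[["mbeta0"]] /
    (p[["deltambeta"]] + p[["deltaAbeta"]] * A0)
  st[["msigma"]] <- p[["msigma0"]] /
    (p[["deltamsigma"]] + p[["deltaAsigma"]] * A0)
  st
}
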