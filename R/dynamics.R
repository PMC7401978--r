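# Time integration, fate classification, and the scripted in-silico
# experiments (miRNA-induced delay, STAT knockdown, APT sweep).

#' Integrate a model variant through time
#'
#' Solves the selected right-hand side with a stiff implicit solver
#' (`deSolve::ode`, method `"lsoda"`, which switches to BDF on stiff
#' stretches) and returns dense output on a uniform grid.
#'
#' @param model One of `"reduced3"` (minimal STAT/APT/SLBO model),
#'   `"full15"` (full mechanistic model) or `"reduced2"` (APT/SLBO
#'   cross-repression at fixed dimer level).
#' @param init Initial state: length 3 `(S, A, B)` for `reduced3`,
#'   length 15 for `full15` (see [initial_full_state()]), length 2
#'   `(A, B)` for `reduced2`.
#' @param U UPD level (nM); ignored by `reduced2`.
#' @param p Parameter set.
#' @param t_end Final time (min), `> 0`.
#' @param n_out Number of output samples (default 201 on `[0, t_end]`).
#' @param rtol,atol Relative/absolute solver tolerances (defaults
#'   `1e-8` / `1e-10`).
#' @param S2star Fixed dimer level for `reduced2`.
#' @param c2_kf,c2_kb APT--dimer sequestration rates for `full15`
#'   (default 0, see [full_rhs()]).
#' @param overrides Optional named record of parameter overrides that
#'   produced `p`; stored as metadata only.
#' @return An object of class `"jak_trajectory"`: list with `times`,
#'   `states` (matrix, one row per time), `model`, `U`, `rtol`, `atol`,
#'   `overrides`.
#' @export
#' @examples
#' p <- default_parameters()
#' tr <- integrate_model("reduced3", c(12, 56, 1.5), U = 4, p, t_end = 500)
#' tail(tr$states, 1)
integrate_model <- function(model = c("reduced3", "full15", "reduced2"),
                            init, U = 0, p = default_parameters(),
                            t_end, n_out = 201,
                            rtol = 1e-8, atol = 1e-10,
                            S2star = 0, c2_kf = 0, c2_kb = 0,
                            overrides = NULL) {
  model <- match.arg(model)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0",
                                            call. = FALSE)
  n_out <- max(2L, as.integer(n_out))
  times <- seq(0, t_end, length.out = n_out)
  dim_needed <- switch(model, reduced3 = 3L, full15 = 15L, reduced2 = 2L)
  init <- as.numeric(init)
  if (length(init) != dim_needed) {
    stop("init must have ", dim_needed, " components for model ", model,
         call. = FALSE)
  }
  rhs3 <- if (model == "reduced3") .rhs3_factory(p)
  func <- switch(model,
    reduced3 = function(t, y, parms) {
      list(rhs3(pmax(y, 0), U))
    },
    # no clipping here: the mass-action terms are defined for (small)
    # negative excursions and supply the stiff restoring forces that
    # keep the solution near the positive octant
    full15 = function(t, y, parms) {
      list(full_rhs(y, U, p, c2_kf = c2_kf, c2_kb = c2_kb))
    },
    reduced2 = function(t, y, parms) {
      list(two_var_rhs(max(y[1], 0), max(y[2], 0), S2star, p))
    }
  )
  sol <- deSolve::ode(y = init, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failed; last good time ",
         max(sol[, 1]), " min", call. = FALSE)
  }
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- switch(model,
    reduced3 = c("S", "A", "B"),
    full15 = full_state_names(),
    reduced2 = c("A", "B"))
  structure(
    list(times = sol[, 1], states = states, model = model, U = U,
         rtol = rtol, atol = atol, overrides = overrides),
    class = "jak_trajectory")
}

#' @export
print.jak_trajectory <- function(x, ...) {
  cat("Trajectory of model", x$model, "at U =", x$U, "nM;",
      length(x$times), "samples on [0,", max(x$times), "] min\n")
  cat("final state:\n")
  print(round(x$states[nrow(x$states), ], 5))
  invisible(x)
}

#' @export
plot.jak_trajectory <- function(x, components = NULL, log = "", ...) {
  st <- x$states
  if (!is.null(components)) st <- st[, components, drop = FALSE]
  graphics::matplot(x$times, st, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "concentration (nM)",
                    log = log, ...)
  graphics::legend("topright", legend = colnames(st), lty = 1,
                   col = seq_len(ncol(st)), bty = "n")
  invisible(x)
}

# relative euclidean distance of x to reference state ss
.rel_dist <- function(x, ss) {
  sqrt(sum((x - ss)^2)) / max(sqrt(sum(ss^2)), 1e-12)
}

#' Classify the cell fate of a trajectory
#'
#' Labels a trajectory `motile` if its endpoint at the deadline lies
#' within a relative tolerance ball of the high-SLBO/low-APT stable
#' state, `stationary` if within tolerance of the high-APT stable
#' state, and `unresolved` otherwise (the operational criterion for an
#' initial condition lying near the separatrix). The convergence time
#' is the first time after which the trajectory remains inside the
#' tolerance ball.
#'
#' @param traj A `"jak_trajectory"` over `(S, A, B)` (model
#'   `"reduced3"`), or any trajectory whose columns include `S`, `A`,
#'   `B`.
#' @param equilibria List of steady states for the same `(U, p)`
#'   (from [find_steady_states()]); must contain the two stable states.
#' @param rel_tol Relative euclidean tolerance (default 0.05).
#' @param deadline Classification deadline in minutes (default 500).
#' @return A list of class `"jak_fate"`: `tag` (`"motile"`,
#'   `"stationary"` or `"unresolved"`), `t_converge` (min or `NA`),
#'   `matched` (the matched steady state or `NULL`).
#' @export
classify_fate <- function(traj, equilibria, rel_tol = 0.05,
                          deadline = 500) {
  stable <- Filter(function(s) s$stability == "stable", equilibria)
  if (length(stable) < 1) stop("equilibria contain no stable state",
                               call. = FALSE)
  st <- traj$states[, c("S", "A", "B"), drop = FALSE]
  keep <- traj$times <= deadline + 1e-9
  st <- st[keep, , drop = FALSE]
  tt <- traj$times[keep]
  endpoint <- st[nrow(st), ]

  d_end <- vapply(stable, function(s) .rel_dist(endpoint, s$state),
                  numeric(1))
  match_state <- NULL
  tag <- "unresolved"
  if (min(d_end) < rel_tol) {
    match_state <- stable[[which.min(d_end)]]
    # motile = SLBO-dominated attractor, stationary = APT-dominated
    tag <- if (match_state$state[["A"]] > match_state$state[["B"]])
      "stationary" else "motile"
  }
  t_conv <- NA_real_
  if (!is.null(match_state)) {
    d <- apply(st, 1, .rel_dist, ss = match_state$state)
    inside <- rev(cumprod(rev(d < rel_tol))) > 0  # inside from here on
    t_conv <- tt[which(inside)[1]]
  }
  structure(list(tag = tag, t_converge = t_conv, matched = match_state),
            class = "jak_fate")
}

#' @export
print.jak_fate <- function(x, ...) {
  cat("fate:", x$tag,
      if (!is.na(x$t_converge)) paste0("(converged at ",
                                       round(x$t_converge, 1), " min)"),
      "\n")
  invisible(x)
}

#' Equilibration time of a single trajectory component
#'
#' First time after which the named component stays within a relative
#' band of its final value; the operational definition of a variable
#' having "equilibrated".
#'
#' @param traj A `"jak_trajectory"`.
#' @param component Column name, e.g. `"S"`.
#' @param rel_band Relative band half-width (default 0.05, i.e. 5%).
#' @return Time in minutes, or `NA` if the component never enters and
#'   stays in the band (non-convergence).
#' @export
convergence_time <- function(traj, component, rel_band = 0.05) {
  x <- traj$states[, component]
  final <- x[length(x)]
  band <- rel_band * max(abs(final), 1e-12)
  ok <- abs(x - final) <= band
  inside <- rev(cumprod(rev(ok))) > 0
  idx <- which(inside)[1]
  if (is.na(idx)) return(NA_real_)
  traj$times[idx]
}

#' miRNA-induced delay experiment (GO / SLOW / STOP)
#'
#' Scans the APT-induced miRNA degradation rate of stat mRNA,
#' `deltaAsigma`, integrating the three-variable model for each value
#' and measuring when STAT equilibrates. Outcomes: `GO` (STAT rises to
#' the elevated branch promptly), `SLOW` (rises, but delayed more than
#' twofold relative to the baseline), `STOP` (STAT never elevates
#' within the horizon). "Elevated" means the final STAT level exceeds
#' the saddle's STAT value at the same `(U, p)`. The first entry of
#' `deltaAsigma_values` is the baseline against which delays are
#' measured.
#'
#' @param p Parameter set.
#' @param deltaAsigma_values Values to scan; default
#'   `c(0.05, 0.17382, 0.18)`.
#' @param U UPD level (default 4).
#' @param initial `(S, A, B)` initial condition (default
#'   `c(12, 56, 1.5)`).
#' @param t_end Horizon in minutes (default 1000).
#' @param n_out Output samples per run (default 2001 for ~0.5 min
#'   resolution of convergence times).
#' @param rel_band Band for [convergence_time()] (default 0.05).
#' @return data.frame with columns `deltaAsigma`, `fate`, `S_final`,
#'   `t_converge`, `delay`.
#' @export
mirna_delay_experiment <- function(p = default_parameters(),
                                   deltaAsigma_values = c(0.05, 0.17382, 0.18),
                                   U = 4, initial = c(12, 56, 1.5),
                                   t_end = 1000, n_out = 2001,
                                   rel_band = 0.05) {
  rows <- lapply(deltaAsigma_values, function(v) {
    pv <- set_parameters(p, deltaAsigma = v)
    tr <- integrate_model("reduced3", initial, U, pv, t_end, n_out = n_out)
    eq <- find_steady_states(U, pv)
    saddle <- Filter(function(s) s$stability == "unstable", eq)
    S_thresh <- if (length(saddle) > 0) saddle[[1]]$state[["S"]] else Inf
    S_final <- tr$states[nrow(tr$states), "S"]
    elevated <- is.finite(S_thresh) && S_final > S_thresh
    tc <- if (elevated) convergence_time(tr, "S", rel_band) else NA_real_
    data.frame(deltaAsigma = v, S_final = unname(S_final),
               t_converge = tc, elevated = elevated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  base_t <- out$t_converge[1]
  if (is.na(base_t)) stop("baseline deltaAsigma value did not converge",
                          call. = FALSE)
  out$delay <- out$t_converge - base_t
  out$fate <- ifelse(!out$elevated | is.na(out$t_converge), "STOP",
                     ifelse(out$t_converge > 2 * base_t, "SLOW", "GO"))
  out[, c("deltaAsigma", "fate", "S_final", "t_converge", "delay")]
}

#' STAT knockdown experiment
#'
#' Runs the three-variable model to its (stationary-fate) steady state,
#' then knocks STAT down by setting the STAT translation rate `kS = 0`
#' and continues from that state. With production gone, STAT decays to
#' zero and APT relaxes to a lower equilibrium; experimentally APT
#' drops by about half, which the model reproduces.
#'
#' @param p Parameter set.
#' @param U UPD level (default 1, in the stationary regime).
#' @param initial `(S, A, B)` initial condition (default
#'   `c(12, 56, 1.5)`).
#' @param t_end Horizon for each of the two runs (default 2000 min).
#' @return List with `A_before`, `A_after`, `ratio`
#'   (`A_after / A_before`), `S_after`, and the two trajectories.
#' @export
stat_knockdown_experiment <- function(p = default_parameters(), U = 1,
                                      initial = c(12, 56, 1.5),
                                      t_end = 2000) {
  tr1 <- integrate_model("reduced3", initial, U, p, t_end)
  before <- tr1$states[nrow(tr1$states), ]
  if (max(abs(three_var_rhs(pmax(before, 0), U, p))) > 1e-4) {
    stop("system did not reach steady state within t_end", call. = FALSE)
  }
  p0 <- set_parameters(p, kS = 0)
  tr2 <- integrate_model("reduced3", pmax(before, 0), U, p0, t_end)
  after <- tr2$states[nrow(tr2$states), ]
  list(A_before = unname(before[["A"]]), A_after = unname(after[["A"]]),
       ratio = unname(after[["A"]] / before[["A"]]),
       S_after = unname(after[["S"]]),
       trajectory_before = tr1, trajectory_after = tr2)
}

#' APT initial-condition sweep
#'
#' Integrates the three-variable model from a range of initial APT
#' levels at fixed initial STAT and SLBO, reporting the final STAT
#' level per run. In the bistable regime, high initial APT pushes the
#' cell below the separatrix, so final STAT is non-increasing in the
#' initial APT level and high-APT starts land on the low-STAT branch.
#'
#' @param p Parameter set.
#' @param U UPD level (default 0.1, inside the bistable window).
#' @param A0_values Initial APT levels to sweep.
#' @param S0,B0 Initial STAT and SLBO (defaults 12 and 1.5).
#' @param t_end Horizon (default 2000 min).
#' @return data.frame with columns `A0`, `S_final`, `A_final`,
#'   `B_final`.
#' @export
apt_sweep_experiment <- function(p = default_parameters(), U = 0.1,
                                 A0_values = seq(0, 100, by = 10),
                                 S0 = 12, B0 = 1.5, t_end = 2000) {
  rows <- lapply(A0_values, function(a0) {
    tr <- integrate_model("reduced3", c(S0, a0, B0), U, p, t_end)
    fin <- tr$states[nrow(tr$states), ]
    data.frame(A0 = a0, S_final = fin[["S"]], A_final = fin[["A"]],
               B_final = fin[["B"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
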