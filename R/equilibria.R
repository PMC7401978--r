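# Steady states of the three-variable model: multistart Newton root
# finding with eigenvalue stability classification, pseudo-arclength
# continuation in UPD with fold (limit-point) detection, and the
# bistable UPD interval.

# Damped Newton iteration for the 3-variable steady state at fixed U.
# Returns the root or NULL on failure.
.newton3 <- function(x0, U, p, tol = 1e-11, maxit = 60,
                     fn = .rhs3_factory(p)) {
  x <- as.numeric(x0)
  for (i in seq_len(maxit)) {
    f <- fn(x, U)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) < tol) return(x)
    J <- .jac3_fn(x, U, fn)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # backtracking keeps iterates finite and the residual decreasing
    lam <- 1
    repeat {
      xn <- x + lam * step
      f_new <- tryCatch(fn(xn, U), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f)) || lam < 1e-3)) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- xn
  }
  f <- fn(x, U)
  if (max(abs(f)) < 1e-9) x else NULL
}

# finite-difference helpers on a factory closure
.jac3_fn <- function(x, U, fn) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- max(1e-6 * abs(x[j]), 1e-9)
    up <- x; up[j] <- x[j] + h
    dn <- x; dn[j] <- x[j] - h
    J[, j] <- (fn(up, U) - fn(dn, U)) / (2 * h)
  }
  J
}

.dFdU_fn <- function(x, U, fn) {
  h <- max(1e-6 * abs(U), 1e-9)
  Ud <- max(U - h, 0)
  (fn(x, U + h) - fn(x, Ud)) / (U + h - Ud)
}

# wrap a converged root as a classified steady state
.make_steady_state <- function(x, U, p, fn = .rhs3_factory(p)) {
  x <- as.numeric(x)
  names(x) <- c("S", "A", "B")
  f <- fn(x, U)
  ev <- eigen(.jac3_fn(x, U, fn), only.values = TRUE)$values
  structure(
    list(state = x, U = U,
         stability = if (all(Re(ev) < 0)) "stable" else "unstable",
         eigenvalues = ev, residual = sqrt(sum(f^2))),
    class = "jak_steady_state")
}

#' @export
print.jak_steady_state <- function(x, ...) {
  cat(sprintf("%s steady state at U = %g nM: S = %.4g, A = %.4g, B = %.4g\n",
              x$stability, x$U, x$state[["S"]], x$state[["A"]],
              x$state[["B"]]))
  invisible(x)
}

#' Find all steady states of the three-variable model at a given UPD
#'
#' Runs damped Newton iterations from a log-spaced multistart lattice
#' (plus any user-supplied seeds, e.g. the solutions at a neighbouring
#' UPD value), deduplicates the converged roots, and classifies each by
#' the eigenvalues of the model Jacobian. For this dissipative system
#' there are one or three steady states; in the bistable window the
#' three are two stable nodes (stationary, high APT; motile, low APT)
#' and a saddle between them.
#'
#' @param U UPD level (nM).
#' @param p Parameter set.
#' @param n_grid Lattice points per axis (default 8, i.e. 512 starts).
#' @param S_range,A_range,B_range Lattice extents (nM), log-spaced.
#' @param seeds Optional list/matrix of additional starting points.
#' @param dedup_tol Relative distance below which two roots are
#'   considered identical (default `1e-4`).
#' @return List of `"jak_steady_state"` objects, sorted by APT
#'   descending.
#' @export
#' @examples
#' ss <- find_steady_states(4, default_parameters())
#' length(ss)  # 3 in the bistable window
find_steady_states <- function(U, p, n_grid = 8,
                               S_range = c(1e-3, 500),
                               A_range = c(1e-3, 200),
                               B_range = c(1e-3, 200),
                               seeds = NULL, dedup_tol = 1e-4) {
  gr <- function(r, n) exp(seq(log(r[1]), log(r[2]), length.out = n))
  lat <- as.matrix(expand.grid(S = gr(S_range, n_grid),
                               A = gr(A_range, n_grid),
                               B = gr(B_range, n_grid)))
  if (!is.null(seeds)) {
    seeds <- if (is.matrix(seeds)) seeds else do.call(rbind, seeds)
    lat <- rbind(as.matrix(seeds), lat)
  }
  fn <- .rhs3_factory(p)
  roots <- list()
  for (i in seq_len(nrow(lat))) {
    x <- .newton3(lat[i, ], U, p, fn = fn)
    if (is.null(x) || any(x < -1e-8)) next
    x <- pmax(x, 0)
    dup <- FALSE
    for (r in roots) {
      if (sqrt(sum((x - r)^2)) / max(sqrt(sum(r^2)), 1) < dedup_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (length(roots) == 0) {
    stop("no steady state found at U = ", U,
         " (unexpected for this dissipative system)", call. = FALSE)
  }
  ss <- lapply(roots, .make_steady_state, U = U, p = p, fn = fn)
  ord <- order(vapply(ss, function(s) s$state[["A"]], numeric(1)),
               decreasing = TRUE)
  ss[ord]
}

# tangent to the solution curve in scaled (S, A, B, U) space: unit null
# vector of the 3x4 bordered Jacobian, oriented along `prev` if given
.branch_tangent <- function(x, U, p, scales, prev = NULL,
                            fn = .rhs3_factory(p)) {
  Aug <- cbind(.jac3_fn(x, U, fn), .dFdU_fn(x, U, fn))
  Aug <- sweep(Aug, 2, scales, "*")       # d/dz with z = y/scales
  t_s <- svd(Aug, nu = 0, nv = 4)$v[, 4]
  t_s <- t_s / sqrt(sum(t_s^2))
  if (!is.null(prev) && sum(t_s * prev) < 0) t_s <- -t_s
  t_s
}

# one predictor-corrector step of pseudo-arclength continuation;
# returns list(y, tangent) or NULL on corrector failure
.pac_step <- function(y, t_s, ds, p, scales, tol = 1e-11, maxit = 25,
                      fn = .rhs3_factory(p)) {
  y_pred <- y + ds * t_s * scales
  yk <- y_pred
  for (i in seq_len(maxit)) {
    f <- fn(yk[1:3], max(yk[4], 0))
    g <- sum(t_s * (yk - y_pred) / scales)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(c(f, g))) < tol) break
    Jx <- .jac3_fn(yk[1:3], max(yk[4], 0), fn)
    Fu <- .dFdU_fn(yk[1:3], max(yk[4], 0), fn)
    M <- rbind(cbind(Jx, Fu), t_s / scales)
    step <- tryCatch(solve(M, -c(f, g)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    yk <- yk + step
    if (i == maxit) return(NULL)
  }
  f <- fn(yk[1:3], max(yk[4], 0))
  if (max(abs(f)) > 1e-9) return(NULL)
  tn <- .branch_tangent(yk[1:3], max(yk[4], 0), p, scales, prev = t_s,
                        fn = fn)
  list(y = yk, tangent = tn)
}

#' Continue a steady-state branch in UPD
#'
#' Pseudo-arclength continuation of a steady-state branch of the
#' three-variable model, treating UPD as the bifurcation parameter.
#' The corrector is a bordered Newton iteration; the step length
#' adapts (halving on failure, growing on easy convergence) between
#' `ds0` and `max_ds` in scaled arclength. Folds (limit points) are
#' detected where the U-component of the branch tangent changes sign
#' and are refined by arclength bisection until the bracketing UPD
#' values differ by less than `fold_tol`.
#'
#' @param p Parameter set.
#' @param U_range Numeric length-2: UPD window to cover; continuation
#'   starts at `U_range[1]` and stops when U leaves the window (after
#'   possibly turning at folds) or `max_steps` is reached.
#' @param seed A `"jak_steady_state"` at (or near) `U_range[1]`, e.g.
#'   from [find_steady_states()].
#' @param ds0 Initial scaled arclength step (default 0.05).
#' @param max_ds Maximum step (default 0.5).
#' @param fold_tol UPD resolution of fold refinement (default `1e-3`).
#' @param max_steps Maximum accepted continuation points.
#' @param scales Positive scaling of (S, A, B, U) used to define
#'   arclength (default `c(10, 10, 10, 1)`).
#' @return Object of class `"jak_branch"`: list with `states` (list of
#'   `"jak_steady_state"` along the path), `folds` (UPD values of
#'   refined limit points), `fold_states`, and `truncated` (`TRUE` if
#'   the corrector gave up before leaving `U_range`).
#' @export
continue_branch <- function(p, U_range, seed, ds0 = 0.05, max_ds = 0.5,
                            fold_tol = 1e-3, max_steps = 5000,
                            scales = c(10, 10, 10, 1)) {
  U0 <- U_range[1]
  fn <- .rhs3_factory(p)
  x <- .newton3(seed$state, U0, p, fn = fn)
  if (is.null(x)) stop("seed does not converge to a steady state at U = ",
                       U0, call. = FALSE)
  y <- c(x, U0)
  t_s <- .branch_tangent(x, U0, p, scales, fn = fn)
  # orient the initial tangent into the U window
  if ((U_range[2] - U_range[1]) * t_s[4] < 0) t_s <- -t_s
  states <- list(.make_steady_state(x, U0, p, fn = fn))
  folds <- numeric(0)
  fold_states <- list()
  ds <- ds0
  truncated <- FALSE
  U_lo <- min(U_range) - fold_tol
  U_hi <- max(U_range) + fold_tol
  for (step in seq_len(max_steps)) {
    res <- .pac_step(y, t_s, ds, p, scales, fn = fn)
    if (is.null(res)) {
      ds <- ds / 2
      if (ds < 1e-6) { truncated <- TRUE; break }
      next
    }
    if (sign(res$tangent[4]) != sign(t_s[4]) && t_s[4] != 0) {
      # fold between y and res$y: bisect in arclength
      ya <- y; ta <- t_s; yb <- res$y
      ds_b <- ds
      while (abs(ya[4] - yb[4]) > fold_tol && ds_b > 1e-8) {
        ds_b <- ds_b / 2
        mid <- .pac_step(ya, ta, ds_b, p, scales, fn = fn)
        if (is.null(mid)) break
        if (sign(mid$tangent[4]) == sign(ta[4])) {
          ya <- mid$y; ta <- mid$tangent
        } else {
          yb <- mid$y
        }
      }
      U_fold <- (ya[4] + yb[4]) / 2
      folds <- c(folds, U_fold)
      fold_states <- c(fold_states,
                       list(.make_steady_state(ya[1:3], max(ya[4], 0), p,
                                               fn = fn)))
    }
    y <- res$y
    t_s <- res$tangent
    states[[length(states) + 1]] <- .make_steady_state(y[1:3],
                                                       max(y[4], 0), p,
                                                       fn = fn)
    ds <- min(ds * 1.3, max_ds)
    if (y[4] < U_lo || y[4] > U_hi) break
    if (step == max_steps) truncated <- TRUE
  }
  structure(list(states = states, folds = folds,
                 fold_states = fold_states, truncated = truncated),
            class = "jak_branch")
}

#' @export
print.jak_branch <- function(x, ...) {
  U <- vapply(x$states, function(s) s$U, numeric(1))
  cat("Continuation branch:", length(x$states), "points, U in [",
      round(min(U), 4), ",", round(max(U), 4), "] nM\n")
  if (length(x$folds) > 0) {
    cat("folds at U =", paste(round(x$folds, 4), collapse = ", "), "nM\n")
  }
  if (x$truncated) cat("warning: branch truncated before leaving window\n")
  invisible(x)
}

#' @export
plot.jak_branch <- function(x, component = "A", ...) {
  U <- vapply(x$states, function(s) s$U, numeric(1))
  v <- vapply(x$states, function(s) s$state[[component]], numeric(1))
  stab <- vapply(x$states, function(s) s$stability, character(1))
  graphics::plot(U, v, type = "n", xlab = "UPD (nM)",
                 ylab = paste(component, "(nM)"), ...)
  graphics::lines(U, v, col = "grey70")
  graphics::points(U, v, pch = ifelse(stab == "stable", 16, 1), cex = 0.5)
  invisible(x)
}

# count stable steady states at U with a light multistart
.count_stable <- function(U, p, n_grid = 5, seeds = NULL,
                          min_sep = 1e-2) {
  ss <- tryCatch(
    find_steady_states(U, p, n_grid = n_grid, seeds = seeds),
    error = function(e) list())
  stable <- Filter(function(s) s$stability == "stable", ss)
  if (length(stable) < 2) return(list(n = length(stable), states = ss))
  # require genuine separation of the stable pair
  st <- do.call(rbind, lapply(stable, function(s) s$state))
  d <- stats::dist(st) / max(sqrt(rowSums(st^2)), 1)
  if (max(d) < min_sep) return(list(n = 1L, states = ss))
  list(n = length(stable), states = ss)
}

#' Bistable UPD interval
#'
#' Finds the interval of UPD over which the three-variable model has
#' two coexisting stable steady states. A coarse geometric UPD grid is
#' scanned with multistart root counting (each level seeded with the
#' roots found at the previous level), then the interval edges are
#' refined by bisection to `tol`.
#'
#' @param p Parameter set.
#' @param U_search Search window, default `c(0, 50)` nM.
#' @param tol Edge resolution (default `1e-3` nM).
#' @param n_coarse Number of coarse grid points (default 14).
#' @param n_grid Multistart lattice size per axis (default 5).
#' @return Numeric `c(U_lo, U_hi)`, or `NULL` if the model is
#'   monostable throughout the window.
#' @export
bistable_interval <- function(p, U_search = c(0, 50), tol = 1e-3,
                              n_coarse = 14, n_grid = 5) {
  lo <- max(U_search[1], 0)
  hi <- U_search[2]
  # geometric grid biased toward small U where the lower fold sits
  Ug <- unique(c(lo, exp(seq(log(max(lo, 1e-3)), log(hi),
                             length.out = n_coarse)), hi))
  Ug <- sort(Ug[Ug >= lo & Ug <= hi])
  seeds <- NULL
  bist <- logical(length(Ug))
  for (i in seq_along(Ug)) {
    cs <- .count_stable(Ug[i], p, n_grid = n_grid, seeds = seeds)
    bist[i] <- cs$n >= 2
    seeds <- lapply(cs$states, function(s) s$state)
  }
  if (!any(bist)) return(NULL)
  idx <- which(bist)
  # refine the lower edge
  refine <- function(U_in, U_out) {
    for (k in 1:60) {
      if (abs(U_in - U_out) < tol) break
      Um <- (U_in + U_out) / 2
      if (.count_stable(Um, p, n_grid = n_grid)$n >= 2) U_in <- Um
      else U_out <- Um
    }
    (U_in + U_out) / 2
  }
  U_lo <- if (idx[1] == 1) Ug[1] else refine(Ug[idx[1]], Ug[idx[1] - 1])
  U_hi <- if (idx[length(idx)] == length(Ug)) Ug[length(Ug)] else
    refine(Ug[idx[length(idx)]], Ug[idx[length(idx)] + 1])
  c(U_lo = U_lo, U_hi = U_hi)
}

#' Long-format table of continuation branches
#'
#' Flattens one or more branches into rows `(branch, U, S, A, B,
#' stability)` suitable for re-plotting the bifurcation diagram of APT
#' or STAT against UPD. Stable points are labelled `stationary` or
#' `motile` by their APT level relative to the saddle (unstable)
#' segment at the nearest UPD; unstable points are labelled `middle`.
#'
#' @param branches A `"jak_branch"` or list of them.
#' @return data.frame with columns `branch`, `U`, `S`, `A`, `B`,
#'   `stability`.
#' @export
bifurcation_table <- function(branches) {
  if (inherits(branches, "jak_branch")) branches <- list(branches)
  rows <- lapply(seq_along(branches), function(bi) {
    br <- branches[[bi]]
    U <- vapply(br$states, function(s) s$U, numeric(1))
    mat <- do.call(rbind, lapply(br$states, function(s) s$state))
    stab <- vapply(br$states, function(s) s$stability, character(1))
    label <- rep("middle", length(U))
    if (any(stab == "stable")) {
      mid_idx <- which(stab == "unstable")
      for (i in which(stab == "stable")) {
        if (length(mid_idx) == 0) {
          label[i] <- if (mat[i, "A"] > stats::median(mat[, "A"]))
            "stationary" else "motile"
        } else {
          j <- mid_idx[which.min(abs(U[mid_idx] - U[i]))]
          label[i] <- if (mat[i, "A"] > mat[j, "A"]) "stationary"
                      else "motile"
        }
      }
    }
    data.frame(branch = label, U = U, S = mat[, "S"], A = mat[, "A"],
               B = mat[, "B"], stability = stab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
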