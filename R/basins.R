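# Basin-of-attraction mapping and separatrix (stable-manifold) surface
# fitting in (S, A, B) space. The saddle's two-dimensional stable
# manifold divides the stationary and motile basins; a grid of initial
# conditions is classified by the steady state reached within a
# deadline, and an implicit surface is fitted to the boundary points.

#' Classify a 3-d grid of initial conditions by cell fate
#'
#' Integrates the three-variable model from every node of a regular
#' grid of initial conditions and labels each node `motile`,
#' `stationary` or `unresolved` (not within tolerance of either stable
#' state by the deadline; such points lie near the separatrix).
#'
#' @param U UPD level (nM); must be in the bistable window for a
#'   two-basin picture.
#' @param p Parameter set.
#' @param S_range,A_range,B_range Axis extents (nM).
#' @param n Nodes per axis (default 21; scalar or length-3).
#' @param deadline Classification deadline (min, default 500).
#' @param rel_tol Relative tolerance ball for [classify_fate()].
#' @param rtol,atol Integrator tolerances; the defaults are looser than
#'   [integrate_model()]'s because thousands of short runs are needed
#'   and fate labels are insensitive at this resolution.
#' @return Object of class `"jak_basin_grid"`: data.frame `points`
#'   with columns `S0`, `A0`, `B0`, `fate`, `t_converge`; plus axis
#'   metadata, `U`, `deadline`, the equilibria used, and the fate
#'   fractions.
#' @export
classify_grid <- function(U, p = default_parameters(),
                          S_range = c(0, 250), A_range = c(0, 120),
                          B_range = c(0, 60), n = 21, deadline = 500,
                          rel_tol = 0.05, rtol = 1e-6, atol = 1e-8) {
  n <- rep(as.integer(n), length.out = 3)
  eq <- find_steady_states(U, p)
  stable <- Filter(function(s) s$stability == "stable", eq)
  if (length(stable) < 2) {
    warning("monostable at U = ", U, "; all resolved points share one fate")
  }
  axes <- list(S = seq(S_range[1], S_range[2], length.out = n[1]),
               A = seq(A_range[1], A_range[2], length.out = n[2]),
               B = seq(B_range[1], B_range[2], length.out = n[3]))
  grid <- expand.grid(S0 = axes$S, A0 = axes$A, B0 = axes$B,
                      KEEP.OUT.ATTRS = FALSE)
  rhs3 <- .rhs3_factory(p)
  func <- function(t, y, parms) list(rhs3(pmax(y, 0), U))
  times <- seq(0, deadline, length.out = 51)
  fate <- character(nrow(grid))
  tconv <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sol <- tryCatch(
      deSolve::ode(y = as.numeric(grid[i, 1:3]), times = times,
                   func = func, parms = NULL, method = "lsoda",
                   rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < length(times)) {
      fate[i] <- "unresolved"; next
    }
    st <- sol[, -1, drop = FALSE]
    colnames(st) <- c("S", "A", "B")
    fl <- classify_fate(
      structure(list(times = sol[, 1], states = st, model = "reduced3",
                     U = U), class = "jak_trajectory"),
      eq, rel_tol = rel_tol, deadline = deadline)
    fate[i] <- fl$tag
    tconv[i] <- fl$t_converge
  }
  pts <- data.frame(grid, fate = fate, t_converge = tconv)
  frac <- c(motile = mean(fate == "motile"),
            stationary = mean(fate == "stationary"),
            unresolved = mean(fate == "unresolved"))
  structure(list(points = pts, axes = axes, U = U, deadline = deadline,
                 equilibria = eq, fractions = frac),
            class = "jak_basin_grid")
}

#' @export
print.jak_basin_grid <- function(x, ...) {
  cat("Basin grid at U =", x$U, "nM:", nrow(x$points), "initial",
      "conditions, deadline", x$deadline, "min\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Extract points lying near the separatrix
#'
#' Returns the unresolved grid points (initial conditions that did not
#' commit to either fate by the deadline) plus the midpoints of every
#' grid edge whose two endpoints converged to opposite fates. On a
#' coarse grid the unresolved set alone can be tiny, so the edge
#' midpoints supply a well-distributed sample of the basin boundary;
#' set `edge_midpoints = FALSE` for the strict unresolved-only set.
#'
#' @param grid A `"jak_basin_grid"`.
#' @param edge_midpoints Include opposite-fate edge midpoints
#'   (default `TRUE`).
#' @return Matrix with columns `S`, `A`, `B` (possibly 0 rows, with a
#'   warning, when the window is monostable).
#' @export
near_manifold_points <- function(grid, edge_midpoints = TRUE) {
  pts <- grid$points
  nn <- vapply(grid$axes, length, integer(1))
  out <- as.matrix(pts[pts$fate == "unresolved", c("S0", "A0", "B0")])
  if (edge_midpoints) {
    fate3 <- array(pts$fate, dim = nn)
    coord <- array(seq_len(nrow(pts)), dim = nn)
    mids <- list()
    for (axis in 1:3) {
      idx_lo <- slice.index(fate3, axis) < nn[axis]
      lo <- which(idx_lo, arr.ind = TRUE)
      hi <- lo; hi[, axis] <- hi[, axis] + 1
      f_lo <- fate3[lo]; f_hi <- fate3[hi]
      opp <- (f_lo == "motile" & f_hi == "stationary") |
             (f_lo == "stationary" & f_hi == "motile")
      if (!any(opp)) next
      p_lo <- pts[coord[lo[opp, , drop = FALSE]], c("S0", "A0", "B0")]
      p_hi <- pts[coord[hi[opp, , drop = FALSE]], c("S0", "A0", "B0")]
      mids[[axis]] <- as.matrix((p_lo + p_hi) / 2)
    }
    out <- rbind(out, do.call(rbind, mids))
  }
  colnames(out) <- c("S", "A", "B")
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no basin boundary found (monostable?)")
  out
}

#' Fit an implicit surface to separatrix points
#'
#' Total-least-squares fit of an implicit surface `g(S, A, B) = 0` to
#' near-manifold points: a plane via the smallest principal direction
#' of the centered cloud, or a quadratic via the smallest singular
#' direction of the degree-2 monomial matrix (unit-norm coefficient
#' constraint). If a source grid is supplied, the fit also reports how
#' well the sign of `g` separates the grid's resolved motile and
#' stationary points ("sided accuracy").
#'
#' @param points Matrix with columns `S`, `A`, `B` (rows are points on
#'   or near the separatrix), e.g. from [near_manifold_points()].
#' @param form `"plane"` or `"quadratic"`.
#' @param grid Optional `"jak_basin_grid"` for sided-accuracy scoring.
#' @return Object of class `"jak_manifold_fit"`: `form`,
#'   `coefficients` (named), `rms_residual` (plane: nM distance;
#'   quadratic: algebraic), `accuracy` (fraction of resolved grid
#'   points correctly sided, or `NA`), `n_points`.
#' @export
fit_manifold <- function(points, form = c("plane", "quadratic"),
                         grid = NULL) {
  form <- match.arg(form)
  pts <- as.matrix(points)
  if (form == "plane" && nrow(pts) < 10) {
    stop("need >= 10 points for a plane fit", call. = FALSE)
  }
  if (form == "quadratic" && nrow(pts) < 30) {
    stop("need >= 30 points for a quadratic fit", call. = FALSE)
  }
  if (form == "plane") {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
      stop("degenerate point cloud (rank < 2)", call. = FALSE)
    }
    nrm <- sv$v[, 3]
    coef <- c(S = nrm[1], A = nrm[2], B = nrm[3],
              intercept = -sum(nrm * ctr))
    gfun <- function(m) m %*% nrm + coef[["intercept"]]
    rms <- sqrt(mean(gfun(pts)^2))
  } else {
    mono <- function(m) cbind(1, m, m[, 1]^2, m[, 2]^2, m[, 3]^2,
                              m[, 1] * m[, 2], m[, 1] * m[, 3],
                              m[, 2] * m[, 3])
    # scale columns for a balanced TLS problem, then undo
    M <- mono(pts)
    cs <- apply(abs(M), 2, max); cs[cs == 0] <- 1
    sv <- svd(sweep(M, 2, cs, "/"))
    if (sv$d[ncol(M) - 1] < 1e-12 * max(sv$d[1], 1)) {
      stop("degenerate point cloud for quadratic fit", call. = FALSE)
    }
    v <- sv$v[, ncol(M)] / cs
    v <- v / sqrt(sum(v^2))
    coef <- stats::setNames(v, c("intercept", "S", "A", "B",
                                 "S2", "A2", "B2", "SA", "SB", "AB"))
    gfun <- function(m) drop(mono(m) %*% v)
    rms <- sqrt(mean(gfun(pts)^2))
  }
  acc <- NA_real_
  if (!is.null(grid)) {
    gp <- grid$points
    res <- gp$fate %in% c("motile", "stationary")
    g <- gfun(as.matrix(gp[res, c("S0", "A0", "B0")]))
    lab <- gp$fate[res]
    # orient so that the motile side is positive
    pos_motile <- mean(g[lab == "motile"] > 0)
    neg_motile <- mean(g[lab == "motile"] < 0)
    side <- if (pos_motile >= neg_motile) 1 else -1
    acc <- mean((side * g > 0) == (lab == "motile"))
  }
  structure(list(form = form, coefficients = coef, rms_residual = rms,
                 accuracy = acc, n_points = nrow(pts),
                 g = gfun),
            class = "jak_manifold_fit")
}

#' @export
print.jak_manifold_fit <- function(x, ...) {
  cat("Separatrix", x$form, "fit from", x$n_points, "points\n")
  cat("RMS residual:", signif(x$rms_residual, 4))
  if (!is.na(x$accuracy)) cat("; sided accuracy:",
                              round(100 * x$accuracy, 1), "%")
  cat("\ncoefficients:\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Evaluate the signed side of a point relative to a fitted surface
#'
#' @param fit A `"jak_manifold_fit"`.
#' @param point Numeric `(S, A, B)` or matrix with 3 columns.
#' @return Signed value(s) of the implicit function `g`.
#' @export
manifold_side <- function(fit, point) {
  m <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  drop(fit$g(m))
}

#' Separatrix shift report across conditions
#'
#' Classifies a basin grid and fits a separatrix surface for each
#' condition in a list (either UPD levels or `deltaAsigma` overrides),
#' reporting the fate fractions, the fit, and the signed side of a
#' probe initial condition. Documents how the separatrix sweeps through
#' phase space as UPD rises (motile basin expands) or as the
#' miRNA-mediated stat degradation strengthens (the surface crosses
#' the probe, flipping its fate).
#'
#' @param p Parameter set.
#' @param U_values UPD levels to compare (used with baseline `p`).
#' @param deltaAsigma_values Alternatively, `deltaAsigma` overrides at
#'   fixed `U_probe`.
#' @param U_probe UPD level used with `deltaAsigma_values` (default 4).
#' @param probe Probe initial condition (default `c(12, 56, 1.5)`).
#' @param form Surface form (default `"plane"`).
#' @param ... Grid options passed to [classify_grid()] (e.g. `n`,
#'   axis ranges).
#' @return data.frame with one row per condition: the condition value,
#'   fate fractions, fit accuracy, probe side sign and probe fate; the
#'   fits themselves are attached as attribute `"fits"`.
#' @export
manifold_shift_report <- function(p = default_parameters(),
                                  U_values = NULL,
                                  deltaAsigma_values = NULL,
                                  U_probe = 4, probe = c(12, 56, 1.5),
                                  form = "plane", ...) {
  if (is.null(U_values) == is.null(deltaAsigma_values)) {
    stop("give exactly one of U_values or deltaAsigma_values",
         call. = FALSE)
  }
  conds <- if (!is.null(U_values)) U_values else deltaAsigma_values
  rows <- list(); fits <- list()
  for (i in seq_along(conds)) {
    if (!is.null(U_values)) {
      Ui <- conds[i]; pi <- p
    } else {
      Ui <- U_probe; pi <- set_parameters(p, deltaAsigma = conds[i])
    }
    bg <- tryCatch(classify_grid(Ui, pi, ...), warning = function(w) {
      warning("condition ", conds[i], ": ", conditionMessage(w))
      suppressWarnings(classify_grid(Ui, pi, ...))
    })
    npts <- near_manifold_points(bg)
    fit <- fit_manifold(npts, form = form, grid = bg)
    side <- manifold_side(fit, probe)
    # fate of the probe itself under this condition
    tr <- integrate_model("reduced3", probe, Ui, pi,
                          t_end = bg$deadline, n_out = 201)
    pf <- classify_fate(tr, bg$equilibria, deadline = bg$deadline)
    rows[[i]] <- data.frame(
      condition = conds[i], U = Ui,
      motile_fraction = bg$fractions[["motile"]],
      stationary_fraction = bg$fractions[["stationary"]],
      unresolved_fraction = bg$fractions[["unresolved"]],
      fit_accuracy = fit$accuracy,
      probe_side = sign(side), probe_fate = pf$tag)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
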