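# Per-parameter robustness of bistability: how far each of the 33 rate
# constants can be moved, one at a time, before the switch stops being
# bistable.

#' Test whether a parameter set supports bistability
#'
#' Two operational criteria are provided, because "is bistable" is
#' underdetermined for a model with a UPD-dependent phase diagram:
#' `"interval"` (default) asks whether *some* UPD level in `U_search`
#' yields two coexisting stable steady states; `"fixedU"` asks whether
#' the reference level `U_fixed` does. Either way the two stable states
#' must be separated by more than `min_sep` relative distance.
#'
#' @param p Parameter set.
#' @param criterion `"interval"` or `"fixedU"`.
#' @param U_search Window for the interval criterion (default
#'   `c(0, 50)` nM).
#' @param U_fixed Reference UPD for the fixed-U criterion (default 4).
#' @param U_values UPD levels probed under the interval criterion
#'   (defaults to a geometric ladder over `U_search`, probed in an
#'   order that exits early for bistable baselines).
#' @param n_grid Multistart lattice size per axis (default 5).
#' @param min_sep Minimum relative separation of the stable pair.
#' @return Logical scalar.
#' @export
is_bistable <- function(p, criterion = c("interval", "fixedU"),
                        U_search = c(0, 50), U_fixed = 4,
                        U_values = NULL, n_grid = 5, min_sep = 1e-2) {
  criterion <- match.arg(criterion)
  if (criterion == "fixedU") {
    return(.count_stable(U_fixed, p, n_grid = n_grid,
                         min_sep = min_sep)$n >= 2)
  }
  if (is.null(U_values)) {
    U_values <- c(4, 0.133, 1, 0.0133, 7, 0.5, 11, 0.05, 2, 20, 35)
  }
  U_values <- U_values[U_values >= U_search[1] & U_values <= U_search[2]]
  for (U in U_values) {
    if (.count_stable(U, p, n_grid = n_grid, min_sep = min_sep)$n >= 2) {
      return(TRUE)
    }
  }
  FALSE
}

#' Bistable range of a single parameter
#'
#' Holds all other parameters at baseline and finds the interval of
#' one parameter over which the model remains bistable, by outward
#' geometric expansion from the baseline followed by bisection of each
#' boundary. The search is capped below at `lower_cap` (default 0) and
#' above at `upper_cap` (default 1100); a boundary at a cap is
#' reported as the cap itself. Assumes the bistable set is an interval
#' along the parameter axis.
#'
#' @param name One of the 33 parameter names.
#' @param p Baseline parameter set (must itself be bistable under the
#'   chosen criterion).
#' @param criterion,U_search,U_fixed,U_values,n_grid Passed to
#'   [is_bistable()].
#' @param lower_cap,upper_cap Search caps.
#' @param tol_rel Relative resolution of each boundary (default 1e-2).
#' @return One-row data.frame: `parameter`, `baseline`,
#'   `bistable_start`, `bistable_end`, `log10_pct_neg`,
#'   `log10_pct_pos`, `criterion`.
#' @export
param_bistable_range <- function(name, p = default_parameters(),
                                 criterion = "interval",
                                 U_search = c(0, 50), U_fixed = 4,
                                 U_values = NULL, n_grid = 5,
                                 lower_cap = 0, upper_cap = 1100,
                                 tol_rel = 1e-2) {
  if (!name %in% parameter_names()) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  base <- p[[name]]
  test <- function(v) {
    pv <- tryCatch(set_parameters(p, .overrides = stats::setNames(v, name)),
                   error = function(e) NULL)
    if (is.null(pv)) return(FALSE)
    tryCatch(is_bistable(pv, criterion = criterion, U_search = U_search,
                         U_fixed = U_fixed, U_values = U_values,
                         n_grid = n_grid),
             error = function(e) FALSE)
  }
  if (!test(base)) {
    stop("baseline is not bistable under criterion '", criterion,
         "'; review the criterion settings", call. = FALSE)
  }
  tol <- max(tol_rel * base, 1e-9)
  bound <- function(direction) {
    inside <- base
    step <- if (base > 0) base else 1
    cap <- if (direction > 0) upper_cap else lower_cap
    repeat {
      outside <- inside + direction * step
      if (direction > 0) outside <- min(outside, cap)
      else outside <- max(outside, cap)
      if (!test(outside)) break
      inside <- outside
      if (outside == cap) return(cap)   # bistable all the way to the cap
      step <- step * 2
    }
    while (abs(inside - outside) > tol) {
      mid <- (inside + outside) / 2
      if (test(mid)) inside <- mid else outside <- mid
    }
    (inside + outside) / 2
  }
  lo <- bound(-1)
  hi <- bound(+1)
  pct <- function(b) abs(b - base) / base * 100
  data.frame(parameter = name, baseline = base,
             bistable_start = lo, bistable_end = hi,
             log10_pct_neg = log10(max(pct(lo), .Machine$double.xmin)),
             log10_pct_pos = log10(max(pct(hi), .Machine$double.xmin)),
             criterion = criterion, stringsAsFactors = FALSE)
}

#' Scan the bistable range of every parameter
#'
#' One-at-a-time robustness scan: for each requested parameter,
#' computes the bistable interval around baseline and the log10
#' percent change each bound represents. Failures for individual
#' parameters are recorded (`NA` row) and the scan continues. Results
#' can be cached per parameter in `cache_dir`, making long scans
#' resumable and re-runs reproducible.
#'
#' @param p Baseline parameter set.
#' @param params Parameter names to scan (default all 33).
#' @param criterion,U_search,U_fixed,U_values,n_grid,lower_cap,upper_cap,tol_rel
#'   Passed to [param_bistable_range()].
#' @param cache_dir Optional directory of per-parameter CSV cache
#'   files.
#' @return data.frame, one row per parameter, columns as in
#'   [param_bistable_range()].
#' @export
scan_bistable_ranges <- function(p = default_parameters(),
                                 params = parameter_names(),
                                 criterion = "interval",
                                 U_search = c(0, 50), U_fixed = 4,
                                 U_values = NULL, n_grid = 5,
                                 lower_cap = 0, upper_cap = 1100,
                                 tol_rel = 1e-2, cache_dir = NULL) {
  rows <- list()
  for (nm in params) {
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0("bistable_range_", criterion, "_",
                                  nm, ".csv"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[nm]] <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(
      param_bistable_range(nm, p, criterion = criterion,
                           U_search = U_search, U_fixed = U_fixed,
                           U_values = U_values, n_grid = n_grid,
                           lower_cap = lower_cap, upper_cap = upper_cap,
                           tol_rel = tol_rel),
      error = function(e) {
        warning("scan failed for ", nm, ": ", conditionMessage(e))
        data.frame(parameter = nm, baseline = p[[nm]],
                   bistable_start = NA_real_, bistable_end = NA_real_,
                   log10_pct_neg = NA_real_, log10_pct_pos = NA_real_,
                   criterion = criterion, stringsAsFactors = FALSE)
      })
    if (!is.null(cache_file)) {
      dir.create(dirname(cache_file), showWarnings = FALSE,
                 recursive = TRUE)
      res_out <- res
      for (j in seq_along(res_out)) {   # full precision: cache is exact
        if (is.numeric(res_out[[j]])) {
          res_out[[j]] <- formatC(res_out[[j]], digits = 17, format = "g")
        }
      }
      utils::write.csv(res_out, cache_file, row.names = FALSE,
                       quote = FALSE)
    }
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank parameters by bistability sensitivity
#'
#' The sensitivity of a parameter is the smaller of how far it can
#' move in either direction while preserving bistability; parameters
#' are ranked by the maximum tolerated percent change (ascending:
#' most sensitive first).
#'
#' @param scan A data.frame from [scan_bistable_ranges()].
#' @return The scan with an added `max_pct_change` column, sorted most
#'   sensitive first.
#' @export
sensitivity_ranking <- function(scan) {
  pct <- pmax(abs(scan$bistable_start - scan$baseline),
              abs(scan$bistable_end - scan$baseline)) /
    scan$baseline * 100
  out <- scan
  out$max_pct_change <- pct
  out[order(out$max_pct_change), ]
}
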