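# Scenario configuration, shipped figure-replication fixtures, and
# deterministic CSV/JSON writers.

.scenario_keys <- c("model", "U", "S0", "A0", "B0", "t_end", "deadline",
                    "rel_tol", "n_out")

#' Load a scenario configuration
#'
#' Reads a flat key/value YAML file describing a simulation scenario.
#' Recognized scenario keys: `model` (`reduced3`/`full15`/`reduced2`),
#' `U` (scalar or list), `S0`, `A0`, `B0`, `t_end`, `deadline`,
#' `rel_tol`, `n_out`. Every other key must be one of the 33 parameter
#' names and is applied as an override of the baseline parameter set.
#' Unknown keys raise an error naming the key; missing fields fall
#' back to defaults (reported with `verbose = TRUE`).
#'
#' @param path Path to a YAML scenario file.
#' @param verbose Report defaulted fields.
#' @return Object of class `"jak_scenario"`: list with `model`, `U`,
#'   `initial` `(S, A, B)`, `t_end`, `deadline`, `rel_tol`, `n_out`,
#'   `overrides` (named list) and `parameters` (resolved
#'   `"jak_params"`).
#' @export
load_scenario <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c(.scenario_keys, parameter_names()))
  if (length(bad) > 0) {
    stop("unknown scenario key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ov <- raw[intersect(names(raw), parameter_names())]
  num_keys <- setdiff(names(raw), "model")
  nonnum <- num_keys[!vapply(raw[num_keys], function(x)
    is.numeric(unlist(x)) && all(is.finite(unlist(x))), logical(1))]
  if (length(nonnum) > 0) {
    stop("non-numeric value for key(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(model = "reduced3", U = 4, S0 = 12, A0 = 56, B0 = 1.5,
                   t_end = 1000, deadline = 500, rel_tol = 0.05,
                   n_out = 201)
  defaulted <- setdiff(.scenario_keys, names(raw))
  if (verbose && length(defaulted) > 0) {
    message("scenario defaults used for: ",
            paste(defaulted, collapse = ", "))
  }
  get <- function(k) if (k %in% names(raw)) raw[[k]] else defaults[[k]]
  model <- as.character(get("model"))
  if (!model %in% c("reduced3", "full15", "reduced2")) {
    stop("model must be reduced3, full15 or reduced2", call. = FALSE)
  }
  structure(
    list(model = model, U = unlist(get("U")),
         initial = c(S = as.numeric(get("S0")), A = as.numeric(get("A0")),
                     B = as.numeric(get("B0"))),
         t_end = as.numeric(get("t_end")),
         deadline = as.numeric(get("deadline")),
         rel_tol = as.numeric(get("rel_tol")),
         n_out = as.integer(get("n_out")),
         overrides = ov,
         parameters = set_parameters(default_parameters(),
                                     .overrides = ov)),
    class = "jak_scenario")
}

#' @export
print.jak_scenario <- function(x, ...) {
  cat("Scenario:", x$model, "model, U =",
      paste(x$U, collapse = ", "), "nM, IC (S, A, B) = (",
      paste(x$initial, collapse = ", "), "), t_end =", x$t_end, "min\n")
  if (length(x$overrides) > 0) {
    cat("parameter overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = " = ",
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Shipped figure-replication scenarios
#'
#' The study conditions used throughout the analyses, as ready-to-run
#' scenario configs: the motile/stationary fate dichotomy
#' (`fig3_motile`, U = 4; `fig3_stationary`, U = 1, both from
#' IC (12, 56, 1.5)), the three miRNA levels (`fig8_go`
#' deltaAsigma = 0.05, `fig8_slow` 0.17382, `fig8_stop` 0.18, all at
#' U = 4), the STAT knockdown (`fig10_knockdown`, U = 1), the APT
#' initial-condition sweep (`fig10_apt_sweep`, U = 0.1) and the
#' separatrix comparison levels (`fig6_manifold`,
#' U in {0.0133, 0.133, 4}).
#'
#' @return Named list of `"jak_scenario"` objects.
#' @export
scenario_fixtures <- function() {
  dir <- system.file("extdata", "scenarios", package = "jakstatswitch")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  out <- lapply(files, load_scenario)
  names(out) <- sub("\\.yaml$", "", basename(files))
  out
}

#' Run a scenario
#'
#' Integrates the scenario's model from its initial condition (one run
#' per value of `U` when `U` is a vector).
#'
#' @param sc A `"jak_scenario"`.
#' @return A `"jak_trajectory"`, or a named list of them when the
#'   scenario carries several UPD levels.
#' @export
run_scenario <- function(sc) {
  run1 <- function(U) {
    init <- switch(sc$model,
      reduced3 = sc$initial,
      full15 = initial_full_state(sc$parameters, sc$initial[["S"]],
                                  sc$initial[["A"]], sc$initial[["B"]]),
      reduced2 = sc$initial[c("A", "B")])
    integrate_model(sc$model, init, U, sc$parameters, sc$t_end,
                    n_out = sc$n_out, overrides = sc$overrides)
  }
  if (length(sc$U) == 1) return(run1(sc$U))
  out <- lapply(sc$U, run1)
  names(out) <- paste0("U_", sc$U)
  out
}

.fmt <- function(x) formatC(x, digits = 12, format = "g")

#' Write a trajectory to CSV
#'
#' Deterministic schema: '#'-prefixed metadata header (model, U,
#' overrides, tolerances), then `t` plus one column per state
#' component, at 12 significant digits.
#'
#' @param traj A `"jak_trajectory"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# model: ", traj$model),
    paste0("# U: ", .fmt(traj$U)),
    paste0("# rtol: ", .fmt(traj$rtol), " atol: ", .fmt(traj$atol)),
    if (length(traj$overrides) > 0) {
      paste0("# overrides: ",
             paste(names(traj$overrides), unlist(traj$overrides),
                   sep = "=", collapse = ";"))
    }), con)
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  writeLines(paste(colnames(df), collapse = ","), con)
  utils::write.table(
    as.data.frame(lapply(df, .fmt)), con, sep = ",",
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path Input path.
#' @return A `"jak_trajectory"` (metadata restored from the header).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(ln) == 0) return(NULL)
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  st <- as.matrix(df[, -1, drop = FALSE])
  structure(
    list(times = df$t, states = st,
         model = meta("model") %||% "reduced3",
         U = as.numeric(meta("U") %||% NA),
         rtol = NA, atol = NA, overrides = NULL),
    class = "jak_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a long-format table to CSV with a provenance header
#'
#' Columns in fixed order, 12 significant digits for numeric fields,
#' '#'-prefixed header carrying the package version; two runs of the
#' same input produce byte-identical data sections.
#'
#' @param df data.frame (e.g. from [bifurcation_table()] or an
#'   experiment).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# jakstatswitch ",
                    as.character(utils::packageVersion("jakstatswitch"))),
             con)
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt(out[[j]])
  }
  writeLines(paste(colnames(out), collapse = ","), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a separatrix fit to JSON
#'
#' @param fit A `"jak_manifold_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifold_json <- function(fit, path) {
  jsonlite::write_json(
    list(form = fit$form,
         coefficients = as.list(fit$coefficients),
         rms_residual = fit$rms_residual,
         accuracy = fit$accuracy,
         n_points = fit$n_points),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
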