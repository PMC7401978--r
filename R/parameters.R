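# Parameterization of the JAK/STAT border-cell switch.
#
# All concentrations are in nM and time is in minutes. The 33 rate
# constants and levels below are the biophysically motivated baseline
# used throughout the package; overrides always act on copies so the
# baseline cannot be corrupted by downstream scans.

.param_names <- c(
  "kUJf", "kUJb", "kc1f", "kc1b", "kc1", "kS2star", "kS", "deltaS",
  "kmsigma", "deltamsigma", "msigma0", "deltaAsigma", "ksigmaf", "ksigmab",
  "JT", "kA", "kmalpha", "malpha0", "deltaA", "deltamalpha", "deltaAbeta",
  "kalphaf", "kalphab", "kB", "kmbeta", "mbeta0", "deltaB", "deltambeta",
  "deltaBalpha", "kbetaf", "kbetab", "kbetaRf", "kbetaRb"
)

# degradation rates that must be strictly positive for finite steady states
.strict_positive <- c("deltaS", "deltaA", "deltaB", "deltamalpha",
                      "deltambeta", "deltamsigma", "JT")

#' Baseline parameter set for the JAK/STAT border-cell model
#'
#' Returns the 33 named rate constants and levels of the model:
#' UPD--JAK binding (`kUJf`, `kUJb`), JAK--STAT complex kinetics (`kc1f`,
#' `kc1b`, `kc1`), STAT dimer turnover (`kS2star`), translation rates
#' (`kS`, `kA`, `kB`), transcription rates (`kmsigma`, `kmalpha`,
#' `kmbeta`), STAT-independent mRNA production (`msigma0`, `malpha0`,
#' `mbeta0`), protein and mRNA degradation rates (`deltaS`, `deltaA`,
#' `deltaB`, `deltamsigma`, `deltamalpha`, `deltambeta`), miRNA-mediated
#' mRNA degradation (`deltaAsigma`, `deltaAbeta`, `deltaBalpha`),
#' gene-state binding/dissociation rates (`ksigmaf`, `ksigmab`, `kalphaf`,
#' `kalphab`, `kbetaf`, `kbetab`, `kbetaRf`, `kbetaRb`) and the total JAK
#' pool `JT`.
#'
#' Concentrations are in nM and time in minutes. The values are used
#' exactly as they enter the model equations.
#'
#' @return A named numeric vector of class `"jak_params"` with 33 entries.
#' @export
#' @examples
#' p <- default_parameters()
#' p["JT"]
default_parameters <- function() {
  p <- c(
    kUJf        = 0.0133,
    kUJb        = 0.1,
    kc1f        = 1,
    kc1b        = 0.1,
    kc1         = 100,
    kS2star     = 0.1,
    kS          = 3,
    deltaS      = 0.1,
    kmsigma     = 1,
    deltamsigma = 0.2,
    msigma0     = 0.5,
    deltaAsigma = 0.05,
    ksigmaf     = 1,
    ksigmab     = 2,
    JT          = 0.15,
    kA          = 0.298,
    kmalpha     = 0.54,
    malpha0     = 0.52,
    deltaA      = 0.04,
    deltamalpha = 0.086,
    deltaAbeta  = 0.1,
    kalphaf     = 100,
    kalphab     = 0.66,
    kB          = 0.312,
    kmbeta      = 0.538,
    mbeta0      = 0.03,
    deltaB      = 0.04,
    deltambeta  = 0.086,
    deltaBalpha = 0.5,
    kbetaf      = 100,
    kbetab      = 0.66,
    kbetaRf     = 100,
    kbetaRb     = 0.522
  )
  class(p) <- "jak_params"
  p
}

#' Validate a parameter set
#'
#' Checks that a parameter vector carries exactly the 33 known names,
#' that every value is finite and nonnegative, and that the degradation
#' rates and the total JAK pool are strictly positive (so that all
#' steady states are finite).
#'
#' @param p Named numeric vector of parameters.
#' @return `p`, invisibly, with class `"jak_params"`.
#' @export
validate_parameters <- function(p) {
  p <- unclass(p)
  if (!is.numeric(p) || is.null(names(p))) {
    stop("parameters must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(.param_names, names(p))
  extra <- setdiff(names(p), .param_names)
  if (length(extra) > 0) {
    stop("unknown parameter name(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(p))) {
    stop("non-finite parameter value(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p < 0)) {
    stop("negative parameter value(s): ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  }
  zero_bad <- .strict_positive[p[.strict_positive] <= 0]
  if (length(zero_bad) > 0) {
    stop("parameter(s) must be strictly positive: ",
         paste(zero_bad, collapse = ", "), call. = FALSE)
  }
  p <- p[.param_names]
  class(p) <- "jak_params"
  invisible(p)
}

#' Copy a parameter set with overrides
#'
#' Returns a modified copy of `p`; the input is never changed, so a
#' baseline passed around a scan cannot be corrupted.
#'
#' @param p A `"jak_params"` vector (e.g. from [default_parameters()]).
#' @param ... Named scalar overrides, e.g. `deltaAsigma = 0.18`.
#' @param .overrides Alternatively, a named list or vector of overrides.
#' @return A new `"jak_params"` vector.
#' @export
#' @examples
#' p_slow <- set_parameters(default_parameters(), deltaAsigma = 0.17382)
set_parameters <- function(p, ..., .overrides = NULL) {
  ov <- c(list(...), as.list(.overrides))
  if (length(ov) == 0) return(p)
  nm <- names(ov)
  if (is.null(nm) || any(nm == "")) {
    stop("all overrides must be named", call. = FALSE)
  }
  bad <- setdiff(nm, .param_names)
  if (length(bad) > 0) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- unclass(p)
  out[nm] <- vapply(ov, function(x) as.numeric(x)[1], numeric(1))
  validate_parameters(out)
  class(out) <- "jak_params"
  out
}

#' @export
print.jak_params <- function(x, ...) {
  cat("JAK/STAT border-cell switch parameters (nM, min):\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Read a parameter configuration file
#'
#' Reads a flat key/value YAML (or JSON, a YAML subset) file of
#' parameter overrides. Unknown keys are an error; keys not present in
#' the file keep their baseline values, and each applied default can be
#' reported with `verbose = TRUE`.
#'
#' @param path Path to a flat YAML/JSON file mapping parameter names to
#'   numeric values.
#' @param base Parameter set supplying defaults for missing keys.
#' @param verbose Report which parameters fell back to defaults.
#' @return A `"jak_params"` vector.
#' @export
read_parameters <- function(path, base = default_parameters(),
                            verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat key: value mapping",
                          call. = FALSE)
  bad <- setdiff(names(raw), .param_names)
  if (length(bad) > 0) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nonnum <- names(raw)[!vapply(raw, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(nonnum) > 0) {
    stop("non-numeric value for key(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  }
  defaulted <- setdiff(.param_names, names(raw))
  if (verbose && length(defaulted) > 0) {
    message("using baseline defaults for: ",
            paste(defaulted, collapse = ", "))
  }
  set_parameters(base, .overrides = raw)
}

#' Write a parameter set to a flat YAML config
#'
#' Values are serialized as decimal strings with full precision
#' (`format(..., digits = 17)`), so a write/read round trip reproduces
#' the numbers bit-exactly.
#'
#' @param p A `"jak_params"` vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  lines <- paste0(names(p), ": ", vapply(unclass(p), function(v)
    format(v, digits = 17, scientific = FALSE), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Names of the model parameters
#'
#' @return Character vector of the 33 parameter names.
#' @export
parameter_names <- function() .param_names
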