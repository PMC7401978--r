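# Shared fixtures: baseline parameters and memoised steady states so
# repeated tests do not redo the multistart search.

p_base <- default_parameters()

.eq_cache <- new.env(parent = emptyenv())

cached_equilibria <- function(U, p = p_base, n_grid = 6) {
  key <- paste0("U", U, "_g", n_grid, "_",
                substr(digest_params(p), 1, 8))
  if (is.null(.eq_cache[[key]])) {
    .eq_cache[[key]] <- find_steady_states(U, p, n_grid = n_grid)
  }
  .eq_cache[[key]]
}

digest_params <- function(p) {
  paste(format(unclass(p), digits = 17), collapse = ",")
}

stable_states <- function(eq) Filter(function(s) s$stability == "stable", eq)
saddle_state <- function(eq) {
  un <- Filter(function(s) s$stability == "unstable", eq)
  if (length(un) == 0) NULL else un[[1]]
}

# random nonnegative full-model state respecting the gene-state simplex
random_full_state <- function() {
  st <- stats::runif(15, 0, 10)
  names(st) <- full_state_names()
  st[["alpha"]] <- stats::runif(1)
  st[["sigma"]] <- stats::runif(1)
  b <- stats::runif(2); b <- b / max(sum(b), 1) * stats::runif(1)
  st[["beta"]] <- b[1]
  st[["betaR"]] <- b[2]
  st
}
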