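# Steady-state finding, continuation, fold detection, and the bistable
# UPD window.

test_that("root multiplicity changes across the bistable window", {
  eq4 <- cached_equilibria(4)
  expect_length(eq4, 3)
  expect_length(stable_states(eq4), 2)
  expect_length(Filter(function(s) s$stability == "unstable", eq4), 1)
  eq15 <- cached_equilibria(15)
  expect_length(stable_states(eq15), 1)
  expect_length(cached_equilibria(0.5), 3)
  # every root satisfies the residual bound and is sorted by APT
  A_order <- vapply(eq4, function(s) s$state[["A"]], numeric(1))
  expect_true(all(diff(A_order) < 0))
  expect_true(all(vapply(eq4, function(s) s$residual, numeric(1)) < 1e-9))
})

test_that("a denser multistart finds no additional roots", {
  dense <- find_steady_states(4, p_base, n_grid = 11)
  expect_length(dense, length(cached_equilibria(4)))
})

test_that("the high-APT state at vanishing UPD matches the analytic balance", {
  eq0 <- cached_equilibria(0)
  expect_length(eq0, 1)
  s <- eq0[[1]]
  expect_identical(s$stability, "stable")
  # with no dimer, the S equation decouples: S = kS*msigma0 /
  # (deltaS*(deltamsigma + deltaAsigma*A))
  A <- s$state[["A"]]
  S_pred <- 3 * 0.5 / (0.1 * (0.2 + 0.05 * A))
  expect_equal(s$state[["S"]], S_pred, tolerance = 1e-8)
  expect_equal(A, 44.356, tolerance = 1e-3)
})

test_that("continuation traverses the fold structure of the S-curve", {
  seed <- cached_equilibria(0)[[1]]
  br <- continue_branch(p_base, c(0, 20), seed)
  expect_false(br$truncated)
  expect_gte(length(br$folds), 2)
  # the two outermost folds bound the bistable window
  expect_equal(max(br$folds), 7.873, tolerance = 1e-2)
  expect_lt(min(br$folds), 0.01)
  expect_true(all(vapply(br$states, function(s) s$residual,
                         numeric(1)) < 1e-9))
  # stability flips only at folds: count transitions along the path
  stab <- vapply(br$states, function(s) s$stability, character(1))
  expect_lte(sum(stab[-1] != stab[-length(stab)]), length(br$folds))
  # near-zero leading eigenvalue at a refined fold
  ev_min <- min(abs(Re(br$fold_states[[1]]$eigenvalues)))
  expect_lt(ev_min, 5e-3)
})

test_that("continuation and multistart agree on the branch states", {
  seed <- cached_equilibria(0)[[1]]
  br <- continue_branch(p_base, c(0, 20), seed)
  U_samples <- c(0.5, 2, 4)
  for (U in U_samples) {
    roots <- find_steady_states(U, p_base, n_grid = 6)
    on_branch <- Filter(function(s) abs(s$U - U) < 0.2, br$states)
    for (bs in on_branch) {
      # nearest multistart root at the sampled U after re-polishing the
      # continuation state there
      rp <- find_steady_states(U, p_base, n_grid = 2,
                               seeds = list(bs$state))
      d <- min(vapply(roots, function(r)
        sqrt(sum((r$state - rp[[1]]$state)^2)) /
          max(sqrt(sum(r$state^2)), 1), numeric(1)))
      expect_lt(d, 1e-6)
    }
  }
})

test_that("the bistable window covers the reference UPD levels", {
  bi <- bistable_interval(p_base, c(0, 50), n_coarse = 10)
  expect_false(is.null(bi))
  expect_lt(bi[["U_lo"]], 0.0133)
  expect_gt(bi[["U_hi"]], 4)
  # upper edge coincides with the continuation fold
  seed <- cached_equilibria(0)[[1]]
  br <- continue_branch(p_base, c(0, 20), seed)
  expect_equal(bi[["U_hi"]], max(br$folds), tolerance = 1e-2)
})

test_that("hysteresis: the reached state depends on the sweep direction", {
  # upward: from the stationary state, below the fold the cell stays
  # put; above the fold it jumps to the motile branch
  stat7 <- stable_states(cached_equilibria(7))
  stat7 <- stat7[[which.max(vapply(stat7, function(s) s$state[["A"]],
                                   numeric(1)))]]
  up_low <- integrate_model("reduced3", stat7$state, 7, p_base, 2000)
  expect_identical(classify_fate(up_low, cached_equilibria(7),
                                 deadline = 2000)$tag, "stationary")
  up_high <- integrate_model("reduced3", stat7$state, 9, p_base, 4000)
  expect_identical(classify_fate(up_high, cached_equilibria(9),
                                 deadline = 4000)$tag, "motile")
  # downward: the motile state persists at very low UPD
  mot <- stable_states(cached_equilibria(4))
  mot <- mot[[which.min(vapply(mot, function(s) s$state[["A"]],
                               numeric(1)))]]
  down <- integrate_model("reduced3", mot$state, 0.01, p_base, 2000)
  expect_identical(classify_fate(down, cached_equilibria(0.01),
                                 deadline = 2000)$tag, "motile")
})

test_that("all steady states respect the closed-form ultimate bounds", {
  p <- p_base
  S_max <- p[["kS"]] * (p[["kmsigma"]] + p[["msigma0"]]) /
    (p[["deltamsigma"]] * p[["deltaS"]])
  A_max <- p[["kA"]] * (p[["kmalpha"]] + p[["malpha0"]]) /
    (p[["deltamalpha"]] * p[["deltaA"]])
  B_max <- p[["kB"]] * (p[["kmbeta"]] + p[["mbeta0"]]) /
    (p[["deltambeta"]] * p[["deltaB"]])
  for (U in c(0, 0.133, 4, 15)) {
    for (s in cached_equilibria(U)) {
      expect_lt(s$state[["S"]], S_max)
      expect_lt(s$state[["A"]], A_max)
      expect_lt(s$state[["B"]], B_max)
    }
  }
})

test_that("the bifurcation table is branch-labelled and export-stable", {
  seed <- cached_equilibria(0)[[1]]
  br <- continue_branch(p_base, c(0, 20), seed)
  tab <- bifurcation_table(br)
  expect_identical(colnames(tab),
                   c("branch", "U", "S", "A", "B", "stability"))
  # stationary rows sit above the middle branch in APT at matched UPD
  mid <- tab[tab$branch == "middle", ]
  stn <- tab[tab$branch == "stationary", ]
  for (i in seq_len(min(nrow(stn), 25))) {
    j <- which.min(abs(mid$U - stn$U[i]))
    expect_gt(stn$A[i], mid$A[j])
  }
  # STAT is higher on the motile branch than the stationary branch
  mot <- tab[tab$branch == "motile", ]
  overlap_U <- mot$U[mot$U < max(stn$U) & mot$U > min(stn$U)]
  for (U in overlap_U[seq(1, length(overlap_U), length.out =
                            min(10, length(overlap_U)))]) {
    i <- which.min(abs(mot$U - U)); j <- which.min(abs(stn$U - U))
    expect_gt(mot$S[i], stn$S[j])
  }
  # round trip through CSV keeps 12 significant digits
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tab, path)
  tab2 <- utils::read.csv(path, comment.char = "#")
  expect_equal(tab2$A, tab$A, tolerance = 1e-11)
})
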