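# Basin-of-attraction grids and separatrix surface fitting. Grids here
# are coarser than the analysis default (21^3) so the suite stays fast;
# the refinement-stability test checks that coarseness is benign.

grid_u4 <- NULL
get_grid_u4 <- function() {
  if (is.null(grid_u4)) grid_u4 <<- classify_grid(4, p_base, n = 11)
  grid_u4
}

test_that("a grid of attractor copies is trivially classified", {
  mot <- stable_states(cached_equilibria(4))
  mot <- mot[[which.min(vapply(mot, function(s) s$state[["A"]],
                               numeric(1)))]]
  eps <- 1e-6
  bg <- classify_grid(4, p_base,
                      S_range = mot$state[["S"]] + c(-eps, eps),
                      A_range = mot$state[["A"]] + c(-eps, eps),
                      B_range = mot$state[["B"]] + c(-eps, eps),
                      n = 2, deadline = 50)
  expect_equal(bg$fractions[["motile"]], 1)
  expect_true(all(bg$points$t_converge == 0))
})

test_that("basin fractions reflect the UPD level", {
  bg4 <- get_grid_u4()
  expect_gt(bg4$fractions[["motile"]], 0.5)
  bg_lo <- classify_grid(0.0133, p_base, n = 9)
  expect_gt(bg_lo$fractions[["stationary"]], 0.5)
  expect_equal(sum(bg4$fractions), 1)
})

test_that("fractions are stable under grid refinement", {
  bg7 <- classify_grid(4, p_base, n = 7)
  bg11 <- get_grid_u4()
  expect_lt(abs(bg7$fractions[["motile"]] - bg11$fractions[["motile"]]),
            0.05)
})

test_that("near-manifold points trace the basin boundary", {
  bg <- get_grid_u4()
  pts <- near_manifold_points(bg)
  expect_gt(nrow(pts), 30)
  # the saddle lies inside the bounding box of the boundary cloud
  sad <- saddle_state(bg$equilibria)$state
  for (k in c("S", "A", "B")) {
    expect_gte(sad[[k]], min(pts[, k]))
    expect_lte(sad[[k]], max(pts[, k]))
  }
  # monostable window: no boundary
  bg15 <- suppressWarnings(classify_grid(15, p_base, n = 5,
                                         deadline = 800))
  expect_warning(empty <- near_manifold_points(bg15), "monostable")
  expect_equal(nrow(empty), 0)
})

test_that("an exact plane is recovered with negligible residual", {
  set.seed(3)
  uv <- matrix(stats::runif(60, -1, 1), ncol = 2)
  pts <- cbind(S = 10 + 3 * uv[, 1] + uv[, 2],
               A = 50 - 2 * uv[, 1] + 4 * uv[, 2],
               B = 5 + uv[, 1] - uv[, 2])
  fit <- fit_manifold(pts, "plane")
  expect_lt(fit$rms_residual, 1e-9)
  expect_error(fit_manifold(pts[1:5, ], "plane"), ">= 10")
  # collinear cloud is degenerate
  line <- cbind(S = 1:20, A = 2 * (1:20), B = 3 * (1:20))
  expect_error(fit_manifold(line, "plane"), "degenerate")
})

test_that("the separatrix is near-planar at U = 4", {
  bg <- get_grid_u4()
  pts <- near_manifold_points(bg)
  fit <- fit_manifold(pts, "plane", grid = bg)
  expect_gt(fit$accuracy, 0.9)
  # the saddle sits close to the fitted surface (within two grid-cell
  # diagonals)
  sad <- saddle_state(bg$equilibria)$state
  nrm <- fit$coefficients[c("S", "A", "B")]
  dist <- abs(manifold_side(fit, sad)) / sqrt(sum(nrm^2))
  cell <- sqrt(sum(vapply(bg$axes, function(a) diff(a[1:2])^2,
                          numeric(1))))
  expect_lt(dist, 2 * cell)
  # quadratic fit also works on the same cloud
  fq <- fit_manifold(pts, "quadratic", grid = bg)
  expect_gte(fq$accuracy, 0.85)
})

test_that("displacement across the fitted plane separates the fates", {
  bg <- get_grid_u4()
  pts <- near_manifold_points(bg)
  fit <- fit_manifold(pts, "plane", grid = bg)
  sad <- saddle_state(bg$equilibria)$state
  nrm <- fit$coefficients[c("S", "A", "B")]
  nrm <- nrm / sqrt(sum(nrm^2))
  box_diag <- sqrt(sum(vapply(bg$axes, function(a)
    diff(range(a))^2, numeric(1))))
  eps <- 0.01 * box_diag
  # sample boundary points near the saddle
  d_sad <- sqrt(rowSums(sweep(pts, 2, sad)^2))
  near <- pts[order(d_sad)[1:10], , drop = FALSE]
  agree <- 0
  for (i in seq_len(nrow(near))) {
    up <- pmax(near[i, ] + eps * nrm, 0)
    dn <- pmax(near[i, ] - eps * nrm, 0)
    f_up <- classify_fate(
      integrate_model("reduced3", up, 4, p_base, 1500, n_out = 101),
      bg$equilibria, deadline = 1500)$tag
    f_dn <- classify_fate(
      integrate_model("reduced3", dn, 4, p_base, 1500, n_out = 101),
      bg$equilibria, deadline = 1500)$tag
    if (f_up != f_dn && f_up != "unresolved" && f_dn != "unresolved") {
      agree <- agree + 1
    }
  }
  expect_gte(agree / nrow(near), 0.9)
})

test_that("the fitted plane aligns with the saddle's stable eigenplane", {
  bg <- get_grid_u4()
  fit <- fit_manifold(near_manifold_points(bg), "plane", grid = bg)
  sad <- saddle_state(bg$equilibria)
  J <- jacobian_three_var(sad$state, 4, p_base)
  # the stable eigenplane's normal is the left eigenvector of the
  # unstable eigenvalue (left/right eigenvectors of distinct eigenvalues
  # are orthogonal)
  evL <- eigen(t(J))
  n_tan <- Re(evL$vectors[, which.max(Re(evL$values))])
  n_fit <- fit$coefficients[c("S", "A", "B")]
  cosang <- abs(sum(n_tan * n_fit)) /
    (sqrt(sum(n_tan^2)) * sqrt(sum(n_fit^2)))
  expect_gt(cosang, cos(25 * pi / 180))
})
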