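test_that("delay embedding follows its definition", {
  tr <- delay_embed(c(1, 2, 3, 4, 5), m = 2, l = 1)
  expect_equal(unname(tr$points), cbind(1:4, 2:5))

  tr1 <- delay_embed(c(3, 1, 4), m = 1, l = 7)
  expect_equal(unname(tr1$points), cbind(c(3, 1, 4)))

  expect_error(delay_embed(1:5, m = 3, l = 3), "at least 7")

  # first coordinate reproduces the series truncated to embedded length
  s <- gen_logistic(200, seed = 1)$values[, 1]
  tr <- delay_embed(s, m = 3, l = 2)
  expect_equal(tr$points[, 1], s[1:(200 - 4)])
})

test_that("nonlinear transforms are componentwise, monotone and injective", {
  tr <- tm_trajectory(cbind(c(-1, 0, 2)))
  expect_equal(unname(nonlinear_transform(tr, "cubic")$points), cbind(c(-1, 0, 8)))
  expect_equal(unname(nonlinear_transform(tr, "quadratic")$points), cbind(c(-1, 0, 4)))

  pts <- withr::with_seed(4, matrix(rnorm(60), ncol = 2))
  for (kind in c("quadratic", "cubic")) {
    q <- nonlinear_transform(tm_trajectory(pts), kind)$points
    expect_equal(nrow(unique(q)), nrow(unique(pts)))
    # strict monotonicity preserves componentwise order
    expect_identical(order(pts[, 1]), order(q[, 1]))
  }
})

test_that("grid fitting matches the total-cell-budget rule", {
  pts <- withr::with_seed(1, matrix(runif(400), ncol = 2))
  g <- fit_grid(pts, n_cells = 900)
  expect_equal(g$counts, c(30L, 30L))
  expect_equal(fit_grid(pts, n_cells = 2500)$counts, c(50L, 50L))

  g1 <- fit_grid(cbind(c(0, 1)), n_cells = 4)
  expect_equal(g1$counts, 4L)
  # equal-size 1-D cells over [0,1]: 0.1 -> cell 1, 0.26 -> cell 2, ...
  sym <- symbolize(tm_trajectory(cbind(c(0.1, 0.26, 0.6, 0.9, 1.0))), g1)
  expect_equal(sym$symbols, c(1L, 2L, 3L, 4L, 4L))

  expect_error(fit_grid(cbind(1:5, rep(2, 5)), n_cells = 100), "degenerate")
})

test_that("symbolization bins correctly with a closed top edge", {
  g <- fit_grid(cbind(c(0, 1)), per_dim = 2)
  s <- symbolize(tm_trajectory(cbind(c(0.1, 0.9, 0.5))), g)
  expect_equal(s$symbols, c(1L, 2L, 2L))
  expect_equal(s$alphabet, c(1L, 2L))

  # the global maximum maps into the top cell, not out of range
  pts <- cbind(c(0.2, 0.7, 1.3), c(-1, 0, 2))
  g2 <- fit_grid(pts, per_dim = c(3, 3))
  expect_silent(symbolize(tm_trajectory(pts), g2))

  # a point outside explicit bounds errors
  gb <- fit_grid(pts, per_dim = c(3, 3),
                 bounds = rbind(c(0, -1), c(1, 2)))
  expect_error(symbolize(tm_trajectory(cbind(1.3, 0)), gb), "outside")
})

test_that("cell centers sit within half a cell width of their points", {
  pts <- withr::with_seed(2, cbind(runif(200, -3, 5), runif(200, 10, 11)))
  g <- fit_grid(pts, per_dim = c(7, 5))
  sym <- symbolize(tm_trajectory(pts), g)
  ctr <- cell_centers(g, sym$symbols)
  half_w <- (g$upper - g$lower) / g$counts / 2
  for (d in 1:2) {
    expect_lte(max(abs(ctr[, d] - pts[, d])), half_w[d] + 1e-12)
  }
})

test_that("refining the grid never merges distinct symbols", {
  pts <- withr::with_seed(3, matrix(runif(600), ncol = 2))
  g1 <- fit_grid(pts, per_dim = c(5, 5))
  g2 <- fit_grid(pts, per_dim = c(10, 10))
  s1 <- symbolize(tm_trajectory(pts), g1)$symbols
  s2 <- symbolize(tm_trajectory(pts), g2)$symbols
  # any two points separated at the coarse level stay separated
  idx <- withr::with_seed(4, cbind(sample(300, 200, TRUE), sample(300, 200, TRUE)))
  coarse_diff <- s1[idx[, 1]] != s1[idx[, 2]]
  fine_same <- s2[idx[, 1]] == s2[idx[, 2]]
  expect_false(any(coarse_diff & fine_same))
})

test_that("partition JSON sidecars round-trip", {
  pts <- withr::with_seed(5, matrix(rnorm(100), ncol = 2))
  g <- fit_grid(pts, per_dim = c(4, 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_partition_json(g, path)
  g2 <- read_partition_json(path)
  expect_equal(g2$lower, g$lower)
  expect_equal(g2$upper, g$upper)
  expect_identical(g2$counts, g$counts)
  expect_identical(symbolize(tm_trajectory(pts), g2)$symbols,
                   symbolize(tm_trajectory(pts), g)$symbols)
})
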