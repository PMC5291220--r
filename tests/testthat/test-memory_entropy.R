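test_that("memory network nodes and weights match hand counts", {
  gt <- temporal_network(c("a", "b", "a", "b", "a"))
  mn <- memory_network(gt, tau = 1)
  expect_equal(nrow(mn$paths), 2)
  expect_setequal(apply(mn$paths, 1, paste, collapse = ""), c("ab", "ba"))
  lab <- apply(mn$paths, 1, paste, collapse = "")
  w <- function(f, t) mn$edges$weight[mn$edges$from == match(f, lab) &
                                      mn$edges$to == match(t, lab)]
  expect_equal(w("ab", "ba"), 2)
  expect_equal(w("ba", "ab"), 1)

  # concatenated mode counts full 2(tau+1)-cell windows
  mc <- memory_network(gt, tau = 1, mode = "concatenated")
  labc <- apply(mc$paths, 1, paste, collapse = "")
  wc <- function(f, t) mc$edges$weight[mc$edges$from == match(f, labc) &
                                       mc$edges$to == match(t, labc)]
  expect_equal(wc("ab", "ab"), 1)  # window (a,b,a,b)
  expect_equal(wc("ba", "ba"), 1)  # window (b,a,b,a)

  expect_error(memory_network(gt, tau = 4), "too short")
})

test_that("order zero reduces to the aggregate network in both modes", {
  s <- random_symbols(300, 1:5, 7)
  gt <- temporal_network(s)
  g0 <- aggregate_network(gt)
  for (mode in c("overlapping", "concatenated")) {
    mn <- memory_network(gt, tau = 0, mode = mode)
    got <- data.frame(source = mn$paths[mn$edges$from, 1],
                      target = mn$paths[mn$edges$to, 1],
                      weight = mn$edges$weight)
    got <- got[order(got$source, got$target), ]
    want <- g0$edges[order(g0$edges$source, g0$edges$target), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    expect_equal(entropy_growth_rate(mn), entropy_growth_rate(g0))
  }
})

test_that("entropy growth rate matches closed forms", {
  # deterministic cycle: every node has a single out-edge
  cyc <- temporal_network(rep(c(1, 2, 3), 40))
  expect_equal(entropy_growth_rate(memory_network(cyc, 0)), 0)
  expect_equal(entropy_profile(cyc, tau_max = 5)$H, rep(0, 6))

  # two equally weighted out-edges from every node, uniform pi -> ln 2
  mn <- structure(list(tau = 0L, mode = "overlapping",
                       paths = matrix(1:2, ncol = 1),
                       edges = data.frame(from = c(1, 1, 2, 2),
                                          to = c(1, 2, 1, 2),
                                          weight = c(5, 5, 5, 5))),
                  class = "tm_memory_network")
  expect_equal(entropy_growth_rate(mn), log(2))

  # i.i.d. uniform symbols on k cells: H(0) -> ln k
  s <- random_symbols(1e5, 1:10, 13)
  H0 <- entropy_growth_rate(memory_network(temporal_network(s), 0))
  expect_equal(H0, log(10), tolerance = 0.02)

  expect_error(entropy_growth_rate(structure(list(edges = NULL),
                                             class = "tm_memory_network")),
               "no edges")
})

test_that("network entropy equals the raw n-gram conditional entropy exactly", {
  for (seed in 1:6) {
    n <- withr::with_seed(seed, sample(100:1000, 1))
    s <- random_symbols(n, 1:4, seed + 100)
    gt <- temporal_network(s)
    for (tau in 0:4) {
      H_net <- entropy_growth_rate(memory_network(gt, tau))
      H_raw <- oracle_block_entropy(s, tau)
      expect_equal(H_net, H_raw, tolerance = 1e-12)
    }
  }
})

test_that("H(tau) is non-increasing for i.i.d. sequences", {
  for (seed in 1:5) {
    s <- random_symbols(2000, 1:6, seed + 50)
    p <- entropy_profile(temporal_network(s), tau_max = 5)
    expect_true(all(diff(p$H) < 1e-9))
  }
})

test_that("memory exponent fits recover exact exponentials and flag degeneracy", {
  prof <- data.frame(tau = 0:2, H = exp(-(0:2)))
  fit <- fit_memory_exponent(prof, window = "all")
  expect_equal(fit$rho, 1)
  expect_equal(fit$r_squared, 1)

  # constant profile (periodic signal) and empty profiles give rho = 0
  expect_equal(fit_memory_exponent(data.frame(tau = 0:6, H = rep(0, 7)))$rho, 0)
  expect_equal(fit_memory_exponent(data.frame(tau = 0:6, H = rep(0.37, 7)),
                                   window = "all")$rho, 0)
  expect_equal(fit_memory_exponent(data.frame(tau = 0:1, H = c(1, 0)))$rho, 0)

  # the scaling window skips a flat head and fits the decaying tail
  prof2 <- data.frame(tau = 0:12, H = c(rep(1, 5), exp(-0.5 * (1:8))))
  fit2 <- fit_memory_exponent(prof2, window = "scaling")
  expect_equal(fit2$rho, 0.5, tolerance = 1e-8)
  expect_true(min(fit2$tau_used) >= 4)
})

test_that("rho is invariant under embedding delay and monotone transforms", {
  hen <- gen_henon(2e4, n_transient = 4000, seed = 11)
  rho_native <- memory_exponent(hen, n_cells = 2500)$rho
  for (l in 1:3) {
    rho_l <- memory_exponent(hen$values[, 1], m = 2, l = l, n_cells = 2500)$rho
    expect_lt(abs(rho_l - rho_native), 0.05)
  }
  for (kind in c("quadratic", "cubic")) {
    tr <- nonlinear_transform(tm_trajectory(hen$values), kind)
    rho_t <- memory_exponent(tr$points, n_cells = 2500)$rho
    expect_lt(abs(rho_t - rho_native), 0.05)
  }
  expect_gte(rho_native, 0)
})
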