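test_that("logistic map iterates exactly and respects the transient", {
  s <- gen_logistic(3, mu = 4, x0 = 0.3)
  expect_equal(s$values[, 1], c(0.3, 0.84, 0.5376))

  # fixed point of 4x(1-x)
  s <- gen_logistic(5, mu = 4, x0 = 0.75)
  expect_equal(s$values[, 1], rep(0.75, 5))

  # first kept sample is the (n_transient+1)-th raw iterate
  raw <- gen_logistic(10, mu = 3.7, x0 = 0.2)
  cut <- gen_logistic(6, mu = 3.7, x0 = 0.2, n_transient = 4)
  expect_equal(cut$values[, 1], raw$values[5:10, 1])

  expect_error(gen_logistic(100, mu = 4.2, x0 = 0.6), "left \\[0, 1\\]")
  expect_error(gen_logistic(10, x0 = 1.2), "inside")
})

test_that("Henon and Ikeda maps iterate exactly and deterministically", {
  h <- gen_henon(2, init = c(0, 0))
  expect_equal(unname(h$values), rbind(c(0, 0), c(1, 0)))

  # Ikeda from the origin: x1 = 1 + u*0 = 1, y1 = 0
  ik <- gen_ikeda(2, init = c(0, 0))
  expect_equal(unname(ik$values), rbind(c(0, 0), c(1, 0)))

  a <- gen_ikeda(500, seed = 9)
  b <- gen_ikeda(500, seed = 9)
  expect_identical(a$values, b$values)

  # periodic preset settles onto a short cycle
  p <- gen_henon(64, preset = "periodic", n_transient = 2000, seed = 3)
  expect_lte(nrow(unique(round(p$values, 9))), 8)
})

test_that("Rossler equilibrium is stationary and the integrator converges", {
  a <- 0.2; b <- 0.2; c <- 5.7
  xeq <- (c - sqrt(c^2 - 4 * a * b)) / 2
  eq <- c(xeq, -xeq / a, xeq / a)
  s <- gen_rossler(10, sample_stride = 0.5, n_transient_time = 0, init = eq)
  expect_lt(max(abs(sweep(s$values, 2, eq))), 1e-8)

  # step-halving agreement ~ O(step^4) over a short arc
  s1 <- gen_rossler(10, sample_stride = 0.1, integrator_step = 0.01,
                    n_transient_time = 0, init = c(-5, 0, 0))
  s2 <- gen_rossler(10, sample_stride = 0.1, integrator_step = 0.005,
                    n_transient_time = 0, init = c(-5, 0, 0))
  expect_lt(max(abs(s1$values - s2$values)), 1e-7)
})

test_that("AR(3) recursion is exact at zero noise and recovers its coefficients", {
  z <- gen_ar3(50, noise_sd = 0, seed = 1)
  expect_equal(max(abs(z$values)), 0)

  s <- gen_ar3(5000, seed = 21)$values[, 1]
  n <- length(s)
  fit <- stats::lm(s[4:n] ~ s[3:(n - 1)] + s[2:(n - 2)] + s[1:(n - 3)])
  expect_equal(unname(stats::coef(fit)[2:4]), c(0.8, -0.5, 0.7),
               tolerance = 0.05)
})

test_that("white noise is uncorrelated and pink noise has a 1/f spectrum", {
  w <- gen_white_noise(2e4, seed = 5)$values[, 1]
  r1 <- stats::cor(w[-1], w[-length(w)])
  expect_lt(abs(r1), 3 / sqrt(length(w)))

  p <- gen_pink_noise(2e4, seed = 5)$values[, 1]
  expect_equal(mean(p), 0, tolerance = 1e-10)
  expect_equal(stats::sd(p), 1, tolerance = 1e-10)
  sp <- stats::spec.pgram(stats::ts(p), plot = FALSE, taper = 0)
  band <- sp$freq > 0.01 & sp$freq < 0.2
  slope <- unname(stats::coef(stats::lm(log(sp$spec[band]) ~ log(sp$freq[band])))[2])
  expect_equal(slope, -1, tolerance = 0.2)

  expect_identical(gen_pink_noise(512, seed = 8)$values,
                   gen_pink_noise(512, seed = 8)$values)
})

test_that("SNR noise injection matches its definition", {
  s <- gen_logistic(1e4, seed = 3)

  expect_identical(add_noise_snr(s, Inf)$values, s$values)

  noisy <- add_noise_snr(s, 0, seed = 4)
  v_sig <- stats::var(s$values[, 1])
  v_noise <- stats::var(noisy$values[, 1] - s$values[, 1])
  expect_equal(v_noise / v_sig, 1, tolerance = 0.05)

  # 28.5 dB corresponds to a variance ratio 10^2.85 ~ 707.9
  n28 <- add_noise_snr(s, 28.5, seed = 4)
  ratio <- v_sig / stats::var(n28$values[, 1] - s$values[, 1])
  expect_equal(ratio, 10^2.85, tolerance = 0.05)

  expect_error(add_noise_snr(tm_series(rep(1, 100)), 10, seed = 1),
               "zero-variance")
})

test_that("long chaotic logistic orbit matches the beta(1/2,1/2) invariant density", {
  x <- gen_logistic(2e4, n_transient = 1000, seed = 17)$values[, 1]
  breaks <- seq(0, 1, length.out = 21)
  obs <- table(cut(x, breaks, include.lowest = TRUE))
  p_exp <- diff(stats::pbeta(breaks, 0.5, 0.5))
  chi <- suppressWarnings(stats::chisq.test(obs, p = p_exp))
  expect_gt(chi$p.value, 0.01)
})

test_that("generators are seed-reproducible", {
  expect_identical(gen_logistic(100, seed = 2)$values,
                   gen_logistic(100, seed = 2)$values)
  expect_identical(gen_ar3(100, seed = 2)$values, gen_ar3(100, seed = 2)$values)
  expect_identical(gen_white_noise(100, seed = 2)$values,
                   gen_white_noise(100, seed = 2)$values)
  # different seeds give different initial conditions
  expect_false(identical(gen_logistic(100, seed = 2)$values,
                         gen_logistic(100, seed = 3)$values))
})
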