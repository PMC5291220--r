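# Benchmark signal generators: deterministic maps and flows plus stochastic
# processes, each returning a `tm_series` with its generation record.

#' Time-series container
#'
#' Light container used by every generator: an n x d matrix of samples
#' (one row per time step), the sampling interval `dt` (1 for maps), and a
#' metadata record (generator name, parameters, seed) sufficient to replay
#' the run.
#'
#' @param values numeric vector (scalar series) or matrix with one column
#'   per coordinate.
#' @param dt sampling interval in model time units.
#' @param meta named list describing provenance.
#' @return An object of class `tm_series`.
#' @export
tm_series <- function(values, dt = 1, meta = list()) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  storage.mode(v) <- "double"
  structure(list(values = v, dt = dt, meta = meta), class = "tm_series")
}

#' @export
print.tm_series <- function(x, ...) {
  cat(sprintf("<tm_series> %d samples x %d coordinate(s), dt = %g, generator = %s\n",
              nrow(x$values), ncol(x$values), x$dt,
              if (is.null(x$meta$generator)) "?" else x$meta$generator))
  invisible(x)
}

#' @export
as.matrix.tm_series <- function(x, ...) x$values

series_values <- function(x) {
  if (inherits(x, "tm_series")) x$values
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), ncol = 1L)
}

#' Logistic map orbit
#'
#' Iterates x[n+1] = mu * x[n] * (1 - x[n]). The initial condition counts as
#' the first raw sample; the first `n_transient` raw samples are discarded.
#'
#' @param n number of samples returned (after transient removal).
#' @param mu control parameter; the fully chaotic regime is mu = 4.
#' @param n_transient leading samples discarded.
#' @param x0 initial condition in (0, 1); drawn uniformly from (0.05, 0.95)
#'   when NULL (reproducible via `seed`).
#' @param seed optional RNG seed for the random initial condition.
#' @return A scalar `tm_series` of length n with dt = 1.
#' @export
gen_logistic <- function(n, mu = 4, n_transient = 0, x0 = NULL, seed = NULL) {
  stopifnot(n >= 1, n_transient >= 0, mu > 0)
  if (is.null(x0)) x0 <- with_seed_if(seed, stats::runif(1, 0.05, 0.95))
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie strictly inside (0, 1)")
  total <- n + n_transient
  x <- numeric(total)
  x[1L] <- x0
  for (i in seq_len(total - 1L)) {
    x[i + 1L] <- mu * x[i] * (1 - x[i])
    if (x[i + 1L] < 0 || x[i + 1L] > 1) {
      stop("logistic orbit left [0, 1] (mu > 4?)", call. = FALSE)
    }
  }
  tm_series(x[(n_transient + 1L):total], dt = 1,
            meta = list(generator = "logistic", mu = mu, x0 = x0,
                        n_transient = n_transient, seed = seed))
}

#' Henon map orbit
#'
#' Iterates x[n+1] = 1 - a x[n]^2 + y[n], y[n+1] = b x[n]. The classical
#' chaotic parameters are (a, b) = (1.4, 0.3); `preset = "periodic"` selects
#' (1.0, 0.3), inside a stable periodic window.
#'
#' @param n samples returned after transient removal.
#' @param a,b map parameters (override the preset when supplied).
#' @param preset `"chaotic"` or `"periodic"`.
#' @param n_transient leading samples discarded.
#' @param init length-2 initial state (x0, y0); small random perturbation of
#'   the origin when NULL.
#' @param seed optional RNG seed for the random initial state.
#' @return A bivariate `tm_series` with dt = 1.
#' @export
gen_henon <- function(n, a = NULL, b = NULL, preset = c("chaotic", "periodic"),
                      n_transient = 0, init = NULL, seed = NULL) {
  preset <- match.arg(preset)
  if (is.null(a)) a <- if (preset == "chaotic") 1.4 else 1.0
  if (is.null(b)) b <- 0.3
  stopifnot(n >= 1, n_transient >= 0)
  if (is.null(init)) init <- with_seed_if(seed, stats::runif(2, -0.1, 0.1))
  total <- n + n_transient
  x <- numeric(total); y <- numeric(total)
  x[1L] <- init[1L]; y[1L] <- init[2L]
  for (i in seq_len(total - 1L)) {
    x[i + 1L] <- 1 - a * x[i]^2 + y[i]
    y[i + 1L] <- b * x[i]
    if (abs(x[i + 1L]) > 1e6) stop("Henon orbit diverged", call. = FALSE)
  }
  keep <- (n_transient + 1L):total
  tm_series(cbind(x = x[keep], y = y[keep]), dt = 1,
            meta = list(generator = "henon", a = a, b = b, preset = preset,
                        init = init, n_transient = n_transient, seed = seed))
}

#' Ikeda map orbit
#'
#' Iterates the Ikeda laser map with u = 0.9:
#' x[n+1] = 1 + u (x cos t - y sin t), y[n+1] = u (x sin t + y cos t),
#' where t = 0.4 - 6 / (1 + x^2 + y^2).
#'
#' @inheritParams gen_henon
#' @param u contraction parameter (default 0.9, the chaotic regime).
#' @return A bivariate `tm_series` with dt = 1.
#' @export
gen_ikeda <- function(n, u = 0.9, n_transient = 0, init = NULL, seed = NULL) {
  stopifnot(n >= 1, n_transient >= 0)
  if (is.null(init)) init <- with_seed_if(seed, stats::runif(2, -0.1, 0.1))
  total <- n + n_transient
  x <- numeric(total); y <- numeric(total)
  x[1L] <- init[1L]; y[1L] <- init[2L]
  for (i in seq_len(total - 1L)) {
    t <- 0.4 - 6 / (1 + x[i]^2 + y[i]^2)
    x[i + 1L] <- 1 + u * (x[i] * cos(t) - y[i] * sin(t))
    y[i + 1L] <- u * (x[i] * sin(t) + y[i] * cos(t))
    if (abs(x[i + 1L]) > 1e6) stop("Ikeda orbit diverged", call. = FALSE)
  }
  keep <- (n_transient + 1L):total
  tm_series(cbind(x = x[keep], y = y[keep]), dt = 1,
            meta = list(generator = "ikeda", u = u, init = init,
                        n_transient = n_transient, seed = seed))
}

#' Rossler flow trajectory
#'
#' Integrates dx/dt = -(y + z), dy/dt = x + a y, dz/dt = b + z (x - c) with
#' a fixed-step 4th-order Runge-Kutta scheme and samples the trajectory
#' every `sample_stride` time units.
#'
#' @param n_samples samples returned.
#' @param a,b,c system parameters; defaults (0.2, 0.2, 5.7) are the
#'   classical chaotic regime.
#' @param sample_stride time between consecutive samples.
#' @param integrator_step RK4 step (must divide `sample_stride` closely).
#' @param n_transient_time leading integration time discarded.
#' @param init length-3 initial state; a point near the attractor when NULL.
#' @param seed optional RNG seed used only when `init` is NULL.
#' @return A trivariate `tm_series` with dt = `sample_stride`.
#' @export
gen_rossler <- function(n_samples, a = 0.2, b = 0.2, c = 5.7,
                        sample_stride = 1.0, integrator_step = 0.01,
                        n_transient_time = 500, init = NULL, seed = NULL) {
  stopifnot(n_samples >= 1, integrator_step > 0, sample_stride >= integrator_step)
  if (is.null(init)) {
    init <- with_seed_if(seed, c(-5, 0, 0) + stats::runif(3, -0.5, 0.5))
  }
  steps_per_sample <- round(sample_stride / integrator_step)
  if (abs(steps_per_sample * integrator_step - sample_stride) > 1e-9) {
    stop("integrator_step must divide sample_stride")
  }
  h <- integrator_step
  deriv <- function(s) c(-(s[2L] + s[3L]),
                         s[1L] + a * s[2L],
                         b + s[3L] * (s[1L] - c))
  rk4_step <- function(s) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- init
  for (i in seq_len(round(n_transient_time / h))) s <- rk4_step(s)
  stop_if_divergent(s, what = "Rossler transient")
  out <- matrix(0, nrow = n_samples, ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  out[1L, ] <- s
  if (n_samples > 1L) {
    for (i in 2L:n_samples) {
      for (j in seq_len(steps_per_sample)) s <- rk4_step(s)
      if (!all(is.finite(s)) || max(abs(s)) > 1e6) {
        stop("Rossler trajectory diverged", call. = FALSE)
      }
      out[i, ] <- s
    }
  }
  tm_series(out, dt = sample_stride,
            meta = list(generator = "rossler", a = a, b = b, c = c,
                        sample_stride = sample_stride,
                        integrator_step = integrator_step,
                        n_transient_time = n_transient_time,
                        init = init, seed = seed))
}

#' Autoregressive AR(3) process
#'
#' Simulates s[n] = 0.8 s[n-1] - 0.5 s[n-2] + 0.7 s[n-3] + e[n] with i.i.d.
#' Gaussian innovations. Note the characteristic polynomial has a unit
#' root, so the process wanders like a random walk rather than mixing.
#'
#' @param n samples returned after transient removal.
#' @param coef the three lag coefficients.
#' @param noise_sd innovation standard deviation (> 0).
#' @param n_transient leading samples discarded.
#' @param seed RNG seed (required for reproducibility).
#' @return A scalar `tm_series` with dt = 1.
#' @export
gen_ar3 <- function(n, coef = c(0.8, -0.5, 0.7), noise_sd = 1,
                    n_transient = 0, seed = NULL) {
  stopifnot(n >= 1, n_transient >= 0, noise_sd >= 0, length(coef) == 3L)
  total <- n + n_transient
  eps <- with_seed_if(seed, stats::rnorm(total, sd = noise_sd))
  s <- numeric(total + 3L)  # three zero pre-samples start the recursion
  for (i in seq_len(total)) {
    j <- i + 3L
    s[j] <- coef[1L] * s[j - 1L] + coef[2L] * s[j - 2L] + coef[3L] * s[j - 3L] + eps[i]
  }
  s <- s[-(1:3)]
  stop_if_divergent(s, what = "AR(3) series")
  tm_series(s[(n_transient + 1L):total], dt = 1,
            meta = list(generator = "ar3", coef = coef, noise_sd = noise_sd,
                        n_transient = n_transient, seed = seed))
}

#' White and 1/f (pink) noise
#'
#' `gen_white_noise` draws i.i.d. standard Gaussian samples. `gen_pink_noise`
#' synthesises 1/f noise in the spectral domain: Fourier amplitudes
#' proportional to f^(-1/2) (power spectral density proportional to 1/f),
#' uniformly random phases, zero-frequency bin set to 0, rescaled to zero
#' mean and unit variance.
#'
#' @param n number of samples.
#' @param seed RNG seed (required for reproducibility).
#' @return A scalar `tm_series` with dt = 1.
#' @export
gen_white_noise <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  x <- with_seed_if(seed, stats::rnorm(n))
  tm_series(x, dt = 1, meta = list(generator = "white", seed = seed))
}

#' @rdname gen_white_noise
#' @export
gen_pink_noise <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  nf <- n %/% 2L
  phases <- with_seed_if(seed, stats::runif(nf, 0, 2 * pi))
  f <- seq_len(nf)
  amp <- f^(-0.5)
  spec <- complex(length.out = n)
  spec[1L + f] <- amp * exp(1i * phases)
  # Hermitian symmetry for a real signal; Nyquist bin kept real for even n
  if (n %% 2L == 0L) spec[1L + nf] <- amp[nf]
  spec[n + 1L - seq_len(nf - (n %% 2L == 0L))] <-
    Conj(spec[1L + seq_len(nf - (n %% 2L == 0L))])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- (x - mean(x)) / stats::sd(x)
  tm_series(x, dt = 1, meta = list(generator = "pink", seed = seed))
}

#' Additive Gaussian observational noise at a given SNR
#'
#' Adds i.i.d. Gaussian noise, per coordinate, with variance
#' var(signal) / 10^(snr_db / 10); SNR is 10 log10(var_signal / var_noise).
#' An infinite `snr_db` returns the input unchanged.
#'
#' @param series a `tm_series` (or numeric vector / matrix).
#' @param snr_db signal-to-noise ratio in decibels.
#' @param seed RNG seed.
#' @return A `tm_series` of the same shape.
#' @export
add_noise_snr <- function(series, snr_db, seed = NULL) {
  v <- series_values(series)
  if (is.infinite(snr_db)) {
    return(tm_series(v, dt = if (inherits(series, "tm_series")) series$dt else 1,
                     meta = c(if (inherits(series, "tm_series")) series$meta,
                              list(snr_db = Inf))))
  }
  vs <- apply(v, 2L, stats::var)
  if (any(vs <= 0)) stop("cannot set an SNR for a zero-variance signal")
  noise_sd <- sqrt(vs / 10^(snr_db / 10))
  eps <- with_seed_if(seed, matrix(stats::rnorm(length(v)), nrow = nrow(v)))
  out <- v + sweep(eps, 2L, noise_sd, `*`)
  tm_series(out, dt = if (inherits(series, "tm_series")) series$dt else 1,
            meta = c(if (inherits(series, "tm_series")) series$meta,
                     list(snr_db = snr_db, noise_seed = seed)))
}
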