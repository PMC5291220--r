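# Memory-entropy analysis: consecutive memory networks G^(tau), the entropy
# growth rate H(tau) of the induced path-state Markov process, and the
# fitted memory exponent rho.

#' Consecutive memory network of order tau
#'
#' The order-tau memory network has one node per distinct tau-step path
#' (a window of tau+1 consecutive cells actually visited). In the default
#' `"overlapping"` mode an edge a -> b counts the windows of tau+2 cells in
#' which path b is the one-step shift of path a, i.e. the observed
#' continuations of each path state. In `"concatenated"` mode an edge
#' a -> b counts occurrences of the 2(tau+1)-cell window formed by a, a
#' linking transition, and b (a path of 2 tau + 1 edges in the aggregate
#' network). At tau = 0 both modes reduce exactly to the aggregate network.
#'
#' @param gt a `tm_temporal_network`.
#' @param tau memory order (>= 0); the sequence must be longer than tau + 1.
#' @param mode `"overlapping"` (default) or `"concatenated"`.
#' @return An object of class `tm_memory_network`: `tau`, `mode`, `paths`
#'   (matrix, one row per node, tau+1 cell labels), and `edges`
#'   (data.frame `from`, `to` node indices and `weight`).
#' @export
memory_network <- function(gt, tau, mode = c("overlapping", "concatenated")) {
  mode <- match.arg(mode)
  stopifnot(tau >= 0)
  s <- tn_symbols(gt)
  n <- length(s)
  need <- if (mode == "overlapping") tau + 2L else 2L * (tau + 1L)
  if (n < need) {
    stop(sprintf("sequence of length %d too short for tau = %d (%s mode)",
                 n, tau, mode))
  }
  lv <- gt$nodes
  codes <- match(s, lv)
  g <- gram_ids(codes, tau + 1L)
  n_nodes <- nrow(g$paths)
  L <- length(g$ids)
  if (mode == "overlapping") {
    from <- g$ids[seq_len(L - 1L)]
    to <- g$ids[-1L]
  } else {
    k <- tau + 1L
    m <- L - k
    from <- g$ids[seq_len(m)]
    to <- g$ids[seq_len(m) + k]
  }
  edges <- count_pairs(from, to, n_nodes)
  paths <- matrix(lv[g$paths], nrow = n_nodes)
  structure(list(tau = as.integer(tau), mode = mode, paths = paths,
                 edges = edges),
            class = "tm_memory_network")
}

#' @export
print.tm_memory_network <- function(x, ...) {
  cat(sprintf("<tm_memory_network> tau = %d (%s): %d path-nodes, %d edges\n",
              x$tau, x$mode, nrow(x$paths), nrow(x$edges)))
  invisible(x)
}

#' Entropy growth rate of a memory network
#'
#' The expected uncertainty (in nats) of the next jump of the path-state
#' process: H = -sum_a pi_a sum_b T_ab log T_ab, with transition
#' probabilities T_ab = w(a,b) / sum_b' w(a,b') and the stationary weights
#' pi taken as the empirical edge marginal pi_a = sum_b w(a,b) / sum w.
#' Nodes without out-edges contribute nothing.
#'
#' @param mn a `tm_memory_network` (or `tm_aggregate`).
#' @return The entropy growth rate in nats (a non-negative scalar).
#' @export
entropy_growth_rate <- function(mn) {
  e <- mn$edges
  if (is.null(e) || nrow(e) == 0L) stop("memory network has no edges")
  w <- e$weight
  from <- if (inherits(mn, "tm_aggregate")) match(e$source, mn$nodes) else e$from
  tot <- sum(w)
  out <- rowsum(w, from)          # out-strength per source node
  T_ab <- w / out[match(from, as.integer(rownames(out)))]
  -sum((w / tot) * log(T_ab))
}

#' Entropy growth rate profile H(tau)
#'
#' Computes H(tau) for tau = 0..tau_max by building each consecutive memory
#' network and evaluating its entropy growth rate.
#'
#' @param gt a `tm_temporal_network`.
#' @param tau_max largest memory order.
#' @inheritParams memory_network
#' @return A data.frame of class `tm_entropy_profile` with columns `tau`,
#'   `H` (nats), and `n_nodes`.
#' @export
entropy_profile <- function(gt, tau_max = 6, mode = c("overlapping", "concatenated")) {
  mode <- match.arg(mode)
  stopifnot(tau_max >= 0)
  rows <- lapply(0:tau_max, function(tau) {
    mn <- memory_network(gt, tau, mode)
    data.frame(tau = tau, H = entropy_growth_rate(mn), n_nodes = nrow(mn$paths))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tm_entropy_profile", "data.frame")
  out
}

#' Fit the memory exponent rho
#'
#' For chaotic signals H(tau) decays exponentially, H(tau) ~ exp(-rho tau);
#' rho is minus the slope of an ordinary least-squares fit of log H(tau)
#' on tau.
#'
#' With `window = "scaling"` (the default) the fit range is the exponential
#' scaling regime, identified automatically: among all windows of
#' consecutive tau with at least `min_width` points, all H above `h_floor`,
#' a total decay of at least `min_decay` nats (so flat plateaus never
#' qualify), and a negative slope, the window with the highest R-squared is
#' chosen (ties: the wider, then the earlier window). Profiles with no
#' qualifying window fall back to the plain rule below.
#'
#' With `window = "all"` the fit simply uses
#' {tau <= tau_fit_max : H(tau) > h_floor}.
#'
#' Degenerate rule: with fewer than two usable points, or a profile
#' constant to within `h_floor`, rho = 0 (the periodic / memoryless case).
#'
#' @param profile a `tm_entropy_profile` (or data.frame with `tau`, `H`).
#' @param h_floor entropy floor below which points are excluded from the
#'   log fit.
#' @param tau_fit_max largest tau used by the `"all"` rule (and its
#'   fallback use).
#' @param window `"scaling"` (automatic scaling-regime window) or `"all"`.
#' @param min_width minimum number of points in a scaling window.
#' @param min_decay minimum total decay of log H (in nats) across a
#'   scaling window.
#' @return An object of class `tm_memory_fit`: list with `rho`, `intercept`,
#'   `tau_used`, and `r_squared`.
#' @export
fit_memory_exponent <- function(profile, h_floor = 1e-12, tau_fit_max = 6,
                                window = c("scaling", "all"),
                                min_width = 5, min_decay = 2) {
  window <- match.arg(window)
  tau <- profile$tau
  H <- profile$H
  if (window == "scaling") {
    best <- scaling_window(tau, H, h_floor, min_width, min_decay)
    if (!is.null(best)) {
      return(structure(list(rho = best$rho, intercept = best$intercept,
                            tau_used = tau[best$idx],
                            r_squared = best$r_squared),
                       class = "tm_memory_fit"))
    }
  }
  use <- which(tau <= tau_fit_max & H > h_floor)
  degenerate <- length(use) < 2L ||
    (max(H[use]) - min(H[use])) <= h_floor
  if (degenerate) {
    fit <- list(rho = 0, intercept = NA_real_, tau_used = integer(0),
                r_squared = NA_real_)
  } else {
    mod <- stats::lm(log(H[use]) ~ tau[use])
    fit <- list(rho = -unname(stats::coef(mod)[2L]),
                intercept = unname(stats::coef(mod)[1L]),
                tau_used = tau[use],
                r_squared = suppressWarnings(summary(mod)$r.squared))
  }
  structure(fit, class = "tm_memory_fit")
}

# Exhaustive search for the best log-linear scaling window (profiles have
# at most a few dozen points, so O(len^2) fits are cheap).
scaling_window <- function(tau, H, h_floor, min_width, min_decay) {
  ok <- H > h_floor
  len <- length(tau)
  best <- NULL
  for (a in seq_len(len)) {
    if (!ok[a]) next
    for (b in seq_len(len)) {
      if (b - a + 1L < min_width) next
      idx <- a:b
      if (!all(ok[idx])) next
      if (log(H[a] / H[b]) < min_decay) next
      mod <- stats::lm(log(H[idx]) ~ tau[idx])
      slope <- unname(stats::coef(mod)[2L])
      if (slope >= 0) next
      r2 <- suppressWarnings(summary(mod)$r.squared)  # exact fits warn
      better <- is.null(best) || r2 > best$r_squared + 1e-12 ||
        (abs(r2 - best$r_squared) <= 1e-12 && length(idx) > length(best$idx))
      if (better) {
        best <- list(rho = -slope, intercept = unname(stats::coef(mod)[1L]),
                     idx = idx, r_squared = r2)
      }
    }
  }
  best
}

#' @export
print.tm_memory_fit <- function(x, ...) {
  cat(sprintf("<tm_memory_fit> rho = %.4f (R^2 = %s, tau in [%s])\n",
              x$rho,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              if (length(x$tau_used)) paste(range(x$tau_used), collapse = ", ")
              else "degenerate"))
  invisible(x)
}

#' Memory exponent of a time series (full pipeline)
#'
#' Convenience wrapper chaining the whole analysis: optional delay
#' embedding of a scalar series, equal-size grid partition, symbolization,
#' temporal network, entropy profile, and the exponential fit. Multivariate
#' input is used as the native phase trajectory (no embedding).
#'
#' @param x a `tm_series`, numeric vector (scalar series), or matrix
#'   (native trajectory).
#' @param m embedding dimension for scalar input (m = 1 symbolizes the raw
#'   series directly, as appropriate for noise without attractor structure).
#' @param l embedding delay in samples.
#' @param n_cells total partition cell budget N.
#' @param per_dim per-dimension cell counts (overrides `n_cells`).
#' @param bounds optional partition bounds override.
#' @param tau_max largest memory order in the profile; the default 16
#'   reaches well into the scaling regime of the finite-sample profiles.
#' @param mode memory-network edge mode.
#' @param h_floor,tau_fit_max,window fit options, see
#'   [fit_memory_exponent()].
#' @return A `tm_memory_fit` with the `tm_entropy_profile` attached as
#'   attribute `"profile"` and the partition as attribute `"partition"`.
#' @export
memory_exponent <- function(x, m = 2, l = 1, n_cells = 900, per_dim = NULL,
                            bounds = NULL, tau_max = 16,
                            mode = c("overlapping", "concatenated"),
                            h_floor = 1e-12, tau_fit_max = 6,
                            window = c("scaling", "all")) {
  mode <- match.arg(mode)
  window <- match.arg(window)
  v <- series_values(x)
  traj <- if (ncol(v) == 1L && m > 1) delay_embed(v[, 1L], m, l)
          else tm_trajectory(v, source = "raw")
  part <- fit_grid(traj, n_cells = n_cells, per_dim = per_dim, bounds = bounds)
  gt <- temporal_network(symbolize(traj, part))
  prof <- entropy_profile(gt, tau_max = tau_max, mode = mode)
  fit <- fit_memory_exponent(prof, h_floor = h_floor,
                             tau_fit_max = tau_fit_max, window = window)
  attr(fit, "profile") <- prof
  attr(fit, "partition") <- part
  fit
}
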