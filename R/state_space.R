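# Phase-space handling: delay embedding, monotone nonlinear transforms,
# equal-size grid partitioning, and symbolization of trajectories.

#' Phase trajectory container
#'
#' An ordered set of m-dimensional points with a provenance record (raw,
#' embedded, or transformed).
#'
#' @param points numeric matrix, one row per point.
#' @param source character provenance tag.
#' @return An object of class `tm_trajectory`.
#' @export
tm_trajectory <- function(points, source = "raw") {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 1L)
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("trajectory contains non-finite coordinates")
  structure(list(points = p, m = ncol(p), source = source),
            class = "tm_trajectory")
}

#' @export
print.tm_trajectory <- function(x, ...) {
  cat(sprintf("<tm_trajectory> %d points in %d-D (%s)\n",
              nrow(x$points), x$m, x$source))
  invisible(x)
}

traj_points <- function(x) {
  if (inherits(x, "tm_trajectory")) x$points
  else if (inherits(x, "tm_series")) x$values
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), ncol = 1L)
}

#' Delay embedding of a scalar series
#'
#' Reconstructs an m-dimensional trajectory from a scalar series using
#' lagged copies: point i is (s[i], s[i+l], ..., s[i+(m-1)l]), giving
#' n - (m-1) l points.
#'
#' @param series scalar `tm_series` or numeric vector.
#' @param m embedding dimension (>= 1).
#' @param l time delay in samples (>= 1).
#' @return A `tm_trajectory`.
#' @export
delay_embed <- function(series, m, l = 1) {
  v <- series_values(series)
  if (ncol(v) != 1L) stop("delay_embed expects a scalar series")
  s <- v[, 1L]
  n <- length(s)
  stopifnot(m >= 1, l >= 1)
  npts <- n - (m - 1) * l
  if (npts < 1) {
    stop(sprintf("series too short for embedding: need at least %d samples",
                 (m - 1) * l + 1))
  }
  pts <- vapply(0:(m - 1), function(j) s[seq_len(npts) + j * l], numeric(npts))
  tm_trajectory(matrix(pts, ncol = m), source = sprintf("embedded(m=%d,l=%d)", m, l))
}

#' Monotone nonlinear phase-space transform
#'
#' Applies a componentwise strictly monotone polynomial map: `"quadratic"`
#' is x -> x |x|, `"cubic"` is x -> x^3. Point ordering is preserved, so
#' downstream symbol dynamics should be essentially unchanged; used to test
#' the invariance of the memory exponent.
#'
#' @param traj a `tm_trajectory` (or matrix).
#' @param kind `"quadratic"` or `"cubic"`.
#' @return A `tm_trajectory`.
#' @export
nonlinear_transform <- function(traj, kind = c("quadratic", "cubic")) {
  kind <- match.arg(kind)
  p <- traj_points(traj)
  q <- if (kind == "quadratic") p * abs(p) else p^3
  tm_trajectory(q, source = sprintf("transformed(%s)", kind))
}

#' Equal-size grid partition of phase space
#'
#' Splits the bounding box of a trajectory into axis-aligned cells of equal
#' size within each dimension. With a total cell budget `n_cells`, each
#' dimension gets k = round(n_cells^(1/m)) cells (exact for square numbers
#' in 2-D, e.g. 900 -> 30 x 30); pass `per_dim` for full control. Bounds
#' default to the data range expanded by 1e-9 of the range on each side.
#'
#' @param traj a `tm_trajectory`, `tm_series`, or matrix.
#' @param n_cells total cell budget N (used as round(N^(1/m)) per dimension).
#' @param per_dim integer vector of per-dimension cell counts (overrides
#'   `n_cells`).
#' @param bounds optional 2 x m matrix (rows: lower, upper) overriding the
#'   data-driven bounding box, e.g. to reuse one partition across noise
#'   levels.
#' @return An object of class `tm_partition` with fields `lower`, `upper`,
#'   `counts`, `m`, and total cell count `n_cells`.
#' @export
fit_grid <- function(traj, n_cells = NULL, per_dim = NULL, bounds = NULL) {
  p <- traj_points(traj)
  m <- ncol(p)
  if (is.null(per_dim)) {
    if (is.null(n_cells)) stop("supply n_cells or per_dim")
    per_dim <- rep(max(1L, as.integer(round(n_cells^(1 / m)))), m)
  }
  stopifnot(length(per_dim) == m, all(per_dim >= 1))
  if (is.null(bounds)) {
    lo <- apply(p, 2L, min)
    hi <- apply(p, 2L, max)
    if (any(hi <= lo)) {
      stop(sprintf("degenerate trajectory: coordinate %d has zero range",
                   which(hi <= lo)[1L]))
    }
  } else {
    lo <- bounds[1L, ]
    hi <- bounds[2L, ]
    if (any(hi <= lo)) stop("invalid bounds: upper must exceed lower")
  }
  structure(list(lower = lo, upper = hi, counts = as.integer(per_dim),
                 m = m, n_cells = prod(per_dim)),
            class = "tm_partition")
}

#' @export
print.tm_partition <- function(x, ...) {
  cat(sprintf("<tm_partition> %s grid, %d cells in %d-D\n",
              paste(x$counts, collapse = " x "), x$n_cells, x$m))
  invisible(x)
}

# Per-dimension bin index of each point: half-open cells [low, high) with a
# closed top edge so the maximal point stays in range.
grid_bin <- function(p, part) {
  m <- part$m
  idx <- matrix(0L, nrow = nrow(p), ncol = m)
  for (d in seq_len(m)) {
    w <- (part$upper[d] - part$lower[d]) / part$counts[d]
    x <- p[, d]
    out <- x < part$lower[d] | x > part$upper[d]
    if (any(out)) {
      stop(sprintf("point %d lies outside the partition bounds in dimension %d",
                   which(out)[1L], d))
    }
    i <- floor((x - part$lower[d]) / w) + 1
    idx[, d] <- as.integer(pmin(i, part$counts[d]))  # closed top edge
  }
  idx
}

#' Symbolize a trajectory over a grid partition
#'
#' Maps every trajectory point to the index of the cell containing it
#' (row-major over dimensions: the last dimension varies fastest), yielding
#' the coarse-grained symbol sequence that the temporal network is built
#' from.
#'
#' @param traj a `tm_trajectory` (or matrix) with the partition's dimension.
#' @param part a `tm_partition`.
#' @return An object of class `tm_symbols`: list with integer `symbols`,
#'   the `alphabet` of occupied cells, and the `partition`.
#' @export
symbolize <- function(traj, part) {
  p <- traj_points(traj)
  if (ncol(p) != part$m) stop("partition dimension does not match trajectory")
  idx <- grid_bin(p, part)
  mult <- rev(cumprod(rev(c(part$counts[-1L], 1L))))
  sym <- as.integer(idx %*% mult - sum(mult) + 1L)
  structure(list(symbols = sym, alphabet = sort(unique(sym)), partition = part),
            class = "tm_symbols")
}

#' @export
print.tm_symbols <- function(x, ...) {
  cat(sprintf("<tm_symbols> %d symbols over %d occupied / %d total cells\n",
              length(x$symbols), length(x$alphabet), x$partition$n_cells))
  invisible(x)
}

#' Cell centers of a grid partition
#'
#' @param part a `tm_partition`.
#' @param cells integer cell indices (row-major, as produced by
#'   [symbolize()]).
#' @return A numeric matrix with one row of center coordinates per cell.
#' @export
cell_centers <- function(part, cells) {
  m <- part$m
  mult <- rev(cumprod(rev(c(part$counts[-1L], 1L))))
  rem <- as.integer(cells) - 1L
  centers <- matrix(0, nrow = length(cells), ncol = m)
  for (d in seq_len(m)) {
    i <- rem %/% mult[d]
    rem <- rem %% mult[d]
    w <- (part$upper[d] - part$lower[d]) / part$counts[d]
    centers[, d] <- part$lower[d] + (i + 0.5) * w
  }
  colnames(centers) <- paste0("c", seq_len(m))
  centers
}
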