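# Internal helpers shared across modules.

# Deterministic sub-seed derivation so one master seed can drive many
# independent stochastic runs (e.g. one seed per mu in a bifurcation scan).
# Pure integer arithmetic in doubles; result always in [1, 2^31 - 2].
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 1299709) %% 2147483629
  as.integer(s) + 1L
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed leaves the global stream untouched.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

stop_if_divergent <- function(x, bound = 1e6, what = "orbit") {
  if (!all(is.finite(x)) || max(abs(x)) > bound) {
    stop(sprintf("%s diverged (non-finite value or |x| > %g)", what, bound),
         call. = FALSE)
  }
  invisible(x)
}

# Identify k-grams of an integer code sequence. Returns, for the L = n-k+1
# windows, an id in 1..U (identical windows share an id, ids numbered by
# first occurrence) and the U x k matrix of the distinct windows.
gram_ids <- function(codes, k) {
  n <- length(codes)
  if (k < 1L || n < k) stop("sequence shorter than requested gram length")
  ids <- match(codes, unique(codes))  # rank by first occurrence
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      m <- length(ids) - 1L
      # pairing key: previous-gram id extended by the next symbol
      key <- (as.double(ids[seq_len(m)]) - 1) * max(codes) + codes[seq_len(m) + j]
      ids <- match(key, unique(key))
    }
  }
  starts <- which(!duplicated(ids))
  u <- length(starts)
  paths <- matrix(codes[rep(starts, each = k) + rep(0:(k - 1L), times = u)],
                  nrow = u, ncol = k, byrow = TRUE)
  list(ids = as.integer(ids), paths = paths)
}

# Count ordered (from, to) pairs of node ids; returns one row per distinct
# directed edge with its occurrence count.
count_pairs <- function(from, to, n_nodes) {
  key <- (as.double(from) - 1) * n_nodes + to
  uk <- unique(key)
  idx <- match(key, uk)
  data.frame(
    from   = as.integer((uk - 1) %/% n_nodes) + 1L,
    to     = as.integer((uk - 1) %% n_nodes) + 1L,
    weight = tabulate(idx, nbins = length(uk))
  )
}

# Mutual information of a non-negative count matrix, 0 log 0 = 0.
mi_from_counts <- function(B, base = 2) {
  tot <- sum(B)
  if (tot <= 0) return(NA_real_)
  P <- B / tot
  p1 <- rowSums(P)
  p2 <- colSums(P)
  pos <- which(P > 0, arr.ind = TRUE)
  p <- P[pos]
  sum(p * log(p / (p1[pos[, 1L]] * p2[pos[, 2L]]), base = base))
}
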