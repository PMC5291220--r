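# Independent brute-force oracles used to cross-check the network-based
# computations. Deliberately naive: string n-grams counted with table(),
# mutual information by enumerating time-stamped edge triples.

# Conditional entropy (nats) of the next symbol given the previous tau+1
# symbols, from raw (tau+2)-gram counts of the sequence.
oracle_block_entropy <- function(symbols, tau) {
  k <- tau + 2L
  n <- length(symbols)
  stopifnot(n >= k)
  win <- vapply(seq_len(n - k + 1L), function(i) {
    paste(symbols[i:(i + k - 1L)], collapse = "\r")
  }, character(1))
  pre <- vapply(seq_len(n - k + 1L), function(i) {
    paste(symbols[i:(i + k - 2L)], collapse = "\r")
  }, character(1))
  cw <- table(win)
  cp <- table(pre)
  pre_of_win <- vapply(strsplit(names(cw), "\r", fixed = TRUE), function(p) {
    paste(p[-length(p)], collapse = "\r")
  }, character(1))
  tot <- sum(cw)
  -sum((cw / tot) * log(cw / as.numeric(cp[pre_of_win])))
}

# Mutual information (bits) of (source-at-t, target-at-t+1) for the two-step
# paths through node v, enumerated directly from the time-stamped edge list.
oracle_bp_mi <- function(gt, v) {
  e <- gt$edges
  pairs <- list()
  for (t in e$time) {
    if (t + 1L > max(e$time)) next
    e1 <- e[e$time == t, ]
    e2 <- e[e$time == t + 1L, ]
    if (e1$target == v && e2$source == v) {
      pairs[[length(pairs) + 1L]] <- as.character(c(e1$source, e2$target))
    }
  }
  if (!length(pairs)) return(NA_real_)
  joint <- table(vapply(pairs, `[`, character(1), 1L),
                 vapply(pairs, `[`, character(1), 2L))
  P <- joint / sum(joint)
  p1 <- rowSums(P)
  p2 <- colSums(P)
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) s <- s + P[i, j] * log2(P[i, j] / (p1[i] * p2[j]))
  }
  as.numeric(s)
}

random_symbols <- function(n, alphabet, seed) {
  withr::with_seed(seed, sample(alphabet, n, replace = TRUE))
}
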