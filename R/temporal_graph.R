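# Temporal network G^T (one time-stamped edge per consecutive sample pair)
# and its time-aggregated weighted directed network G^(0).

#' Build a temporal network from a symbol sequence
#'
#' Every consecutive pair of symbols contributes one time-stamped edge
#' (symbols[t], symbols[t+1]; t), t = 1..n-1 (timestamps are 1-based).
#' Consecutive identical symbols produce self-loop edges; set
#' `collapse_repeats = TRUE` to drop consecutive duplicates first (useful
#' for flows sampled faster than the cell-crossing time). The ordered edge
#' list determines the symbol sequence uniquely, so the mapping between a
#' series and its temporal network is one-to-one.
#'
#' @param symbols a `tm_symbols`, or any atomic vector of cell labels
#'   (integers or characters), length >= 2.
#' @param collapse_repeats drop consecutive duplicate symbols before
#'   building edges.
#' @return An object of class `tm_temporal_network`: list with `edges`
#'   (data.frame `source`, `target`, `time`), `n` (sequence length),
#'   `nodes` (occupied cells), and the originating `partition` when known.
#' @export
temporal_network <- function(symbols, collapse_repeats = FALSE) {
  part <- NULL
  if (inherits(symbols, "tm_symbols")) {
    part <- symbols$partition
    symbols <- symbols$symbols
  }
  if (!is.atomic(symbols)) stop("symbols must be an atomic vector")
  if (collapse_repeats && length(symbols) > 1L) {
    keep <- c(TRUE, symbols[-1L] != symbols[-length(symbols)])
    symbols <- symbols[keep]
  }
  n <- length(symbols)
  if (n < 2L) stop("need at least 2 symbols to form a transition")
  edges <- data.frame(source = symbols[-n], target = symbols[-1L],
                      time = seq_len(n - 1L))
  structure(list(edges = edges, n = n, nodes = sort(unique(symbols)),
                 partition = part),
            class = "tm_temporal_network")
}

#' @export
print.tm_temporal_network <- function(x, ...) {
  cat(sprintf("<tm_temporal_network> %d time-stamped edges over %d nodes\n",
              nrow(x$edges), length(x$nodes)))
  invisible(x)
}

# The symbol sequence encoded by the ordered time-stamped edge list.
tn_symbols <- function(gt) {
  e <- gt$edges
  c(e$source[1L], e$target)
}

#' Time-aggregated weighted network
#'
#' Collapses a temporal network into its null aggregate network: a directed
#' edge (v, w) with weight equal to the number of timestamps at which the
#' transition v -> w occurred. Total weight equals n - 1.
#'
#' @param gt a `tm_temporal_network`.
#' @return An object of class `tm_aggregate`: list with `edges`
#'   (data.frame `source`, `target`, `weight`) and `nodes`.
#' @export
aggregate_network <- function(gt) {
  e <- gt$edges
  lv <- gt$nodes
  from <- match(e$source, lv)
  to <- match(e$target, lv)
  w <- count_pairs(from, to, length(lv))
  edges <- data.frame(source = lv[w$from], target = lv[w$to], weight = w$weight)
  structure(list(edges = edges, nodes = lv), class = "tm_aggregate")
}

#' @export
print.tm_aggregate <- function(x, ...) {
  cat(sprintf("<tm_aggregate> %d weighted edges over %d nodes, total weight %d\n",
              nrow(x$edges), length(x$nodes), sum(x$edges$weight)))
  invisible(x)
}

#' Read and write temporal edge lists
#'
#' Plain TSV with header `source  target  time`, one row per time-stamped
#' edge in temporal order; the round trip is lossless.
#'
#' @param gt a `tm_temporal_network`.
#' @param path file path.
#' @return `read_temporal_edges` returns a `tm_temporal_network`;
#'   `write_temporal_edges` returns `path` invisibly.
#' @export
write_temporal_edges <- function(gt, path) {
  utils::write.table(gt$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_temporal_edges
#' @export
read_temporal_edges <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (!identical(names(raw), c("source", "target", "time"))) {
    stop("expected TSV header: source, target, time")
  }
  tnum <- suppressWarnings(as.numeric(raw$time))
  bad <- which(!is.finite(tnum) | tnum != round(tnum))
  if (length(bad)) {
    stop(sprintf("malformed time field at line %d", bad[1L] + 1L))
  }
  t <- as.integer(tnum)
  if (!identical(t, seq_len(length(t)))) {
    stop("timestamps must be the consecutive integers 1..n-1")
  }
  chain_ok <- length(t) < 2L ||
    all(raw$source[-1L] == raw$target[-length(t)])
  if (!chain_ok) stop("edge list is not a single trajectory chain")
  sym <- c(raw$source[1L], raw$target)
  num <- suppressWarnings(as.integer(sym))
  if (!anyNA(num)) sym <- num
  temporal_network(sym)
}
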