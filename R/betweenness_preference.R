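# Betweenness preference: does a node route incoming flows to preferred
# targets? Quantified per node by the mutual information (in bits) between
# the source and destination of the two-step time-respecting paths through
# it.

#' Betweenness preference matrix of a node
#'
#' B^v[w1, w2] counts the timestamps t at which the time-stamped edge
#' (w1, v; t) is immediately followed by (v, w2; t+1), i.e. the traversals
#' w1 -> v -> w2. Rows and columns are indexed by v's observed in- and
#' out-neighbors in the aggregate network, so rows or columns may be all
#' zero (e.g. an in-edge arriving only at the final timestamp).
#'
#' @param gt a `tm_temporal_network`.
#' @param v a node (cell label) occurring in `gt`.
#' @return An integer count matrix with in-neighbors as rows and
#'   out-neighbors as columns; all zero when v is never traversed.
#' @export
betweenness_matrix <- function(gt, v) {
  s <- tn_symbols(gt)
  n <- length(s)
  if (!v %in% s) stop("node not present in the temporal network")
  in_nb <- sort(unique(s[which(s[-1L] == v)]))          # u with edge u -> v
  out_nb <- sort(unique(s[which(s[-n] == v) + 1L]))     # w with edge v -> w
  B <- matrix(0L, nrow = length(in_nb), ncol = length(out_nb),
              dimnames = list(as.character(in_nb), as.character(out_nb)))
  if (n >= 3L) {
    mid <- which(s[2:(n - 1L)] == v)                    # t with s[t+1] = v
    if (length(mid)) {
      i <- match(s[mid], in_nb)
      j <- match(s[mid + 2L], out_nb)
      for (k in seq_along(mid)) B[i[k], j[k]] <- B[i[k], j[k]] + 1L
    }
  }
  B
}

#' Betweenness preference score of a node
#'
#' The mutual information I^v (base 2 by default, in bits) of the joint
#' distribution P = B^v / sum(B^v) against the product of its marginals:
#' I^v = sum P(w1, w2) log2[ P(w1, w2) / (P1(w1) P2(w2)) ], with
#' 0 log 0 = 0. I^v = 0 whenever the node has a single observed in- or
#' out-neighbor, and for every node of a periodic series. Nodes that are
#' never traversed (sum(B^v) = 0) are degenerate and get NA.
#'
#' @inheritParams betweenness_matrix
#' @param base logarithm base (2 gives bits).
#' @param normalized divide by min(H(P1), H(P2)) (a non-standard variant;
#'   0 when that entropy is 0).
#' @return The score, or NA for a degenerate node.
#' @export
betweenness_preference <- function(gt, v, base = 2, normalized = FALSE) {
  B <- betweenness_matrix(gt, v)
  score_bp_matrix(B, base = base, normalized = normalized)
}

score_bp_matrix <- function(B, base = 2, normalized = FALSE) {
  tot <- sum(B)
  if (tot == 0) return(NA_real_)
  I <- mi_from_counts(B, base = base)
  if (normalized) {
    P <- B / tot
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p, base = base)) }
    hmin <- min(ent(rowSums(P)), ent(colSums(P)))
    I <- if (hmin > 0) I / hmin else 0
  }
  I
}

#' Betweenness preference of every node
#'
#' Computes I^v for every node traversed at least once (an in-edge followed
#' by an out-edge); nodes never traversed are reported separately as
#' degenerate. Forced-zero nodes (single in- or out-neighbor) are included
#' with I = 0.
#'
#' @inheritParams betweenness_preference
#' @return A data.frame of class `tm_bp_distribution` with columns `node`,
#'   `I`, and `n_traversals`; the excluded degenerate nodes are in
#'   attribute `"degenerate"`.
#' @export
bp_distribution <- function(gt, base = 2, normalized = FALSE) {
  s <- tn_symbols(gt)
  n <- length(s)
  nodes <- gt$nodes
  res <- lapply(nodes, function(v) {
    B <- betweenness_matrix(gt, v)
    data.frame(node = v, I = score_bp_matrix(B, base, normalized),
               n_traversals = sum(B))
  })
  out <- do.call(rbind, res)
  degen <- out$node[is.na(out$I)]
  out <- out[!is.na(out$I), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degen
  class(out) <- c("tm_bp_distribution", "data.frame")
  out
}

#' Spatial map of betweenness preference
#'
#' Attaches the phase-space cell-center coordinates of each scored node,
#' for colour-coded attractor plots of where routing preference
#' concentrates.
#'
#' @param bp a `tm_bp_distribution` whose nodes are cell indices of `part`.
#' @param part the `tm_partition` the network's symbols came from.
#' @return A data.frame with m center-coordinate columns followed by `I`
#'   and `n_traversals`.
#' @export
bp_spatial_map <- function(bp, part) {
  cells <- suppressWarnings(as.integer(bp$node))
  if (anyNA(cells) || any(cells < 1L) || any(cells > part$n_cells)) {
    stop("nodes are not valid cell indices of this partition")
  }
  cbind(as.data.frame(cell_centers(part, cells)),
        I = bp$I, n_traversals = bp$n_traversals)
}
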