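# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: components by hand-written BFS, CAR moments by
# dense linear algebra, graphs by brute-force enumeration.

# connected-component partition by breadth-first search over a neighbor list
bfs_components <- function(neighbors) {
  n <- length(neighbors)
  lab <- integer(n)
  nxt <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in neighbors[[v]]) {
        if (lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# all connected labelled simple graphs on n nodes, as adjacency matrices
enumerate_connected_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    A <- matrix(0, n, n)
    for (k in seq_len(m)) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L) {
        A[pairs[1, k], pairs[2, k]] <- A[pairs[2, k], pairs[1, k]] <- 1
      }
    }
    nb <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
    if (max(bfs_components(nb)) == 1L) out[[length(out) + 1L]] <- A
  }
  out
}

# conditional mean/variance of component i of a zero-mean MVN with the given
# (possibly improper) precision matrix, by dense linear algebra
dense_mvn_conditional <- function(P, x, i) {
  list(mean = -sum(P[i, -i] * x[-i]) / P[i, i], variance = 1 / P[i, i])
}

graph_from_adjmat <- function(A, ids = sprintf("n%02d", seq_len(nrow(A)))) {
  adjacency_graph(ids, lapply(seq_len(nrow(A)), function(i) which(A[i, ] == 1)))
}

# axis-aligned unit-square polygon with lower-left corner (x, y)
unit_square <- function(x, y) {
  rbind(c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1), c(x, y))
}
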