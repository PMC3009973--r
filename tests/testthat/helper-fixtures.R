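# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (plain-R loops, Floyd-Warshall) so they do
# not share code paths with the package implementation.

path_map <- function(n, prefix = "v") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  cell_map(data.frame(a = ids[-n], b = ids[-1]), name = "path")
}

triangle_map <- function() {
  cell_map(data.frame(a = c("a", "b", "a"), b = c("b", "c", "c")))
}

# Erdos-Renyi edge table built with base R only (no igraph)
random_edges <- function(n, p, seed, prefix = "n") {
  set.seed(seed)
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(a = ids[pairs[keep, 1]], b = ids[pairs[keep, 2]],
             stringsAsFactors = FALSE)
}

# Floyd-Warshall all-pairs shortest paths on an undirected unit-length edge
# list; returns a matrix indexed by node id (Inf where unreachable)
floyd_warshall <- function(ids, edges) {
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$a[r], ids); j <- match(edges$b[r], ids)
    D[i, j] <- 1; D[j, i] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# naive set-distance statistics from a full distance matrix (loop form)
oracle_set_stats <- function(D, A, B) {
  fwd <- vapply(A, function(a) min(D[a, B]), numeric(1))
  rev <- vapply(B, function(b) min(D[b, A]), numeric(1))
  list(pooled_mean = mean(c(fwd, rev)),
       mean_of_means = (mean(fwd) + mean(rev)) / 2,
       min_pairwise = min(vapply(A, function(a) min(D[a, B]), numeric(1))))
}

# a hand-built embedding2d for density tests that need known coordinates
manual_embedding <- function(x, y, ids = sprintf("p%04d", seq_along(x))) {
  structure(list(coords = tibble::tibble(id = ids, x = x, y = y),
                 stress = 0, excluded = character(0),
                 method = "classical", seed = 1L),
            class = "embedding2d")
}

# naive recursive flood fill (4-connectivity) labelling of a logical matrix
oracle_label4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        c0 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        ci <- c0[1]; cj <- c0[2]
        if (ci < 1 || cj < 1 || ci > nrow(mask) || cj > ncol(mask)) next
        if (!mask[ci, cj] || lab[ci, cj] != 0L) next
        lab[ci, cj] <- cur
        stack <- c(stack, list(c(ci - 1, cj), c(ci + 1, cj),
                               c(ci, cj - 1), c(ci, cj + 1)))
      }
    }
  }
  lab
}
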