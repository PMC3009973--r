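#' Two-dimensional geodesic embedding of a map
#'
#' Projects the map into the plane so that proteins separated by few jumps
#' plot close together: all-pairs jump distances are computed on the largest
#' connected component and embedded by classical (Torgerson) multidimensional
#' scaling — double centering of the squared geodesic distance matrix
#' followed by the top-2 eigenvectors, the Isomap construction. The result is
#' centred at the origin and its orientation is fixed by a deterministic sign
#' convention: each axis is flipped, if needed, so that the coordinate of the
#' lexicographically smallest protein id is nonnegative. Classical MDS is
#' fully deterministic; `seed` only matters for the iterative `"sammon"`
#' refinement, which is itself initialised from the classical solution and
#' therefore also deterministic (the argument is recorded for provenance).
#'
#' Proteins outside the largest component are excluded and listed in the
#' result rather than placed at an arbitrary distance.
#'
#' @param map a [cell_map()] whose largest component has at least 2 nodes.
#' @param method `"classical"` (default) or `"sammon"` (iterative
#'   least-squares refinement of the classical solution via [MASS::sammon()]).
#' @param seed integer recorded in the result.
#' @return An object of class `embedding2d`: `coords` (tibble `id`, `x`,
#'   `y`), `stress` (normalised residual between embedded and geodesic
#'   distances), `excluded` (ids outside the largest component), `method`,
#'   `seed`.
#' @examples
#' m <- cell_map(data.frame(a = c("a", "b"), b = c("b", "c")))
#' geodesic_mds(m)$coords
#' @export
geodesic_mds <- function(map, method = c("classical", "sammon"), seed = 1L) {
  stopifnot(inherits(map, "cell_map"))
  method <- match.arg(method)
  lc <- quiet_largest_component(map)
  if (nrow(lc$nodes) < 2) abort("largest component has fewer than 2 nodes")
  excluded <- setdiff(map$nodes$id, lc$nodes$id)

  D <- igraph::distances(lc$graph, mode = "all")
  ids <- rownames(D)
  fit <- suppressWarnings(cmdscale(D, k = min(2L, nrow(D) - 1L), eig = FALSE))
  if (ncol(fit) < 2) fit <- cbind(fit, matrix(0, nrow(fit), 2 - ncol(fit)))
  if (method == "sammon") {
    fit <- withr::with_seed(as.integer(seed), {
      MASS::sammon(D, y = jitter_free(fit), trace = FALSE)$points
    })
  }
  # exact centering, then the deterministic orientation rule
  fit <- sweep(fit, 2, colMeans(fit))
  ref <- match(min_id_clocale(ids), ids)
  for (j in 1:2) if (fit[ref, j] < 0) fit[, j] <- -fit[, j]

  emb_d <- stats::dist(fit)
  geo_d <- stats::as.dist(D)
  stress <- sqrt(sum((emb_d - geo_d)^2) / sum(geo_d^2))

  structure(list(
    coords = tibble(id = ids, x = unname(fit[, 1]), y = unname(fit[, 2])),
    stress = stress, excluded = excluded,
    method = method, seed = as.integer(seed)
  ), class = "embedding2d")
}

# sammon() refuses duplicate configurations; nudge exact ties apart
# deterministically (by rank order) before refinement
jitter_free <- function(y) {
  key <- paste(y[, 1], y[, 2])
  dup <- duplicated(key)
  if (any(dup)) y[dup, 1] <- y[dup, 1] + 1e-8 * seq_len(sum(dup))
  y
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %s MDS of %d proteins, stress %.4f (%d excluded)\n",
              x$method, nrow(x$coords), x$stress, length(x$excluded)))
  invisible(x)
}

#' Tidy / summarise an embedding
#' @param x an [geodesic_mds()] result.
#' @param ... unused.
#' @return `tidy()`: the coordinates tibble; `glance()`: one row with
#'   `method`, `n`, `stress`, `n_excluded`.
#' @method tidy embedding2d
#' @export
tidy.embedding2d <- function(x, ...) x$coords

#' @rdname tidy.embedding2d
#' @method glance embedding2d
#' @export
glance.embedding2d <- function(x, ...) {
  tibble(method = x$method, n = nrow(x$coords), stress = x$stress,
         n_excluded = length(x$excluded))
}

#' How well the embedding preserves jump distances
#'
#' Spearman rank correlation between the jump distance and the Euclidean
#' embedded distance over a seeded sample of node pairs — the quantitative
#' check behind the claim that proteins closer in the map plot closer in 2D.
#'
#' @param embedding an [geodesic_mds()] result.
#' @param map the [cell_map()] it was computed from.
#' @param n_pairs number of node pairs to sample.
#' @param seed RNG seed for the pair sample.
#' @return A one-row tibble: `spearman` (NA with a note if fewer than 2
#'   usable pairs), `n_pairs`, `note`.
#' @export
distance_preservation <- function(embedding, map, n_pairs = 1000, seed = 1L) {
  stopifnot(inherits(embedding, "embedding2d"), inherits(map, "cell_map"))
  co <- embedding$coords
  n <- nrow(co)
  total <- n * (n - 1) / 2
  n_pairs <- min(n_pairs, total)
  if (n_pairs < 2) {
    return(tibble(spearman = NA_real_, n_pairs = as.integer(n_pairs),
                  note = "correlation undefined for fewer than 2 pairs"))
  }
  pk <- withr::with_seed(as.integer(seed), sample.int(total, n_pairs))
  # unrank the sampled upper-triangle indices (column-major over i < j)
  j <- ceiling((1 + sqrt(1 + 8 * pk)) / 2)
  i <- pk - (j - 1) * (j - 2) / 2
  src <- unique(co$id[i])
  D <- igraph::distances(map$graph, v = src, to = co$id[unique(j)] , mode = "all")
  gd <- D[cbind(match(co$id[i], src), match(co$id[j], colnames(D)))]
  ed <- sqrt((co$x[i] - co$x[j])^2 + (co$y[i] - co$y[j])^2)
  if (sd(gd) == 0 || sd(ed) == 0) {
    return(tibble(spearman = NA_real_, n_pairs = as.integer(n_pairs),
                  note = "correlation undefined: constant distances"))
  }
  tibble(spearman = suppressWarnings(cor(gd, ed, method = "spearman")),
         n_pairs = as.integer(n_pairs), note = NA_character_)
}
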