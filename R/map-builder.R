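#' Build a condition map by recursive expansion from seed proteins
#'
#' Starting from the seed proteins, the map incorporates all known
#' relationships of the current frontier, one recursion step at a time: after
#' `depth` steps the map is the induced subgraph of the universe on all
#' proteins within `depth` jumps of any seed, including *all* universe edges
#' among the included proteins (induced closure, not just the expansion
#' tree). Seed nodes are flagged `is_seed`; seeds absent from the universe
#' are kept as isolated seed nodes (with a warning) so presence statistics
#' against the seed list stay well defined.
#'
#' @param seeds nonempty character vector of seed accessions.
#' @param store the relationship universe, a [cell_map()] (any graph reader
#'   returns one).
#' @param depth number of expansion steps (nonnegative integer). Depth 0
#'   keeps only the seeds and the universe edges among them.
#' @param name name of the resulting map.
#' @return A [cell_map()] with seed nodes flagged.
#' @examples
#' uni <- cell_map(data.frame(a = c("h", "h"), b = c("l1", "l2")))
#' build_map("l1", uni, depth = 1)
#' @export
build_map <- function(seeds, store, depth = 1, name = "condition_map") {
  stopifnot(inherits(store, "cell_map"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) abort("empty node set")
  if (depth < 0) abort("depth must be nonnegative")
  in_universe <- intersect(seeds, store$nodes$id)
  absent <- setdiff(seeds, in_universe)
  if (length(absent) > 0) {
    warn(paste0(length(absent), " seed(s) absent from the universe kept as isolated nodes"))
  }
  keep <- character(0)
  if (length(in_universe) > 0) {
    d <- jumps_from_set(store$graph, in_universe)
    keep <- names(d)[is.finite(d) & d <= depth]
  }
  ids <- union(keep, seeds)
  edges <- store$edges[store$edges$a %in% ids & store$edges$b %in% ids, , drop = FALSE]
  nodes <- tibble(id = sort(ids), is_seed = sort(ids) %in% seeds)
  cell_map(edges = edges, nodes = nodes, name = name)
}

#' Growth profile of the recursive expansion
#'
#' Summarises the map that [build_map()] would return at every depth from 0
#' to `max_depth`, so users can pick an expansion depth producing a map of
#' the intended size.
#'
#' @inheritParams build_map
#' @param max_depth largest depth to profile.
#' @return A tibble with columns `depth`, `n_nodes`, `n_edges`, `n_seeds`;
#'   counts are nondecreasing in depth.
#' @export
expansion_profile <- function(seeds, store, max_depth = 3) {
  stopifnot(inherits(store, "cell_map"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) abort("empty node set")
  if (max_depth < 0) abort("depth must be nonnegative")
  in_universe <- intersect(seeds, store$nodes$id)
  if (length(setdiff(seeds, in_universe)) > 0) {
    warn(paste0(length(setdiff(seeds, in_universe)),
                " seed(s) absent from the universe kept as isolated nodes"))
  }
  d <- if (length(in_universe) > 0) jumps_from_set(store$graph, in_universe) else numeric(0)
  extra <- length(setdiff(seeds, in_universe))  # isolated absent seeds, present at every depth
  e <- store$edges
  de <- pmax(d[e$a], d[e$b])  # edge enters the induced map once both endpoints are in
  bind_rows(lapply(0:max_depth, function(k) {
    node_ids <- names(d)[is.finite(d) & d <= k]
    tibble(depth = k,
           n_nodes = length(node_ids) + extra,
           n_edges = sum(is.finite(de) & de <= k),
           n_seeds = length(seeds))
  }))
}
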