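#' Construct a cell map
#'
#' A cell map is an undirected, typed protein-relationship graph: nodes are
#' proteins (identified by accession), edges are known relationships of one or
#' more of three types (`interactome`, `metabolome`, `signaling_other`).
#' Self-loops are dropped at construction (they cannot affect jump distances)
#' and parallel records for the same unordered protein pair are merged, taking
#' the union of their relationship types.
#'
#' @param edges a data frame with character columns `a` and `b` (protein
#'   accessions) and optionally `type` (a single relationship type per row) or
#'   `types` (a list column of type sets), and `provenance` (free-text source
#'   tag). May have zero rows.
#' @param nodes optional data frame with columns `id` and optionally `is_seed`
#'   (logical). Defaults to the edge endpoints, none flagged as seed. Node ids
#'   not appearing in `edges` become isolated nodes.
#' @param name map name, carried through summaries and files.
#'
#' @return An object of class `cell_map` with tibble accessors
#'   [map_nodes()] and [map_edges()].
#' @examples
#' m <- cell_map(data.frame(a = c("P1", "P2"), b = c("P2", "P3"),
#'                          type = "interactome"))
#' map_summary(m)
#' @export
cell_map <- function(edges = NULL, nodes = NULL, name = "cell_map") {
  if (is.null(edges)) {
    edges <- tibble(a = character(), b = character(), types = list())
  }
  edges <- as_tibble(edges)
  if (!all(c("a", "b") %in% names(edges))) {
    abort("`edges` must have columns `a` and `b`")
  }
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  if ("types" %in% names(edges)) {
    edges$types <- lapply(edges$types, as.character)
  } else if ("type" %in% names(edges)) {
    edges$types <- as.list(as.character(edges$type))
    edges$type <- NULL
  } else {
    edges$types <- rep(list("interactome"), nrow(edges))
  }
  if (!"provenance" %in% names(edges)) edges$provenance <- rep(NA_character_, nrow(edges))

  bad <- setdiff(unique(unlist(edges$types)), RELATION_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown relationship type(s): ", paste(bad, collapse = ", ")))
  }
  if (nrow(edges) > 0 && any(!nzchar(edges$a) | !nzchar(edges$b))) {
    abort("protein ids must be nonempty strings")
  }

  loops <- edges$a == edges$b
  if (any(loops)) {
    warn(paste0("dropped ", sum(loops), " self-loop record(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }

  # canonical unordered pair, then merge parallel records (union of types)
  u <- pmin(edges$a, edges$b)
  v <- pmax(edges$a, edges$b)
  edges$a <- u
  edges$b <- v
  if (nrow(edges) > 0) {
    key <- paste(edges$a, edges$b, sep = "\r")
    if (anyDuplicated(key)) {
      split_idx <- split(seq_len(nrow(edges)), key)
      merged <- lapply(split_idx, function(i) {
        list(a = edges$a[i[1]], b = edges$b[i[1]],
             types = sort(unique(unlist(edges$types[i]))),
             provenance = {
               pv <- unique(edges$provenance[i])
               pv <- pv[!is.na(pv)]
               if (length(pv) == 0) NA_character_ else paste(pv, collapse = ";")
             })
      })
      edges <- tibble(
        a = unname(map_chr(merged, "a")), b = unname(map_chr(merged, "b")),
        types = unname(map(merged, "types")),
        provenance = unname(map_chr(merged, "provenance"))
      )
    } else {
      edges$types <- lapply(edges$types, function(t) sort(unique(t)))
    }
    edges <- arrange(edges, .data$a, .data$b)
  }

  endpoint_ids <- unique(c(edges$a, edges$b))
  if (is.null(nodes)) {
    nodes <- tibble(id = sort(endpoint_ids), is_seed = FALSE)
  } else {
    nodes <- as_tibble(nodes)
    if (!"id" %in% names(nodes)) abort("`nodes` must have a column `id`")
    nodes$id <- as.character(nodes$id)
    if (!"is_seed" %in% names(nodes)) nodes$is_seed <- FALSE
    if (any(!nzchar(nodes$id))) abort("protein ids must be nonempty strings")
    if (anyDuplicated(nodes$id)) abort("node ids must be unique within a map")
    missing <- setdiff(endpoint_ids, nodes$id)
    if (length(missing) > 0) {
      nodes <- bind_rows(nodes, tibble(id = missing, is_seed = FALSE))
    }
    nodes <- arrange(nodes, .data$id)
  }

  graph <- igraph::graph_from_data_frame(
    d = edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = nodes$id, stringsAsFactors = FALSE)
  )

  structure(
    list(nodes = nodes, edges = edges, graph = graph, name = name),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  s <- map_summary(x)
  cat(sprintf("<cell_map> %s: %d proteins, %d relationships (%d seed, %d component%s)\n",
              x$name, s$n_nodes, s$n_edges, s$n_seeds, s$n_components,
              if (s$n_components == 1) "" else "s"))
  invisible(x)
}

#' Node and edge tables of a cell map
#'
#' @param map a [cell_map()].
#' @return A tibble of nodes (`id`, `is_seed`) or edges (`a`, `b`, `types`,
#'   `provenance`).
#' @export
map_nodes <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  map$nodes
}

#' @rdname map_nodes
#' @export
map_edges <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  map$edges
}

#' Seed protein ids of a map
#' @param map a [cell_map()].
#' @return character vector of seed accessions.
#' @export
map_seeds <- function(map) {
  map$nodes$id[map$nodes$is_seed]
}

# induced subgraph on a set of ids, preserving seed flags and edge types
subset_map <- function(map, ids, name = map$name) {
  keep <- map$nodes$id %in% ids
  nodes <- map$nodes[keep, , drop = FALSE]
  edges <- map$edges[map$edges$a %in% ids & map$edges$b %in% ids, , drop = FALSE]
  cell_map(edges = edges, nodes = nodes, name = name)
}

#' Minimum jump distances from a set of source proteins
#'
#' Breadth-first search on the undirected, unweighted view of the map: a
#' "jump" is one edge traversal. Every source maps to 0; nodes unreachable
#' from all sources are absent from the result.
#'
#' @param map a [cell_map()].
#' @param sources character vector of source protein ids, all present in the
#'   map.
#' @return A tibble with columns `id` and `jumps` (integer), one row per
#'   reachable node.
#' @examples
#' m <- cell_map(data.frame(a = c("v1", "v2"), b = c("v2", "v3")))
#' bfs_jumps(m, "v1")
#' @export
bfs_jumps <- function(map, sources) {
  stopifnot(inherits(map, "cell_map"))
  sources <- unique(as.character(sources))
  if (length(sources) == 0) abort("empty node set")
  missing <- setdiff(sources, map$nodes$id)
  if (length(missing) > 0) {
    abort(paste0("source protein(s) not in map: ", paste(missing, collapse = ", ")))
  }
  d <- jumps_from_set(map$graph, sources)
  keep <- is.finite(d)
  tibble(id = names(d)[keep], jumps = as.integer(d[keep]))
}

# named numeric vector of min jump distance from any source to every vertex
# (Inf where unreachable)
jumps_from_set <- function(graph, sources) {
  m <- igraph::distances(graph, v = sources, mode = "all")
  res <- m[1, ]
  if (nrow(m) > 1) for (i in 2:nrow(m)) res <- pmin(res, m[i, ])
  res
}

#' Restrict a map to its largest connected component
#'
#' Ties between equally large components are broken in favour of the
#' component containing the lexicographically smallest protein id. The number
#' of dropped nodes is reported as a message.
#'
#' @param map a nonempty [cell_map()].
#' @return A [cell_map()] induced on the largest component.
#' @export
largest_component <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  if (nrow(map$nodes) == 0) abort("empty map")
  comp <- igraph::components(map$graph)
  if (comp$no == 1) return(map)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  ids <- igraph::V(map$graph)$name
  if (length(cand) > 1) {
    # representative = smallest member id, compared in C locale
    reps <- map_chr(cand, function(ci) {
      min_id_clocale(ids[comp$membership == ci])
    })
    cand <- cand[order_clocale(reps)[1]]
  }
  keep <- ids[comp$membership == cand]
  inform(paste0("largest_component: dropped ", nrow(map$nodes) - length(keep),
                " node(s) outside the largest component"))
  subset_map(map, keep)
}

# locale-independent lexicographic helpers (radix sort = C locale)
order_clocale <- function(x) order(x, method = "radix")
min_id_clocale <- function(x) x[order_clocale(x)[1]]

#' Summarise a cell map
#'
#' @param map a [cell_map()].
#' @return A one-row tibble: `name`, `n_nodes`, `n_edges`, `n_seeds`, degree
#'   quartiles (`deg_q1`, `deg_median`, `deg_q3`; each neighbour counted once
#'   regardless of how many relationship types the edge carries) and
#'   `n_components`.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  n_nodes <- nrow(map$nodes)
  if (n_nodes == 0) {
    return(tibble(name = map$name, n_nodes = 0L, n_edges = 0L, n_seeds = 0L,
                  deg_q1 = NA_real_, deg_median = NA_real_, deg_q3 = NA_real_,
                  n_components = 0L))
  }
  deg <- igraph::degree(map$graph)
  q <- unname(quantile(deg, c(0.25, 0.5, 0.75)))
  tibble(
    name = map$name,
    n_nodes = n_nodes,
    n_edges = nrow(map$edges),
    n_seeds = sum(map$nodes$is_seed),
    deg_q1 = q[1], deg_median = q[2], deg_q3 = q[3],
    n_components = igraph::components(map$graph)$no
  )
}
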