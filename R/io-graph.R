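#' Read and write protein-relationship graphs
#'
#' Three on-disk dialects are supported and round-trip losslessly (node ids,
#' edge set and relationship type sets are preserved exactly):
#'
#' * SIF: `node <TAB> relation <TAB> node [node ...]`, one line per relation
#'   type; an edge carrying several types appears on several lines.
#' * 3-column TSV: header `a  type  b`, one row per (edge, type).
#' * GraphML via igraph, with the type set collapsed into a `types` edge
#'   attribute (`|`-separated) and `is_seed` as a node attribute.
#'
#' @param path file path.
#' @param name map name for the returned object.
#' @return A [cell_map()].
#' @export
read_sif <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(cell_map(name = name))
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) return(tibble(a = f[1], type = NA_character_, b = NA_character_))
    if (length(f) < 3) abort(paste0("malformed SIF line ", i, ": ", lines[[i]]))
    tibble(a = f[1], type = f[2], b = f[3:length(f)])
  })
  recs <- bind_rows(recs)
  isolated <- recs$a[is.na(recs$b)]
  recs <- recs[!is.na(recs$b), , drop = FALSE]
  nodes <- tibble(id = sort(unique(c(recs$a, recs$b, isolated))), is_seed = FALSE)
  cell_map(edges = recs, nodes = nodes, name = name)
}

#' @rdname read_sif
#' @param map a [cell_map()].
#' @export
write_sif <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  e <- map$edges
  lines <- character(0)
  if (nrow(e) > 0) {
    lines <- unlist(lapply(seq_len(nrow(e)), function(i) {
      paste(e$a[i], e$types[[i]], e$b[i], sep = "\t")
    }))
  }
  isolated <- setdiff(map$nodes$id, c(e$a, e$b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' @rdname read_sif
#' @export
read_edge_tsv <- function(path, name = basename(path)) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("a", "type", "b") %in% names(df))) {
    abort("edge TSV must have columns a, type, b")
  }
  cell_map(edges = df[, c("a", "type", "b")], name = name)
}

#' @rdname read_sif
#' @export
write_edge_tsv <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  e <- tidyr::unnest(
    mutate(map$edges, type = .data$types), c("type")
  )
  readr::write_tsv(e[, c("a", "type", "b")], path, progress = FALSE)
  invisible(path)
}

#' @rdname read_sif
#' @export
write_graphml <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  g <- map$graph
  igraph::V(g)$is_seed <- as.integer(map$nodes$is_seed[match(igraph::V(g)$name, map$nodes$id)])
  igraph::E(g)$types <- map_chr(map$edges$types, paste, collapse = "|")
  pv <- map$edges$provenance
  igraph::E(g)$provenance <- ifelse(is.na(pv), "", pv)
  igraph::graph_attr(g, "name") <- map$name
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname read_sif
#' @export
read_graphml <- function(path, name = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  types <- igraph::edge_attr(g, "types") %||% rep("interactome", nrow(el))
  pv <- igraph::edge_attr(g, "provenance") %||% rep(NA_character_, nrow(el))
  pv[!is.na(pv) & !nzchar(pv)] <- NA_character_
  edges <- tibble(a = el[, 1], b = el[, 2],
                  types = strsplit(types, "|", fixed = TRUE),
                  provenance = pv)
  is_seed <- igraph::vertex_attr(g, "is_seed") %||% rep(0, igraph::vcount(g))
  nodes <- tibble(id = igraph::V(g)$name, is_seed = as.logical(is_seed))
  nm <- name %||% (igraph::graph_attr(g, "name") %||% basename(path))
  cell_map(edges = edges, nodes = nodes, name = nm)
}

# dispatch on extension
read_map_auto <- function(path, name = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    sif = read_sif(path, name = name),
    graphml = read_graphml(path, name = name),
    tsv = read_edge_tsv(path, name = name),
    txt = read_edge_tsv(path, name = name),
    abort(paste0("unrecognised graph file extension: .", ext))
  )
}

#' Read a seed protein list
#'
#' Plain text, one accession per line; `#` starts a comment; blank lines are
#' ignored.
#'
#' @param path file path.
#' @return character vector of accessions.
#' @export
read_seed_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @rdname read_seed_list
#' @param ids character vector of accessions.
#' @export
write_seed_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
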