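#' Direct links between seed and effector proteins
#'
#' Enumerates every map edge with one endpoint among the effectors and the
#' other among the seeds — the "direct relationships (1 jump)" of the
#' protein-level analysis. One protein can establish more than one relation;
#' a protein belonging to both sets contributes through each of its
#' qualifying incident edges (an edge inside the intersection is reported in
#' both orientations).
#'
#' @param map a [cell_map()].
#' @param seeds,effector_ids nonempty character vectors of protein ids.
#' @return An object of class `link_report`: `direct_edges` (tibble
#'   `effector`, `seed`, `types`, ordered by effector then seed), `n_direct`,
#'   `n_effectors_involved`, `n_seeds_involved`. [k_jump_links()] adds the
#'   k-jump fields.
#' @export
direct_links <- function(map, seeds, effector_ids) {
  stopifnot(inherits(map, "cell_map"))
  seeds <- unique(as.character(seeds))
  effector_ids <- unique(as.character(effector_ids))
  if (length(seeds) == 0 || length(effector_ids) == 0) abort("empty node set")
  e <- map$edges
  ab <- e[e$a %in% effector_ids & e$b %in% seeds, , drop = FALSE]
  ba <- e[e$b %in% effector_ids & e$a %in% seeds, , drop = FALSE]
  de <- bind_rows(
    tibble(effector = ab$a, seed = ab$b, types = ab$types),
    tibble(effector = ba$b, seed = ba$a, types = ba$types)
  )
  de <- distinct(de, .data$effector, .data$seed, .keep_all = TRUE)
  de <- de[order_clocale2(de$effector, de$seed), , drop = FALSE]
  structure(list(
    direct_edges = de,
    n_direct = nrow(de),
    n_effectors_involved = length(unique(de$effector)),
    n_seeds_involved = length(unique(de$seed)),
    k = NULL, k_jump_pairs = NULL, n_relationships = NULL
  ), class = "link_report")
}

order_clocale2 <- function(a, b) order(a, b, method = "radix")

#' Seed-effector pairs within k jumps
#'
#' All (effector, seed) pairs of distinct proteins whose jump distance in
#' the map is at most `k`, annotated with the distance — the protein-level
#' "relationships" count at a configurable radius. Pairs at distance 1
#' coincide with the endpoint pairs of [direct_links()].
#'
#' @inheritParams direct_links
#' @param k maximum number of jumps (at least 1). Default 2.
#' @return A `link_report` with both the direct fields and `k`,
#'   `k_jump_pairs` (tibble `effector`, `seed`, `jumps`), `n_relationships`.
#' @export
k_jump_links <- function(map, seeds, effector_ids, k = 2) {
  if (k < 1) abort("k must be at least 1")
  rep_ <- direct_links(map, seeds, effector_ids)
  seeds <- unique(as.character(seeds))
  effector_ids <- unique(as.character(effector_ids))
  e_in <- intersect(effector_ids, map$nodes$id)
  s_in <- intersect(seeds, map$nodes$id)
  pairs <- tibble(effector = character(), seed = character(), jumps = integer())
  if (length(e_in) > 0 && length(s_in) > 0) {
    D <- igraph::distances(map$graph, v = e_in, to = s_in, mode = "all")
    hit <- which(D >= 1 & D <= k, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pairs <- tibble(effector = e_in[hit[, 1]], seed = s_in[hit[, 2]],
                      jumps = as.integer(D[hit]))
      pairs <- pairs[order_clocale2(pairs$effector, pairs$seed), , drop = FALSE]
    }
  }
  rep_$k <- as.integer(k)
  rep_$k_jump_pairs <- pairs
  rep_$n_relationships <- nrow(pairs)
  rep_
}

#' @export
print.link_report <- function(x, ...) {
  cat(sprintf("<link_report> %d direct link(s) between %d effector(s) and %d seed(s)",
              x$n_direct, x$n_effectors_involved, x$n_seeds_involved))
  if (!is.null(x$k)) {
    cat(sprintf("; %d relationship(s) within %d jump(s)", x$n_relationships, x$k))
  }
  cat("\n")
  invisible(x)
}

#' Tidy / summarise a link report
#' @param x a `link_report`.
#' @param ... unused.
#' @return `tidy()`: the k-jump pair table if present, else the direct-edge
#'   table; `glance()`: one row of the counts.
#' @method tidy link_report
#' @export
tidy.link_report <- function(x, ...) {
  if (!is.null(x$k_jump_pairs)) x$k_jump_pairs else x$direct_edges
}

#' @rdname tidy.link_report
#' @method glance link_report
#' @export
glance.link_report <- function(x, ...) {
  tibble(n_direct = x$n_direct,
         n_effectors_involved = x$n_effectors_involved,
         n_seeds_involved = x$n_seeds_involved,
         k = x$k %||% NA_integer_,
         n_relationships = x$n_relationships %||% NA_integer_)
}

#' Per-motive breakdown of direct links
#'
#' Attributes each direct link to the motive(s) of its effector protein: a
#' link whose effector belongs to several motives is counted once per motive
#' (flagged in `multi_motive`). Effectors with no motive are bucketed under
#' `"unassigned"` with a warning. Percentages are floors of
#' `100 * count / n_direct`.
#'
#' @param report a [direct_links()] or [k_jump_links()] result.
#' @param db a [condition_db()].
#' @param condition the condition whose motives partition the effectors.
#' @return A tibble: `motive`, `n_direct`, `pct` (integer floor),
#'   `multi_motive` (count of links counted in more than one motive).
#' @export
motive_breakdown <- function(report, db, condition) {
  stopifnot(inherits(report, "link_report"), inherits(db, "condition_db"))
  motives <- unique(db$motive[db$condition == condition])
  if (length(motives) == 0) abort(paste0("unknown condition: ", condition))
  de <- report$direct_edges
  memb <- db[db$condition == condition, c("motive", "protein")]
  n_motives_of <- table(factor(memb$protein[memb$protein %in% de$effector]))
  assigned <- left_join(de, memb, by = c(effector = "protein"),
                        relationship = "many-to-many")
  unass <- is.na(assigned$motive)
  if (any(unass)) {
    warn(paste0(length(unique(assigned$effector[unass])),
                " effector(s) with no motive bucketed as unassigned"))
    assigned$motive[unass] <- "unassigned"
  }
  assigned$multi <- unname(n_motives_of[assigned$effector] > 1)
  assigned$multi[is.na(assigned$multi)] <- FALSE
  out <- summarise(group_by(assigned, .data$motive),
                   n_direct = n(), multi_motive = sum(.data$multi), .groups = "drop")
  lv <- c(motives, if (any(unass)) "unassigned")
  out <- out[match(intersect(lv, out$motive), out$motive), , drop = FALSE]
  mutate(out, pct = as.integer(floor(100 * .data$n_direct / report$n_direct)),
         .after = "n_direct")
}
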