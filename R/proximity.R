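#' Topological distance between two protein sets
#'
#' The distance between two sets of proteins is built from directed minima:
#' for each protein of one set, the minimum number of jumps to the closest
#' protein of the other set, and vice versa (the average-minimum, "modified
#' Hausdorff" form). Several symmetric aggregations are reported:
#'
#' * `pooled_mean` — mean of all `|A| + |B|` directed minima (the headline
#'   statistic);
#' * `mean_of_means` — average of the two directional means, weighting both
#'   directions equally regardless of set size;
#' * `min_pairwise` — smallest jump count between any pair (integer);
#' * `hausdorff_max` — the classical max-min Hausdorff distance, as an
#'   optional diagnostic.
#'
#' Proteins outside the map's largest connected component are dropped before
#' computing (counted in `n_dropped`), mirroring the use of only the
#' effectors present in the map; every reported value is therefore finite.
#'
#' @param map a [cell_map()].
#' @param a,b nonempty character vectors of protein ids.
#' @return An object of class `set_distance`; see [tidy.set_distance()] for
#'   the one-row tibble form.
#' @examples
#' m <- cell_map(data.frame(a = c("u", "v"), b = c("v", "w")))
#' set_distance(m, "u", c("v", "w"))
#' @export
set_distance <- function(map, a, b) {
  stopifnot(inherits(map, "cell_map"))
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) abort("empty node set")
  lc <- quiet_largest_component(map)
  a2 <- intersect(a, lc$nodes$id)
  b2 <- intersect(b, lc$nodes$id)
  n_dropped <- (length(a) - length(a2)) + (length(b) - length(b2))
  if (length(a2) == 0 || length(b2) == 0) abort("no representatives in map")
  m <- igraph::distances(lc$graph, v = a2, to = b2, mode = "all")
  dist_from_matrix(m, n_dropped = n_dropped,
                   n_a = length(a2), n_b = length(b2))
}

quiet_largest_component <- function(map) {
  withCallingHandlers(largest_component(map),
                      message = function(m) invokeRestart("muffleMessage"))
}

# aggregate a |A| x |B| jump matrix into the set_distance statistics
dist_from_matrix <- function(m, n_dropped = 0L, n_a = nrow(m), n_b = ncol(m)) {
  fwd <- apply(m, 1, min)
  rev <- apply(m, 2, min)
  structure(list(
    forward_mean = mean(fwd),
    reverse_mean = mean(rev),
    pooled_mean = mean(c(fwd, rev)),
    mean_of_means = (mean(fwd) + mean(rev)) / 2,
    min_pairwise = as.integer(min(m)),
    hausdorff_max = max(c(fwd, rev)),
    n_a = n_a, n_b = n_b, n_dropped = as.integer(n_dropped)
  ), class = "set_distance")
}

#' @export
print.set_distance <- function(x, ...) {
  cat(sprintf(
    "<set_distance> pooled_mean %.3f | mean_of_means %.3f | min %d jumps (|A|=%d, |B|=%d, %d dropped)\n",
    x$pooled_mean, x$mean_of_means, x$min_pairwise, x$n_a, x$n_b, x$n_dropped))
  invisible(x)
}

#' Tidy a set distance
#' @param x a [set_distance()] result.
#' @param ... unused.
#' @return A one-row tibble with all distance statistics.
#' @method tidy set_distance
#' @export
tidy.set_distance <- function(x, ...) {
  tibble(forward_mean = x$forward_mean, reverse_mean = x$reverse_mean,
         pooled_mean = x$pooled_mean, mean_of_means = x$mean_of_means,
         min_pairwise = x$min_pairwise, hausdorff_max = x$hausdorff_max,
         n_a = x$n_a, n_b = x$n_b, n_dropped = x$n_dropped)
}

#' Empirical null distribution of condition-to-condition distances
#'
#' Computes the chosen distance statistic for every unordered pair of
#' conditions in a database (the all-pairs empirical null used to judge how
#' unusual an observed distance is), or — when `versus` is given — between
#' one fixed protein set and every condition, the reference distribution for
#' seed-set or pathway comparisons.
#'
#' Conditions with no effector inside the map's largest component are
#' skipped with a warning.
#'
#' @param map a [cell_map()].
#' @param db a [condition_db()].
#' @param statistic which [set_distance()] field to collect.
#' @param versus optional character vector of protein ids; if given, one
#'   value per usable condition (distance of `versus` to its effectors)
#'   instead of one per condition pair.
#' @return An object of class `null_distribution` with elements `values` (a
#'   tibble), `statistic`, `n_comparisons`, `mean`, `sd` and `ecdf`.
#' @export
null_distribution <- function(map, db,
                              statistic = c("pooled_mean", "mean_of_means", "min_pairwise"),
                              versus = NULL) {
  stopifnot(inherits(map, "cell_map"), inherits(db, "condition_db"))
  statistic <- match.arg(statistic)
  lc <- quiet_largest_component(map)
  lc_ids <- lc$nodes$id

  sets <- lapply(split(db$protein, db$condition), function(p) intersect(unique(p), lc_ids))
  usable <- names(sets)[lengths(sets) > 0]
  skipped <- setdiff(names(sets), usable)
  if (length(skipped) > 0) {
    warn(paste0(length(skipped), " condition(s) with no in-map effectors skipped"))
  }
  sets <- sets[usable]
  k <- length(sets)

  if (is.null(versus)) {
    if (k < 2) abort("need at least 2 conditions with effectors in the map")
    nodes <- unique(unlist(sets))
    D <- igraph::distances(lc$graph, v = nodes, to = nodes, mode = "all")
    idx <- lapply(sets, function(s) match(s, nodes))
    pairs <- utils::combn(k, 2)
    vals <- vapply(seq_len(ncol(pairs)), function(j) {
      sub <- D[idx[[pairs[1, j]]], idx[[pairs[2, j]]], drop = FALSE]
      stat_from_matrix(sub, statistic)
    }, numeric(1))
    values <- tibble(condition_a = usable[pairs[1, ]],
                     condition_b = usable[pairs[2, ]],
                     value = vals)
  } else {
    versus <- unique(as.character(versus))
    if (length(versus) == 0) abort("empty node set")
    v2 <- intersect(versus, lc_ids)
    if (length(v2) == 0) abort("no representatives in map")
    if (k < 1) abort("no condition with effectors in the map")
    nodes <- unique(unlist(sets))
    D <- igraph::distances(lc$graph, v = v2, to = nodes, mode = "all")
    vals <- vapply(sets, function(s) {
      stat_from_matrix(D[, match(s, nodes), drop = FALSE], statistic)
    }, numeric(1))
    values <- tibble(condition = usable, value = unname(vals))
  }

  structure(list(
    values = values, statistic = statistic,
    n_comparisons = nrow(values),
    mean = mean(values$value),
    sd = if (nrow(values) > 1) sd(values$value) else 0,
    ecdf = ecdf(values$value)
  ), class = "null_distribution")
}

stat_from_matrix <- function(m, statistic) {
  fwd <- apply(m, 1, min)
  rev <- apply(m, 2, min)
  switch(statistic,
    pooled_mean = mean(c(fwd, rev)),
    mean_of_means = (mean(fwd) + mean(rev)) / 2,
    min_pairwise = min(m))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s over %d comparisons: mean %.3f jumps, sd %.3f\n",
              x$statistic, x$n_comparisons, x$mean, x$sd))
  invisible(x)
}

#' Tidy / summarise a null distribution
#' @param x a [null_distribution()].
#' @param ... unused.
#' @return `tidy()`: the per-comparison values; `glance()`: a one-row tibble
#'   with `statistic`, `n_comparisons`, `mean`, `sd`.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) x$values

#' @rdname tidy.null_distribution
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(statistic = x$statistic, n_comparisons = x$n_comparisons,
         mean = x$mean, sd = x$sd)
}

#' Percentile of a distance under an empirical null
#'
#' Empirical `P(value <= d)` (closed comparison) under the null, alongside
#' the percentile implied by a normal fit with the null's mean and standard
#' deviation, for comparison with normal descriptions of the distribution.
#'
#' @param null a [null_distribution()].
#' @param d observed distance(s), in jumps.
#' @return A tibble with one row per element of `d`: `d`, `percentile`
#'   (empirical, in `[0, 1]`), `normal_percentile`.
#' @export
percentile_of <- function(null, d) {
  stopifnot(inherits(null, "null_distribution"))
  tibble(d = d,
         percentile = null$ecdf(d),
         normal_percentile = pnorm(d, mean = null$mean, sd = max(null$sd, .Machine$double.eps)))
}

#' Pathway-to-motive distance table
#'
#' One [set_distance()] per (pathway, motive) combination: the pathway sets
#' are named seed sub-lists (e.g. the proteins of one source pathway), the
#' motives come from one condition of the database.
#'
#' @param map a [cell_map()].
#' @param pathway_sets named list of character vectors.
#' @param db a [condition_db()].
#' @param condition name of the condition whose motives to compare against.
#' @return A tibble: `pathway`, `motive`, `pooled_mean`, `mean_of_means`,
#'   `min_pairwise`, `n_dropped`.
#' @export
pathway_to_motive_distances <- function(map, pathway_sets, db, condition) {
  stopifnot(inherits(db, "condition_db"))
  if (is.null(names(pathway_sets)) || any(!nzchar(names(pathway_sets)))) {
    abort("pathway_sets must be a named list")
  }
  motives <- unique(db$motive[db$condition == condition])
  if (length(motives) == 0) abort(paste0("unknown condition: ", condition))
  grid <- expand.grid(pathway = names(pathway_sets), motive = motives,
                      stringsAsFactors = FALSE)
  bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    sd_ <- set_distance(map, pathway_sets[[grid$pathway[i]]],
                        effectors(db, condition, grid$motive[i]))
    tibble(pathway = grid$pathway[i], motive = grid$motive[i],
           pooled_mean = sd_$pooled_mean, mean_of_means = sd_$mean_of_means,
           min_pairwise = sd_$min_pairwise, n_dropped = sd_$n_dropped)
  }))
}
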