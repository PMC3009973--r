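#' Generate a synthetic protein-relationship universe
#'
#' Emulates the statistical shape of public interaction snapshots: a
#' connected preferential-attachment (Barabási–Albert) graph, whose
#' heavy-tailed degree distribution mimics real interactomes, with each
#' edge's relationship type drawn from a configurable mix. Fully
#' reproducible from the seed. An Erdős–Rényi variant is available for
#' tests wanting a simpler oracle model.
#'
#' @param n_proteins number of proteins (at least 10).
#' @param attachment edges brought in by each new node of the
#'   preferential-attachment process (`attachment = 1` yields a tree).
#' @param type_mix named nonnegative probabilities over
#'   `interactome`, `metabolome`, `signaling_other`, summing to 1.
#' @param seed integer RNG seed.
#' @param model `"pa"` (preferential attachment, default) or `"er"`
#'   (Erdős–Rényi `G(n, m)` with the same expected edge count).
#' @return A [cell_map()] universe; its `manifest` attribute records the
#'   generating spec and exact node/edge counts.
#' @export
generate_universe <- function(n_proteins = 2000, attachment = 3,
                              type_mix = c(interactome = 0.5, metabolome = 0.3,
                                           signaling_other = 0.2),
                              seed = 1L, model = c("pa", "er")) {
  model <- match.arg(model)
  if (n_proteins < 10) abort("n_proteins must be at least 10")
  if (is.null(names(type_mix)) || !setequal(names(type_mix), RELATION_TYPES)) {
    abort("type_mix must be named over interactome, metabolome, signaling_other")
  }
  type_mix <- type_mix[RELATION_TYPES]
  if (any(type_mix < 0) || abs(sum(type_mix) - 1) > 1e-9) {
    abort("type_mix must be nonnegative and sum to 1")
  }
  if (attachment < 1) abort("attachment must be at least 1")

  universe <- withr::with_seed(as.integer(seed), {
    g <- if (model == "pa") {
      igraph::sample_pa(n_proteins, m = attachment, directed = FALSE)
    } else {
      igraph::sample_gnm(n_proteins, m = attachment * n_proteins)
    }
    ids <- sprintf("P%05d", seq_len(n_proteins))
    el <- igraph::as_edgelist(g, names = FALSE)
    types <- sample(RELATION_TYPES, nrow(el), replace = TRUE, prob = type_mix)
    cell_map(
      edges = tibble(a = ids[el[, 1]], b = ids[el[, 2]], type = types,
                     provenance = "synthetic"),
      nodes = tibble(id = ids, is_seed = FALSE),
      name = "synthetic_universe"
    )
  })
  attr(universe, "manifest") <- list(
    kind = "universe", model = model, n_proteins = n_proteins,
    attachment = attachment, type_mix = as.list(type_mix), seed = as.integer(seed),
    n_nodes = nrow(universe$nodes), n_edges = nrow(universe$edges)
  )
  universe
}

#' Generate a synthetic condition database
#'
#' Emulates a curated condition database: each condition gets a few motives
#' whose effector sets are drawn uniformly without replacement from the
#' universe. Optionally, one *planted* condition draws its effectors from
#' within 1 jump of a target seed set (excluding the seeds themselves, so
#' presence and distance signals stay distinguishable) — the positive
#' control for planted-signal recovery experiments.
#'
#' @param universe a [cell_map()] universe.
#' @param n_conditions number of conditions (at least 2, planted included).
#' @param effectors_per_condition inclusive integer range, e.g. `c(10, 40)`.
#' @param motives_per_condition inclusive integer range, e.g. `c(1, 3)`.
#' @param planted optional list with elements `seeds` (character vector) and
#'   optionally `name` (default `"planted_condition"`); the planted
#'   condition replaces the last generated one.
#' @param seed integer RNG seed.
#' @return A [condition_db()]; its `manifest` attribute records the spec,
#'   all memberships, and the planted pool size.
#' @export
generate_condition_db <- function(universe, n_conditions = 160,
                                  effectors_per_condition = c(10, 40),
                                  motives_per_condition = c(1, 3),
                                  planted = NULL, seed = 1L) {
  stopifnot(inherits(universe, "cell_map"))
  if (n_conditions < 2) abort("n_conditions must be at least 2")
  er <- as.integer(effectors_per_condition); mr <- as.integer(motives_per_condition)
  if (length(er) != 2 || any(er < 1) || er[1] > er[2]) abort("bad effectors_per_condition range")
  if (length(mr) != 2 || any(mr < 1) || mr[1] > mr[2]) abort("bad motives_per_condition range")
  ids <- universe$nodes$id
  if (length(ids) < er[2]) abort("universe has too few proteins for the effector range")

  db <- withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(n_conditions), function(i) {
      cname <- sprintf("C%03d", i)
      n_eff <- if (er[1] == er[2]) er[1] else sample(er[1]:er[2], 1)
      n_mot <- min(if (mr[1] == mr[2]) mr[1] else sample(mr[1]:mr[2], 1), n_eff)
      planted_here <- !is.null(planted) && i == n_conditions
      if (planted_here) {
        cname <- planted$name %||% "planted_condition"
        pool <- planted_pool(universe, planted$seeds)
        if (length(pool) < n_eff) {
          abort(paste0("infeasible planting: 1-jump neighbourhood has ",
                       length(pool), " proteins, need ", n_eff))
        }
        eff <- sample(pool, n_eff)
      } else {
        eff <- sample(ids, n_eff)
      }
      # every motive nonempty: one effector each, remainder assigned at random
      motive_of <- c(seq_len(n_mot),
                     if (n_eff > n_mot) sample(n_mot, n_eff - n_mot, replace = TRUE))
      tibble(condition = cname,
             motive = sprintf("%s_m%d", cname, motive_of),
             protein = eff)
    })
    condition_db(bind_rows(rows))
  })
  attr(db, "manifest") <- list(
    kind = "condition_db", n_conditions = n_conditions,
    effectors_per_condition = er, motives_per_condition = mr,
    planted = if (is.null(planted)) NULL else list(
      name = planted$name %||% "planted_condition",
      n_target_seeds = length(unique(planted$seeds)),
      pool_size = length(planted_pool(universe, planted$seeds))
    ),
    seed = as.integer(seed),
    n_memberships = nrow(db),
    n_effectors_total = nrow(db)
  )
  db
}

# proteins within exactly 1 jump of the target seed set (seeds excluded)
planted_pool <- function(universe, target_seeds) {
  target_seeds <- intersect(unique(as.character(target_seeds)), universe$nodes$id)
  if (length(target_seeds) == 0) abort("infeasible planting: no target seed in the universe")
  d <- jumps_from_set(universe$graph, target_seeds)
  names(d)[is.finite(d) & d == 1]
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates and writes to disk everything a full analysis run needs: a
#' relationship universe (SIF), a seed list, a condition database (GMT) with
#' one planted condition near the seeds, and a manifest (JSON) with the
#' generating parameters, exact counts and file checksums.
#'
#' Scales:
#' * `small` — a 300-protein universe, 30 seeds, 12 conditions; seconds to
#'   analyse, used throughout the test suite.
#' * `paper_like` — a 20,000-protein universe (attachment 4), 447 seeds and
#'   161 conditions; a depth-1 expansion from the seeds yields a map of
#'   roughly 3,000–4,000 proteins, matching the scale of a published
#'   seed-expanded interaction map.
#'
#' @param outdir output directory (created if missing).
#' @param scale `"small"` or `"paper_like"`.
#' @param seed integer RNG seed.
#' @return Invisibly, a named list of the written paths (`universe`,
#'   `seeds`, `conditions`, `manifest`).
#' @export
generate_fixture_bundle <- function(outdir, scale = c("small", "paper_like"),
                                    seed = 1L) {
  scale <- match.arg(scale)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- if (scale == "small") {
    list(n = 300, attachment = 2, n_seeds = 30, n_conditions = 12,
         eff_range = c(4, 8), mot_range = c(1, 2))
  } else {
    list(n = 20000, attachment = 4, n_seeds = 447, n_conditions = 161,
         eff_range = c(10, 40), mot_range = c(1, 3))
  }
  seed <- as.integer(seed)
  universe <- generate_universe(p$n, p$attachment, seed = seed)
  seeds <- withr::with_seed(seed + 1L, sample(universe$nodes$id, p$n_seeds))
  db <- generate_condition_db(universe, p$n_conditions, p$eff_range, p$mot_range,
                              planted = list(seeds = seeds), seed = seed + 2L)

  paths <- list(universe = file.path(outdir, "universe.sif"),
                seeds = file.path(outdir, "seeds.txt"),
                conditions = file.path(outdir, "conditions.gmt"),
                manifest = file.path(outdir, "manifest.json"))
  write_sif(universe, paths$universe)
  write_seed_list(seeds, paths$seeds)
  write_conditions_gmt(db, paths$conditions)

  manifest <- list(
    scale = scale, seed = seed,
    universe = attr(universe, "manifest"),
    conditions = attr(db, "manifest"),
    n_seeds = length(seeds),
    files = lapply(paths[c("universe", "seeds", "conditions")], function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
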