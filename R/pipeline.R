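#' Default analysis configuration
#'
#' Every under-specified methodological choice of the workflow (expansion
#' depth, distance statistic, percentile reference, link radius, embedding
#' method, density settings) surfaces here, so a run is self-documenting.
#'
#' @param universe,seeds,conditions input file paths (universe graph, seed
#'   list, condition database).
#' @param focal_condition name of the condition to analyse in depth.
#' @param outdir output directory.
#' @return A named list of settings (an `AnalysisConfig`).
#' @export
default_config <- function(universe, seeds, conditions, focal_condition,
                           outdir = "cellmapr_run") {
  list(
    universe = universe, seeds = seeds, conditions = conditions,
    focal_condition = focal_condition, outdir = outdir,
    depth = 1L,                  # expansion steps from the seed list
    statistic = "pooled_mean",   # headline set-distance statistic
    reference = "pairs",         # percentile reference: "pairs" or "seeds"
    k = 2L,                      # radius (jumps) for the relationship count
    embed_method = "classical",
    embed_seed = 1L,
    resolution = c(256L, 256L),
    density_mode = "kde",
    bandwidth = NULL,            # NULL = Scott's rule per subset
    peak_quantile = 0.9
  )
}

#' @rdname default_config
#' @param path where to write the YAML; the config list is returned
#'   invisibly.
#' @param config a config list to serialise (default: a template).
#' @export
init_config <- function(path, config = default_config(
                          "universe.sif", "seeds.txt", "conditions.gmt",
                          "planted_condition")) {
  yaml::write_yaml(config, path)
  invisible(config)
}

#' Run the full map analysis
#'
#' Orchestrates the whole workflow from a configuration (a list from
#' [default_config()] or a YAML path): build the map from the seeds, run
#' presence analysis per condition and per motive, compute the focal
#' condition's distance to the seeds with its percentile under the empirical
#' null, embed the map in 2D, produce background/overlay density grids for
#' the focal condition and each of its motives, and enumerate direct and
#' k-jump links. Every stage writes its artifact to `outdir` and downstream
#' stages re-read what they need from disk, so any single stage can be rerun
#' in isolation with identical results; the run is fully deterministic for a
#' fixed configuration.
#'
#' @param config a config list or path to a YAML file.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of all written artifacts.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("universe", "seeds", "conditions", "focal_condition", "outdir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) abort(paste0("config is missing: ", paste(missing, collapse = ", ")))
  cfg <- utils::modifyList(default_config(config$universe, config$seeds,
                                          config$conditions, config$focal_condition,
                                          config$outdir),
                           config)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  manifest <- list(config = cfg, package_version = as.character(utils::packageVersion("cellmapr")),
                   stages = list(), incomplete = TRUE)
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$incomplete <<- TRUE
      write_manifest()
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)), parent = e)
    })
    manifest$stages[[name]] <<- list(done = TRUE)
    res
  }

  # -- build ----------------------------------------------------------------
  map <- stage("build", {
    universe <- read_map_auto(cfg$universe)
    seeds <- read_seed_list(cfg$seeds)
    m <- build_map(seeds, universe, depth = cfg$depth)
    write_graphml(m, out("map.graphml"))
    m
  })

  # -- presence -------------------------------------------------------------
  pres <- stage("presence", {
    m <- read_graphml(out("map.graphml"))
    db <- read_conditions(cfg$conditions)
    pc <- presence_report(m, db, by = "condition")
    pm <- presence_report(m, db, by = "motive")
    readr::write_tsv(pc, out("presence_conditions.tsv"), progress = FALSE)
    readr::write_tsv(pm, out("presence_motives.tsv"), progress = FALSE)
    list(conditions = pc, motives = pm)
  })

  # -- distance + null ------------------------------------------------------
  prox <- stage("proximity", {
    m <- read_graphml(out("map.graphml"))
    db <- read_conditions(cfg$conditions)
    focal_eff <- effectors(db, cfg$focal_condition)
    d_focal <- set_distance(m, map_seeds(m), focal_eff)
    null <- suppressWarnings(
      if (cfg$reference == "seeds") {
        null_distribution(m, db, statistic = cfg$statistic, versus = map_seeds(m))
      } else {
        null_distribution(m, db, statistic = cfg$statistic)
      })
    pct <- percentile_of(null, d_focal[[cfg$statistic]])
    null_meta <- c(sprintf("# statistic: %s", null$statistic),
                   sprintf("# reference: %s", cfg$reference),
                   sprintf("# n_comparisons: %d", null$n_comparisons),
                   sprintf("# mean: %.15g", null$mean),
                   sprintf("# sd: %.15g", null$sd))
    writeLines(c(null_meta, readr::format_tsv(tidy(null))),
               out("null.tsv"))
    jsonlite::write_json(
      list(focal_condition = cfg$focal_condition,
           statistic = cfg$statistic, reference = cfg$reference,
           distance = tidy(d_focal), percentile = pct,
           null = glance(null)),
      out("distance.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
    list(distance = d_focal, null = null, percentile = pct)
  })

  # -- embedding ------------------------------------------------------------
  emb <- stage("embed", {
    m <- read_graphml(out("map.graphml"))
    e <- geodesic_mds(m, method = cfg$embed_method, seed = cfg$embed_seed)
    readr::write_tsv(e$coords, out("coords.tsv"), progress = FALSE)
    e
  })

  # -- density --------------------------------------------------------------
  dens <- stage("density", {
    m <- read_graphml(out("map.graphml"))
    db <- read_conditions(cfg$conditions)
    co <- readr::read_tsv(out("coords.tsv"),
                          col_types = readr::cols(id = readr::col_character(),
                                                  x = readr::col_double(),
                                                  y = readr::col_double()),
                          progress = FALSE)
    e <- structure(list(coords = co, stress = emb$stress, excluded = emb$excluded,
                        method = emb$method, seed = emb$seed), class = "embedding2d")
    write_grid <- function(g, f) readr::write_tsv(tidy(g), out(f), progress = FALSE)
    overlays <- list(focal = effectors(db, cfg$focal_condition))
    for (mo in unique(db$motive[db$condition == cfg$focal_condition])) {
      overlays[[paste0("motive_", mo)]] <- effectors(db, cfg$focal_condition, mo)
    }
    grids <- list()
    bg <- density_grid(e, NULL, cfg$resolution, cfg$density_mode, cfg$bandwidth)
    write_grid(bg, "density_background.tsv")
    grids$background <- bg
    for (nm in names(overlays)) {
      ids <- intersect(overlays[[nm]], co$id)
      if (length(ids) == 0) next
      g <- density_grid(e, ids, cfg$resolution, cfg$density_mode, cfg$bandwidth)
      write_grid(g, paste0("density_", nm, ".tsv"))
      grids[[nm]] <- g
    }
    grids
  })

  # -- links ----------------------------------------------------------------
  links <- stage("links", {
    m <- read_graphml(out("map.graphml"))
    db <- read_conditions(cfg$conditions)
    lr <- k_jump_links(m, map_seeds(m), effectors(db, cfg$focal_condition), k = cfg$k)
    readr::write_tsv(lr$k_jump_pairs, out("links.tsv"), progress = FALSE)
    de <- mutate(lr$direct_edges, types = map_chr(.data$types, paste, collapse = "|"))
    readr::write_tsv(de, out("links_direct.tsv"), progress = FALSE)
    mb <- if (lr$n_direct > 0) {
      suppressWarnings(motive_breakdown(lr, db, cfg$focal_condition))
    } else tibble(motive = character(), n_direct = integer(), pct = integer(),
                  multi_motive = integer())
    readr::write_tsv(mb, out("links_motives.tsv"), progress = FALSE)
    list(report = lr, motives = mb)
  })

  # -- manifest -------------------------------------------------------------
  artifacts <- c("map.graphml", "presence_conditions.tsv", "presence_motives.tsv",
                 "null.tsv", "distance.json", "coords.tsv",
                 "density_background.tsv", "density_focal.tsv",
                 "links.tsv", "links_direct.tsv", "links_motives.tsv")
  artifacts <- artifacts[file.exists(file.path(cfg$outdir, artifacts))]
  manifest$incomplete <- FALSE
  manifest$map_summary <- as.list(map_summary(map))
  manifest$artifacts <- lapply(setNames(artifacts, artifacts), function(f) {
    list(md5 = unname(tools::md5sum(out(f))), bytes = file.size(out(f)))
  })
  write_manifest()

  invisible(list(config = cfg, map = map, presence = pres, proximity = prox,
                 embedding = emb, density = dens, links = links,
                 outdir = cfg$outdir))
}
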