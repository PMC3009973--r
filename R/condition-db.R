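#' Condition databases
#'
#' A condition database maps physiological conditions (diseases, syndromes,
#' metabolic states) to their effector proteins — the proteins finally
#' responsible for the phenotypic effect — grouped into pathophysiological
#' motives (sub-mechanisms, e.g. "insulin resistance"). It is represented as
#' a long tibble with one row per (condition, motive, protein) membership.
#'
#' @param memberships data frame with character columns `condition`, `motive`,
#'   `protein`.
#' @return A tibble of class `condition_db`.
#' @export
condition_db <- function(memberships) {
  db <- as_tibble(memberships)
  need <- c("condition", "motive", "protein")
  if (!all(need %in% names(db))) {
    abort("condition database needs columns condition, motive, protein")
  }
  db <- db[, need]
  db$condition <- as.character(db$condition)
  db$motive <- as.character(db$motive)
  db$protein <- as.character(db$protein)
  if (any(!nzchar(db$protein))) abort("effector ids must be nonempty strings")
  dup <- duplicated(db)
  if (any(dup)) {
    warn(paste0("dropped ", sum(dup), " duplicate effector record(s) within a motive"))
    db <- db[!dup, , drop = FALSE]
  }
  class(db) <- c("condition_db", class(tibble()))
  db
}

#' @export
print.condition_db <- function(x, ...) {
  cat(sprintf("<condition_db> %d conditions, %d motives, %d effector memberships\n",
              length(unique(x$condition)),
              nrow(distinct(as_tibble(x)[, c("condition", "motive")])),
              nrow(x)))
  NextMethod()
}

#' Names and effector sets of a condition database
#'
#' `condition_names()` lists the conditions; `effectors()` returns the
#' effector set of one condition (the exact union of its motive sets), or of
#' one motive within it.
#'
#' @param db a [condition_db()].
#' @param condition condition name.
#' @param motive optional motive name within `condition`.
#' @return `condition_names()`: character vector. `effectors()`: character
#'   vector of protein ids.
#' @export
condition_names <- function(db) {
  unique(db$condition)
}

#' @rdname condition_names
#' @export
effectors <- function(db, condition, motive = NULL) {
  rows <- db$condition == condition
  if (!any(rows)) abort(paste0("unknown condition: ", condition))
  if (!is.null(motive)) {
    rows <- rows & db$motive == motive
    if (!any(rows)) abort(paste0("unknown motive for ", condition, ": ", motive))
  }
  unique(db$protein[rows])
}

#' Read a condition database
#'
#' Two dialects are accepted and yield identical databases:
#'
#' * GMT: `set-name <TAB> description <TAB> id ...` where `set-name` is
#'   `condition|motive` (a name without `|` is its own single motive);
#' * long TSV with header `condition  motive  protein`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension / content), `"gmt"` or `"tsv"`.
#' @return A [condition_db()].
#' @export
read_conditions <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gmt") "gmt" else if (ext %in% c("tsv", "txt")) "tsv" else {
      first <- readLines(path, n = 1)
      if (grepl("^condition\tmotive\tprotein", first)) "tsv" else "gmt"
    }
  }
  if (format == "gmt") read_conditions_gmt(path) else read_conditions_tsv(path)
}

read_conditions_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty condition database file")
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(paste0("malformed GMT line ", i, ": expected set-name, description, ids"))
    nm <- strsplit(f[1], "|", fixed = TRUE)[[1]]
    if (length(nm) > 2 || !nzchar(nm[1])) abort(paste0("malformed set name at line ", i, ": ", f[1]))
    tibble(condition = nm[1],
           motive = if (length(nm) == 2) nm[2] else nm[1],
           protein = f[3:length(f)])
  })
  condition_db(bind_rows(recs))
}

read_conditions_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) abort("empty condition database file")
  condition_db(df)
}

#' @rdname read_conditions
#' @param db a [condition_db()].
#' @export
write_conditions_gmt <- function(db, path) {
  stopifnot(inherits(db, "condition_db"))
  groups <- split(db$protein, paste(db$condition, db$motive, sep = "|"))
  # keep first-appearance order of condition|motive
  ord <- unique(paste(db$condition, db$motive, sep = "|"))
  lines <- vapply(ord, function(k) {
    paste(c(k, "", groups[[k]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_conditions
#' @export
write_conditions_tsv <- function(db, path) {
  stopifnot(inherits(db, "condition_db"))
  readr::write_tsv(as_tibble(db), path, progress = FALSE)
  invisible(path)
}

#' Presence of an effector set in a map
#'
#' Presence analysis evaluates how many of a condition's effector proteins
#' are contained in the map, as a fraction of all its known effectors. The
#' percentage uses the floor convention: `pct = floor(100 * n_present /
#' n_total)`.
#'
#' @param effector_ids nonempty character vector of effector protein ids.
#' @param map a [cell_map()].
#' @return A one-row tibble: `n_total`, `n_present`, `pct` (integer), and
#'   `present_ids` (list column).
#' @examples
#' m <- cell_map(data.frame(a = "P1", b = "P2"))
#' presence(c("P1", "P9"), m)
#' @export
presence <- function(effector_ids, map) {
  stopifnot(inherits(map, "cell_map"))
  effector_ids <- unique(as.character(effector_ids))
  if (length(effector_ids) == 0) abort("empty node set")
  present <- intersect(effector_ids, map$nodes$id)
  n_total <- length(effector_ids)
  n_present <- length(present)
  tibble(n_total = n_total, n_present = n_present,
         pct = as.integer(floor(100 * n_present / n_total)),
         present_ids = list(present))
}

#' Presence report over a whole condition database
#'
#' Applies [presence()] to every condition (and optionally every motive) of a
#' database against a map.
#'
#' @param map a [cell_map()].
#' @param db a [condition_db()].
#' @param by `"condition"` or `"motive"` granularity.
#' @return A tibble with one row per condition (or per condition-motive
#'   pair): names, `n_total`, `n_present`, `pct`.
#' @export
presence_report <- function(map, db, by = c("condition", "motive")) {
  by <- match.arg(by)
  if (by == "condition") {
    sets <- split(db$protein, db$condition)
    out <- bind_rows(lapply(names(sets), function(cn) {
      mutate(presence(sets[[cn]], map), condition = cn, .before = 1)
    }))
  } else {
    key <- paste(db$condition, db$motive, sep = "\r")
    sets <- split(seq_len(nrow(db)), key)
    out <- bind_rows(lapply(sets, function(i) {
      mutate(presence(db$protein[i], map),
             condition = db$condition[i[1]], motive = db$motive[i[1]], .before = 1)
    }))
  }
  select(out, -"present_ids")
}
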