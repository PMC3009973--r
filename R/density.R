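#' Protein density grid over a 2D embedding
#'
#' Discretises the embedded map into a regular grid and measures protein
#' density per cell — the quantity behind density-coloured map images
#' (proteins per pixel squared). Two modes:
#'
#' * `count`: each point falls in exactly one cell (cells are half-open, with
#'   the right/top edges of the final row and column closed), so the grid sum
#'   equals the number of points exactly;
#' * `kde`: an isotropic Gaussian kernel density estimate evaluated at cell
#'   centres, with Scott's-rule bandwidth by default.
#'
#' The grid extent defaults to the bounding box of the *full* embedding,
#' padded by 5% per side, so that grids of different subsets share
#' coordinates and can be overlaid.
#'
#' @param embedding an [geodesic_mds()] result.
#' @param subset optional character vector of protein ids; defaults to every
#'   embedded protein. Ids not embedded are ignored; an empty effective
#'   subset is an error.
#' @param resolution integer vector `c(nx, ny)`, at least `c(2, 2)`.
#' @param mode `"count"` or `"kde"`.
#' @param bandwidth kernel bandwidth (embedding units) for `kde` mode;
#'   default is Scott's rule on the subset, `n^(-1/6) * sqrt((var(x) +
#'   var(y)) / 2)`. Must be positive.
#' @param extent optional `c(x0, x1, y0, y1)` overriding the shared default.
#' @return An object of class `density_grid`: `values` (an `nx` by `ny`
#'   matrix, x indexing rows), `xb`/`yb` (cell boundaries), `mode`,
#'   `bandwidth`, `n_points`, `resolution`.
#' @export
density_grid <- function(embedding, subset = NULL, resolution = c(256, 256),
                         mode = c("count", "kde"), bandwidth = NULL,
                         extent = NULL) {
  stopifnot(inherits(embedding, "embedding2d"))
  mode <- match.arg(mode)
  resolution <- as.integer(resolution)
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  if (any(resolution < 2)) abort("resolution must be at least 2x2")
  co <- embedding$coords
  if (!is.null(subset)) {
    co <- co[co$id %in% as.character(subset), , drop = FALSE]
  }
  if (nrow(co) == 0) abort("empty effective subset")
  extent <- extent %||% default_extent(embedding)
  nx <- resolution[1]; ny <- resolution[2]
  xb <- seq(extent[1], extent[2], length.out = nx + 1)
  yb <- seq(extent[3], extent[4], length.out = ny + 1)

  if (mode == "count") {
    inside <- co$x >= extent[1] & co$x <= extent[2] &
              co$y >= extent[3] & co$y <= extent[4]
    if (any(!inside)) {
      warn(paste0(sum(!inside), " point(s) outside the grid extent dropped"))
      co <- co[inside, , drop = FALSE]
    }
    ix <- findInterval(co$x, xb, rightmost.closed = TRUE)
    iy <- findInterval(co$y, yb, rightmost.closed = TRUE)
    values <- matrix(0, nx, ny)
    tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
    values[] <- as.numeric(tab)
    bw <- NA_real_
  } else {
    bw <- bandwidth %||% scott_bandwidth(co$x, co$y)
    if (!is.finite(bw) || bw <= 0) abort("bandwidth must be positive")
    cx <- (xb[-1] + xb[-(nx + 1)]) / 2
    cy <- (yb[-1] + yb[-(ny + 1)]) / 2
    # separable Gaussian kernel: grid density = A %*% B / (n 2 pi h^2)
    A <- exp(-outer(cx, co$x, "-")^2 / (2 * bw^2))
    B <- exp(-outer(co$y, cy, "-")^2 / (2 * bw^2))
    values <- (A %*% B) / (nrow(co) * 2 * pi * bw^2)
  }

  structure(list(values = values, xb = xb, yb = yb, mode = mode,
                 bandwidth = bw, n_points = nrow(co),
                 resolution = resolution),
            class = "density_grid")
}

default_extent <- function(embedding) {
  co <- embedding$coords
  rx <- range(co$x); ry <- range(co$y)
  px <- max(diff(rx) * 0.05, 0.5 * (diff(rx) == 0))
  py <- max(diff(ry) * 0.05, 0.5 * (diff(ry) == 0))
  c(rx[1] - px, rx[2] + px, ry[1] - py, ry[2] + py)
}

scott_bandwidth <- function(x, y) {
  n <- length(x)
  s <- sqrt((var(x) + var(y)) / 2)
  if (!is.finite(s) || s == 0) s <- 1e-3
  n^(-1 / 6) * s
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s, %d x %d cells, %d points%s\n",
              x$mode, x$resolution[1], x$resolution[2], x$n_points,
              if (x$mode == "kde") sprintf(", bandwidth %.4g", x$bandwidth) else ""))
  invisible(x)
}

#' Total mass of a density grid
#'
#' Count mode: the grid sum (equal to the number of binned points). KDE
#' mode: the Riemann integral of the density over the grid, close to 1 when
#' the extent pads the data by several bandwidths.
#'
#' @param grid a [density_grid()].
#' @return scalar mass.
#' @export
grid_mass <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  if (grid$mode == "count") sum(grid$values)
  else sum(grid$values) * diff(grid$xb[1:2]) * diff(grid$yb[1:2])
}

#' Tidy a density grid into long form
#' @param x a [density_grid()].
#' @param ... unused.
#' @return A tibble: `ix`, `iy`, `x`, `y` (cell centres), `value`.
#' @method tidy density_grid
#' @export
tidy.density_grid <- function(x, ...) {
  nx <- x$resolution[1]; ny <- x$resolution[2]
  cx <- (x$xb[-1] + x$xb[-(nx + 1)]) / 2
  cy <- (x$yb[-1] + x$yb[-(ny + 1)]) / 2
  vals <- as.vector(x$values)
  tibble(ix = rep(1:nx, times = ny), iy = rep(1:ny, each = nx),
         x = rep(cx, times = ny), y = rep(cy, each = nx),
         value = vals)
}

#' Background/overlay density pair for cluster images
#'
#' Computes two density grids on the same extent and resolution — a
#' background (typically the whole map) and an overlay (a condition or
#' motive effector set) — as used to locate a condition's cluster on the map
#' projection.
#'
#' @inheritParams density_grid
#' @param background,overlay character vectors of protein ids (each must
#'   intersect the embedded ids).
#' @return A named list of two [density_grid()] objects, `background` and
#'   `overlay`.
#' @export
cluster_overlay <- function(embedding, background, overlay,
                            resolution = c(256, 256), mode = c("count", "kde"),
                            bandwidth = NULL) {
  mode <- match.arg(mode)
  ext <- default_extent(embedding)
  list(
    background = density_grid(embedding, background, resolution, mode,
                              bandwidth, extent = ext),
    overlay = density_grid(embedding, overlay, resolution, mode,
                           bandwidth, extent = ext)
  )
}

#' High-density regions of a grid
#'
#' Identifies the connected regions of cells whose density reaches a given
#' quantile of the positive cell values — the "cluster" regions of the
#' density images. Connectivity is 4-neighbour; regions are sorted by total
#' contained mass (ties broken by the smallest cell index, x fastest).
#'
#' @param grid a [density_grid()].
#' @param quantile threshold quantile of positive cell values, in (0, 1).
#' @return A tibble with one row per region: `region`, `n_cells`, `mass`,
#'   and `cells` (list column of tibbles `ix`, `iy`). Empty for an all-zero
#'   grid.
#' @export
peak_regions <- function(grid, quantile = 0.9) {
  stopifnot(inherits(grid, "density_grid"))
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  v <- grid$values
  pos <- v[v > 0]
  empty <- tibble(region = integer(), n_cells = integer(), mass = numeric(),
                  cells = list())
  if (length(pos) == 0) return(empty)
  thr <- unname(stats::quantile(pos, quantile))
  mask <- which(v >= thr)
  if (length(mask) == 0) return(empty)
  nx <- nrow(v)
  ix <- ((mask - 1) %% nx) + 1
  iy <- ((mask - 1) %/% nx) + 1
  # label 4-connected components on the masked cells via a lattice graph
  idx_of <- setNames(seq_along(mask), mask)
  right <- mask[ix < nx][(mask[ix < nx] + 1) %in% mask]
  up <- mask[iy < ncol(v)][(mask[iy < ncol(v)] + nx) %in% mask]
  edges <- rbind(
    cbind(idx_of[as.character(right)], idx_of[as.character(right + 1)]),
    cbind(idx_of[as.character(up)], idx_of[as.character(up + nx)])
  )
  g <- igraph::make_empty_graph(n = length(mask), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  regions <- lapply(split(seq_along(mask), memb), function(i) {
    list(n_cells = length(i), mass = sum(v[mask[i]]), first = min(mask[i]),
         cells = tibble(ix = ix[i], iy = iy[i]))
  })
  out <- tibble(
    n_cells = unname(map_int(regions, "n_cells")),
    mass = unname(map_dbl(regions, "mass")),
    first = unname(map_dbl(regions, "first")),
    cells = unname(map(regions, "cells"))
  )
  out <- arrange(out, desc(.data$mass), .data$first)
  mutate(select(out, -"first"), region = row_number(), .before = 1)
}
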