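test_that("map construction canonicalises edges: loops dropped, parallels merged", {
  expect_warning(
    m <- cell_map(data.frame(a = c("x", "x", "y", "x"),
                             b = c("x", "y", "x", "y"),
                             type = c("interactome", "interactome",
                                      "metabolome", "signaling_other"))),
    "self-loop")
  expect_equal(nrow(map_edges(m)), 1)
  expect_setequal(map_edges(m)$types[[1]],
                  c("interactome", "metabolome", "signaling_other"))
  expect_error(cell_map(data.frame(a = "x", b = "y", type = "magic")), "unknown relationship")
  expect_error(cell_map(data.frame(a = "", b = "y")), "nonempty")
  expect_error(cell_map(nodes = data.frame(id = c("a", "a"))), "unique")
})

test_that("bfs_jumps matches hand counts on a path and handles edge cases", {
  m <- path_map(3)
  d <- bfs_jumps(m, "v01")
  expect_equal(setNames(d$jumps, d$id), c(v01 = 0L, v02 = 1L, v03 = 2L))
  # every node a source -> all zeros
  d0 <- bfs_jumps(m, map_nodes(m)$id)
  expect_true(all(d0$jumps == 0L))
  expect_error(bfs_jumps(m, character(0)), "empty node set")
  expect_error(bfs_jumps(m, "nope"), "nope")
})

test_that("bfs_jumps agrees with a Floyd-Warshall oracle on random graphs", {
  e <- random_edges(30, 0.1, seed = 42)
  m <- cell_map(e)
  ids <- map_nodes(m)$id
  D <- floyd_warshall(ids, map_edges(m))
  for (src in ids[c(1, 7, 19)]) {
    got <- bfs_jumps(m, src)
    want <- D[src, ]
    want <- want[is.finite(want)]
    expect_equal(setNames(got$jumps, got$id)[names(want)],
                 setNames(as.integer(want), names(want)))
  }
})

test_that("jump distances are symmetric, satisfy the triangle inequality, and
           survive duplicate-edge merging", {
  e <- random_edges(25, 0.15, seed = 7)
  m <- cell_map(e)
  ids <- map_nodes(m)$id
  D <- floyd_warshall(ids, map_edges(m))
  set.seed(1)
  for (rep in 1:30) {
    trip <- sample(ids, 3)
    expect_identical(D[trip[1], trip[2]], D[trip[2], trip[1]])
    expect_gte(D[trip[1], trip[2]] + D[trip[2], trip[3]], D[trip[1], trip[3]])
  }
  # duplicating every edge record (in both orientations) changes nothing
  e2 <- rbind(e, data.frame(a = e$b, b = e$a))
  m2 <- cell_map(e2)
  d1 <- bfs_jumps(m, ids[1]); d2 <- bfs_jumps(m2, ids[1])
  expect_equal(d1, d2)
})

test_that("largest_component keeps the right component and its output is connected", {
  m <- path_map(6)
  expect_identical(suppressMessages(largest_component(m))$nodes$id, m$nodes$id)
  # components of size 5 and 3
  two <- cell_map(data.frame(
    a = c("a1", "a2", "a3", "a4", "z1", "z2"),
    b = c("a2", "a3", "a4", "a5", "z2", "z3")))
  expect_message(big <- largest_component(two), "dropped 3")
  expect_setequal(map_nodes(big)$id, c("a1", "a2", "a3", "a4", "a5"))
  # tie: two components of size 4 -> the one with the alphabetically first id
  tie <- cell_map(data.frame(
    a = c("m1", "m2", "m3", "b1", "b2", "b3"),
    b = c("m2", "m3", "m4", "b2", "b3", "b4")))
  keep <- suppressMessages(largest_component(tie))
  expect_setequal(map_nodes(keep)$id, c("b1", "b2", "b3", "b4"))
  # connectivity check by BFS reach
  reach <- bfs_jumps(keep, map_nodes(keep)$id[1])
  expect_setequal(reach$id, map_nodes(keep)$id)
  expect_error(largest_component(cell_map()), "empty")
})

test_that("map_summary counts exactly, including the naive-recount oracle", {
  expect_equal(map_summary(cell_map())$n_nodes, 0L)
  expect_equal(map_summary(cell_map())$n_edges, 0L)
  expect_equal(map_summary(cell_map())$n_components, 0L)

  tri <- triangle_map()
  s <- map_summary(tri)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3L)
  expect_equal(unname(unlist(s[, c("deg_q1", "deg_median", "deg_q3")])), c(2, 2, 2))

  e <- random_edges(40, 0.08, seed = 11)
  m <- cell_map(e)
  # naive recount: unique unordered pairs, neighbour sets per node
  key <- unique(paste(pmin(e$a, e$b), pmax(e$a, e$b)))
  s2 <- map_summary(m)
  expect_equal(s2$n_edges, length(key))
  deg <- vapply(map_nodes(m)$id, function(id) {
    length(unique(c(e$b[e$a == id], e$a[e$b == id])))
  }, integer(1))
  expect_equal(unname(unlist(s2[, c("deg_q1", "deg_median", "deg_q3")])),
               unname(quantile(deg, c(.25, .5, .75))))
})

test_that("graph files round-trip: node ids, edge sets and type sets survive", {
  e <- random_edges(15, 0.2, seed = 3)
  set.seed(5)
  e$type <- sample(c("interactome", "metabolome", "signaling_other"),
                   nrow(e), replace = TRUE)
  extra <- data.frame(a = e$a[1], b = e$b[1], type = "metabolome")
  m <- cell_map(rbind(e, extra),
                nodes = data.frame(id = c(unique(c(e$a, e$b)), "lonely"),
                                   is_seed = FALSE))
  for (fmt in c("sif", "tsv", "graphml")) {
    f <- tempfile(fileext = paste0(".", fmt))
    switch(fmt,
      sif = write_sif(m, f), tsv = write_edge_tsv(m, f),
      graphml = write_graphml(m, f))
    m2 <- switch(fmt, sif = read_sif(f), tsv = read_edge_tsv(f),
                 graphml = read_graphml(f))
    if (fmt == "tsv") {
      # the 3-column dialect carries no isolated nodes
      expect_setequal(map_nodes(m2)$id, setdiff(map_nodes(m)$id, "lonely"))
    } else {
      expect_setequal(map_nodes(m2)$id, map_nodes(m)$id)
    }
    expect_equal(map_edges(m2)[, c("a", "b", "types")],
                 map_edges(m)[, c("a", "b", "types")])
    unlink(f)
  }
})

test_that("seed lists read back with comments and blanks stripped", {
  f <- tempfile()
  writeLines(c("# pathway A", "P1", "P2  ", "", "P3 # trailing note"), f)
  expect_equal(read_seed_list(f), c("P1", "P2", "P3"))
  unlink(f)
})
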