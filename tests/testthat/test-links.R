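test_that("direct links enumerate the seed-effector cut exactly", {
  m <- path_map(4)
  none <- direct_links(m, "v01", "v04")
  expect_equal(none$n_direct, 0)
  expect_equal(nrow(none$direct_edges), 0)
  # bipartite: 2 effectors each linked to 3 distinct seeds
  e <- expand.grid(a = c("e1", "e2"), b = NA)
  edges <- data.frame(a = rep(c("e1", "e2"), each = 3),
                      b = paste0("s", 1:6))
  mb <- cell_map(edges)
  r <- direct_links(mb, seeds = paste0("s", 1:6), effector_ids = c("e1", "e2"))
  expect_equal(r$n_direct, 6)
  expect_equal(r$n_effectors_involved, 2)
  expect_equal(r$n_seeds_involved, 6)
  expect_equal(r$direct_edges$effector, rep(c("e1", "e2"), each = 3))
  expect_error(direct_links(mb, character(0), "e1"), "empty node set")
})

test_that("direct links equal an exhaustive edge-scan oracle and the cut size", {
  e <- random_edges(30, 0.15, seed = 23)
  m <- cell_map(e)
  ids <- map_nodes(m)$id
  set.seed(6)
  seeds <- sample(ids, 8)
  eff <- sample(setdiff(ids, seeds), 6)
  r <- direct_links(m, seeds, eff)
  # oracle: scan every edge record
  cnt <- 0
  me <- map_edges(m)
  for (i in seq_len(nrow(me))) {
    if ((me$a[i] %in% eff && me$b[i] %in% seeds) ||
        (me$b[i] %in% eff && me$a[i] %in% seeds)) cnt <- cnt + 1
  }
  expect_equal(r$n_direct, cnt)
  # disjoint sets on a simple graph: n_direct is the cut size
  expect_equal(r$n_direct, sum(vapply(seq_len(nrow(me)), function(i) {
    xor(me$a[i] %in% eff, me$a[i] %in% seeds) &&
      ((me$a[i] %in% eff && me$b[i] %in% seeds) ||
       (me$a[i] %in% seeds && me$b[i] %in% eff))
  }, logical(1))))
})

test_that("k-jump pairs match a per-effector BFS oracle and nest in k", {
  # path e - x - s: one pair at distance 2
  m <- cell_map(data.frame(a = c("e", "x"), b = c("x", "s")))
  r2 <- k_jump_links(m, seeds = "s", effector_ids = "e", k = 2)
  expect_equal(r2$n_relationships, 1)
  expect_equal(r2$k_jump_pairs$jumps, 2L)
  r1 <- k_jump_links(m, seeds = "s", effector_ids = "e", k = 1)
  expect_equal(r1$n_relationships, 0)

  e <- random_edges(30, 0.1, seed = 29)
  mm <- cell_map(e)
  ids <- map_nodes(mm)$id
  set.seed(9)
  seeds <- sample(ids, 7)
  eff <- sample(ids, 5)  # may overlap the seeds
  D <- floyd_warshall(ids, map_edges(mm))
  r <- k_jump_links(mm, seeds, eff, k = 3)
  oracle <- 0
  for (a in eff) for (s in seeds) {
    if (a != s && is.finite(D[a, s]) && D[a, s] <= 3) oracle <- oracle + 1
  }
  expect_equal(r$n_relationships, oracle)
  for (i in seq_len(nrow(r$k_jump_pairs))) {
    expect_equal(r$k_jump_pairs$jumps[i],
                 as.integer(D[r$k_jump_pairs$effector[i], r$k_jump_pairs$seed[i]]))
  }
  # k = 1 coincides with the endpoint pairs of the direct edges
  rk1 <- k_jump_links(mm, seeds, eff, k = 1)
  expect_equal(rk1$k_jump_pairs[, c("effector", "seed")],
               rk1$direct_edges[, c("effector", "seed")])
  # monotone in k
  counts <- vapply(1:4, function(k) k_jump_links(mm, seeds, eff, k)$n_relationships,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(k_jump_links(mm, seeds, eff, k = 0), "at least 1")
})

test_that("motive breakdown uses floor percentages and the once-per-motive rule", {
  # two motives splitting 4 direct links 3/1
  edges <- data.frame(a = c("e1", "e1", "e1", "e2"), b = paste0("s", 1:4))
  m <- cell_map(edges)
  db <- condition_db(data.frame(condition = "D",
                                motive = c("alpha", "beta"),
                                protein = c("e1", "e2")))
  r <- direct_links(m, seeds = paste0("s", 1:4), effector_ids = c("e1", "e2"))
  bd <- motive_breakdown(r, db, "D")
  expect_equal(bd$n_direct[bd$motive == "alpha"], 3L)
  expect_equal(bd$pct[bd$motive == "alpha"], 75L)
  expect_equal(bd$pct[bd$motive == "beta"], 25L)
  # an effector in two motives is counted once per motive, flagged
  db2 <- condition_db(data.frame(condition = "D",
                                 motive = c("alpha", "beta", "beta"),
                                 protein = c("e1", "e1", "e2")))
  bd2 <- motive_breakdown(r, db2, "D")
  expect_equal(bd2$n_direct[bd2$motive == "alpha"], 3L)
  expect_equal(bd2$n_direct[bd2$motive == "beta"], 4L)  # 3 from e1 + 1 from e2
  expect_equal(bd2$multi_motive[bd2$motive == "beta"], 3L)
  # single motive holding every effector -> 100%
  db3 <- condition_db(data.frame(condition = "D", motive = "only",
                                 protein = c("e1", "e2")))
  expect_equal(motive_breakdown(r, db3, "D")$pct, 100L)
  # effector with no motive -> warned, bucketed as unassigned
  db4 <- condition_db(data.frame(condition = "D", motive = "alpha", protein = "e1"))
  expect_warning(bd4 <- motive_breakdown(r, db4, "D"), "unassigned")
  expect_equal(bd4$n_direct[bd4$motive == "unassigned"], 1L)
})

test_that("direct-link counts ignore edge-type annotations", {
  base <- data.frame(a = c("e1", "e1"), b = c("s1", "s2"))
  m1 <- cell_map(cbind(base, type = "interactome"))
  m2 <- cell_map(cbind(base, type = c("metabolome", "signaling_other")))
  expect_equal(direct_links(m1, c("s1", "s2"), "e1")$n_direct,
               direct_links(m2, c("s1", "s2"), "e1")$n_direct)
})
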