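test_that("set_distance on hand-enumerable cases", {
  m <- path_map(5)
  # identity: a set against itself is 0 in every field
  s0 <- set_distance(m, c("v02", "v04"), c("v02", "v04"))
  expect_equal(s0$pooled_mean, 0)
  expect_equal(s0$mean_of_means, 0)
  expect_equal(s0$min_pairwise, 0L)
  expect_equal(s0$hausdorff_max, 0)
  # adjacent singletons
  s1 <- set_distance(m, "v01", "v02")
  expect_equal(tidy(s1)$pooled_mean, 1)
  expect_equal(s1$min_pairwise, 1L)
  # A = {v1}, B = {v4, v5}: directed minima 3 | 3, 4
  s2 <- set_distance(m, "v01", c("v04", "v05"))
  expect_equal(s2$forward_mean, 3)
  expect_equal(s2$reverse_mean, 3.5)
  expect_equal(s2$pooled_mean, 10 / 3)
  expect_equal(s2$mean_of_means, 3.25)
  expect_equal(s2$min_pairwise, 3L)
  expect_error(set_distance(m, character(0), "v01"), "empty node set")
  expect_error(set_distance(m, "zz", "v01"), "no representatives")
})

test_that("set_distance matches the exhaustive oracle and drops out-of-component proteins", {
  e <- random_edges(30, 0.12, seed = 5)
  m <- suppressMessages(largest_component(cell_map(e)))
  ids <- map_nodes(m)$id
  D <- floyd_warshall(ids, map_edges(m))
  set.seed(2)
  for (rep in 1:10) {
    A <- sample(ids, sample(2:5, 1))
    B <- sample(ids, sample(2:5, 1))
    got <- set_distance(m, A, B)
    want <- oracle_set_stats(D, A, B)
    expect_equal(got$pooled_mean, want$pooled_mean)
    expect_equal(got$mean_of_means, want$mean_of_means)
    # symmetry of the symmetric aggregations
    rev_ <- set_distance(m, B, A)
    expect_equal(rev_$pooled_mean, got$pooled_mean)
    expect_equal(rev_$mean_of_means, got$mean_of_means)
    expect_equal(rev_$min_pairwise, got$min_pairwise)
    expect_gte(got$pooled_mean, got$min_pairwise)
  }
  # proteins outside the map / component are counted as dropped
  s <- set_distance(m, c(ids[1], "ghost1"), c(ids[2], "ghost2"))
  expect_equal(s$n_dropped, 2L)
})

test_that("null_distribution has C(k,2) comparisons and handles degenerate sets", {
  m <- path_map(6)
  db3 <- condition_db(data.frame(
    condition = rep(c("A", "B", "C"), each = 2), motive = "m",
    protein = c("v01", "v02", "v03", "v04", "v05", "v06")))
  nd <- null_distribution(m, db3)
  expect_equal(nd$n_comparisons, 3L)
  expect_s3_class(tidy(nd), "tbl_df")
  # all conditions identical -> all distances 0, sd 0
  dbi <- condition_db(data.frame(
    condition = rep(c("A", "B", "C"), each = 2), motive = "m",
    protein = rep(c("v01", "v02"), 3)))
  ndi <- null_distribution(m, dbi)
  expect_true(all(tidy(ndi)$value == 0))
  expect_equal(ndi$sd, 0)
  # conditions entirely off-map are skipped with a warning
  dbo <- condition_db(data.frame(
    condition = c("A", "A", "B", "B", "Z"), motive = "m",
    protein = c("v01", "v02", "v03", "v04", "offmap")))
  expect_warning(ndo <- null_distribution(m, dbo), "skipped")
  expect_equal(ndo$n_comparisons, 1L)
  expect_error(
    suppressWarnings(null_distribution(m, condition_db(
      data.frame(condition = "A", motive = "m", protein = "v01")))),
    "at least 2")
})

test_that("null mean and sd match a naive double-loop recomputation", {
  uni <- generate_universe(150, 2, seed = 31)
  db <- generate_condition_db(uni, n_conditions = 15,
                              effectors_per_condition = c(4, 8),
                              motives_per_condition = c(1, 2), seed = 32)
  nd <- null_distribution(uni, db)
  ids <- map_nodes(uni)$id
  D <- igraph::distances(uni$graph)
  sets <- lapply(split(db$protein, db$condition), unique)
  vals <- c()
  nm <- names(sets)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) vals <- c(vals, oracle_set_stats(D, sets[[i]], sets[[j]])$pooled_mean)
  }
  expect_equal(nd$n_comparisons, choose(15, 2))
  expect_equal(nd$mean, mean(vals), tolerance = 1e-13)
  expect_equal(nd$sd, sd(vals), tolerance = 1e-13)
})

test_that("percentile_of is a valid closed ECDF with a normal comparison", {
  nd <- structure(list(values = tibble::tibble(value = c(1, 2, 3, 4)),
                       statistic = "pooled_mean", n_comparisons = 4L,
                       mean = 2.5, sd = sd(1:4), ecdf = ecdf(c(1, 2, 3, 4))),
                  class = "null_distribution")
  expect_equal(percentile_of(nd, 0.5)$percentile, 0)
  expect_equal(percentile_of(nd, 2)$percentile, 0.5)
  expect_equal(percentile_of(nd, 4)$percentile, 1)
  expect_equal(percentile_of(nd, nd$mean + 10 * nd$sd)$percentile, 1)
  grid <- percentile_of(nd, seq(0, 5, by = 0.1))
  expect_true(all(diff(grid$percentile) >= 0))
  expect_true(all(grid$percentile >= 0 & grid$percentile <= 1))
  expect_true(all(abs(grid$normal_percentile - pnorm(grid$d, 2.5, sd(1:4))) < 1e-12))
})

test_that("pathway-to-motive tables agree with per-cell set_distance calls", {
  uni <- generate_universe(120, 2, seed = 8)
  ids <- map_nodes(uni)$id
  db <- condition_db(data.frame(
    condition = "focal",
    motive = rep(c("m1", "m2"), each = 4),
    protein = ids[11:18]))
  pw <- list(alpha = ids[1:5], beta = ids[21:26])
  tab <- pathway_to_motive_distances(uni, pw, db, "focal")
  expect_equal(nrow(tab), 4)
  for (i in seq_len(nrow(tab))) {
    ref <- set_distance(uni, pw[[tab$pathway[i]]],
                        effectors(db, "focal", tab$motive[i]))
    expect_equal(tab$pooled_mean[i], ref$pooled_mean)
    expect_equal(tab$min_pairwise[i], ref$min_pairwise)
  }
  # identity row: pathway equal to the motive set
  tab0 <- pathway_to_motive_distances(uni, list(self = ids[11:14]), db, "focal")
  expect_equal(tab0$pooled_mean[tab0$motive == "m1"], 0)
  expect_equal(tab0$min_pairwise[tab0$motive == "m1"], 0L)
})
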