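edge_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("edge lists are deduplicated, de-looped and validated", {
  f <- edge_file(c("gene_a\tgene_b", "a\tb", "b\ta", "a\ta"))
  expect_message(expect_message(g <- load_edge_list(f), "self-loop"),
                 "duplicate")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)

  tri <- load_edge_list(edge_file(c("# comment", "a\tb", "b\tc", "c\ta")))
  expect_equal(igraph::vcount(tri), 3)
  expect_equal(igraph::ecount(tri), 3)
  expect_true(igraph::is_connected(tri))

  expect_error(load_edge_list(edge_file(character(0))), "empty")
  expect_error(load_edge_list(edge_file(c("a\tb", "broken-line"))),
               "line 2")
  expect_error(load_edge_list(tempfile()), "not found")
})

test_that("largest connected component extraction and its tie rule", {
  g <- load_edge_list(edge_file(c("a\tb", "b\tc", "c\ta", "x\ty")))
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c"))
  # already-connected graph maps to itself
  expect_equal(igraph::vcount(largest_connected_component(lcc)), 3)
  # equal-size components: the one holding the alphabetically first node wins
  g2 <- load_edge_list(edge_file(c("m\tn", "a\tz")))
  expect_setequal(igraph::V(largest_connected_component(g2))$name,
                  c("a", "z"))
})

test_that("geodesic distances: path graph, symmetry, unknown nodes", {
  g <- load_edge_list(edge_file(c("a\tb", "b\tc")))
  D <- geodesic_distances(g)
  expect_equal(D["a", "c"], 2)
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D, t(D))
  expect_error(geodesic_distances(g, "nope"), "nope")
})

test_that("BFS distances equal an independent all-pairs oracle", {
  g <- generate_network(200, 6, "erdos_renyi", seed = 17)
  ed <- igraph::as_edgelist(g)
  D_oracle <- oracle_all_pairs_bfs(as.data.frame(ed), igraph::V(g)$name)
  D <- geodesic_distances(g)
  expect_equal(D, D_oracle[rownames(D), colnames(D)])
})

test_that("localization test: planted module, calibration, self-comparison", {
  # ring lattice: a contiguous block has much smaller internal distances
  g <- generate_network(100, 4, "watts_strogatz", seed = 3, rewire_p = 0)
  block <- igraph::V(g)$name[1:8]
  r <- localization_test(g, block)
  expect_lt(r$p, 1e-4)
  expect_lt(r$median_subset, r$median_all)
  # subset = all nodes compares a distribution with itself
  r_all <- localization_test(g, igraph::V(g)$name)
  expect_gt(r_all$p, 0.3)
  # random subsets are not localized (calibration at a light touch)
  set.seed(4)
  p_rand <- replicate(20, localization_test(
    g, sample(igraph::V(g)$name, 10))$p)
  expect_gt(mean(p_rand > 0.05), 0.7)
  # nodes off the network are dropped with a warning; too few survivors error
  expect_warning(localization_test(g, c(block, "ghost")), "dropped")
  expect_error(suppressWarnings(localization_test(g, c("ghost", "wraith"))),
               "fewer than 2")
})

test_that("degree comparison sees hubs and nothing in random subsets", {
  g <- generate_network(300, 6, "barabasi_albert", seed = 5)
  deg <- igraph::degree(g)
  hubs <- names(sort(deg, decreasing = TRUE))[1:30]
  expect_lt(degree_comparison(g, hubs)$p, 1e-6)
  expect_equal(degree_comparison(g, igraph::V(g)$name)$D, 0)
  set.seed(6)
  expect_gt(degree_comparison(g, sample(igraph::V(g)$name, 50))$p, 0.01)
  expect_error(degree_comparison(g, character(0)))
})

test_that("distance-phase profile reports per-class medians", {
  g <- load_edge_list(edge_file(c("a\tb", "b\tc", "c\td")))
  # two genes at distance 1, phases 3 and 7 -> one pair, median 4
  pr <- phase_distance_profile(g, c(a = 3, b = 7), min_pairs = 1)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$d, 1L)
  expect_equal(pr$n_pairs, 1L)
  expect_equal(pr$median_dphi, 4)
  # identical phases: median 0 at every distance
  pr0 <- phase_distance_profile(g, c(a = 5, b = 5, c = 5, d = 5),
                                min_pairs = 1)
  expect_true(all(pr0$median_dphi == 0))
  expect_equal(pr0$d, 1:3)
  # uniform phases on a large graph: median near 6 h at every distance
  g2 <- generate_network(300, 8, "erdos_renyi", seed = 19)
  set.seed(20)
  ph <- setNames(runif(300, 0, 24), igraph::V(g2)$name)
  pr6 <- phase_distance_profile(largest_connected_component(g2), ph,
                                min_pairs = 50)
  expect_true(all(abs(pr6$median_dphi - 6) < 1))
})

test_that("median trend: exact line, flat convention, planted slope", {
  mk_prof <- function(d, m) {
    out <- data.frame(d = d, n_pairs = 100L, median_dphi = m)
    class(out) <- c("phase_distance_profile", "data.frame")
    out
  }
  tr <- median_trend(mk_prof(1:3, c(2, 3, 4)))
  expect_equal(tr$slope, 1)
  flat <- median_trend(mk_prof(1:4, rep(3, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  expect_error(median_trend(mk_prof(1:2, c(1, 2))), ">= 3 distance classes")
  set.seed(8)
  cover <- replicate(50, {
    m <- 2 + 0.5 * (1:6) + rnorm(6, 0, 0.2)
    fit <- median_trend(mk_prof(1:6, m))
    se <- 0.2 / sqrt(sum((1:6 - 3.5)^2))
    abs(fit$slope - 0.5) < 3 * se
  })
  expect_gt(mean(cover), 0.9)
})

test_that("permutation null preserves invariants and is seed-deterministic", {
  g <- largest_connected_component(
    generate_network(150, 8, "erdos_renyi", seed = 23))
  set.seed(24)
  nodes <- sample(igraph::V(g)$name, 40)
  ph <- setNames(runif(40, 0, 24), nodes)
  org1 <- permutation_null(g, ph, n_perm = 200, seed = 5, min_pairs = 10)
  org2 <- permutation_null(g, ph, n_perm = 200, seed = 5, min_pairs = 10)
  expect_identical(org1$profile, org2$profile)
  expect_identical(org1$null_medians, org2$null_medians)
  # add-one estimator: p in [1/(n+1), 1], never 0
  expect_true(all(org1$profile$empirical_p >= 1 / 201))
  expect_true(all(org1$profile$empirical_p <= 1))
  # the stored null vectors reproduce the reported p (auditability)
  j <- 1
  p_re <- (1 + sum(org1$null_medians[, j] <= org1$profile$median_dphi[j],
                   na.rm = TRUE)) /
    (1 + sum(!is.na(org1$null_medians[, j])))
  expect_equal(org1$profile$empirical_p[j], p_re)
  # null medians converge on the all-pairs median of the phase multiset
  all_pairs_med <- median(phase_difference(outer(ph, ph, "-"),
                                           0)[upper.tri(diag(40))])
  expect_lt(abs(mean(org1$null_medians[, j]) - all_pairs_med), 0.5)

  # degenerate phases: everything identical -> p = 1 in every class
  ph0 <- setNames(rep(4, 40), nodes)
  org0 <- permutation_null(g, ph0, n_perm = 100, seed = 6, min_pairs = 10)
  expect_true(all(org0$profile$empirical_p == 1))
  expect_true(all(org0$profile$median_dphi == 0))

  # disconnected input and off-network genes are rejected
  g2 <- suppressWarnings(igraph::disjoint_union(g, igraph::make_ring(3)))
  expect_error(permutation_null(g2, ph, n_perm = 10), "connected")
  ph_bad <- c(ph, ghost = 1)
  expect_error(permutation_null(g, ph_bad, n_perm = 10), "ghost")
})

test_that("the bundled synthetic fixture network loads and is usable", {
  f <- system.file("extdata", "synthetic_network_edges.tsv",
                   package = "circanet")
  g <- load_edge_list(f)
  expect_equal(igraph::vcount(g), 80)
  expect_gt(igraph::ecount(g), 100)
  lcc <- largest_connected_component(g)
  expect_gte(igraph::vcount(lcc), 60)
})
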