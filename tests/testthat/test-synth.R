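test_that("network generator hits the complete-graph limit and is seeded", {
  k4 <- generate_network(4, 3, "erdos_renyi", seed = 1)
  expect_equal(igraph::ecount(k4), 6)
  expect_equal(igraph::vcount(k4), 4)
  g1 <- generate_network(100, 6, "watts_strogatz", seed = 1)
  g2 <- generate_network(100, 6, "watts_strogatz", seed = 1)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  g3 <- generate_network(100, 6, "watts_strogatz", seed = 2)
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
  # odd mean degree cannot define the ring lattice
  expect_error(generate_network(100, 5, "watts_strogatz"), "even mean_degree")
})

test_that("Erdos-Renyi mean degree matches its binomial expectation", {
  g <- generate_network(500, 8, "erdos_renyi", seed = 7)
  p <- 8 / 499
  # mean degree = 2E/n; Var(E) binomial over C(n,2) pairs
  se <- sqrt(4 * choose(500, 2) * p * (1 - p)) / 500
  expect_lt(abs(mean(igraph::degree(g)) - 8), 3 * se)
  expect_equal(sum(igraph::which_loop(g)), 0)
  expect_equal(sum(igraph::which_multiple(g)), 0)
})

test_that("planted phases are uniform and unorganized at coupling zero", {
  med_nb <- vapply(1:20, function(s) {
    net <- generate_network(200, 8, "erdos_renyi", seed = s)
    truth <- plant_phases(net, 1, coupling = 0, seed = s)
    ed <- igraph::as_edgelist(net)
    ph <- setNames(truth$phase_true, truth$gene_id)
    median(phase_difference(ph[ed[, 1]], ph[ed[, 2]]))
  }, 0)
  # uniform circular differences have median 6 h on the folded 0-12 h scale
  expect_lt(abs(mean(med_nb) - 6), 0.5)
})

test_that("coupling plus smoothing synchronizes network neighbours", {
  closer <- vapply(1:20, function(s) {
    net <- generate_network(200, 8, "erdos_renyi", seed = s)
    truth <- plant_phases(net, 0.5, coupling = 0.9, n_smooth = 20, seed = s)
    ph <- setNames(truth$phase_true, truth$gene_id)
    cyc <- truth$gene_id[truth$is_cycling]
    ed <- igraph::as_edgelist(igraph::induced_subgraph(net, cyc))
    nb <- median(phase_difference(ph[ed[, 1]], ph[ed[, 2]]))
    rnd <- median(phase_difference(sample(ph[cyc]), sample(ph[cyc])))
    nb < rnd
  }, TRUE)
  expect_gte(mean(closer), 0.95)
})

test_that("truth table bookkeeping: counts, flat genes, phase domain", {
  net <- generate_network(50, 4, "erdos_renyi", seed = 2)
  truth <- plant_phases(net, 1, seed = 2)
  expect_equal(sum(truth$is_cycling), 50)
  truth2 <- plant_phases(net, 0.4, seed = 2)
  expect_equal(sum(truth2$is_cycling), 20)
  flat <- truth2[!truth2$is_cycling, ]
  expect_true(all(flat$amplitude_true == 0))
  expect_true(all(is.na(flat$phase_true)))
  cyc <- truth2[truth2$is_cycling, ]
  expect_true(all(cyc$phase_true >= 0 & cyc$phase_true < 24))
  expect_true(all(truth2$mesor_true > 0))
})

test_that("noiseless simulation reproduces the cosinor model exactly", {
  truth <- data.frame(gene_id = c("cyc", "flat"), is_cycling = c(TRUE, FALSE),
                      phase_true = c(8, NA), amplitude_true = c(3, 0),
                      mesor_true = c(5, 7), condition = "18C",
                      stringsAsFactors = FALSE)
  design <- sim_design(noise_cv = 0, phase_jitter_sd = 0, seed = 1)
  mats <- simulate_experiment(truth, design)
  expect_named(mats, c("V1_18C", "V2_18C"))
  t <- tc_times <- mats$V1_18C$sample_meta$zt_hours
  expect_equal(unname(mats$V1_18C$values["cyc", ]),
               5 + 3 * cos(2 * pi * (t - 8) / 24), tolerance = 1e-12)
  expect_equal(unname(mats$V2_18C$values["flat", ]), rep(7, length(t)))
})

test_that("lognormal noise has the designed coefficient of variation", {
  truth <- data.frame(gene_id = paste0("g", 1:1000), is_cycling = FALSE,
                      phase_true = NA_real_, amplitude_true = 0,
                      mesor_true = 50, condition = "25C",
                      stringsAsFactors = FALSE)
  design <- sim_design(noise_cv = 0.2, seed = 4)
  m <- simulate_experiment(truth, design)$V1_25C$values
  cv <- apply(m, 1, function(x) sd(x) / mean(x))
  expect_lt(abs(mean(cv) - 0.2), 0.01)
  expect_true(all(m >= 0))
})

test_that("fixture bundles round-trip through the readers, byte-stable", {
  study <- make_small_study(n_nodes = 60, seed = 5)
  out1 <- file.path(tempdir(), "bundle1")
  out2 <- file.path(tempdir(), "bundle2")
  write_fixture_bundle(out1, study$net, study$truths, study$matrices)
  study_again <- make_small_study(n_nodes = 60, seed = 5)
  write_fixture_bundle(out2, study_again$net, study_again$truths,
                       study_again$matrices)

  g <- load_edge_list(file.path(out1, "edges.tsv"))
  expect_setequal(igraph::V(g)$name[igraph::degree(g) > 0],
                  igraph::V(study$net)$name[igraph::degree(study$net) > 0])
  ek <- function(gr) {
    e <- igraph::as_edgelist(gr)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(ek(g), ek(study$net))

  tc <- read_time_course(file.path(out1, "V1_18C_tpm.tsv"),
                         file.path(out1, "V1_18C_meta.tsv"))
  expect_equal(tc$values, study$matrices$V1_18C$values, tolerance = 1e-12)
  expect_equal(nrow(tc$sample_meta), ncol(tc$values))

  # same seed, fresh generation: byte-identical numeric content
  for (f in list.files(out1)) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
  unlink(c(out1, out2), recursive = TRUE)
})
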