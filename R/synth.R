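#' Generate a synthetic gene-interaction network
#'
#' Random undirected simple graphs standing in for a curated interaction
#' network (e.g. a pathway-database export), with synthetic gene identifiers
#' `g0001`, `g0002`, ... as node names. Three standard models are supported;
#' `mean_degree` parameterises each one (edge probability
#' `mean_degree/(n-1)` for Erdős–Rényi, `mean_degree/2` lattice neighbours
#' for Watts–Strogatz, `mean_degree/2` edges per new node for
#' Barabási–Albert).
#'
#' @param n_nodes number of genes (>= 3).
#' @param mean_degree target mean degree, < `n_nodes`.
#' @param model one of `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"barabasi_albert"`.
#' @param seed integer seed; the same seed reproduces the same edge set.
#' @param rewire_p Watts–Strogatz rewiring probability.
#' @return an [igraph::igraph] object (undirected, simple, named nodes).
#' @export
generate_network <- function(n_nodes, mean_degree,
                             model = c("erdos_renyi", "watts_strogatz",
                                       "barabasi_albert"),
                             seed = 1L, rewire_p = 0.05) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 3, mean_degree > 0, mean_degree < n_nodes)
  g <- with_stream(seed, "network", {
    switch(model,
      erdos_renyi = igraph::sample_gnp(n_nodes, p = mean_degree / (n_nodes - 1)),
      watts_strogatz = {
        nei <- mean_degree / 2
        if (nei != round(nei) || nei < 1)
          stop("watts_strogatz requires an even mean_degree >= 2 ",
               "(ring-lattice neighbourhood size mean_degree/2)")
        igraph::sample_smallworld(1, n_nodes, nei = nei, p = rewire_p)
      },
      barabasi_albert = {
        m <- max(1L, round(mean_degree / 2))
        igraph::sample_pa(n_nodes, m = m, directed = FALSE)
      })
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("g%04d", seq_len(n_nodes))
  g
}

#' Plant cycling genes and network-organized phases
#'
#' Marks a uniform random subset of nodes as cycling, draws their peak phases
#' uniformly on `[0, 24)`, then applies `n_smooth` rounds of circular
#' relaxation: each cycling node's unit phasor is replaced by
#' `(1 - coupling) * own + coupling * mean(phasor of cycling neighbours)` and
#' renormalised. `coupling = 0` leaves phases independent of network position;
#' `coupling` near 1 with enough rounds synchronises network-adjacent cyclers,
#' planting the distance-decaying phase similarity the organization test is
#' designed to detect. Cycling nodes with no cycling neighbour keep their
#' phase.
#'
#' Baseline expression (mesor) is drawn lognormally for every gene, and
#' cycling genes get amplitude `rel_amplitude * mesor`; non-cycling genes
#' have amplitude 0 and no phase.
#'
#' @param net an igraph network with named nodes (see [generate_network()]).
#' @param frac_cycling fraction of nodes marked cycling, in (0, 1].
#' @param coupling neighbour-coupling strength in `[0, 1]`.
#' @param n_smooth number of relaxation rounds (>= 0).
#' @param seed integer seed.
#' @param condition condition label stored in the truth table.
#' @param mesor_meanlog,mesor_sdlog lognormal parameters of baseline TPM.
#' @param rel_amplitude amplitude of cycling genes as a fraction of mesor.
#' @return a `data.frame` truth table with columns `gene_id`, `is_cycling`,
#'   `phase_true` (hours in `[0,24)`, `NA` for flat genes), `amplitude_true`,
#'   `mesor_true`, `condition`.
#' @export
plant_phases <- function(net, frac_cycling, coupling = 0, n_smooth = 0,
                         seed = 1L, condition = "18C",
                         mesor_meanlog = log(30), mesor_sdlog = 0.8,
                         rel_amplitude = 0.5) {
  stopifnot(frac_cycling > 0, frac_cycling <= 1,
            coupling >= 0, coupling <= 1, n_smooth >= 0)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  n_cyc <- round(frac_cycling * n)
  with_stream(seed, "planting", {
    cyc_idx <- sort(sample.int(n, n_cyc))
    phase0 <- runif(n_cyc, 0, 24)
    mesor <- rlnorm(n, meanlog = mesor_meanlog, sdlog = mesor_sdlog)
    z <- exp(1i * phase0 * 2 * pi / 24)
    if (coupling > 0 && n_smooth > 0 && n_cyc >= 2) {
      # adjacency restricted to cycling nodes; synchronous relaxation
      sub <- igraph::induced_subgraph(net, cyc_idx)
      A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
      deg <- rowSums(A)
      has_nb <- deg > 0
      for (it in seq_len(n_smooth)) {
        nb_mean <- as.vector(A %*% z)
        nb_mean[has_nb] <- nb_mean[has_nb] / deg[has_nb]
        znew <- z
        znew[has_nb] <- (1 - coupling) * z[has_nb] + coupling * nb_mean[has_nb]
        mod <- Mod(znew)
        keep <- mod > 1e-12
        z[keep] <- znew[keep] / mod[keep]  # degenerate phasors keep old phase
      }
    }
    phase <- (Arg(z) * 24 / (2 * pi)) %% 24
    out <- data.frame(gene_id = nodes, is_cycling = FALSE,
                      phase_true = NA_real_, amplitude_true = 0,
                      mesor_true = mesor, condition = condition,
                      stringsAsFactors = FALSE)
    out$is_cycling[cyc_idx] <- TRUE
    out$phase_true[cyc_idx] <- phase
    out$amplitude_true[cyc_idx] <- rel_amplitude * mesor[cyc_idx]
    out
  })
}

#' Simulation design for synthetic time courses
#'
#' Sampling every 2 h across a stable two-day window with two independent
#' experiments is the default, matching a replicated circadian profiling
#' design. The two experiments share the planted phases but receive
#' independent multiplicative noise and a small per-gene, per-experiment
#' phase jitter, emulating biological and technical replication error.
#'
#' @param timepoints strictly increasing ZT hours; at least 6 per 24 h cycle.
#' @param n_replicates replicates per timepoint.
#' @param experiments experiment labels.
#' @param period oscillation period in hours (fixed 24 for circadian use).
#' @param noise_cv coefficient of variation of lognormal multiplicative noise.
#' @param phase_jitter_sd SD (hours) of the per-gene inter-experiment phase
#'   jitter.
#' @param seed integer master seed.
#' @return a list of class `sim_design`.
#' @export
sim_design <- function(timepoints = seq(0, 46, by = 2), n_replicates = 1,
                       experiments = c("V1", "V2"), period = 24,
                       noise_cv = 0.2, phase_jitter_sd = 0.5, seed = 1L) {
  stopifnot(all(diff(timepoints) > 0), n_replicates >= 1,
            length(experiments) >= 1, noise_cv >= 0, phase_jitter_sd >= 0)
  span <- max(timepoints) - min(timepoints)
  if (length(timepoints) < 6 * max(1, span / period))
    stop("need >= 6 timepoints per ", period,
         " h cycle to resolve one harmonic")
  structure(list(timepoints = timepoints, n_replicates = n_replicates,
                 experiments = experiments, period = period,
                 noise_cv = noise_cv, phase_jitter_sd = phase_jitter_sd,
                 seed = seed),
            class = "sim_design")
}

#' Simulate replicated time-course TPM matrices from a truth table
#'
#' For each experiment, a cycling gene g is observed as
#' `mesor + amplitude * cos(2*pi*(t - phase - eps)/period)` where
#' `eps ~ N(0, phase_jitter_sd)` is drawn once per gene per experiment; flat
#' genes sit at their mesor. Every observation is multiplied by lognormal
#' noise with unit mean and the design's coefficient of variation, and
#' clipped at zero (a guard only — multiplicative lognormal noise cannot
#' produce negative TPM).
#'
#' @param truth a truth table from [plant_phases()].
#' @param design a [sim_design()].
#' @return named list of [time_course_matrix()] objects, one per experiment,
#'   named `<experiment>_<condition>`.
#' @export
simulate_experiment <- function(truth, design) {
  stopifnot(inherits(design, "sim_design"),
            all(c("gene_id", "is_cycling", "phase_true", "amplitude_true",
                  "mesor_true", "condition") %in% names(truth)))
  condition <- unique(truth$condition)
  if (length(condition) != 1)
    stop("truth table must carry a single condition label")
  tp <- rep(design$timepoints, each = design$n_replicates)
  repl <- rep(seq_len(design$n_replicates), times = length(design$timepoints))
  n_g <- nrow(truth)
  n_s <- length(tp)
  amp <- truth$amplitude_true
  phase <- ifelse(truth$is_cycling, truth$phase_true, 0)
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  out <- list()
  for (exp_lab in design$experiments) {
    key <- paste0(exp_lab, "_", condition)
    values <- with_stream(design$seed, paste0("noise_", key), {
      eps <- rnorm(n_g, 0, design$phase_jitter_sd)
      ang <- outer(phase + eps, tp,
                   function(ph, t) 2 * pi * (t - ph) / design$period)
      mu <- truth$mesor_true + amp * cos(ang)
      if (design$noise_cv > 0) {
        # unit-mean lognormal noise: meanlog = -sdlog^2/2
        noise <- matrix(rlnorm(n_g * n_s, meanlog = -sdlog^2 / 2,
                               sdlog = sdlog), n_g, n_s)
        mu <- mu * noise
      }
      pmax(mu, 0)
    })
    sample_id <- sprintf("%s_%s_ZT%02g_r%d", exp_lab, condition, tp, repl)
    rownames(values) <- truth$gene_id
    colnames(values) <- sample_id
    meta <- data.frame(sample_id = sample_id, zt_hours = tp,
                       replicate = repl, experiment = exp_lab,
                       condition = condition, stringsAsFactors = FALSE)
    out[[key]] <- time_course_matrix(values, meta)
  }
  out
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the network edge list (`edges.tsv`), the ground-truth table
#' (`truth.tsv`) and, for every time-course matrix, an expression TSV
#' (`<key>_tpm.tsv`) plus sample-metadata TSV (`<key>_meta.tsv`). The files
#' round-trip losslessly through [load_edge_list()] and [read_time_course()].
#'
#' @param outdir output directory (created if needed).
#' @param net igraph network.
#' @param truth one truth table, or a list of truth tables (one per
#'   condition) which are row-bound.
#' @param matrices named list of [time_course_matrix()] objects.
#' @return invisibly, a named list of written paths.
#' @export
write_fixture_bundle <- function(outdir, net, truth, matrices) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!is.data.frame(truth)) truth <- do.call(rbind, truth)
  paths <- list()
  ed <- igraph::as_edgelist(net)
  edge_path <- file.path(outdir, "edges.tsv")
  ok <- tryCatch({
    writeLines(c("gene_a\tgene_b", paste(ed[, 1], ed[, 2], sep = "\t")),
               edge_path)
    TRUE
  }, error = function(e) stop("failed writing ", edge_path, ": ",
                              conditionMessage(e)))
  paths$edges <- edge_path
  paths$truth <- file.path(outdir, "truth.tsv")
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (key in names(matrices)) {
    expr_path <- file.path(outdir, paste0(key, "_tpm.tsv"))
    meta_path <- file.path(outdir, paste0(key, "_meta.tsv"))
    write_time_course(matrices[[key]], expr_path, meta_path)
    paths[[paste0(key, "_tpm")]] <- expr_path
    paths[[paste0(key, "_meta")]] <- meta_path
  }
  invisible(paths)
}
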