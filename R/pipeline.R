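#' Build a validated pipeline configuration
#'
#' Assembles and checks the configuration for [run_pipeline()]. `matrices`
#' names the four input time courses (two experiments x two conditions);
#' each entry is a list with `expr` and `meta` TSV paths, keyed
#' `<experiment>_<condition>` (e.g. `V1_18C`). Thresholds default to the
#' standard design: median TPM filter 5, per-experiment p < 0.1,
#' inter-experiment phase agreement < 3 h, 24 h period, 5000 permutations.
#'
#' @param matrices named list of `list(expr=, meta=)` path pairs.
#' @param edge_list path to the network edge-list TSV.
#' @param outdir output directory.
#' @param experiments,conditions label vectors (2 each by default).
#' @param median_tpm,p_thresh,dphi_max,period,n_perm,min_pairs thresholds.
#' @param seed master seed.
#' @param log_transform fit harmonics on `log2(TPM+1)`.
#' @param alternative sidedness of the permutation test.
#' @param plotting write a profile plot per condition (PDF).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrices, edge_list, outdir,
                            experiments = c("V1", "V2"),
                            conditions = c("18C", "25C"),
                            median_tpm = 5, p_thresh = 0.1, dphi_max = 3,
                            period = 24, n_perm = 5000, min_pairs = 50,
                            seed = 1L, log_transform = FALSE,
                            alternative = "less", plotting = FALSE) {
  stopifnot(median_tpm > 0, p_thresh > 0, dphi_max > 0, period > 0,
            n_perm >= 1, min_pairs >= 1)
  want <- as.vector(outer(experiments, conditions, paste, sep = "_"))
  miss <- setdiff(want, names(matrices))
  if (length(miss))
    stop("config$matrices lacks entries: ", paste(miss, collapse = ", "))
  for (key in want) {
    m <- matrices[[key]]
    if (!is.list(m) || is.null(m$expr) || is.null(m$meta))
      stop("matrices$", key, " must be list(expr=, meta=)")
  }
  structure(list(matrices = matrices, edge_list = edge_list, outdir = outdir,
                 experiments = experiments, conditions = conditions,
                 median_tpm = median_tpm, p_thresh = p_thresh,
                 dphi_max = dphi_max, period = period, n_perm = n_perm,
                 min_pairs = min_pairs, seed = as.integer(seed),
                 log_transform = log_transform, alternative = alternative,
                 plotting = plotting),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full circadian network analysis pipeline
#'
#' Executes, in order: expression filtering, per-experiment harmonic fits,
#' dual-experiment cycling calls per condition, phase-distribution analyses
#' (KS comparison between conditions, density peaks, paired phase shift of
#' common cyclers, circular correlation, variance and amplitude signed-rank
#' tests), and the network stage (LCC extraction, representativeness, degree
#' and localization tests, distance-phase profile with trend and permutation
#' null). All stage outputs are written under `config$outdir` as TSV/JSON
#' along with a run manifest (configuration, seed, package version, stage
#' counts). Identical configuration and seed yield identical outputs.
#'
#' @param config a [pipeline_config()], or a YAML path understood by
#'   [read_pipeline_config()].
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(config = unclass(cfg), package_version =
                   as.character(utils::packageVersion("circanet")))

  ## --- load + filter ------------------------------------------------------
  mats <- stage("load", {
    out <- lapply(cfg$matrices, function(m) read_time_course(m$expr, m$meta))
    names(out) <- names(cfg$matrices)
    out
  })
  retained <- stage("filter",
                    median_expression_filter(mats, cfg$median_tpm,
                                             experiments = cfg$experiments,
                                             conditions = cfg$conditions))
  writeLines(retained, file.path(cfg$outdir, "retained_genes.txt"))
  report$counts <- list(genes_input = nrow(mats[[1]]$values),
                        genes_retained = length(retained))

  ## --- harmonic fits + cycling calls --------------------------------------
  keys <- as.vector(outer(cfg$experiments, cfg$conditions, paste, sep = "_"))
  fits <- stage("fit", {
    f <- lapply(keys, function(key) {
      tc <- mats[[key]]
      fit_harmonic_matrix(tc$values[retained, , drop = FALSE],
                          times = tc_times(tc), period = cfg$period,
                          log_transform = cfg$log_transform)
    })
    names(f) <- keys
    f
  })
  for (key in keys)
    write.table(fits[[key]], file.path(cfg$outdir, paste0("fits_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- stage("call", {
    cl <- lapply(cfg$conditions, function(cond) {
      call_cycling(fits[[paste0(cfg$experiments[1], "_", cond)]],
                   fits[[paste0(cfg$experiments[2], "_", cond)]],
                   p_thresh = cfg$p_thresh, dphi_max_hours = cfg$dphi_max,
                   condition = cond)
    })
    names(cl) <- cfg$conditions
    cl
  })
  n_called <- vapply(calls, function(x) sum(x$is_cycling), 0L)
  common_cyc <- Reduce(intersect, lapply(calls, function(x)
    x$gene_id[x$is_cycling]))
  fdr <- chance_fdr_summary(length(retained),
                            pmax(n_called, 1L),
                            cfg$p_thresh, cfg$dphi_max)
  report$cycling <- list(
    n_tested = length(retained), n_called = as.list(n_called),
    n_overlap = length(common_cyc),
    expected_by_chance = fdr$expected_chance,
    fdr_percent = as.list(setNames(as.numeric(fdr$fdr_percent),
                                   names(n_called))))
  for (cond in cfg$conditions)
    write.table(calls[[cond]],
                file.path(cfg$outdir, paste0("calls_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- phase analyses ------------------------------------------------------
  report$phase <- stage("phases", {
    ph <- list()
    c1 <- cfg$conditions[1]; c2 <- cfg$conditions[2]
    if (all(n_called >= 5)) {
      ph$ks_between_conditions <-
        compare_phase_distributions(calls[[c1]], calls[[c2]])
      ph$density_peaks <- lapply(calls, function(x) {
        pk <- phase_density_peaks(x)
        list(peak_zt = pk$peak_zt, density = pk$density)
      })
    }
    if (length(common_cyc) >= 3) {
      shift <- paired_phase_shift(calls[[c1]], calls[[c2]])
      write.table(shift$per_gene,
                  file.path(cfg$outdir, "paired_phase_shift.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ph$paired_shift <- shift[c("mean_shift", "fraction_advance", "n")]
      pa <- calls[[c1]]$consensus_phase[match(common_cyc,
                                              calls[[c1]]$gene_id)]
      pb <- calls[[c2]]$consensus_phase[match(common_cyc,
                                              calls[[c2]]$gene_id)]
      ph$circular_correlation_common <-
        as.numeric(circular_correlation(pa, pb))
    }
    # variance: condition vs condition within each experiment, on the
    # filtered universe (dominated by non-rhythmic genes)
    ph$variance <- lapply(cfg$experiments, function(ex) {
      paired_variance_test(mats[[paste0(ex, "_", c1)]],
                           mats[[paste0(ex, "_", c2)]], retained)
    })
    names(ph$variance) <- cfg$experiments
    if (length(common_cyc) >= 2) {
      ph$amplitude <- lapply(cfg$experiments, function(ex) {
        paired_amplitude_test(fits[[paste0(ex, "_", c1)]],
                              fits[[paste0(ex, "_", c2)]], common_cyc)
      })
      names(ph$amplitude) <- cfg$experiments
    }
    ph
  })

  ## --- network stage --------------------------------------------------------
  report$network <- stage("network", {
    net <- load_edge_list(cfg$edge_list)
    lcc <- largest_connected_component(net)
    res <- list(n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
                lcc_nodes = igraph::vcount(lcc),
                lcc_edges = igraph::ecount(lcc))
    for (cond in cfg$conditions) {
      ph <- named_phases(calls[[cond]])
      on_net <- intersect(names(ph), igraph::V(lcc)$name)
      r <- list(n_cycling = length(ph), n_on_lcc = length(on_net))
      if (length(on_net) >= 3) {
        r$representativeness <-
          representativeness_test(ph[on_net], as.numeric(ph))
        r$degree <- degree_comparison(lcc, on_net)
        if (length(on_net) >= 2)
          r$localization <- localization_test(lcc, on_net,
                                              seed = cfg$seed)
        org <- tryCatch(
          permutation_null(lcc, ph[on_net], n_perm = cfg$n_perm,
                           seed = substream_seed(cfg$seed,
                                                 paste0("perm_", cond)),
                           min_pairs = cfg$min_pairs,
                           alternative = cfg$alternative),
          error = function(e) e)
        if (!inherits(org, "error")) {
          write.table(org$profile,
                      file.path(cfg$outdir,
                                paste0("phase_organization_", cond, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          if (isTRUE(cfg$plotting)) {
            grDevices::pdf(file.path(cfg$outdir,
                                     paste0("profile_", cond, ".pdf")))
            plot(org, main = cond)
            grDevices::dev.off()
          }
          r$organization <- list(
            profile = org$profile[, c("d", "n_pairs", "median_dphi",
                                      "empirical_p")],
            trend = org$trend)
        } else {
          r$organization <- list(skipped = conditionMessage(org))
        }
      }
      res[[cond]] <- r
    }
    res
  })

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   package_version = report$package_version,
                   r_version = R.version.string,
                   counts = report$counts, cycling = report$cycling)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
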