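#' Load an undirected gene network from a two-column edge list
#'
#' Reads a TSV with columns `gene_a`, `gene_b` (a header line and leading
#' `#` comment lines are tolerated), drops self-loops and duplicate edges
#' (reporting counts), and returns a simple undirected igraph whose node set
#' is every mentioned gene.
#'
#' @param path edge-list TSV path.
#' @return an igraph object (undirected, simple, named).
#' @export
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("edge list is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed edge-list line(s) (need 2 tab-separated columns) at line ",
         paste(head(lineno[bad], 5), collapse = ", "), " of ", path)
  a <- vapply(parts, `[[`, "", 1)
  b <- vapply(parts, `[[`, "", 2)
  if (identical(tolower(c(a[1], b[1])), c("gene_a", "gene_b"))) {
    a <- a[-1]; b <- b[-1]
  }
  if (!length(a)) stop("edge list has a header but no edges: ", path)
  loops <- a == b
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped from ", basename(path))
  a <- a[!loops]; b <- b[!loops]
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate edge(s) dropped from ", basename(path))
  g <- igraph::graph_from_edgelist(cbind(a[!dup], b[!dup]), directed = FALSE)
  igraph::simplify(g)
}

#' Largest connected component
#'
#' Induced subgraph on the largest component. When several components tie for
#' the largest size, the one containing the lexicographically smallest node
#' name is returned, making the choice deterministic.
#'
#' @param net igraph object (non-empty).
#' @return igraph object: the LCC as an induced subgraph.
#' @export
largest_connected_component <- function(net) {
  stopifnot(igraph::vcount(net) > 0)
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k)
      min(igraph::V(net)$name[comp$membership == k]), "")
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Geodesic (shortest-path hop) distances
#'
#' Unweighted breadth-first-search distances between node sets. Unreachable
#' pairs are `Inf` (they cannot occur within a connected component).
#'
#' @param net igraph object.
#' @param sources,targets character vectors of node names (default: all).
#' @return numeric matrix of hop counts, `sources` x `targets`.
#' @export
geodesic_distances <- function(net, sources = NULL, targets = NULL) {
  all_nodes <- igraph::V(net)$name
  sources <- sources %||% all_nodes
  targets <- targets %||% all_nodes
  unknown <- setdiff(c(sources, targets), all_nodes)
  if (length(unknown))
    stop("node(s) not in network: ", paste(head(unknown, 5), collapse = ", "))
  igraph::distances(net, v = sources, to = targets, algorithm = "unweighted")
}

#' Phase-distribution representativeness of network genes
#'
#' KS comparison of the phases of cycling genes that lie on the network
#' against the phases of all detected cycling genes, to check that the
#' network-covered genes are a representative phase sample before any
#' network-based inference. Delegates to [compare_phase_distributions()].
#'
#' @param phases_network_genes,phases_all_cyclers phase vectors (hours) or
#'   objects accepted by the phase extractor.
#' @inheritParams compare_phase_distributions
#' @return as [compare_phase_distributions()].
#' @export
representativeness_test <- function(phases_network_genes, phases_all_cyclers,
                                    cut = 0) {
  compare_phase_distributions(phases_network_genes, phases_all_cyclers,
                              cut = cut)
}

#' Compare degree distributions of a node subset against the whole network
#'
#' Two-sample KS test between the degrees of `subset` and the degrees of all
#' nodes, asking whether a gene's connectivity is predictive of membership
#' (e.g. of being called cycling).
#'
#' @param net igraph object.
#' @param subset character vector of node names (non-empty, within `net`).
#' @return list with `D`, `p`, `median_subset`, `median_all`, `n_subset`.
#' @export
degree_comparison <- function(net, subset) {
  stopifnot(length(subset) > 0)
  unknown <- setdiff(subset, igraph::V(net)$name)
  if (length(unknown))
    stop("subset node(s) not in network: ",
         paste(head(unknown, 5), collapse = ", "))
  deg_all <- igraph::degree(net)
  deg_sub <- deg_all[subset]
  kt <- suppressWarnings(ks.test(deg_sub, deg_all))
  list(D = unname(kt$statistic), p = kt$p.value,
       median_subset = median(deg_sub), median_all = median(deg_all),
       n_subset = length(subset))
}

#' Network localization of a gene subset
#'
#' Tests whether pairwise geodesic distances within `subset` are smaller than
#' pairwise distances among all nodes of the (assumed connected) network —
#' evidence that the subset clusters on the graph. One-sided Wilcoxon
#' rank-sum, alternative "subset distances smaller". All-pairs distances are
#' computed exactly by repeated BFS; above `pair_ceiling` pairs a uniform
#' subsample of that size is drawn under `seed` and reported in the result.
#'
#' @param net connected igraph object (use [largest_connected_component()]
#'   first). Subset nodes outside the network are dropped with a warning; at
#'   least 2 must survive.
#' @param subset character vector of node names.
#' @param pair_ceiling maximum number of all-pairs distances used exactly.
#' @param seed seed for the subsample, used only above the ceiling.
#' @return list with `statistic`, `p`, `median_subset`, `median_all`,
#'   `n_pairs_subset`, `n_pairs_all`, `subsampled`.
#' @export
localization_test <- function(net, subset, pair_ceiling = 1e7, seed = 1L) {
  nodes <- igraph::V(net)$name
  outside <- setdiff(subset, nodes)
  if (length(outside)) {
    warning(length(outside), " subset node(s) outside the network dropped")
    subset <- intersect(subset, nodes)
  }
  if (length(subset) < 2)
    stop("fewer than 2 subset nodes on the network; localization undefined")
  d_sub <- upper_tri_values(geodesic_distances(net, subset, subset))
  D <- geodesic_distances(net)
  d_all <- upper_tri_values(D)
  subsampled <- FALSE
  if (length(d_all) > pair_ceiling) {
    d_all <- with_stream(seed, "localization_subsample",
                         sample(d_all, pair_ceiling))
    subsampled <- TRUE
  }
  wt <- suppressWarnings(wilcox.test(d_sub, d_all, alternative = "less"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_subset = median(d_sub), median_all = median(d_all),
       n_pairs_subset = length(d_sub), n_pairs_all = length(d_all),
       subsampled = subsampled)
}

upper_tri_values <- function(M) M[upper.tri(M)]

#' Median phase difference by geodesic distance
#'
#' For every unordered pair of cycling genes at geodesic distance
#' `d <= d_max`, the circular phase difference [phase_difference()] is
#' computed; the profile reports the pair count and median difference per
#' distance class with at least `min_pairs` pairs. By default `d_max` is the
#' largest distance retaining `min_pairs` pairs, since medians of sparse
#' classes are unstable.
#'
#' @param distances square distance matrix over cycling genes (named rows and
#'   columns), e.g. from [geodesic_distances()], or a connected igraph from
#'   which it is computed.
#' @param phases named numeric vector of phases (hours) covering the cycling
#'   genes, or an object accepted by the phase extractor carrying `gene_id`.
#' @param d_max maximum distance class (default: all classes with enough
#'   pairs).
#' @param min_pairs minimum pairs per reported class (default 50).
#' @return `data.frame` of class `phase_distance_profile` with columns `d`,
#'   `n_pairs`, `median_dphi`; zero rows (with a warning) when no class
#'   qualifies.
#' @export
phase_distance_profile <- function(distances, phases, d_max = NULL,
                                   min_pairs = 50) {
  ph <- named_phases(phases)
  if (igraph::is_igraph(distances)) {
    genes <- intersect(names(ph), igraph::V(distances)$name)
    distances <- geodesic_distances(distances, genes, genes)
  }
  stopifnot(is.matrix(distances),
            identical(rownames(distances), colnames(distances)))
  genes <- rownames(distances)
  miss <- setdiff(genes, names(ph))
  if (length(miss))
    stop("phases missing for gene(s): ", paste(head(miss, 5), collapse = ", "))
  ph <- ph[genes]
  ut <- upper.tri(distances)
  d <- distances[ut]
  dphi <- phase_difference(outer(ph, ph, "-"), 0)[ut]
  profile_from_pairs(d, dphi, d_max, min_pairs)
}

profile_from_pairs <- function(d, dphi, d_max = NULL, min_pairs = 1) {
  ok <- is.finite(d) & d >= 1
  d <- d[ok]; dphi <- dphi[ok]
  if (!length(d)) {
    warning("no gene pairs at any geodesic distance; empty profile")
    out <- data.frame(d = integer(0), n_pairs = integer(0),
                      median_dphi = numeric(0))
    class(out) <- c("phase_distance_profile", "data.frame")
    return(out)
  }
  dd <- sort(unique(d))
  if (!is.null(d_max)) dd <- dd[dd <= d_max]
  np <- vapply(dd, function(k) sum(d == k), 0)
  med <- vapply(dd, function(k) median(dphi[d == k]), 0)
  keep <- np >= min_pairs
  if (is.null(d_max) && any(keep)) {
    # default d_max: largest distance still meeting min_pairs
    keep <- keep & dd <= max(dd[keep])
  }
  out <- data.frame(d = as.integer(dd[keep]), n_pairs = as.integer(np[keep]),
                    median_dphi = med[keep])
  if (!nrow(out)) warning("no distance class reaches min_pairs = ", min_pairs)
  class(out) <- c("phase_distance_profile", "data.frame")
  rownames(out) <- NULL
  out
}

named_phases <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x[!is.na(x)])
  if (inherits(x, "cycling_calls") || is.data.frame(x)) {
    ph <- phases_of(x)
    ids <- if (inherits(x, "cycling_calls"))
      x$gene_id[x$is_cycling & !is.na(x$consensus_phase)]
    else x$gene_id[!is.na(x[[grep("phase", names(x), value = TRUE)[1]]])]
    return(setNames(ph, ids))
  }
  stop("phases must be a named numeric vector or a table with gene_id")
}

#' Linear trend of the median phase difference across distance classes
#'
#' Ordinary least squares of the per-class median phase difference on the
#' geodesic distance, one (unweighted) point per class. A positive slope
#' means network-close gene pairs have more similar phases than distant
#' ones. With an exactly flat profile the slope is 0 and p = 1 by
#' convention; an exact non-flat line gives p = 0.
#'
#' @param profile a [phase_distance_profile()] with >= 3 distance classes.
#' @return list with `slope` (hours per hop), `intercept`, `p` (two-sided t
#'   test), `n_classes`.
#' @export
median_trend <- function(profile) {
  if (nrow(profile) < 3)
    stop("need >= 3 distance classes to estimate a trend (have ",
         nrow(profile), ")")
  fit <- lm(median_dphi ~ d, data = profile)
  cf <- coef(fit)
  res <- residuals(fit)
  if (sum(res^2) < 1e-20 * max(1, sum(profile$median_dphi^2))) {
    p <- if (abs(cf[2]) < 1e-12) 1 else 0
  } else {
    p <- summary(fit)$coefficients["d", "Pr(>|t|)"]
  }
  list(slope = unname(cf[2]), intercept = unname(cf[1]), p = unname(p),
       n_classes = nrow(profile))
}

#' Permutation null for network phase organization
#'
#' Tests whether cycling genes that are close on the network have more
#' similar phases than expected by chance. Each permutation re-places the
#' cycling genes: it draws the same number of node positions uniformly
#' without replacement from the network and attaches the observed phase
#' multiset to them in random order, then recomputes the median phase
#' difference per geodesic-distance class. The one-sided empirical p per
#' class uses the add-one estimator
#' `p = (1 + #(null medians <= observed)) / (1 + #valid permutations)`,
#' so p is never exactly 0. Distance classes empty in a permutation are
#' recorded as missing for that permutation, not as zero.
#'
#' @param net connected igraph (the LCC).
#' @param phases named phase vector (hours) over the cycling genes, or a
#'   `cycling_calls` table; all cycling genes must lie in `net`.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed; results are deterministic given it.
#' @param d_max,min_pairs as in [phase_distance_profile()].
#' @param alternative `"less"` (phases of close pairs more similar than
#'   null; default), `"greater"`, or `"two.sided"`.
#' @return object of class `phase_organization`: list with `profile`
#'   (observed per-class medians plus `empirical_p` and null quantiles
#'   `null_q025`, `null_q50`, `null_q975`, `n_perm_valid`), `null_medians`
#'   (n_perm x n_class matrix), `trend` (from [median_trend()], `NULL` if
#'   < 3 classes), `n_perm`, `seed`, `alternative`.
#' @export
permutation_null <- function(net, phases, n_perm = 5000, seed = 1L,
                             d_max = NULL, min_pairs = 50,
                             alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ph <- named_phases(phases)
  nodes <- igraph::V(net)$name
  if (!igraph::is_connected(net))
    stop("network must be connected; extract the LCC first")
  outside <- setdiff(names(ph), nodes)
  if (length(outside))
    stop(length(outside), " cycling gene(s) not on the network: ",
         paste(head(outside, 5), collapse = ", "))
  k <- length(ph)
  if (k < 2) stop("need >= 2 cycling genes on the network")

  D <- geodesic_distances(net)            # full LCC distance matrix, once
  obs_idx <- match(names(ph), nodes)
  ut <- upper.tri(matrix(0, k, k))
  # pairwise |dphi| of the phase multiset in fixed order; permutations only
  # re-draw positions, so this matrix is computed once
  PD <- phase_difference(outer(ph, ph, "-"), 0)
  dphi_pairs <- PD[ut]

  obs_d <- D[obs_idx, obs_idx][ut]
  obs_profile <- profile_from_pairs(obs_d, dphi_pairs, d_max, min_pairs)
  if (!nrow(obs_profile))
    stop("observed profile has no distance class with min_pairs = ",
         min_pairs)
  classes <- obs_profile$d

  n_nodes <- length(nodes)
  null_med <- with_stream(seed, "permutation", {
    nm <- matrix(NA_real_, n_perm, length(classes))
    for (b in seq_len(n_perm)) {
      pos <- sample.int(n_nodes, k)
      # random positions + fixed phase order == random one-to-one assignment
      dp <- D[pos, pos][ut]
      for (j in seq_along(classes)) {
        v <- dphi_pairs[dp == classes[j]]
        if (length(v)) nm[b, j] <- median(v)
      }
    }
    nm
  })
  colnames(null_med) <- paste0("d", classes)

  n_valid <- colSums(!is.na(null_med))
  p_less <- (1 + colSums(sweep(null_med, 2, obs_profile$median_dphi, "<="),
                         na.rm = TRUE)) / (1 + n_valid)
  p_greater <- (1 + colSums(sweep(null_med, 2, obs_profile$median_dphi, ">="),
                            na.rm = TRUE)) / (1 + n_valid)
  emp_p <- switch(alternative,
                  less = p_less, greater = p_greater,
                  two.sided = pmin(1, 2 * pmin(p_less, p_greater)))

  obs_profile$empirical_p <- as.numeric(emp_p)
  obs_profile$null_q025 <- apply(null_med, 2, quantile, 0.025, na.rm = TRUE)
  obs_profile$null_q50 <- apply(null_med, 2, quantile, 0.5, na.rm = TRUE)
  obs_profile$null_q975 <- apply(null_med, 2, quantile, 0.975, na.rm = TRUE)
  obs_profile$n_perm_valid <- as.integer(n_valid)

  trend <- if (nrow(obs_profile) >= 3)
    median_trend(obs_profile) else NULL
  structure(list(profile = obs_profile, null_medians = null_med,
                 trend = trend, n_perm = n_perm, seed = seed,
                 alternative = alternative, n_cycling = k),
            class = "phase_organization")
}

#' @export
print.phase_organization <- function(x, ...) {
  cat("Network phase organization:", x$n_cycling, "cycling genes,",
      x$n_perm, "permutations (alternative:", x$alternative, ")\n")
  print(x$profile, row.names = FALSE)
  if (!is.null(x$trend))
    cat(sprintf("trend: slope %.3f h/hop, p = %.3g (%d classes)\n",
                x$trend$slope, x$trend$p, x$trend$n_classes))
  invisible(x)
}

#' Plot a distance-phase profile against its permutation null
#'
#' Observed per-class median phase differences (points) over the null 2.5 to
#' 97.5 percent band (shaded) and null median (line).
#'
#' @param x a `phase_organization` result.
#' @param ... passed to [plot()].
#' @export
plot.phase_organization <- function(x, ...) {
  pr <- x$profile
  ylim <- range(c(pr$median_dphi, pr$null_q025, pr$null_q975))
  plot(pr$d, pr$median_dphi, pch = 19, xlab = "geodesic distance (hops)",
       ylab = "median phase difference (h)", ylim = ylim, ...)
  graphics::polygon(c(pr$d, rev(pr$d)), c(pr$null_q025, rev(pr$null_q975)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(pr$d, pr$null_q50, lty = 2)
  graphics::points(pr$d, pr$median_dphi, pch = 19)
  invisible(x)
}
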