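#' Compare two phase distributions (two-sample KS test)
#'
#' Phases live on a circle, but the Kolmogorov–Smirnov test compares linear
#' distributions, so both samples are linearised by cutting the circle at
#' `cut` (i.e. mapped to `(phase - cut) mod 24`). The p-value depends on the
#' cut, which is therefore part of the result; the default cut is ZT0
#' (lights-on). The D statistic is invariant to rotating both samples and the
#' cut together.
#'
#' @param a,b numeric phase vectors in ZT hours (non-empty).
#' @param cut cut point of the circle, in ZT hours.
#' @param period circle length in hours.
#' @return list with `D`, `p`, `cut`, `n_a`, `n_b`.
#' @export
compare_phase_distributions <- function(a, b, cut = 0, period = 24) {
  a <- phases_of(a); b <- phases_of(b)
  stopifnot(length(a) > 0, length(b) > 0)
  a2 <- (a - cut) %% period
  b2 <- (b - cut) %% period
  kt <- suppressWarnings(ks.test(a2, b2))
  list(D = unname(kt$statistic), p = kt$p.value, cut = cut,
       n_a = length(a), n_b = length(b))
}

# Accept a bare numeric vector, a cycling_calls table (consensus phases of
# called genes) or a data.frame with a phase-like column.
phases_of <- function(x) {
  if (is.numeric(x)) return(x[!is.na(x)])
  if (inherits(x, "cycling_calls"))
    return(x$consensus_phase[x$is_cycling & !is.na(x$consensus_phase)])
  if (is.data.frame(x)) {
    for (col in c("consensus_phase", "phase", "phase_true"))
      if (col %in% names(x)) return(x[[col]][!is.na(x[[col]])])
  }
  stop("cannot extract phases from object of class ",
       paste(class(x), collapse = "/"))
}

#' Peaks of a circular phase density
#'
#' Kernel density estimate on the circle with a von Mises kernel,
#' \deqn{\hat f(\theta) = \frac{1}{n}\sum_i
#'   \frac{e^{\kappa\cos(\theta-\theta_i)}}{2\pi I_0(\kappa)},}
#' evaluated on a 0.1 h grid. Peaks are strict local maxima (on the circular
#' grid) whose density exceeds `prominence` times the circular mean density;
#' they are returned in order of decreasing density. Fewer peaks than hoped
#' for is not an error — the function returns what exists.
#'
#' The default concentration `kappa = 8` gives a kernel with circular SD of
#' about 1.4 h, enough to resolve modes 4 h apart or more.
#'
#' @param phases numeric phases in hours (>= 5), or an object accepted by
#'   the phase extractors (e.g. a `cycling_calls` table).
#' @param kernel_concentration von Mises kappa (> 0).
#' @param prominence peak threshold as a multiple of the mean density.
#' @param period circle length in hours.
#' @return `data.frame` with columns `peak_zt` (hours) and `density`,
#'   ordered by decreasing density; zero rows when nothing passes.
#' @export
phase_density_peaks <- function(phases, kernel_concentration = 8,
                                prominence = 1.2, period = 24) {
  phases <- phases_of(phases)
  stopifnot(length(phases) >= 5, kernel_concentration > 0)
  grid <- seq(0, period - 0.1, by = 0.1)
  ang_g <- grid * 2 * pi / period
  ang_p <- phases * 2 * pi / period
  kap <- kernel_concentration
  # n_grid x n_phase kernel matrix; normalisation constant 2*pi*I0(kappa)
  dens <- rowMeans(exp(kap * cos(outer(ang_g, ang_p, "-")))) /
    (2 * pi * besselI(kap, 0, expon.scaled = FALSE))
  n <- length(grid)
  left <- dens[c(n, seq_len(n - 1))]
  right <- dens[c(seq_len(n - 1) + 1, 1)]
  is_peak <- dens > left & dens > right & dens > prominence * mean(dens)
  out <- data.frame(peak_zt = grid[is_peak], density = dens[is_peak])
  out[order(-out$density), , drop = FALSE]
}

#' Paired phase shift between two conditions
#'
#' For genes called cycling in both conditions, the signed shift
#' `wrap(phase_cond_b - phase_cond_a)` into `(-12, 12]` hours. With
#' `a` the colder condition, a positive shift means the gene peaks earlier
#' (phase advance) in the cold. The summary reports the circular mean shift
#' and the fraction of genes with a positive shift.
#'
#' @param calls_a,calls_b `cycling_calls` tables (see [call_cycling()]) for
#'   the two conditions; by convention `a` = colder condition.
#' @return list with `per_gene` (`data.frame`: `gene_id`, `phase_a`,
#'   `phase_b`, `shift_hours`), `mean_shift` (circular mean, hours in
#'   `(-12, 12]`), `fraction_advance`, `n`.
#' @export
paired_phase_shift <- function(calls_a, calls_b) {
  ga <- calls_a$gene_id[calls_a$is_cycling]
  gb <- calls_b$gene_id[calls_b$is_cycling]
  common <- intersect(ga, gb)
  if (!length(common))
    stop("no gene is called cycling in both conditions; ",
         "paired phase shift is undefined")
  pa <- calls_a$consensus_phase[match(common, calls_a$gene_id)]
  pb <- calls_b$consensus_phase[match(common, calls_b$gene_id)]
  shift <- wrap_signed(pb - pa)
  mean_shift <- wrap_signed(circular_mean(shift))
  list(per_gene = data.frame(gene_id = common, phase_a = pa, phase_b = pb,
                             shift_hours = shift, stringsAsFactors = FALSE),
       mean_shift = mean_shift,
       fraction_advance = mean(shift > 0),
       n = length(common))
}

#' Paired gene-expression variance comparison
#'
#' Per-gene sample variance across all samples of each matrix, compared by a
#' two-tailed Wilcoxon signed-rank test over the common gene list. Used to
#' ask whether one condition is globally noisier than another (most genes
#' being non-rhythmic, variance is dominated by noise).
#'
#' @param mat_a,mat_b [time_course_matrix()] objects covering `genes`.
#' @param genes gene IDs to compare (non-empty, present in both).
#' @return list with `statistic`, `p`, `direction` (`"a"`, `"b"` or
#'   `"none"`, the side with larger median paired variance), `n`.
#' @export
paired_variance_test <- function(mat_a, mat_b, genes) {
  stopifnot(length(genes) > 0)
  miss <- setdiff(genes, intersect(rownames(mat_a$values),
                                   rownames(mat_b$values)))
  if (length(miss))
    stop("gene(s) missing from a matrix: ",
         paste(head(miss, 5), collapse = ", "))
  va <- apply(mat_a$values[genes, , drop = FALSE], 1, var)
  vb <- apply(mat_b$values[genes, , drop = FALSE], 1, var)
  paired_signed_rank(va, vb)
}

#' Paired amplitude comparison of common cyclers
#'
#' Two-tailed Wilcoxon signed-rank test on fitted harmonic amplitudes of
#' genes detected as cycling under both conditions — e.g. to ask whether
#' oscillations are damped at one temperature (as loss of cell-cell synchrony
#' in bulk tissue would produce).
#'
#' @param fits_a,fits_b fit tables from [fit_harmonic_matrix()].
#' @param common_cyclers gene IDs cycling in both conditions (>= 2).
#' @return as [paired_variance_test()].
#' @export
paired_amplitude_test <- function(fits_a, fits_b, common_cyclers) {
  if (length(common_cyclers) < 2)
    stop("signed-rank test undefined for fewer than 2 paired genes")
  miss <- setdiff(common_cyclers, intersect(fits_a$gene_id, fits_b$gene_id))
  if (length(miss))
    stop("gene(s) missing from a fit table: ",
         paste(head(miss, 5), collapse = ", "))
  aa <- fits_a$amplitude[match(common_cyclers, fits_a$gene_id)]
  ab <- fits_b$amplitude[match(common_cyclers, fits_b$gene_id)]
  paired_signed_rank(aa, ab)
}

# Shared two-tailed Wilcoxon signed-rank with a p = 1 convention for
# all-ties input (the test statistic is then undefined).
paired_signed_rank <- function(a, b) {
  d <- b - a
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(statistic = NA_real_, p = 1, direction = "none",
                n = length(a)))
  }
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                     alternative = "two.sided"))
  md <- median(d)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = if (md > 0) "b" else if (md < 0) "a" else "none",
       n = length(a))
}
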