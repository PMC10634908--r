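#' Harmonic (cosinor) regression at a fixed period
#'
#' Ordinary least squares of expression on
#' `[1, cos(2*pi*t/period), sin(2*pi*t/period)]`, i.e. the model
#' `y = mesor + amplitude * cos(2*pi*(t - phase)/period)`. Evidence of
#' cycling is the F test of the two harmonic coefficients jointly zero, with
#' p from `F(2, n - 3)`. The amplitude is `sqrt(b_cos^2 + b_sin^2)` and the
#' peak phase is `(period/2*pi) * atan2(b_sin, b_cos) mod period`, in the
#' units of `times` (ZT hours). Replicates enter as independent observations.
#'
#' A constant series has amplitude 0 and, by convention, p = 1; the phase is
#' then undefined (`NA`). A design in which all times coincide modulo the
#' period is singular and is an error.
#'
#' @param times observation times in hours.
#' @param values expression values (TPM), same length as `times`.
#' @param period fixed period in hours (default 24).
#' @return a one-row `data.frame` with columns `mesor`, `amplitude`, `phase`,
#'   `f_stat`, `p_value`, `n_obs`, `period`.
#' @examples
#' t <- seq(0, 46, by = 2)
#' fit_harmonic(t, 5 + 3 * cos(2 * pi * (t - 8) / 24))
#' @export
fit_harmonic <- function(times, values, period = 24) {
  stopifnot(length(times) == length(values), all(is.finite(times)),
            all(is.finite(values)))
  m <- matrix(values, nrow = 1, dimnames = list("g", NULL))
  out <- fit_harmonic_matrix(m, times, period)
  out[, setdiff(names(out), "gene_id"), drop = FALSE]
}

#' Harmonic regression across a gene x sample matrix
#'
#' Vectorised [fit_harmonic()] over the rows of a matrix (or of a
#' [time_course_matrix()], whose metadata supplies the times). All genes share
#' the design matrix, so the fit is a single linear solve.
#'
#' @param x numeric gene x sample matrix with gene rownames, or a
#'   [time_course_matrix()].
#' @param times observation times in hours (ignored when `x` is a
#'   `time_course_matrix`).
#' @param period fixed period in hours.
#' @param log_transform fit on `log2(TPM + 1)` instead of raw TPM.
#' @return `data.frame` with one row per gene: `gene_id`, `mesor`,
#'   `amplitude`, `phase`, `f_stat`, `p_value`, `n_obs`, `period`.
#' @export
fit_harmonic_matrix <- function(x, times = NULL, period = 24,
                                log_transform = FALSE) {
  if (inherits(x, "time_course_matrix")) {
    times <- tc_times(x)
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(times), length(times) == ncol(x))
  if (length(unique(round(times %% period, 9))) < 4)
    stop("need >= 4 distinct timepoints modulo the period")
  if (log_transform) x <- log2(x + 1)
  n <- ncol(x)
  ang <- 2 * pi * times / period
  X <- cbind(intercept = 1, c = cos(ang), s = sin(ang))
  XtX <- crossprod(X)
  if (rcond_sym(XtX) < 1e-12)
    stop("singular harmonic design: times coincide modulo the period")
  B <- x %*% X %*% solve(XtX)              # genes x 3 coefficients
  fitted <- B %*% t(X)
  sse <- rowSums((x - fitted)^2)
  ybar <- rowMeans(x)
  ss0 <- rowSums((x - ybar)^2)
  amplitude <- sqrt(B[, 2]^2 + B[, 3]^2)
  phase <- wrap_period(atan2(B[, 3], B[, 2]) * period / (2 * pi), period)

  f_stat <- ((ss0 - sse) / 2) / (sse / (n - 3))
  p <- pf(f_stat, 2, n - 3, lower.tail = FALSE)
  # perfect (noiseless) fits: sse ~ 0 but real harmonic signal
  exact <- sse <= 1e-10 * pmax(ss0, 1e-300) & ss0 > 0
  f_stat[exact] <- Inf
  p[exact] <- 0
  # constant series: no variance at all -> amplitude 0, p = 1 by convention
  const <- ss0 <= 1e-12 * n * pmax(ybar^2, 1)
  amplitude[const] <- 0
  phase[const] <- NA_real_
  f_stat[const] <- 0
  p[const] <- 1

  data.frame(gene_id = rownames(x) %||% paste0("g", seq_len(nrow(x))),
             mesor = unname(B[, 1]), amplitude = unname(amplitude),
             phase = unname(phase), f_stat = unname(f_stat),
             p_value = unname(p), n_obs = n, period = period,
             stringsAsFactors = FALSE)
}

# reciprocal condition estimate of a small symmetric matrix
rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Dual-experiment cycling call
#'
#' A gene is called cycling when its harmonic-regression p-value is below
#' `p_thresh` in BOTH experiments and the two phase estimates agree to within
#' `dphi_max_hours` on the circle (strict inequalities). Replication across
#' independent experiments, rather than multiple-testing correction, is the
#' error control; [expected_chance_cyclers()] quantifies the residual chance
#' rate. The consensus phase (circular mean of the two estimates) is reported
#' for called genes.
#'
#' @param fits_v1,fits_v2 per-gene fit tables from [fit_harmonic_matrix()]
#'   for the two experiments; gene universes must intersect. Genes present in
#'   only one experiment are excluded with a message.
#' @param p_thresh per-experiment p-value threshold (default 0.1).
#' @param dphi_max_hours maximum inter-experiment phase difference in hours
#'   (default 3).
#' @param condition optional condition label carried into the result.
#' @return `data.frame` of class `cycling_calls`: `gene_id`, `p_v1`, `p_v2`,
#'   `phase_v1`, `phase_v2`, `delta_phi` (hours in `[0,12]`), `is_cycling`,
#'   `consensus_phase` (`NA` for genes not called), `condition`.
#' @export
call_cycling <- function(fits_v1, fits_v2, p_thresh = 0.1,
                         dphi_max_hours = 3, condition = NA_character_) {
  stopifnot(p_thresh > 0, dphi_max_hours > 0)
  common <- intersect(fits_v1$gene_id, fits_v2$gene_id)
  if (!length(common)) stop("fit tables share no genes")
  n_only <- length(unique(c(fits_v1$gene_id, fits_v2$gene_id))) - length(common)
  if (n_only > 0)
    message(n_only, " gene(s) present in one experiment only were excluded")
  f1 <- fits_v1[match(common, fits_v1$gene_id), ]
  f2 <- fits_v2[match(common, fits_v2$gene_id), ]
  # flat genes carry NA phases (amplitude 0); their dphi stays NA
  ok <- !is.na(f1$phase) & !is.na(f2$phase)
  dphi <- rep(NA_real_, length(common))
  dphi[ok] <- phase_difference(f1$phase[ok], f2$phase[ok])
  is_cyc <- f1$p_value < p_thresh & f2$p_value < p_thresh &
    !is.na(dphi) & dphi < dphi_max_hours
  consensus <- rep(NA_real_, length(common))
  if (any(is_cyc)) {
    consensus[is_cyc] <- mapply(function(a, b) circular_mean(c(a, b)),
                                f1$phase[is_cyc], f2$phase[is_cyc])
  }
  out <- data.frame(gene_id = common, p_v1 = f1$p_value, p_v2 = f2$p_value,
                    phase_v1 = f1$phase, phase_v2 = f2$phase,
                    delta_phi = dphi, is_cycling = is_cyc,
                    consensus_phase = consensus, condition = condition,
                    stringsAsFactors = FALSE)
  class(out) <- c("cycling_calls", "data.frame")
  out
}

#' Expected number of chance cycling calls
#'
#' Under the null that every gene is non-rhythmic, the two experiments give
#' independent uniform p-values and an inter-experiment phase difference
#' uniform on `[0, 12]` h, so the expected number of genes passing the dual
#' criterion by chance is
#' `n_genes * p_thresh^2 * (dphi_max_hours / 12)`.
#'
#' @param n_genes number of genes tested.
#' @param p_thresh per-experiment p threshold in (0, 1].
#' @param dphi_max_hours phase-agreement threshold in (0, 12] hours.
#' @return expected count (real).
#' @examples
#' expected_chance_cyclers(6774, 0.1, 3)  # 16.935, i.e. ~17 genes
#' @export
expected_chance_cyclers <- function(n_genes, p_thresh = 0.1,
                                    dphi_max_hours = 3) {
  stopifnot(n_genes >= 0, p_thresh > 0, p_thresh <= 1,
            dphi_max_hours > 0, dphi_max_hours <= 12)
  n_genes * p_thresh^2 * (dphi_max_hours / 12)
}

#' Chance-cycler false-discovery summary
#'
#' Expresses the expected chance calls as a percentage of the observed number
#' of detected cycling genes, per condition.
#'
#' @param n_genes number of genes tested.
#' @param n_detected named (or unnamed) vector of detected cycling-gene
#'   counts, e.g. `c("18C" = 242, "25C" = 364)`.
#' @inheritParams expected_chance_cyclers
#' @return list with `expected_chance` (real count) and `fdr_percent`
#'   (vector, 100 * expected / detected).
#' @export
chance_fdr_summary <- function(n_genes, n_detected, p_thresh = 0.1,
                               dphi_max_hours = 3) {
  stopifnot(all(n_detected > 0))
  exp_n <- expected_chance_cyclers(n_genes, p_thresh, dphi_max_hours)
  list(expected_chance = exp_n, fdr_percent = 100 * exp_n / n_detected)
}
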