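#' Circular phase difference on the 24 h clock
#'
#' Distance between two peak phases on the circadian circle: the smaller of
#' the two arcs separating them, so the result is always in `[0, period/2]`
#' hours. Inputs are reduced modulo the period, and the function is symmetric
#' in its arguments. Vectorised with recycling.
#'
#' @param phi1,phi2 phases in ZT hours (any real values; reduced mod `period`).
#' @param period circle length in hours (default 24).
#' @return numeric vector of phase differences in hours, in `[0, period/2]`.
#' @examples
#' phase_difference(6, 2)   # 4
#' phase_difference(23, 1)  # 2, wrapping midnight
#' @export
phase_difference <- function(phi1, phi2, period = 24) {
  stopifnot(is.numeric(phi1), is.numeric(phi2), all(is.finite(c(phi1, phi2))))
  d <- abs(phi1 - phi2) %% period
  pmin(d, period - d)
}

#' Circular mean of phases
#'
#' Mean direction of the unit phasors exp(2*pi*i*phase/period), mapped back to
#' hours in `[0, period)`. When the resultant vector is (numerically) zero the
#' mean direction is undefined — e.g. for an antipodal pair — and `NA` is
#' returned with attribute `undefined = TRUE` so the caller can decide.
#'
#' @param phases numeric vector of phases in hours; at least one value.
#' @param period circle length in hours.
#' @param tol resultant-length tolerance below which the mean is undefined.
#' @return circular mean in `[0, period)` hours, or `NA` (attr `undefined`).
#' @export
circular_mean <- function(phases, period = 24, tol = 1e-8) {
  stopifnot(length(phases) >= 1, is.numeric(phases))
  ang <- phases * 2 * pi / period
  zc <- mean(cos(ang)); zs <- mean(sin(ang))
  if (sqrt(zc^2 + zs^2) < tol) {
    return(structure(NA_real_, undefined = TRUE))
  }
  wrap_period(atan2(zs, zc) * period / (2 * pi), period)
}

#' Circular correlation of two phase samples
#'
#' The Jammalamadaka–SenGupta circular correlation coefficient
#' \deqn{r = \frac{\sum_i \sin(\alpha_i-\bar\alpha)\sin(\beta_i-\bar\beta)}
#'   {\sqrt{\sum_i \sin^2(\alpha_i-\bar\alpha)\sum_i \sin^2(\beta_i-\bar\beta)}}}
#' where \eqn{\bar\alpha,\bar\beta} are circular means. Phases in hours are
#' converted to angles via `2*pi/period`. Returns `NA` with attribute
#' `undefined = TRUE` when either sample has zero circular variance.
#'
#' @param a,b numeric phase vectors in hours, equal length >= 3.
#' @param period circle length in hours.
#' @return correlation in `[-1, 1]`, or `NA` (attr `undefined`).
#' @export
circular_correlation <- function(a, b, period = 24) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  to_ang <- function(x) x * 2 * pi / period
  am <- circular_mean(a, period); bm <- circular_mean(b, period)
  if (is.na(am) || is.na(bm)) return(structure(NA_real_, undefined = TRUE))
  sa <- sin(to_ang(a) - to_ang(am))
  sb <- sin(to_ang(b) - to_ang(bm))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) return(structure(NA_real_, undefined = TRUE))
  sum(sa * sb) / den
}

# Wrap hours into [0, period), snapping values within tol of the period to 0
# so results like 23.999999999 from atan2 round-off report as 0.
wrap_period <- function(x, period = 24, tol = 1e-9) {
  r <- x %% period
  r[r >= period - tol] <- 0
  r
}

# Wrap signed hour differences into (-period/2, period/2].
wrap_signed <- function(x, period = 24) {
  s <- x %% period
  s[s > period / 2] <- s[s > period / 2] - period
  s
}
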