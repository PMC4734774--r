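#' Fixation probability of the k-th surviving passenger mutation
#'
#' Probability that the k-th successful mutation (mutations with surviving
#' lineage, labeled by order of appearance) eventually becomes clonal,
#' i.e. present in all cells of the expanding population:
#' \deqn{\rho_k = \left(\frac{u}{u - \log\delta}\right)^k.}
#' Fixation of the k-th surviving mutation implies fixation of the first
#' k - 1. In a pure birth process (`delta = 0`) the founder lineage never
#' dies, so no mutation can fix and the probability is 0.
#'
#' @param k Appearance-order index of the successful mutation (integer >= 1,
#'   vectorized).
#' @param params A [branching_params()] object.
#' @return Fixation probability in `[0, 1)`.
#' @examples
#' p <- branching_params(delta = 0.99)
#' fixation_probability(1:5, p)
#' @export
fixation_probability <- function(k, params) {
  params <- as_branching_params(params)
  check_k(k)
  if (params$delta == 0) return(rep(0, length(k)))
  (params$u / (params$u - log(params$delta)))^k
}

#' Fixation probability by quadrature over the origin population size
#'
#' Independent evaluation of the fixation probability of the k-th surviving
#' mutation by integrating over the (Poisson-process) population size z at
#' which it appears:
#' \deqn{\rho_k = \int_0^\infty \frac{(zu)^{k-1} e^{-zu} u}{(k-1)!}\,
#'   \delta^z \, dz,}
#' the gamma-weighted probability that all z coexisting lineages die out.
#' Serves as a numerical cross-check of [fixation_probability()].
#'
#' @inheritParams fixation_probability
#' @param rel.tol,abs.tol Quadrature tolerances passed to
#'   [stats::integrate()].
#' @return Fixation probability.
#' @export
fixation_probability_integral <- function(k, params,
                                          rel.tol = 1e-10, abs.tol = 1e-12) {
  params <- as_branching_params(params)
  check_k(k)
  if (length(k) > 1L)
    return(vapply(k, fixation_probability_integral, numeric(1L),
                  params = params, rel.tol = rel.tol, abs.tol = abs.tol))
  u <- params$u; delta <- params$delta
  if (delta == 0) return(0)
  integrand <- function(z)
    exp((k - 1) * log(z * u) - z * u + log(u) - lgamma(k) + z * log(delta))
  res <- stats::integrate(integrand, 0, Inf,
                          rel.tol = rel.tol, abs.tol = abs.tol)
  if (res$message != "OK")
    stop("quadrature failed: ", res$message, " (k = ", k, ", abs.error = ",
         format(res$abs.error), ")", call. = FALSE)
  res$value
}

#' Cumulative distribution of the k-th surviving mutation's cell fraction
#'
#' Probability that the fraction of cells eventually carrying the k-th
#' successful mutation is at most `alpha`:
#' \deqn{F_k(\alpha) = 1 - \left[1 -
#'   \frac{\log(1 - \alpha(1-\delta))}{u}\right]^{-k}.}
#' The law does not reach 1 as `alpha` approaches 1: the missing mass is the
#' fixation probability, \eqn{\rho_k = 1 - F_k(1)}.
#'
#' @param k Appearance-order index (integer >= 1).
#' @param alpha Cell fraction(s) in (0, 1).
#' @inheritParams fixation_probability
#' @return CDF value(s).
#' @seealso [frequency_pdf()], [median_frequency()]
#' @export
frequency_cdf <- function(k, alpha, params) {
  params <- as_branching_params(params)
  check_k(k); check_alpha_open(alpha)
  u <- params$u; delta <- params$delta
  1 - (1 - log(1 - alpha * (1 - delta)) / u)^(-k)
}

#' Density of the k-th surviving mutation's cell fraction
#'
#' Analytic derivative of [frequency_cdf()] with respect to `alpha`,
#' \deqn{g_k(\alpha) = k \left[1 - \frac{\log(1-\alpha(1-\delta))}{u}
#'   \right]^{-k-1} \frac{1-\delta}{u\,(1-\alpha(1-\delta))}.}
#' The density of the subclonal part of the law; it integrates to
#' \eqn{1 - \rho_k} on (0, 1).
#'
#' @inheritParams frequency_cdf
#' @return Density value(s).
#' @export
frequency_pdf <- function(k, alpha, params) {
  params <- as_branching_params(params)
  check_k(k); check_alpha_open(alpha)
  u <- params$u; delta <- params$delta
  A <- 1 - log(1 - alpha * (1 - delta)) / u
  k * A^(-k - 1) * (1 - delta) / (u * (1 - alpha * (1 - delta)))
}

#' Median cell fraction of the k-th surviving mutation
#'
#' Closed-form median of the eventual frequency law, capped at 1:
#' \deqn{\mathrm{Med}(x_k) = \min\!\left(1,\;
#'   \frac{1 - e^{u(1 - 2^{1/k})}}{1-\delta}\right).}
#' Whenever the fixation probability exceeds 1/2 the median sits at
#' fixation and equals 1.
#'
#' @inheritParams fixation_probability
#' @return Median fraction in (0, 1].
#' @export
median_frequency <- function(k, params) {
  params <- as_branching_params(params)
  check_k(k)
  u <- params$u; delta <- params$delta
  pmin(1, (1 - exp(u * (1 - 2^(1 / k)))) / (1 - delta))
}

#' Expected eventual frequency of a mutation arising among z other cells
#'
#' A surviving mutation that appears when `z` other cells are present
#' eventually reaches expected cell fraction
#' \deqn{E(x) = \frac{1 - \delta^{z+1}}{(1-\delta)(z+1)}.}
#' For `delta = 0` this is the deterministic 1/(z+1); death (`delta` near 1)
#' pushes it far higher because coexisting lineages often die out.
#'
#' @param z Number of other cells present at appearance (integer >= 0,
#'   vectorized).
#' @inheritParams fixation_probability
#' @return Expected fraction in (0, 1].
#' @export
expected_frequency_given_z <- function(z, params) {
  params <- as_branching_params(params)
  check_z(z, min = 0)
  delta <- params$delta
  if (delta == 0) return(1 / (z + 1))
  (1 - delta^(z + 1)) / ((1 - delta) * (z + 1))
}

#' Frequency law of a mutation conditioned on its origin population size
#'
#' Distribution of the eventual cell fraction x of a surviving mutation that
#' appeared when `z` other cells were present:
#' \deqn{P(x \le \alpha \mid z) = 1 - (1 - \alpha + \delta\alpha)^z, \qquad
#'   f_z(\alpha) = (1-\delta)\, z\, (1 - \alpha + \delta\alpha)^{z-1}.}
#' The subclonal density integrates to \eqn{1 - \delta^z}; the remaining
#' mass \eqn{\delta^z} is the probability that all z coexisting lineages die
#' and the mutation fixes.
#'
#' @param z Number of other cells at appearance (integer >= 1).
#' @param alpha Cell fraction(s) in (0, 1).
#' @inheritParams fixation_probability
#' @return A list with components `cdf`, `pdf` and `fixation_mass`
#'   (\eqn{\delta^z}).
#' @export
frequency_law_given_z <- function(z, alpha, params) {
  params <- as_branching_params(params)
  check_z(z, min = 1); check_alpha_open(alpha)
  delta <- params$delta
  base <- 1 - alpha * (1 - delta)
  list(cdf = 1 - base^z,
       pdf = (1 - delta) * z * base^(z - 1),
       fixation_mass = delta^z)
}

#' Maximum-likelihood origin population size of an observed mutation
#'
#' Inverting the frequency law: a subclonal mutation observed at cell
#' fraction `alpha` most likely arose when
#' \deqn{\hat z_{ML} = \frac{-1}{\log(1 - \alpha(1-\delta))}}
#' cells were already present. For `delta = 0` and small `alpha` this
#' approaches the deterministic estimate 1/alpha; cell death inflates it up
#' to a hundred-fold.
#'
#' @param alpha Observed cell fraction(s), strictly inside (0, 1).
#' @inheritParams fixation_probability
#' @return Estimated number of cells (real, > 0).
#' @export
zhat_ml <- function(alpha, params) {
  params <- as_branching_params(params)
  check_alpha_open(alpha)
  -1 / log(1 - alpha * (1 - params$delta))
}

#' Maximum a posteriori origin population size
#'
#' As [zhat_ml()] but with a geometric prior on the origin size with rate
#' `v` (the chance that the specific mutation arises at a division and
#' survives):
#' \deqn{\hat z_{MAP} = \frac{-1}{\log(1-v) +
#'   \log(1 - \alpha(1-\delta))}.}
#' For realistic `v` of order 1e-9 the prior term is negligible and the MAP
#' and ML estimates coincide to within a relative 1e-5.
#'
#' @inheritParams zhat_ml
#' @param est An [estimator_config()] object holding `v`.
#' @return Estimated number of cells (real, > 0).
#' @export
zhat_map <- function(alpha, params, est = estimator_config()) {
  params <- as_branching_params(params)
  check_alpha_open(alpha)
  stopifnot(inherits(est, "estimator_config"))
  -1 / (log1p(-est$v) + log(1 - alpha * (1 - params$delta)))
}

#' Expected number of subclonal mutations above a cell fraction
#'
#' Expected number of subclonal passenger mutations present in more than a
#' fraction `alpha` of cells in the expanded population:
#' \deqn{\bar m_s(\alpha) = \frac{u\,(1-\alpha)}{(1-\delta)\,\alpha}.}
#' This is the cumulative frequency spectrum that the cohort-fitting
#' pipeline matches to sequencing data.
#'
#' @param alpha Cell fraction threshold(s) in (0, 1].
#' @inheritParams fixation_probability
#' @return Expected mutation count(s).
#' @export
expected_subclonal <- function(alpha, params) {
  params <- as_branching_params(params)
  check_alpha(alpha, lo = 0, hi = 1, lo_open = TRUE, hi_open = FALSE)
  params$u * (1 - alpha) / ((1 - params$delta) * alpha)
}

#' Expected number of clonal passenger mutations
#'
#' Expected number of passenger mutations that reach fixation during the
#' clonal expansion (beyond those already present in the founder cell):
#' \deqn{\bar m_c = \frac{\delta u}{1 - \delta}.}
#' Zero in a pure birth process; of order u/(1-delta) for `delta` near 1.
#'
#' @inheritParams fixation_probability
#' @return Expected mutation count.
#' @export
expected_clonal <- function(params) {
  params <- as_branching_params(params)
  params$delta * params$u / (1 - params$delta)
}

#' Expected total number of surviving passenger mutations
#'
#' In a population grown to `M` cells the average number of passenger
#' mutations with surviving lineage is `M * u`, independent of the
#' death-birth ratio. Almost all of them sit at undetectably low frequency.
#'
#' @param M Population size (>= 1).
#' @param u Per-division passenger mutation probability.
#' @return Expected count `M * u`.
#' @export
expected_total_surviving_mutations <- function(M, u) {
  stopifnot(is.numeric(M), all(M >= 1), is.numeric(u), all(u >= 0))
  M * u
}

#' Expected mutation count in a window of allele fractions
#'
#' For a diploid tumor with all mutations heterozygous and no LOH, allele
#' fraction is half the cell fraction. The expected number of mutations
#' with allele fraction in `(alpha, 0.25]` is
#' \deqn{\frac{u}{2(1-\delta)} \left(\frac{1}{\alpha} -
#'   \frac{1}{0.25}\right),}
#' i.e. the subclonal spectrum evaluated on cell fractions (2 alpha, 0.5].
#' This is the functional form fitted to sequencing data, with coefficient
#' `a = u / (2 (1 - delta))`.
#'
#' @param alpha Allele fraction threshold(s) in (0, 0.25].
#' @inheritParams fixation_probability
#' @param upper Upper allele-fraction cutoff (default 0.25; above it
#'   mutations may be clonal).
#' @return Expected mutation count(s).
#' @export
allele_count_in_window <- function(alpha, params, upper = 0.25) {
  params <- as_branching_params(params)
  check_alpha(alpha, lo = 0, hi = upper, lo_open = TRUE, hi_open = FALSE)
  a <- params$u / (2 * (1 - params$delta))
  a * (1 / alpha - 1 / upper)
}

#' Expected clonal/subclonal mutation counts across death-birth ratios
#'
#' Tabulates the expected number of subclonal mutations above cell-fraction
#' thresholds, and the expected number of clonal passengers, for a set of
#' death-birth ratios at fixed mutation probability `u`.
#'
#' @param deltas Death-birth ratios to tabulate.
#' @param thresholds Cell-fraction thresholds for the subclonal counts.
#' @param u Per-division passenger mutation probability.
#' @param b Division rate (irrelevant to the counts; kept for completeness).
#' @return A data.frame with one row per `delta`: threshold columns and
#'   `clonal`.
#' @examples
#' theory_table()
#' @export
theory_table <- function(deltas = c(0, 0.72, 0.96, 0.99, 0.999),
                         thresholds = c(0.001, 0.01, 0.1, 0.5),
                         u = 0.015, b = 0.25) {
  rows <- lapply(deltas, function(delta) {
    p <- branching_params(b = b, delta = delta, u = u)
    counts <- vapply(thresholds, expected_subclonal, numeric(1L), params = p)
    c(delta = delta, stats::setNames(counts, paste0("gt_", thresholds)),
      clonal = expected_clonal(p))
  })
  as.data.frame(do.call(rbind, rows))
}

# --- argument checks ---------------------------------------------------------

check_k <- function(k) {
  if (!is.numeric(k) || any(k < 1) || any(k != floor(k)))
    stop("`k` must be a positive integer", call. = FALSE)
  invisible(k)
}

check_z <- function(z, min) {
  if (!is.numeric(z) || any(z < min) || any(z != floor(z)))
    stop("`z` must be an integer >= ", min, call. = FALSE)
  invisible(z)
}

check_alpha <- function(alpha, lo, hi, lo_open, hi_open) {
  ok <- is.numeric(alpha) & is.finite(alpha) &
    (if (lo_open) alpha > lo else alpha >= lo) &
    (if (hi_open) alpha < hi else alpha <= hi)
  if (!all(ok))
    stop("`alpha` must lie in ", if (lo_open) "(" else "[", lo, ", ", hi,
         if (hi_open) ")" else "]", call. = FALSE)
  invisible(alpha)
}

check_alpha_open <- function(alpha)
  check_alpha(alpha, lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
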