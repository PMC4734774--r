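#' Filter tumor samples on ploidy and purity
#'
#' Keeps samples whose copy-number profile is near-diploid (ploidy within
#' `ploidy_range`, closed interval) and whose purity estimate is at least
#' `purity_min` (inclusive), so that allele fractions can be interpreted as
#' half cell fractions after purity correction. Samples with missing
#' metadata are excluded, not errors.
#'
#' @param meta A data.frame of per-sample metadata with columns `sample`,
#'   `purity`, `ploidy` (and optionally others, carried through).
#' @param ploidy_range Closed ploidy interval, default `c(1.8, 2.2)`.
#' @param purity_min Inclusive purity minimum, default 0.70.
#' @return The qualifying subset of `meta`, with an attribute
#'   `"exclusions"`: a data.frame of excluded samples and reasons.
#' @export
filter_samples <- function(meta, ploidy_range = c(1.8, 2.2),
                           purity_min = 0.70) {
  stopifnot(is.data.frame(meta),
            all(c("sample", "purity", "ploidy") %in% names(meta)))
  if (nrow(meta) == 0L) {
    out <- meta
    attr(out, "exclusions") <- data.frame(sample = character(),
                                          reason = character())
    return(out)
  }
  reason <- rep(NA_character_, nrow(meta))
  missing <- is.na(meta$purity) | is.na(meta$ploidy)
  reason[missing] <- "missing-metadata"
  bad_ploidy <- !missing & (meta$ploidy < ploidy_range[1] |
                              meta$ploidy > ploidy_range[2])
  reason[bad_ploidy] <- "ploidy-out-of-range"
  bad_purity <- !missing & !bad_ploidy & meta$purity < purity_min
  reason[bad_purity] <- "low-purity"
  keep <- is.na(reason)
  out <- meta[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(sample = meta$sample[!keep],
                                        reason = reason[!keep])
  out
}

#' Purity-correct observed allele fractions
#'
#' Divides observed allele fractions by sample purity so they refer to the
#' tumor-cell population. Corrected values above 0.5 (possible clonal or
#' aneuploid variants) are retained but flagged in the
#' `"flagged_clonal"` attribute; the fitting window removes them anyway.
#'
#' @param af Observed allele fraction(s) in [0, 1].
#' @param purity Tumor purity in (0, 1].
#' @return Corrected allele fractions (may exceed 1 for noisy input; such
#'   values are flagged, never silently dropped).
#' @export
correct_allele_fraction <- function(af, purity) {
  stopifnot(is.numeric(af), all(af >= 0 & af <= 1))
  if (!is.numeric(purity) || any(purity <= 0) || any(purity > 1))
    stop("`purity` must lie in (0, 1]", call. = FALSE)
  out <- af / purity
  attr(out, "flagged_clonal") <- which(out > 0.5)
  out
}

#' Cumulative mutation-count curve inside the fitting window
#'
#' For each corrected allele fraction alpha_i inside `window`, counts the
#' mutations strictly above it and at most the upper cutoff:
#' `count_i = #\{j : alpha_j > alpha_i and alpha_j <= window[2]\}`.
#' The evaluation points are the observed in-window fractions themselves.
#' The lower edge excludes fractions where detection is underpowered; above
#' the upper edge mutations may be clonal.
#'
#' @param fractions Corrected allele fractions.
#' @param window Allele-fraction window, default `c(0.12, 0.25)`; points
#'   with `window[1] <= alpha <= window[2]` are evaluation points.
#' @return A data.frame with columns `alpha`, `count`, sorted by `alpha`.
#' @export
cumulative_curve <- function(fractions, window = c(0.12, 0.25)) {
  stopifnot(is.numeric(fractions), length(window) == 2L,
            window[1] < window[2])
  a <- fractions[fractions >= window[1] & fractions <= window[2]]
  if (length(a) == 0L)
    stop("no mutations inside the window [", window[1], ", ", window[2],
         "]; cannot build a cumulative curve", call. = FALSE)
  a <- sort(a)
  count <- vapply(a, function(x) sum(a > x), numeric(1L))
  data.frame(alpha = a, count = count)
}

#' Least-squares fit of the neutral allele-fraction spectrum
#'
#' Fits the cumulative curve to the neutral expectation
#' `count = a * (1/alpha - 1/upper)` by ordinary least squares through the
#' origin (the form vanishes at `alpha = upper`). Reports the coefficient
#' `a = u / (2 (1 - delta))`, its t-based 95 percent confidence interval,
#' and R-squared computed as `1 - SS_res / SS_tot` with `SS_tot` about the
#' mean count (so that a flat curve scores 0, not 1).
#'
#' @param points A data.frame with columns `alpha` and `count`
#'   (from [cumulative_curve()]).
#' @param upper Upper window cutoff used in the functional form
#'   (default 0.25).
#' @param conf Confidence level for the interval (default 0.95).
#' @return An object of class `fit_result`: list with `a`, `ci95`
#'   (length-2), `r_squared`, `n_points`, `window`, `se`.
#' @export
fit_neutral_model <- function(points, upper = 0.25, conf = 0.95) {
  stopifnot(is.data.frame(points), all(c("alpha", "count") %in% names(points)))
  n <- nrow(points)
  if (n < 2L)
    stop("insufficient data: need at least 2 points for a fit, got ", n,
         call. = FALSE)
  x <- 1 / points$alpha - 1 / upper
  y <- points$count
  sxx <- sum(x^2)
  if (sxx == 0 || stats::var(x) == 0)
    stop("degenerate fit: no variance in 1/alpha across points",
         call. = FALSE)
  a <- sum(x * y) / sxx
  res <- y - a * x
  df <- n - 1L
  se <- sqrt(sum(res^2) / df / sxx)
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) as.numeric(sum(res^2) == 0) else 1 - sum(res^2) / ss_tot
  structure(list(a = a, ci95 = c(a - tq * se, a + tq * se),
                 se = se, r_squared = r2, n_points = n,
                 window = c(min(points$alpha), upper)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Neutral spectrum fit: a = %.3f (95%% CI %.3f-%.3f), R^2 = %.3f, n = %d\n",
    x$a, x$ci95[1], x$ci95[2], x$r_squared, x$n_points))
  invisible(x)
}

#' Death-birth ratio implied by a fitted spectrum coefficient
#'
#' Inverts the coefficient convention `a = u / (2 (1 - delta))` of the
#' allele-fraction spectrum: `delta = 1 - u / (2 a)`. The mutation
#' probability `u` must be assumed; a tenfold higher `u` lowers the
#' inferred `delta` accordingly.
#'
#' @param a Fitted spectrum coefficient (> 0), or a `fit_result`.
#' @param u Assumed per-division passenger mutation probability.
#' @return The death-birth ratio `delta` in [0, 1). If `a` is a
#'   `fit_result`, a list with `delta` and `ci95` (mapped from the
#'   coefficient CI, truncated to [0, 1)).
#' @export
delta_from_fit <- function(a, u = 0.015) {
  if (inherits(a, "fit_result")) {
    fit <- a
    d <- delta_from_fit(fit$a, u)
    lo <- if (fit$ci95[1] <= u / 2) 0 else 1 - u / (2 * fit$ci95[1])
    hi <- if (fit$ci95[2] <= u / 2) 0 else 1 - u / (2 * fit$ci95[2])
    return(list(delta = d, ci95 = c(lo, hi)))
  }
  stopifnot(is.numeric(a), all(a > 0), u > 0)
  if (any(u / (2 * a) > 1))
    stop("u/(2a) > 1: no death-birth ratio in [0, 1) matches this ",
         "coefficient at the assumed mutation rate (evidence against a ",
         "neutral fit at this u)", call. = FALSE)
  1 - u / (2 * a)
}

#' Spectrum coefficient implied by a death-birth ratio
#'
#' @param delta Death-birth ratio in [0, 1).
#' @param u Per-division passenger mutation probability.
#' @return `a = u / (2 (1 - delta))`.
#' @export
a_from_delta <- function(delta, u = 0.015) {
  stopifnot(all(delta >= 0 & delta < 1), u > 0)
  u / (2 * (1 - delta))
}

#' Microsatellite-status call from the total mutation burden
#'
#' Hypermutated (microsatellite-instable) colorectal tumors are separated
#' from stable ones by total exome mutation count; the default threshold of
#' 500 reflects the usual bimodal split of exome burdens, and is strictly
#' exceeded for an MSI call.
#'
#' @param n_mutations Total mutation count(s) per sample.
#' @param threshold MSI if `n_mutations > threshold` (default 500).
#' @return Character vector, `"MSI"` or `"MSS"`.
#' @export
classify_msi <- function(n_mutations, threshold = 500) {
  stopifnot(is.numeric(n_mutations), all(n_mutations >= 0))
  ifelse(n_mutations > threshold, "MSI", "MSS")
}

#' Clonal mutations attributable to the founder cell
#'
#' For slow expansion (`delta` near 1) the expected number of subclonal
#' mutations above 50 percent cell frequency approximately equals the
#' number of clonal passengers collected during growth, so subtracting it
#' from the observed clonal count estimates the mutations already present
#' in the first malignant cell (floored at zero).
#'
#' @param n_clonal Observed number of clonal mutations (>= 0).
#' @param n_subclonal_above_half Number of subclonal mutations above 50
#'   percent cell frequency (>= 0).
#' @return `max(0, n_clonal - n_subclonal_above_half)`.
#' @export
clonal_origin_estimate <- function(n_clonal, n_subclonal_above_half) {
  stopifnot(n_clonal >= 0, n_subclonal_above_half >= 0)
  pmax(0, n_clonal - n_subclonal_above_half)
}

#' Generate a synthetic tumor mutation table
#'
#' Emulates the sequencing readout of a diploid tumor evolving neutrally:
#' subclonal cell fractions are drawn from the density implied by the
#' expected spectrum (proportional to 1/alpha^2 on `[alpha_min, 1]`), with
#' the number of mutations Poisson with mean equal to the expected
#' subclonal count above `alpha_min` (overridable via `n_expected`).
#' Heterozygous diploid allele fraction is cellfraction/2, diluted by
#' `purity`; the observed fraction comes from binomial sampling of reads at
#' Poisson-distributed per-site depth.
#'
#' @inheritParams fixation_probability
#' @param depth Mean sequencing depth (>= 1).
#' @param purity Tumor purity in (0, 1].
#' @param alpha_min Smallest generated cell fraction (detection floor on
#'   the cell-fraction scale).
#' @param n_expected Optional override of the Poisson mean mutation count.
#' @param sample_id Sample name written into the table.
#' @param seed Optional integer seed.
#' @return A data.frame (MAF-dialect mutation table), one row per variant:
#'   `sample`, `cell_fraction` (true), `allele_fraction` (true, diluted),
#'   `t_alt_count`, `t_depth`, `observed_allele_fraction`; with attributes
#'   `purity`, `ploidy` (2.0), `msi_status`, and a `meta` data.frame row
#'   ready for [filter_samples()].
#' @export
generate_synthetic_table <- function(params, depth = 100, purity = 0.85,
                                     alpha_min = 0.05, n_expected = NULL,
                                     sample_id = "synthetic-01",
                                     seed = NULL) {
  params <- as_branching_params(params)
  stopifnot(depth >= 1, purity > 0, purity <= 1,
            alpha_min > 0, alpha_min < 1)
  if (!is.null(seed)) set.seed(seed)
  if (purity * alpha_min / 2 * depth < 2)
    warning("depth ", depth, " is underpowered for cell fractions near ",
            alpha_min, " at purity ", purity, call. = FALSE)
  mean_n <- if (is.null(n_expected)) expected_subclonal(alpha_min, params)
            else n_expected
  n <- stats::rpois(1L, mean_n)
  # inverse transform of the spectrum density ~ 1/alpha^2 on [alpha_min, 1]:
  # survival S(alpha) = ((1-alpha)/alpha) / ((1-alpha_min)/alpha_min)
  uu <- stats::runif(n)
  cf <- 1 / (1 + uu * (1 / alpha_min - 1))
  af <- purity * cf / 2
  dp <- pmax(1L, stats::rpois(n, depth))
  alt <- stats::rbinom(n, dp, af)
  tab <- data.frame(sample = rep(sample_id, n),
                    cell_fraction = cf,
                    allele_fraction = af,
                    t_alt_count = alt,
                    t_depth = dp,
                    observed_allele_fraction = alt / dp)
  attr(tab, "purity") <- purity
  attr(tab, "ploidy") <- 2.0
  attr(tab, "msi_status") <- classify_msi(n)
  attr(tab, "meta") <- data.frame(sample = sample_id, purity = purity,
                                  ploidy = 2.0,
                                  msi = classify_msi(n),
                                  n_mutations = n)
  tab
}

#' Fit one sample end to end
#'
#' Convenience wrapper: purity-correct the observed allele fractions, build
#' the cumulative in-window curve, and fit the neutral spectrum; optionally
#' convert the coefficient to a death-birth ratio.
#'
#' @param table A mutation table with column
#'   `observed_allele_fraction` (or `allele_fraction` as fallback).
#' @param purity Sample purity; defaults to the table's `purity` attribute.
#' @param window Allele-fraction window after purity correction.
#' @param u Mutation probability for the `delta` conversion; `NULL` skips it.
#' @return A `fit_result` with an extra `delta` element when `u` is given.
#' @export
fit_sample <- function(table, purity = attr(table, "purity"),
                       window = c(0.12, 0.25), u = 0.015) {
  af_col <- if ("observed_allele_fraction" %in% names(table))
    table$observed_allele_fraction else table$allele_fraction
  corrected <- correct_allele_fraction(af_col, purity)
  fit <- fit_neutral_model(cumulative_curve(corrected, window),
                           upper = window[2])
  if (!is.null(u)) fit$delta <- delta_from_fit(fit, u)
  fit
}
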