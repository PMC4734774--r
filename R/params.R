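#' Branching-process parameters
#'
#' Bundle the three parameters of the supercritical birth-death branching
#' process with infinite-allele passenger mutation: per-cell division rate
#' `b` (per day), per-cell death rate `d` (per day), and the probability `u`
#' that, at a division, one daughter cell acquires a new passenger mutation.
#' The death-birth ratio `delta = d/b` is the extinction probability of a
#' single cell's lineage and is the quantity that actually governs fixation
#' probabilities, frequency spectra and tree shapes; `b` only sets the clock.
#'
#' Either `d` or `delta` may be supplied; if both are given they must agree.
#' The process must be supercritical (`delta < 1`), since every closed-form
#' result carries a `1 - delta` denominator.
#'
#' @param b Division rate per day (> 0). Default 0.25, a typical value for
#'   colorectal cancer.
#' @param d Death rate per day (>= 0). Exactly one of `d`, `delta` is
#'   required (or both, consistently).
#' @param u Per-division probability that one daughter gains a new passenger
#'   mutation (0 <= u < 1). Default 0.015, the product of the normal point
#'   mutation rate per division (~5e-10) and the exome length (~3e7 bp).
#' @param delta Death-birth ratio d/b in [0, 1).
#'
#' @return An object of class `branching_params`: a list with fields `b`,
#'   `d`, `u`, `delta`.
#' @examples
#' branching_params(b = 0.25, d = 0.18, u = 0.015)
#' branching_params(delta = 0.99)
#' @export
branching_params <- function(b = 0.25, d = NULL, u = 0.015, delta = NULL) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u), u >= 0, u < 1)
  if (is.null(d) && is.null(delta))
    stop("supply either `d` or `delta`", call. = FALSE)
  if (!is.null(d)) {
    stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d >= 0)
    if (!is.null(delta) && abs(delta - d / b) > 1e-8)
      stop("`delta` inconsistent with d/b = ", format(d / b), call. = FALSE)
    delta <- d / b
  } else {
    stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta), delta >= 0)
    d <- delta * b
  }
  if (delta >= 1)
    stop("supercritical growth required: delta = d/b must be < 1 (got ",
         format(delta), ")", call. = FALSE)
  structure(list(b = b, d = d, u = u, delta = delta),
            class = "branching_params")
}

#' @export
print.branching_params <- function(x, ...) {
  cat(sprintf(
    "Birth-death branching process: b = %g/day, d = %g/day (delta = %g), u = %g\n",
    x$b, x$d, x$delta, x$u))
  invisible(x)
}

as_branching_params <- function(params) {
  if (inherits(params, "branching_params")) return(params)
  stop("`params` must be created by branching_params()", call. = FALSE)
}

#' Configuration for the origin-size a-posteriori estimator
#'
#' The maximum a posteriori estimate of the population size at a mutation's
#' origin uses a geometric prior on the origin size with per-division success
#' probability `v`: the chance that one *specific* genomic position mutates
#' at a given division and founds a surviving lineage. For point mutations
#' this is of order 1e-9, which makes the MAP and ML estimates practically
#' identical.
#'
#' @param v Per-division probability of the specific mutation (0 < v < 1).
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(v = 1e-9) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v), v > 0, v < 1)
  structure(list(v = v), class = "estimator_config")
}
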