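#' Probability that the second surviving mutation arises in the first's lineage
#'
#' Under the approximation that "mutation 2 descends from mutation 1" has
#' probability equal to the eventual cell fraction of mutation 1, the
#' offspring probability is
#' \deqn{p_{1\to 2} \approx E(x_1) = \rho_1 + \int_0^1 \alpha\,
#'   g_1(\alpha)\, d\alpha,}
#' with \eqn{g_1} the density of the first surviving mutation's eventual
#' frequency ([frequency_pdf()]) and \eqn{\rho_1} its fixation probability.
#'
#' @inheritParams fixation_probability
#' @return Probability in [0, 1].
#' @examples
#' offspring_probability(branching_params(b = 0.25, d = 0.18))
#' @export
offspring_probability <- function(params) {
  params <- as_branching_params(params)
  fixation_probability(1L, params) + mean_alpha_integral(1L, params)
}

# \int_0^1 alpha g_k(alpha) d alpha, the subclonal part of E(x_k).
# Evaluated under the substitution alpha = 1 - e^{-t}: the transformed
# integrand (1-e^{-t}) k A^{-k-1} (1-delta) e^{-t} / (u w), with
# w = delta + (1-delta) e^{-t} and A = 1 - log(w)/u, is smooth on (0, Inf)
# even at delta = 0, where the density itself has an integrable
# singularity at alpha = 1.
mean_alpha_integral <- function(k, params, rel.tol = 1e-10) {
  u <- params$u; delta <- params$delta
  if (u == 0) return(0)
  f <- if (delta == 0) {
    # w = e^{-t} exactly: log(w) = -t avoids underflow at large t
    function(t) (1 - exp(-t)) * k * (1 + t / u)^(-k - 1) / u
  } else {
    function(t) {
      et <- exp(-t)
      w <- delta + (1 - delta) * et
      A <- 1 - log(w) / u
      (1 - et) * k * A^(-k - 1) * (1 - delta) * et / (u * w)
    }
  }
  res <- stats::integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = 1e-12)
  if (res$message != "OK")
    stop("quadrature failed for mean fraction of mutation ", k, ": ",
         res$message, call. = FALSE)
  res$value
}

#' Conditional mean fractions entering the tree likelihoods
#'
#' Quadrature evaluation of the building blocks of the six-tree likelihoods:
#' \describe{
#'   \item{rho1, rho2}{fixation probabilities of the first two surviving
#'     mutations;}
#'   \item{sub1, sub2}{mean eventual fractions of mutations 1 and 2
#'     conditioned on being subclonal,
#'     \eqn{\mathrm{sub}_k = \int_0^1 \alpha g_k / (1 - \rho_k)};}
#'   \item{sub21c}{mean fraction of mutation 2 given 1 clonal and 2 not;
#'     equals `sub1`;}
#'   \item{sub21nc}{mean fraction of mutation 2 given neither fixes,
#'     \eqn{(1+\rho_1)\mathrm{sub}_2 - \rho_1 \mathrm{sub}_1};}
#'   \item{sub21nc2nc1}{mean fraction of mutation 2 given 1 subclonal and 2
#'     a subclonal offspring of 1,
#'     \eqn{(\mathrm{sub21nc} - \rho_1\mathrm{sub}_1)/(1-\rho_1)}.}
#' }
#'
#' @inheritParams fixation_probability
#' @return A list of class `tree_quantities` with the fields above.
#' @export
tree_helper_quantities <- function(params) {
  params <- as_branching_params(params)
  rho1 <- fixation_probability(1L, params)
  rho2 <- fixation_probability(2L, params)
  sub1 <- mean_alpha_integral(1L, params) / (1 - rho1)
  sub2 <- mean_alpha_integral(2L, params) / (1 - rho2)
  sub21nc <- (1 + rho1) * sub2 - rho1 * sub1
  sub21nc2nc1 <- if (rho1 == 0) sub21nc else (sub21nc - rho1 * sub1) / (1 - rho1)
  structure(list(rho1 = rho1, rho2 = rho2, sub1 = sub1, sub2 = sub2,
                 sub21c = sub1, sub21nc = sub21nc,
                 sub21nc2nc1 = sub21nc2nc1),
            class = "tree_quantities")
}

#' Likelihoods of the six phylogenies of the first three surviving mutations
#'
#' Closed-form (approximate) probabilities of the six rooted trees that the
#' founder type 0 and the first three successful mutations can form,
#' indexed as in [classify_tree()] (tree 1 is the star, tree 6 the linear
#' chain). With h = [tree_helper_quantities()]:
#' \deqn{p_1 = (1-\rho_1)(1-s_1)(1 - s_1 - \mathrm{sub21nc})}
#' \deqn{p_2 = p_4 = (1-\rho_1)(1-s_1)\,s_1}
#' \deqn{p_3 = (1-\rho_1)(1-s_1)\,\mathrm{sub21nc}}
#' \deqn{p_5 = (1-\rho_1)\left[\rho_1(1-s_1) + (1+\rho_1)s_1(s_1 -
#'   s_2)\right]}
#' \deqn{p_6 = \rho_1^2 + \rho_1(1-\rho_1)s_1(1-s_1) +
#'   (1-\rho_1^2)s_1 s_2}
#' The formulas are approximations (one conditional independence step), so
#' the six values need not sum exactly to 1; they are not renormalized by
#' default, since the raw values are what the theory prints.
#'
#' @inheritParams fixation_probability
#' @param normalize If `TRUE`, rescale the six probabilities to sum to 1
#'   (a convenience view only).
#' @return Named numeric vector `p1` .. `p6`.
#' @examples
#' tree_probabilities(branching_params(b = 0.25, delta = 0.72))
#' @export
tree_probabilities <- function(params, normalize = FALSE) {
  params <- as_branching_params(params)
  h <- tree_helper_quantities(params)
  r1 <- h$rho1; s1 <- h$sub1; s2 <- h$sub2
  p2 <- (1 - r1) * (1 - s1) * s1
  p <- c(
    p1 = (1 - r1) * (1 - s1) * (1 - s1 - h$sub21nc),
    p2 = p2,
    p3 = (1 - r1) * (1 - s1) * h$sub21nc,
    p4 = p2, # identical by the theory, kept bitwise equal
    p5 = (1 - r1) * (r1 * (1 - s1) + (1 + r1) * s1 * (s1 - s2)),
    p6 = r1^2 + r1 * (1 - r1) * s1 * (1 - s1) + (1 - r1^2) * s1 * s2
  )
  bad <- p < -1e-12 | p > 1 + 1e-12
  if (any(bad))
    stop("tree probability outside [0,1]: ",
         paste(names(p)[bad], format(p[bad]), collapse = ", "), call. = FALSE)
  p <- pmin(pmax(p, 0), 1)
  if (normalize) p <- p / sum(p)
  p
}

#' Tree topology of the first three surviving mutations
#'
#' Maps the parent labels of mutations 2 and 3 (the nearest *successful*
#' ancestor mutation; 0 for the founder lineage) to the canonical index
#' 1-6 of the six possible rooted phylogenies:
#'
#' | parent of 2 | parent of 3 | tree |
#' |---|---|---|
#' | 0 | 0 | 1 (star) |
#' | 0 | 1 | 2 |
#' | 0 | 2 | 3 |
#' | 1 | 0 | 4 |
#' | 1 | 1 | 5 |
#' | 1 | 2 | 6 (linear chain) |
#'
#' @param parent_of_2 Parent label of mutation 2: 0 or 1 (vectorized).
#' @param parent_of_3 Parent label of mutation 3: 0, 1 or 2 (vectorized).
#' @return Integer tree index (1-6), same length as the inputs.
#' @examples
#' classify_tree(0, 0) # star
#' classify_tree(1, 2) # linear chain
#' @export
classify_tree <- function(parent_of_2, parent_of_3) {
  if (!all(parent_of_2 %in% c(0L, 1L)))
    stop("`parent_of_2` must be 0 or 1", call. = FALSE)
  if (!all(parent_of_3 %in% c(0L, 1L, 2L)))
    stop("`parent_of_3` must be 0, 1 or 2", call. = FALSE)
  as.integer(3L * parent_of_2 + parent_of_3 + 1L)
}

#' Newick strings for the six three-mutation topologies
#'
#' Labels are the founder type `0` (root) and the first three successful
#' mutations `1`, `2`, `3`; nesting encodes "arose in the lineage of".
#'
#' @param index Tree index 1-6 (vectorized).
#' @return Character vector of Newick strings.
#' @export
tree_newick <- function(index) {
  nwk <- c("(1,2,3)0;", "((3)1,2)0;", "(1,(3)2)0;",
           "((2)1,3)0;", "((2,3)1)0;", "(((3)2)1)0;")
  if (!all(index %in% 1:6)) stop("tree `index` must be in 1..6", call. = FALSE)
  nwk[index]
}
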