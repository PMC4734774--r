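# shared parameter sets: fast-growing (delta = 0.72) and slow-growing
# (delta = 0.99) tumors at the default exome mutation probability
p72 <- branching_params(b = 0.25, d = 0.18, u = 0.015)
p96 <- branching_params(b = 0.25, delta = 0.96, u = 0.015)
p99 <- branching_params(b = 0.25, delta = 0.99, u = 0.015)
p0  <- branching_params(b = 0.25, d = 0, u = 0.015)

# two-sided Kolmogorov-Smirnov distance between a sample and an analytic CDF
# evaluated on a fine fixed grid of (0,1)
ks_distance <- function(x, cdf_fun) {
  grid <- seq(5e-4, 1 - 5e-4, by = 5e-4)
  emp <- stats::ecdf(x)
  max(abs(emp(grid) - cdf_fun(grid)))
}
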