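test_that("fixation probabilities reproduce the published values", {
  expect_equal(fixation_probability(1, p99), 0.599, tolerance = 1e-3)
  expect_equal(fixation_probability(5, p99), 0.077, tolerance = 2e-2)
  expect_equal(fixation_probability(2, p99), 0.3586, tolerance = 1e-3)
  expect_equal(fixation_probability(1, p72), 0.0437, tolerance = 1e-2)
  expect_equal(fixation_probability(1, p96), 0.27, tolerance = 1e-2)
  expect_equal(fixation_probability(1, p0), 0) # pure birth: nothing fixes
  expect_error(fixation_probability(0, p99), "positive integer")
})

test_that("fixation probability is decreasing in k, increasing in delta and u", {
  ks <- 1:6
  expect_true(all(diff(fixation_probability(ks, p99)) < 0))
  deltas <- c(0.3, 0.5, 0.72, 0.9, 0.96, 0.99)
  rho1 <- vapply(deltas, function(d)
    fixation_probability(1, branching_params(delta = d)), numeric(1))
  expect_true(all(diff(rho1) > 0))
  us <- c(0.005, 0.015, 0.05, 0.15)
  rho_u <- vapply(us, function(u)
    fixation_probability(1, branching_params(delta = 0.9, u = u)), numeric(1))
  expect_true(all(diff(rho_u) > 0))
})

test_that("quadrature over origin sizes agrees with the closed form", {
  for (delta in c(0.5, 0.72, 0.96, 0.99)) {
    p <- branching_params(delta = delta)
    for (k in 1:5)
      expect_equal(fixation_probability_integral(k, p),
                   fixation_probability(k, p), tolerance = 1e-8)
  }
  expect_equal(fixation_probability_integral(1, branching_params(delta = 0)), 0)
})

test_that("frequency CDF endpoints and printed value check out", {
  # CDF -> 0 at the origin, missing mass at 1 equals the fixation probability
  expect_equal(frequency_cdf(3, 1e-12, p99), 0, tolerance = 1e-9)
  for (k in 1:4)
    expect_equal(1 - frequency_cdf(k, 1 - 1e-12, p72),
                 fixation_probability(k, p72), tolerance = 1e-9)
  expect_equal(frequency_cdf(1, 0.05, p72), 0.4845, tolerance = 1e-4)
  expect_true(all(diff(frequency_cdf(2, seq(0.01, 0.99, 0.01), p99)) > 0))
  expect_error(frequency_cdf(1, 1.5, p99), "alpha")
})

test_that("frequency pdf is the derivative of the CDF and integrates to 1 - rho_k", {
  h <- 1e-7
  for (a in c(0.1, 0.5, 0.9))
    expect_equal(frequency_pdf(2, a, p72),
                 (frequency_cdf(2, a + h, p72) - frequency_cdf(2, a - h, p72)) /
                   (2 * h), tolerance = 1e-5)
  for (k in 1:3) {
    mass <- integrate(function(a) frequency_pdf(k, a, p99), 0, 1,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1 - fixation_probability(k, p99), tolerance = 1e-8)
  }
})

test_that("median frequency matches numerical inversion of the CDF", {
  # rho_1(0.99) > 1/2 forces the median to fixation
  expect_equal(median_frequency(1, p99), 1)
  expect_equal(median_frequency(1, p72), 0.0532, tolerance = 1e-3)
  expect_equal(median_frequency(3, p99), 0.389, tolerance = 1e-3)
  # independent oracle: solve F_k(alpha) = 1/2
  for (spec in list(list(k = 1, p = p72), list(k = 3, p = p99),
                    list(k = 2, p = p96))) {
    root <- uniroot(function(a) frequency_cdf(spec$k, a, spec$p) - 0.5,
                    c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    expect_equal(median_frequency(spec$k, spec$p), root, tolerance = 1e-9)
  }
})

test_that("expected eventual frequency given origin size matches the closed form", {
  expect_equal(expected_frequency_given_z(100, p99), 0.631, tolerance = 1e-3)
  expect_equal(expected_frequency_given_z(100, p0), 1 / 101)
  expect_equal(expected_frequency_given_z(0, p72), 1)
  expect_equal(expected_frequency_given_z(0, p99), 1)
  z <- c(1, 5, 20, 100, 1000)
  expect_true(all(diff(expected_frequency_given_z(z, p99)) < 0))
  # quadrature oracle: delta^z + int alpha f_z(alpha) d alpha
  for (z in c(1, 10, 100)) {
    law <- function(a) frequency_law_given_z(z, a, p96)$pdf
    ev <- p96$delta^z + integrate(function(a) a * law(a), 0, 1,
                                  rel.tol = 1e-10)$value
    expect_equal(expected_frequency_given_z(z, p96), ev, tolerance = 1e-8)
  }
})

test_that("conditional frequency law normalizes to the subclonal mass", {
  for (z in c(1, 10, 100)) {
    mass <- integrate(function(a) frequency_law_given_z(z, a, p99)$pdf,
                      0, 1, rel.tol = 1e-10)$value
    expect_equal(mass, 1 - p99$delta^z, tolerance = 1e-8)
  }
  # z = 1, delta = 0: the Beta(1,1) uniform law
  expect_equal(frequency_law_given_z(1, c(0.2, 0.5, 0.9), p0)$pdf, rep(1, 3))
  expect_equal(frequency_law_given_z(50, 1 - 1e-12, p96)$cdf,
               1 - p96$delta^50, tolerance = 1e-6)
  expect_equal(frequency_law_given_z(100, 0.5, p99)$cdf, 0.3942,
               tolerance = 1e-4)
})

test_that("origin-size estimators invert the frequency law", {
  expect_equal(zhat_ml(0.1, p99), 999.5, tolerance = 1e-3)
  expect_equal(zhat_ml(0.5, p99), 199.5, tolerance = 1e-3)
  expect_equal(zhat_ml(0.1, p0), 9.491, tolerance = 1e-3)
  # increasing in delta
  zs <- vapply(c(0, 0.5, 0.9, 0.99), function(d)
    zhat_ml(0.1, branching_params(delta = d)), numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(zhat_ml(1, p99), "alpha")
  # MAP with tiny v is ML to within 1e-5 relative
  expect_equal(zhat_map(0.1, p99, estimator_config(1e-9)),
               zhat_ml(0.1, p99), tolerance = 1e-5)
  expect_equal(zhat_map(0.5, p0, estimator_config(0.5)), 0.7213,
               tolerance = 1e-4)
})

test_that("expected subclonal/clonal counts reproduce the published table", {
  expect_equal(expected_subclonal(0.01, p99), 148.5)
  expect_equal(expected_subclonal(0.001, p72), 53.5, tolerance = 1e-2)
  expect_equal(expected_subclonal(1, p99), 0)
  expect_equal(expected_clonal(p0), 0)
  expect_equal(expected_clonal(p99), 1.485)
  expect_equal(expected_clonal(branching_params(delta = 0.999)), 14.985)
  tab <- theory_table()
  expect_equal(tab$gt_0.1[tab$delta == 0.96], 3.37, tolerance = 1e-2)
  expect_equal(tab$gt_0.001[tab$delta == 0.999], 14985)
  # monotonicity: decreasing in alpha, increasing in delta
  expect_true(all(diff(expected_subclonal(c(0.001, 0.01, 0.1, 0.5), p96)) < 0))
  expect_true(all(diff(vapply(c(0.3, 0.72, 0.96, 0.99), function(d)
    expected_subclonal(0.01, branching_params(delta = d)), numeric(1))) > 0))
})

test_that("total surviving mutation count is M u", {
  expect_equal(expected_total_surviving_mutations(1e9, 0.015), 1.5e7)
  expect_equal(expected_total_surviving_mutations(1e6, 0), 0)
  expect_equal(expected_total_surviving_mutations(1, 0.015), 0.015)
})

test_that("allele-fraction window count is the diploid spectrum difference", {
  expect_equal(allele_count_in_window(0.25, p99), 0)
  for (a in c(0.01, 0.05, 0.12, 0.2))
    expect_equal(allele_count_in_window(a, p72),
                 expected_subclonal(2 * a, p72) - expected_subclonal(0.5, p72),
                 tolerance = 1e-12)
  # with coefficient a = u/(2(1-delta)) = 1.23: 1.23 (1/0.12 - 4) = 5.33
  p <- branching_params(delta = delta_from_fit(1.23, 0.015), u = 0.015)
  expect_equal(allele_count_in_window(0.12, p), 1.23 * (1 / 0.12 - 4),
               tolerance = 1e-9)
  expect_error(allele_count_in_window(0.3, p99), "alpha")
})
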