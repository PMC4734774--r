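test_that("sample filters apply the ploidy and purity thresholds inclusively", {
  meta <- data.frame(sample = c("a", "b", "c", "d", "e"),
                     purity = c(0.85, 0.90, 0.69, 0.70, NA),
                     ploidy = c(2.0, 2.5, 2.0, 1.8, 2.0))
  kept <- filter_samples(meta)
  expect_identical(kept$sample, c("a", "d")) # boundary 1.8 / 0.70 included
  excl <- attr(kept, "exclusions")
  expect_identical(excl$reason[excl$sample == "b"], "ploidy-out-of-range")
  expect_identical(excl$reason[excl$sample == "c"], "low-purity")
  expect_identical(excl$reason[excl$sample == "e"], "missing-metadata")
  empty <- filter_samples(meta[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("purity correction rescales and flags potentially clonal fractions", {
  expect_equal(as.numeric(correct_allele_fraction(0.10, 0.85)), 0.1176,
               tolerance = 1e-3)
  expect_equal(as.numeric(correct_allele_fraction(0.3, 1)), 0.3)
  out <- correct_allele_fraction(c(0.1, 0.5, 0.3), 0.85)
  expect_identical(attr(out, "flagged_clonal"), 2L)
  expect_error(correct_allele_fraction(0.1, 0), "purity")
})

test_that("cumulative curve counts strictly-greater in-window mutations", {
  cc <- cumulative_curve(c(0.13, 0.15, 0.20, 0.30))
  expect_equal(cc$alpha, c(0.13, 0.15, 0.20))
  expect_equal(cc$count, c(2, 1, 0))
  expect_equal(cumulative_curve(0.2)$count, 0)
  # ties: strict ">" means duplicates do not count each other
  expect_equal(cumulative_curve(c(0.15, 0.15))$count, c(0, 0))
  expect_error(cumulative_curve(c(0.05, 0.3)), "window")
  # counts nonincreasing in alpha
  set.seed(8)
  cc <- cumulative_curve(runif(200, 0.1, 0.3))
  expect_true(all(diff(cc$count) <= 0))
})

test_that("fit recovers an exact spectrum with R^2 = 1", {
  a_true <- 1.23
  alpha <- seq(0.12, 0.25, by = 0.01)
  pts <- data.frame(alpha = alpha, count = a_true * (1 / alpha - 4))
  fit <- fit_neutral_model(pts)
  expect_equal(fit$a, a_true, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$ci95[1] <= fit$a && fit$a <= fit$ci95[2])
  expect_identical(fit$n_points, length(alpha))
  expect_error(fit_neutral_model(pts[1, ]), "insufficient")
  expect_error(fit_neutral_model(data.frame(alpha = c(0.2, 0.2),
                                            count = c(1, 1))), "degenerate")
})

test_that("death-birth ratio maps to and from the spectrum coefficient", {
  expect_equal(delta_from_fit(2.86, 0.015), 0.9974, tolerance = 1e-4)
  expect_equal(delta_from_fit(2.86, 0.15), 0.9738, tolerance = 1e-3)
  expect_equal(delta_from_fit(0.015 / 2, 0.015), 0)
  expect_error(delta_from_fit(0.001, 0.015), "neutral")
  for (d in c(0, 0.72, 0.99, 0.997))
    expect_equal(delta_from_fit(a_from_delta(d, 0.015), 0.015), d)
  # interval mapping keeps delta in [0, 1)
  fit <- structure(list(a = 2.86, ci95 = c(0.004, 5)), class = "fit_result")
  dd <- delta_from_fit(fit, 0.015)
  expect_equal(dd$ci95[1], 0)
  expect_lt(dd$ci95[2], 1)
})

test_that("MSI classification uses a strict mutation-count threshold", {
  expect_identical(classify_msi(100, 500), "MSS")
  expect_identical(classify_msi(5000, 500), "MSI")
  expect_identical(classify_msi(500, 500), "MSS")
})

test_that("founder-cell clonal mutation estimate subtracts with a floor", {
  expect_equal(clonal_origin_estimate(100, 15), 85)
  expect_equal(clonal_origin_estimate(10, 15), 0)
  # for delta -> 1 the subclonal count above 50% approaches the clonal count
  for (d in c(0.99, 0.999, 0.9999)) {
    p <- branching_params(delta = d)
    expect_equal(expected_subclonal(0.5, p) / expected_clonal(p), 1 / d,
                 tolerance = 1e-12)
  }
})

test_that("synthetic tables are reproducible and obey their construction", {
  p <- branching_params(delta = 0.997, u = 0.015)
  t1 <- generate_synthetic_table(p, depth = 100, purity = 0.85, seed = 5)
  t2 <- generate_synthetic_table(p, depth = 100, purity = 0.85, seed = 5)
  expect_identical(t1, t2)
  expect_identical(attr(t1, "ploidy"), 2.0)
  expect_true(all(t1$cell_fraction >= 0.05 & t1$cell_fraction <= 1))
  expect_equal(t1$allele_fraction, 0.85 * t1$cell_fraction / 2)
  expect_equal(t1$observed_allele_fraction, t1$t_alt_count / t1$t_depth)
  # purity correction of true allele fractions recovers cellfraction / 2
  corr <- correct_allele_fraction(t1$allele_fraction, 0.85)
  expect_equal(as.numeric(corr), t1$cell_fraction / 2)
  expect_warning(generate_synthetic_table(p, depth = 30, alpha_min = 0.01,
                                          seed = 1), "underpowered")
})

test_that("noise-free synthetic spectra match the window formula", {
  # with infinite depth and full purity the generated cumulative curve is a
  # Poisson sample of the analytic window count
  p <- branching_params(delta = 0.997, u = 0.015)
  set.seed(12)
  nrep <- 60
  counts <- numeric(nrep)
  for (i in seq_len(nrep)) {
    tab <- generate_synthetic_table(p, depth = 1e6, purity = 1)
    counts[i] <- sum(tab$allele_fraction > 0.12 & tab$allele_fraction <= 0.25)
  }
  expected <- allele_count_in_window(0.12, p)
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(nrep))
})

test_that("the fitted coefficient is close to truth on large synthetic samples", {
  p <- branching_params(delta = 0.997, u = 0.015)
  # boost the mutation count to shrink Poisson noise; a scales out
  set.seed(33)
  tab <- generate_synthetic_table(p, depth = 1e6, purity = 1,
                                  n_expected = 40 * expected_subclonal(0.05, p))
  fit <- fit_neutral_model(cumulative_curve(tab$allele_fraction))
  expect_equal(fit$a / 40, a_from_delta(0.997), tolerance = 0.1)
  expect_gt(fit$r_squared, 0.97)
})
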