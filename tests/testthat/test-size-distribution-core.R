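test_that("make_log_edges produces geometric spacing with exact endpoints", {
  expect_equal(make_log_edges(1, 4, 2), c(1, 2, 4))
  e <- make_log_edges(1.4, 42, 400)
  expect_length(e, 401)
  expect_identical(e[1], 1.4)
  expect_identical(e[401], 42)
  ratios <- e[-1] / e[-401]
  expect_equal(ratios, rep((42 / 1.4)^(1 / 400), 400), tolerance = 1e-12)
  expect_error(make_log_edges(2, 2, 1), class = "granulofit_invalid_argument")
  expect_error(make_log_edges(-1, 2, 1), class = "granulofit_invalid_argument")
  expect_error(make_log_edges(1, 2, 0), class = "granulofit_invalid_argument")
})

test_that("binned_distribution validates its invariants", {
  expect_error(binned_distribution(c(2, 1, 4), c(50, 50), "volume", "percent"),
               class = "granulofit_invalid_argument")
  expect_error(binned_distribution(c(1, 2, 4), c(-1, 101), "volume", "percent"),
               class = "granulofit_invalid_argument")
  expect_error(binned_distribution(c(1, 2, 4), c(40, 70), "volume", "percent"),
               class = "granulofit_validation_error")
  expect_error(binned_distribution(c(1, 2, 4), c(10, 10), "volume",
                                   "percent_density"),
               class = "granulofit_validation_error")
  d <- binned_distribution(c(1, 2, 4), c(40, 30), "volume", "percent_density")
  expect_s3_class(d, "binned_distribution")
})

test_that("to_density divides by widths and from_density inverts exactly", {
  d <- binned_distribution(c(1, 2, 4), c(40, 60), "volume", "percent")
  dens <- to_density(d)
  expect_equal(dens$values, c(40, 30))
  expect_equal(sum(dens$values * bin_widths(dens)), 100)
  expect_equal(from_density(dens)$values, d$values, tolerance = 1e-12)
  expect_error(to_density(dens), class = "granulofit_contract_error")
  expect_error(from_density(d), class = "granulofit_contract_error")
})

test_that("density round trip conserves the integral on random percents", {
  set.seed(401)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    e <- make_log_edges(runif(1, 0.5, 2), runif(1, 20, 80), n)
    v <- runif(n)
    d <- binned_distribution(e, 100 * v / sum(v), "volume", "percent")
    dens <- to_density(d)
    expect_equal(sum(dens$values * bin_widths(dens)), 100, tolerance = 1e-9)
    expect_equal(from_density(dens)$values, d$values, tolerance = 1e-12)
  }
})

test_that("counts_to_percent normalizes and rejects empty input", {
  d <- binned_distribution(c(1, 2, 4, 8), c(1, 1, 2), "number", "count")
  expect_equal(counts_to_percent(d)$values, c(25, 25, 50))
  one <- binned_distribution(c(1, 2), 5, "number", "count")
  expect_equal(counts_to_percent(one)$values, 100)
  zero <- binned_distribution(c(1, 2, 4), c(0, 0), "number", "count")
  expect_error(counts_to_percent(zero),
               class = "granulofit_empty_distribution")
})

test_that("convert_weighting follows the d^3 rule and is an involution", {
  # two single-granule bins whose geometric centers sit at d = 2 and 4
  e <- c(2 / sqrt(2), 2 * sqrt(2), 4 * sqrt(2))
  d <- binned_distribution(e, c(50, 50), "number", "percent")
  v <- convert_weighting(d, "volume")
  expect_equal(v$values, c(100 / 9, 800 / 9), tolerance = 1e-9)
  # identity on matching target; single bin unchanged
  expect_identical(convert_weighting(d, "number"), d)
  single <- binned_distribution(c(1, 2), 100, "number", "percent")
  expect_equal(convert_weighting(single, "volume")$values, 100)
  # involution on random distributions
  set.seed(402)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    e <- make_log_edges(1.4, 42, n)
    val <- runif(n)
    dd <- binned_distribution(e, 100 * val / sum(val), "number", "percent")
    back <- convert_weighting(convert_weighting(dd, "volume"), "number")
    expect_equal(back$values, dd$values, tolerance = 1e-9)
  }
  dens <- to_density(d)
  expect_error(convert_weighting(dens, "volume"),
               class = "granulofit_contract_error")
})

test_that("converted number-mode binning matches direct volume-mode binning", {
  # Monte-Carlo oracle: bin pi/6 d^3 directly vs convert the count bins
  spec <- sim_spec(n_granules = 1e5, f_B_volume = 0.25, seed = 4021,
                   n_bins = 400)
  pop <- simulate_population(spec)
  e <- make_log_edges(1.4, 42, 400)
  direct <- bin_population(pop, e, "volume")
  converted <- convert_weighting(counts_to_percent(bin_population(pop, e,
                                                                  "number")),
                                 "volume")
  nz <- direct$values > 0
  expect_lt(max(abs(converted$values[nz] - direct$values[nz]) /
                  direct$values[nz]), 0.02)
})

test_that("bin_population counts, half-open bins, and overflow report", {
  pop <- granule_population(c(1.5, 2.5, 2.6))
  d <- bin_population(pop, c(1, 2, 3), "number")
  expect_equal(d$values, c(1, 2))
  # boundary granule falls in the upper bin (half-open [low, high)),
  # last bin closed at the top edge
  pop2 <- granule_population(c(2, 3))
  d2 <- bin_population(pop2, c(1, 2, 3), "number")
  expect_equal(d2$values, c(0, 2))
  # volume weighting with centers at 2 and 4
  e <- c(2 / sqrt(2), 2 * sqrt(2), 4 * sqrt(2))
  pop3 <- granule_population(c(2, 4))
  expect_equal(bin_population(pop3, e, "volume")$values,
               c(100 / 9, 800 / 9), tolerance = 1e-9)
  # overflow is tallied, never dropped
  pop4 <- granule_population(c(0.5, 1.5, 9))
  d4 <- bin_population(pop4, c(1, 2, 3), "number")
  ov <- attr(d4, "overflow")
  expect_equal(ov$n_below, 1)
  expect_equal(ov$n_above, 1)
  expect_equal(ov$n_total, 3)
  expect_equal(sum(d4$values) + ov$n_below + ov$n_above, ov$n_total)
  expect_error(bin_population(granule_population(100), c(1, 2, 3), "number"),
               class = "granulofit_empty_distribution")
})

test_that("binned density of a large log-normal sample matches the pdf", {
  set.seed(403)
  pop <- granule_population(rlnorm(1e6, log(20), 0.2))
  e <- make_log_edges(1.4, 42, 128)
  dens <- to_density(counts_to_percent(bin_population(pop, e, "number")))
  pdf <- 100 * dlnorm(bin_centers(dens), log(20), 0.2)
  sel <- pdf > 0.1   # pdf > 0.001 on the unscaled axis
  # agreement within 1% of the peak density everywhere the pdf is visible
  expect_lt(max(abs(dens$values[sel] - pdf[sel])) / max(pdf), 0.01)
})

test_that("sample_prep validates the dilution scheme", {
  expect_error(sample_prep(2, 1, 100, 10),
               class = "granulofit_invalid_argument")
  expect_error(sample_prep(1, 100, 0, 10),
               class = "granulofit_invalid_argument")
  expect_error(sample_prep(1, 100, 100, -5),
               class = "granulofit_invalid_argument")
  p <- sample_prep(1, 100, 150, 5000)
  expect_s3_class(p, "sample_prep")
})
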