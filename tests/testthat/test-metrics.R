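test_that("total sum scaling normalises the selected subset", {
  p <- make_profile(c("A", "B"), c("sequins", "sequins"), c(1, 3))
  expect_equal(total_sum_scale(p), c(A = 0.25, B = 0.75))
  p3 <- make_profile(c("A", "B", "C"), rep("sequins", 3), c(2, 2, 6))
  expect_equal(unname(total_sum_scale(p3)), c(0.2, 0.2, 0.6))
  single <- make_profile("X", "sequins", 7)
  expect_equal(total_sum_scale(single), c(X = 1))
  mixed <- make_profile(c("A", "g1", "g2"),
                        c("sequins", "kit_contaminant", "endogenous_contaminant"),
                        c(50, 30, 20))
  expect_equal(total_sum_scale(mixed, "contaminant"), c(g1 = 0.6, g2 = 0.4))
  expect_error(total_sum_scale(mixed, "nonexistent_label"), "empty profile")
})

test_that("jsd matches its definition on worked and degenerate cases", {
  expect_equal(jsd(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7)), 0)
  expect_equal(jsd(c(a = 1), c(b = 1)), 1)
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), jsd_oracle(c(1, 0), c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), 0.5579230, tolerance = 1e-6)
  # union support: missing taxa are zeros
  expect_equal(jsd(c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.25, c = 0.25)),
               jsd_oracle(c(0.5, 0.5, 0), c(0.5, 0.25, 0.25)), tolerance = 1e-12)
})

test_that("jsd is a bounded metric on random profiles", {
  set.seed(20)
  for (i in 1:1000) {
    p <- random_abundance()
    q <- random_abundance()
    r <- random_abundance()
    d_pq <- jsd(p, q)
    expect_gte(d_pq, 0)
    expect_lte(d_pq, 1)
    expect_equal(d_pq, jsd(q, p), tolerance = 1e-12)
    expect_lte(d_pq, jsd(p, r) + jsd(r, q) + 1e-12)
  }
})

test_that("fidelity and reproducibility are 1 - JSD and bounded", {
  p <- c(a = 0.2, b = 0.8)
  expect_equal(fidelity(p, p), 1)
  expect_equal(fidelity(c(a = 1), c(b = 1)), 0)
  expect_equal(fidelity(c(1, 0), c(0.5, 0.5)), 1 - jsd_oracle(c(1, 0), c(0.5, 0.5)),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:50) {
    f <- reproducibility(random_abundance(), random_abundance())
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("proportion of designated reads is the sequins read share", {
  all_seq <- make_profile(c("a", "b"), c("sequins", "sequins"), c(5, 5))
  expect_equal(proportion_designated(all_seq), 1)
  nc <- make_profile("g", "kit_contaminant", 100, input_pg = 0)
  expect_equal(proportion_designated(nc), 0)
  mix <- make_profile(c("a", "g"), c("sequins", "kit_contaminant"), c(900, 100))
  expect_equal(proportion_designated(mix), 0.9)
  empty <- make_profile("a", "sequins", 0)
  expect_error(proportion_designated(empty), "zero depth")
})

test_that("conversion rate follows the PCR-corrected mass ratio", {
  # perfect-efficiency identity: library quantity doubles per cycle
  expect_equal(conversion_rate(5 * 2^10, 5, 10, 1), 1)
  expect_equal(conversion_rate(100, 5, 10, 0), 0)
  expect_equal(conversion_rate(5120, 5, 10, 0.5), 0.5)
  expect_error(conversion_rate(10, 0, 5, 1), "positive")
  # linearity in q_library and r_designated
  set.seed(8)
  for (i in 1:20) {
    q <- runif(1, 1, 100); inp <- runif(1, 0.1, 10); n <- sample(5:15, 1)
    r <- runif(1)
    base <- conversion_rate(q, inp, n, r)
    expect_equal(conversion_rate(3 * q, inp, n, r), 3 * base, tolerance = 1e-12)
    expect_equal(conversion_rate(q, inp, n, 0.5 * r), 0.5 * base, tolerance = 1e-12)
  }
})

test_that("duplication rate uses the molecule bookkeeping", {
  p <- make_profile(c("a", "b"), c("sequins", "sequins"), c(600, 400))
  expect_error(duplication_rate(p), "bookkeeping")
  attr(p, "n_unique_molecules") <- 1000
  expect_equal(duplication_rate(p), 0)
  # one molecule, D reads
  attr(p, "n_unique_molecules") <- 1
  expect_equal(duplication_rate(p), 999 / 1000)
})

test_that("abundance bias is the measured/reference ratio with zero refs skipped", {
  ref <- c(a = 0.25, b = 0.75)
  expect_equal(abundance_bias(ref, ref), c(a = 1, b = 1))
  measured <- c(a = 0.4, b = 0.6)
  expect_equal(abundance_bias(measured, ref), c(a = 1.6, b = 0.8))
  ref0 <- c(a = 0.5, b = 0.5, c = 0)
  expect_warning(out <- abundance_bias(c(a = 0.3, b = 0.3, c = 0.4), ref0), "zero reference")
  expect_named(out, c("a", "b"))
  expect_length(abundance_bias(c(x = 1), c(y = 1)), 0)
})

test_that("length-bias regression agrees with the normal-equations oracle", {
  lengths <- c(2000, 3500, 5000, 6500, 8000, 9000)
  set.seed(31)
  bias <- 0.5 + 1e-4 * lengths + rnorm(6, sd = 0.05)
  fit <- length_bias_regression(bias, lengths)
  # closed-form least squares
  sxx <- sum((lengths - mean(lengths))^2)
  slope <- sum((lengths - mean(lengths)) * (bias - mean(bias))) / sxx
  intercept <- mean(bias) - slope * mean(lengths)
  resid <- bias - intercept - slope * lengths
  r2 <- 1 - sum(resid^2) / sum((bias - mean(bias))^2)
  tstat <- slope / sqrt(sum(resid^2) / 4 / sxx)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit$p_value, 2 * pt(abs(tstat), 4, lower.tail = FALSE), tolerance = 1e-10)
  # exact affine relation and constant bias
  exact <- suppressWarnings(length_bias_regression(2 + 0.001 * lengths, lengths))
  expect_equal(exact$r_squared, 1, tolerance = 1e-9)
  flat <- suppressWarnings(
    length_bias_regression(rep(2, 6) + rnorm(6, sd = 1e-12), lengths)
  )
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_error(length_bias_regression(1:2, 1:2), "3 points")
  expect_error(length_bias_regression(1:3, rep(5, 3)), "variance")
})

test_that("gc shift is zero for unbiased data and single components", {
  d <- mock_design(seed = 6)
  cfg <- library_config("lib", "Tn5_V", 5, depth = 1e6, seed = 2)
  pool <- contaminant_pool("Tn5_V",
    data.frame(genus = "g", shared = TRUE, meanlog = 0, sdlog = 0.1),
    load_median_pg = 0
  )
  p <- simulate_library(d, cfg, pool, bias = bias_model(0, 0, 0, 0),
                        endogenous = data.frame(genus = character(), fraction = numeric()))
  expect_lt(abs(gc_shift(p, d)), 0.005)
  # single-component design: measured GC is the design GC exactly
  d1 <- d
  d1$components <- d1$components[1, ]
  d1$components$mass_fraction <- 1
  p1 <- make_profile(d1$components$id, "sequins", 100)
  expect_equal(gc_shift(p1, d1), 0)
  nc <- make_profile("g", "kit_contaminant", 10, input_pg = 0)
  expect_error(gc_shift(nc, d), "no sequins reads")
})

test_that("rarefaction subsamples without replacement", {
  p <- make_profile(c("a", "b", "c", "z"),
                    c("sequins", "sequins", "kit_contaminant", "sequins"),
                    c(5, 5, 10, 0))
  same <- rarefy_profile(p, 20, seed = 1)
  expect_equal(same$reads, p$reads)
  zero <- rarefy_profile(p, 0, seed = 1)
  expect_equal(sum(zero$reads), 0)
  expect_error(rarefy_profile(p, 21), "exceeds")
  for (s in 1:20) {
    r <- rarefy_profile(p, 10, seed = s)
    expect_equal(sum(r$reads), 10)
    expect_true(all(r$reads <= p$reads))
    expect_equal(r$reads[4], 0) # zero taxa stay zero
  }
})

test_that("rarefied counts follow the hypergeometric distribution", {
  p <- make_profile(c("a", "b"), c("sequins", "sequins"), c(5, 15))
  draws <- vapply(1:10000, function(s) rarefy_profile(p, 10, seed = s)$reads[1], numeric(1))
  observed <- tabulate(draws + 1, nbins = 6)
  expected <- dhyper(0:5, 5, 15, 10) * 10000
  # mean matches the expectation count*depth/total
  expect_equal(mean(draws), 5 * 10 / 20, tolerance = 0.02)
  chi2 <- sum((observed - expected)^2 / expected)
  expect_gt(pchisq(chi2, df = 5, lower.tail = FALSE), 0.01)
})
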