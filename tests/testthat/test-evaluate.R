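call_all <- function(taxa, value) {
  structure(data.frame(taxon = taxa, call = value, stringsAsFactors = FALSE),
            class = c("contaminant_call", "data.frame"))
}

test_that("confusion counts tally reads by truth and call", {
  p <- make_profile(c("g", "s"), c("kit_contaminant", "sequins"), c(100, 900))
  cc <- confusion_counts(call_all(c("g", "s"), "contaminant"), p)
  expect_equal(cc, list(tp = 100, fn = 0, tn = 0, fp = 900))
  perfect <- call_all(c("g", "s"), c("contaminant", "true_component"))
  cc2 <- confusion_counts(perfect, p)
  expect_equal(cc2$fn + cc2$fp, 0)
  # five-taxon hand tally
  p5 <- make_profile(
    c("a", "b", "c", "d", "e"),
    c("sequins", "sequins", "kit_contaminant", "kit_contaminant", "endogenous_contaminant"),
    c(10, 20, 30, 40, 50)
  )
  call5 <- call_all(c("a", "b", "c", "d", "e"),
                    c("true_component", "contaminant", "contaminant",
                      "true_component", "contaminant"))
  cc5 <- confusion_counts(call5, p5)
  expect_equal(cc5, list(tp = 80, fn = 40, tn = 10, fp = 20))
  expect_error(confusion_counts(call_all("a", "contaminant"), p5), "uncalled")
})

test_that("confusion counts conserve total reads", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    p <- make_profile(
      sprintf("t%d", 1:n),
      sample(c("sequins", "kit_contaminant"), n, replace = TRUE),
      sample(0:100, n, replace = TRUE)
    )
    cl <- call_all(p$taxon, sample(c("contaminant", "true_component"), n, replace = TRUE))
    cc <- confusion_counts(cl, p)
    expect_equal(cc$tp + cc$fn + cc$tn + cc$fp, sum(p$reads))
    expect_equal(cc$tp + cc$fn, sum(p$reads[p$label != "sequins"]))
  }
})

test_that("precision and recall handle undefined denominators", {
  pr <- precision_recall(list(tp = 100, fn = 0, tn = 0, fp = 900))
  expect_equal(pr$precision, 0.1)
  expect_equal(pr$recall, 1)
  expect_equal(precision_recall(list(tp = 5, fn = 0, tn = 10, fp = 0)),
               list(precision = 1, recall = 1))
  none <- precision_recall(list(tp = 0, fn = 0, tn = 10, fp = 0))
  expect_true(is.na(none$precision))
  expect_true(is.na(none$recall)) # no contaminants in truth
})

test_that("threshold optimisation equals exhaustive search", {
  set.seed(29)
  grid <- threshold_grid()
  for (i in 1:25) {
    n <- 20
    scores <- data.frame(
      taxon = sprintf("t%d", 1:n),
      score_freq = ifelse(runif(n) < 0.15, NA, runif(n)),
      score_prev = ifelse(runif(n) < 0.15, NA, runif(n))
    )
    p <- make_profile(
      scores$taxon,
      sample(c("sequins", "kit_contaminant"), n, replace = TRUE, prob = c(0.6, 0.4)),
      sample(1:200, n, replace = TRUE)
    )
    mode <- sample(c("frequency", "prevalence", "either"), 1)
    sw <- optimize_threshold(scores, p, mode = mode, grid = grid)
    # independent exhaustive sweep
    prec <- rec <- numeric(length(grid))
    for (j in seq_along(grid)) {
      cl <- classify_contaminants(scores, mode, grid[j], grid[j])
      cc <- confusion_counts(cl, p)
      prec[j] <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA
      rec[j] <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA
    }
    ok <- !is.na(prec) & prec == 1
    expected <- if (any(ok)) {
      cand <- which(ok)
      best <- cand[which(rec[cand] == max(rec[cand], na.rm = TRUE))]
      grid[max(best)]
    } else {
      cand <- which(prec == max(prec, na.rm = TRUE))
      best <- cand[which(rec[cand] == max(rec[cand], na.rm = TRUE))]
      grid[max(best)]
    }
    expect_equal(sw$chosen, expected)
    expect_equal(sw$attained_perfect_precision, any(ok))
  }
})

test_that("optimizer picks the largest threshold under unbroken precision", {
  scores <- data.frame(taxon = c("g1", "g2"), score_freq = c(0.01, 0.05),
                       score_prev = NA_real_)
  p <- make_profile(c("g1", "g2", "s"),
                    c("kit_contaminant", "kit_contaminant", "sequins"),
                    c(50, 50, 900))
  scores <- rbind(scores, data.frame(taxon = "s", score_freq = 0.99, score_prev = NA))
  sw <- optimize_threshold(scores, p, mode = "frequency")
  expect_equal(sw$chosen, 0.5)
  expect_true(sw$attained_perfect_precision)
  single <- optimize_threshold(scores, p, mode = "frequency", grid = 0.3)
  expect_equal(single$chosen, 0.3)
  expect_error(optimize_threshold(scores, p, grid = numeric()), "empty")
})

test_that("decontaminated profiles are compared to the actual signal", {
  p <- make_profile(c("s1", "s2", "g"),
                    c("sequins", "sequins", "kit_contaminant"),
                    c(600, 300, 100))
  perfect <- call_all(c("s1", "s2", "g"),
                      c("true_component", "true_component", "contaminant"))
  expect_equal(decontaminated_jsd(p, perfect), 0)
  # one false negative: oracle via the jsd metric itself on hand profiles
  miss <- call_all(c("s1", "s2", "g"), c("true_component", "true_component", "true_component"))
  expect_equal(decontaminated_jsd(p, miss),
               jsd(c(s1 = 0.6, s2 = 0.3, g = 0.1), c(s1 = 2 / 3, s2 = 1 / 3)))
  all_gone <- call_all(c("s1", "s2", "g"), "contaminant")
  expect_warning(d <- decontaminated_jsd(p, all_gone), "removed every taxon")
  expect_equal(d, 1)
})

test_that("permanova recovers a perfect block structure with R2 = 1", {
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  diag(d) <- 0
  res <- permanova(d, c(1, 1, 1, 2, 2, 2), n_permutations = 99, seed = 1)
  expect_equal(res$r_squared, 1)
  # at N = 6, 10% of relabelings reproduce the perfect partition (F ties)
  expect_lte(res$p_value, 0.25)
})

test_that("exact permutation p equals brute-force enumeration at N = 6", {
  set.seed(37)
  x <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(x))
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  res <- permanova(d, g, exact = TRUE)
  expect_equal(res$n_permutations, 720)
  # independent oracle: recursive enumeration and direct F recomputation
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  f_of <- function(grp) {
    d2 <- d^2
    sst <- sum(d2[upper.tri(d2)]) / 6
    ssw <- 0
    for (lev in unique(grp)) {
      i <- which(grp == lev)
      sub <- d2[i, i, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  f_obs <- f_of(as.integer(g))
  f_all <- apply(perms, 1, function(p) f_of(as.integer(g)[p]))
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-12)
})

test_that("permanova matches vegan::adonis2 on random data", {
  skip_if_not_installed("vegan")
  set.seed(55)
  x <- matrix(rnorm(40), 10, 4)
  d <- dist(x)
  g <- factor(rep(c("u", "v"), each = 5))
  mine <- permanova(as.matrix(d), g, n_permutations = 199, seed = 2)
  ref <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("permanova R2 is invariant to relabeling and distance scaling", {
  set.seed(61)
  d <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  g <- factor(rep(c("a", "b"), 4))
  base <- permanova(d, g, n_permutations = 49, seed = 3)
  relab <- permanova(d, factor(rep(c("x", "y"), 4)), n_permutations = 49, seed = 3)
  scaled <- permanova(3.7 * d, g, n_permutations = 49, seed = 3)
  expect_equal(base$r_squared, relab$r_squared, tolerance = 1e-12)
  expect_equal(base$r_squared, scaled$r_squared, tolerance = 1e-12)
  expect_error(permanova(matrix(1:9, 3, 3), rep(1, 3)), "symmetric")
})

test_that("permutation p is approximately uniform under exchangeability", {
  set.seed(71)
  d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  ps <- vapply(1:100, function(i) {
    g <- factor(sample(rep(c("a", "b"), 6)))
    permanova(d, g, n_permutations = 99, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.1), 0.25)
})
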