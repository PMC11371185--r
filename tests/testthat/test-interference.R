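test_that("gof chi-square equals the brute-force sum and matches known layouts", {
  d <- foci_distribution_from_counts(c(54, 238, 220, 39))
  for (policy in c("excel_k_minus_1", "folded_k_minus_2")) {
    fit <- poisson_gof(d, policy)
    expect_equal(fit$chi2, sum((fit$observed - fit$expected)^2 / fit$expected),
                 tolerance = 1e-10)
    expect_equal(fit$lambda_hat, 795 / 551)
    expect_gte(fit$p_value, 0)
    expect_lte(fit$p_value, 1)
  }
  excel <- poisson_gof(d, "excel_k_minus_1")
  expect_equal(excel$df, 4L) # categories 0..4 (one extra empty), minus 1
  expect_equal(sum(excel$observed), 551)
  folded <- poisson_gof(d, "folded_k_minus_2")
  expect_true(all(folded$expected >= 5))
  expect_equal(folded$df, length(folded$categories) - 2L)
})

test_that("gof preconditions are enforced", {
  expect_error(poisson_gof(foci_distribution_from_counts(c(5, 6))), ">= 20")
  expect_error(poisson_gof(foci_distribution_from_counts(c(30))), "2 categories")
})

test_that("folded-policy p-values are uniform under a true Poisson null", {
  set.seed(401)
  pv <- vapply(seq_len(400), function(i) {
    x <- rpois(551, 1.44)
    d <- foci_distribution_from_counts(tabulate(x + 1L, nbins = max(x) + 1L))
    poisson_gof(d, "folded_k_minus_2")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("homogeneity test: identical distributions give chi2 = 0, p = 1", {
  d <- foci_distribution_from_counts(c(54, 238, 220, 39))
  h <- chisq_homogeneity(d, d)
  expect_equal(h$chi2, 0)
  expect_equal(h$p_value, 1)
})

test_that("homogeneity test agrees with the standard Pearson chi-square", {
  a <- foci_distribution_from_counts(c(40, 160, 150, 50))
  b <- foci_distribution_from_counts(c(70, 140, 120, 30))
  h <- chisq_homogeneity(a, b)
  oracle <- stats::chisq.test(rbind(c(40, 160, 150, 50),
                                    c(70, 140, 120, 30)), correct = FALSE)
  expect_equal(h$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(h$df, unname(oracle$parameter))
  expect_equal(h$p_value, oracle$p.value, tolerance = 1e-10)
})

test_that("homogeneity test is calibrated under a shared multinomial", {
  set.seed(402)
  probs <- c(0.1, 0.45, 0.35, 0.1)
  rej <- 0L
  for (i in seq_len(800)) {
    a <- foci_distribution_from_counts(as.integer(stats::rmultinom(1, 500, probs)))
    b <- foci_distribution_from_counts(as.integer(stats::rmultinom(1, 500, probs)))
    if (chisq_homogeneity(a, b)$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 800 - 0.05), 0.02)
})

test_that("homogeneity test separates the wild-type-like and no-interference presets", {
  presets <- genotype_presets()
  wt <- simulate_experiment(presets$AACC_wt, 300, seed = 403)
  mut <- simulate_experiment(presets$aaCc, 300, seed = 404)
  h <- chisq_homogeneity(foci_distribution(wt), foci_distribution(mut))
  expect_lt(h$p_value, 0.001)
})

test_that("spacing CV tracks interference strength analytically", {
  expect_equal(spacing_cv(rep(0.4, 10)), 0)
  set.seed(405)
  expect_equal(spacing_cv(diff(sample_gamma_renewal(5000, 2, 1))), 1,
               tolerance = 0.1)
  expect_equal(spacing_cv(diff(sample_gamma_renewal(5000, 2, 9))), 1 / 3,
               tolerance = 0.1)
  expect_error(spacing_cv(0.5), ">= 2")
})

test_that("mean spacing and spacing CV fall as interference weakens", {
  # matched mean focus count, nu from strong interference to none
  set.seed(406)
  stats_by_nu <- vapply(c(8, 4, 2, 1), function(nu) {
    gaps <- unlist(lapply(seq_len(1500), function(i) {
      adjacent_relative_distances(sample_gamma_renewal(1, 2, nu))
    }))
    c(mean(gaps), spacing_cv(gaps))
  }, numeric(2))
  expect_true(all(diff(stats_by_nu[1, ]) < 0)) # mean spacing decreases
  expect_true(all(diff(stats_by_nu[2, ]) > 0)) # CV rises toward Poisson
})

test_that("gamma-shape MLE recovers known shapes and matches the reference fit", {
  set.seed(407)
  x5 <- rgamma(10000, shape = 5, rate = 10)
  est5 <- estimate_nu(x5, n_boot = 0)
  expect_gt(est5$nu_hat, 4.5)
  expect_lt(est5$nu_hat, 5.5)
  oracle <- suppressWarnings(MASS::fitdistr(x5, "gamma"))
  expect_equal(est5$nu_hat, unname(oracle$estimate["shape"]), tolerance = 1e-3)

  x1 <- rexp(10000, rate = 3) # exponential = gamma(1)
  expect_equal(estimate_nu(x1, n_boot = 0)$nu_hat, 1, tolerance = 0.15)
})

test_that("bootstrap interval is seeded, reproducible, and covers the truth", {
  set.seed(408)
  x <- rgamma(500, shape = 3, rate = 6)
  e1 <- estimate_nu(x, n_boot = 200, seed = 42)
  e2 <- estimate_nu(x, n_boot = 200, seed = 42)
  expect_identical(e1$ci, e2$ci)
  expect_lt(e1$ci[1], 3)
  expect_gt(e1$ci[2], 3)
  expect_error(estimate_nu(rgamma(10, 2)), ">= 30")
  expect_error(estimate_nu(c(rep(1, 40)) * 1), "constant")
})

test_that("Games-Howell: equal groups give mean_diff 0 and p near 1", {
  x <- c(rnorm(20, 5, 1))
  gh <- games_howell(c(x, x), rep(c("a", "b"), each = 20))
  expect_equal(gh$mean_diff, 0)
  expect_gt(gh$p_adjusted, 0.999)
  expect_error(games_howell(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)),
               "zero variance")
  expect_error(games_howell(1:4, rep("a", 4)), ">= 2 groups")
})

test_that("Games-Howell matches Tukey HSD under equal variances and n", {
  set.seed(409)
  n <- 1000; k <- 3
  # groups scaled to exactly unit variance so the two procedures share SEs
  g <- lapply(c(0, 0.08, 0.14), function(m) as.numeric(scale(rnorm(n))) + m)
  values <- unlist(g)
  groups <- rep(c("g1", "g2", "g3"), each = n)
  gh <- games_howell(values, groups)
  # independent classical Tukey: pooled variance, df = k(n-1)
  s2p <- mean(vapply(g, var, numeric(1)))
  for (j in seq_len(nrow(gh))) {
    ma <- mean(values[groups == gh$group_a[j]])
    mb <- mean(values[groups == gh$group_b[j]])
    q <- abs(ma - mb) / sqrt(s2p / n)
    p_tukey <- ptukey(q, nmeans = k, df = k * (n - 1), lower.tail = FALSE)
    expect_lt(abs(gh$p_adjusted[j] - p_tukey) / p_tukey, 0.05)
  }
})

test_that("Games-Howell attains its family-wise error rate under the global null", {
  set.seed(410)
  fw <- 0L
  for (i in seq_len(1000)) {
    values <- rnorm(4 * 50)
    gh <- games_howell(values, rep(paste0("g", 1:4), each = 50))
    if (any(gh$p_adjusted < 0.05)) fw <- fw + 1L
  }
  expect_lt(abs(fw / 1000 - 0.05), 0.02)
})
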