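test_that("minimum chiasma scoring applies ring=2, rod=1, univalent=0", {
  df <- make_rod_cells(1)
  df$config[1:13] <- "ring"
  df$n_chiasmata[1:13] <- 2L
  est <- score_min_chiasmata(df)
  expect_equal(est$min_chiasmata, 2 * 13 + 6)
  expect_equal(est$n_ring, 13)
  expect_equal(est$n_rod, 6)

  df2 <- make_rod_cells(1)
  df2$config <- "univalent_pair"
  df2$n_chiasmata <- 0L
  df2$n_labeled_chiasmata <- 0L
  df2$n_class1_foci <- 0L
  df2$focus_positions <- replicate(19, numeric(0), simplify = FALSE)
  expect_equal(score_min_chiasmata(df2)$min_chiasmata, 0)

  df3 <- make_rod_cells(1)
  df3$config[5] <- "unknown"
  expect_error(score_min_chiasmata(df3), "unknown")
})

test_that("expected minimum chiasmata reproduces the configuration algebra", {
  expect_equal(round(expected_min_chiasmata(0.6595, 0.3405, 0, 19), 2), 31.53)
  expect_equal(expected_min_chiasmata(1, 0, 0, 19), 38)
  expect_equal(expected_min_chiasmata(0, 0, 1, 19), 0)
  expect_error(expected_min_chiasmata(0.5, 0.4, 0, 19), "sum to 1")
})

test_that("crossover accounting partitions labelled vs unlabelled chiasmata", {
  df <- make_rod_cells(1)
  df$config[1] <- "ring"
  df$n_chiasmata[1] <- 2L
  df$n_labeled_chiasmata[1] <- 1L # one unlabelled chiasma -> class II
  acct <- account_crossovers(df)
  expect_equal(acct$n_class2, 1)
  expect_equal(acct$n_class1, 19) # 18 rods + 1 labelled on the ring
  expect_equal(acct$n_total, acct$n_class1 + acct$n_class2)

  all_labelled <- make_rod_cells(1)
  acct2 <- account_crossovers(all_labelled)
  expect_equal(acct2$n_class2, 0)
  expect_equal(acct2$n_total, acct2$n_class1)

  bad <- make_rod_cells(1)
  bad$n_chiasmata[3] <- NA_integer_
  expect_error(account_crossovers(bad), "must be present")
  zyg <- make_rod_cells(1, stage = "zygotene_early_pachytene")
  expect_error(account_crossovers(zyg), "diakinesis")
})

test_that("on full-detection simulations, per-cell totals equal simulator truth", {
  preset <- genotype_presets()$AACC_wt
  df <- simulate_experiment(preset, 25, seed = 301, keep_truth = TRUE)
  acct <- account_crossovers(df)
  truth <- tapply(df$n_class1_true + df$n_class2_true, df$cell_id, sum)
  expect_equal(acct$n_total, as.integer(truth[acct$cell_id]),
               ignore_attr = TRUE)
})

test_that("scoring is conservative: min chiasmata <= true crossovers", {
  presets <- genotype_presets()
  set.seed(302)
  for (lab in c("AACC_wt", "aaCc")) {
    df <- simulate_experiment(presets[[lab]], 25, seed = NULL,
                              keep_truth = TRUE)
    est <- score_min_chiasmata(df)
    truth <- tapply(df$n_class1_true + df$n_class2_true, df$cell_id, sum)
    expect_true(all(est$min_chiasmata <= truth[est$cell_id]))
  }
})

test_that("foci distribution reproduces the printed count/percentage table", {
  # 551 bivalents: proportions 9.80 / 43.19 / 39.93 / 7.08 percent
  d <- foci_distribution_from_counts(c(54, 238, 220, 39))
  expect_equal(d$n_bivalents, 551)
  expect_equal(round(100 * d$proportions, 2), c(9.80, 43.19, 39.93, 7.08))
  expect_equal(sum(d$proportions), 1, tolerance = 1e-12)
  expect_equal(d$counts, round(d$proportions * d$n_bivalents))
})

test_that("foci distribution from records handles selection and the univalent flag", {
  df <- make_rod_cells(2)
  d <- foci_distribution(df, "diakinesis")
  expect_equal(d$categories, c(0, 1))
  expect_equal(d$proportions, c(0, 1)) # every bivalent exactly 1 focus
  df$config[1] <- "univalent_pair"
  df$n_chiasmata[1] <- 0L
  df$n_labeled_chiasmata[1] <- 0L
  df$n_class1_foci[1] <- 0L
  df$focus_positions[[1]] <- numeric(0)
  expect_equal(foci_distribution(df)$n_bivalents, 37)
  expect_equal(foci_distribution(df, count_univalents_as_zero = TRUE)$n_bivalents, 38)
  expect_error(foci_distribution(df, stage = "zygotene_early_pachytene"),
               "no bivalents")
})

test_that("adjacent relative distances are consecutive differences", {
  expect_equal(adjacent_relative_distances(c(0.2, 0.7)), 0.5)
  expect_equal(adjacent_relative_distances(c(0, 1)), 1)
  expect_equal(adjacent_relative_distances(0.4), numeric(0))
  expect_equal(adjacent_relative_distances(numeric(0)), numeric(0))
  expect_equal(adjacent_relative_distances(c(0.1, 0.4, 0.9)), c(0.3, 0.5))
})

test_that("relative_spacings pools, or averages per bivalent", {
  df <- make_rod_cells(1, n_pairs = 3)
  df$focus_positions <- list(c(0.1, 0.5), c(0.2, 0.4, 0.9), 0.5)
  df$n_class1_foci <- c(2L, 3L, 1L)
  df$n_chiasmata <- c(2L, 3L, 1L)
  df$n_labeled_chiasmata <- c(2L, 3L, 1L)
  expect_equal(sort(relative_spacings(df)), sort(c(0.4, 0.2, 0.5)))
  expect_equal(sort(relative_spacings(df, per_bivalent_average = TRUE)),
               sort(c(0.4, 0.35)))
})

test_that("intensity normalization sets the reference mean to 1", {
  df <- data.frame(
    genotype = c("wt", "wt", "mut", "mut"),
    cell_id = c("c1", "c2", "c3", "c4"),
    stage = "zygotene_early_pachytene",
    raw_intensity = c(110, 130, 50, 40),
    background = c(10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
  norm <- normalize_intensity(df, "wt")
  expect_equal(mean(norm$normalized[norm$genotype == "wt"]), 1)
  # invariance to uniform rescaling of raw values
  df2 <- df
  df2$raw_intensity <- df2$raw_intensity * 3
  df2$background <- df2$background * 3
  norm2 <- normalize_intensity(df2, "wt")
  expect_equal(norm2$normalized, norm$normalized)
  # raw == background -> exactly 0
  df3 <- df
  df3$raw_intensity[3] <- df3$background[3]
  expect_equal(normalize_intensity(df3, "wt")$normalized[3], 0)
  expect_error(normalize_intensity(df, "missing"), "no records")
})

test_that("a mutant normalized mean of 0.3423 reads as a 65.77% decrease", {
  # construct a mutant group whose normalized mean is exactly 0.3423
  ref <- data.frame(genotype = "wt", cell_id = c("r1", "r2"),
                    stage = "zygotene_early_pachytene",
                    raw_intensity = c(90, 110), background = 0,
                    stringsAsFactors = FALSE)
  mut <- data.frame(genotype = "aaCc", cell_id = c("m1", "m2"),
                    stage = "zygotene_early_pachytene",
                    raw_intensity = 100 * 0.3423 + c(-5, 5), background = 0,
                    stringsAsFactors = FALSE)
  norm <- normalize_intensity(rbind(ref, mut), "wt")
  dec <- 100 * (1 - mean(norm$normalized[norm$genotype == "aaCc"]))
  expect_equal(dec, 65.77, tolerance = 1e-10)
})

test_that("percent change matches the printed whole-percent convention", {
  expect_equal(percent_change(38.38, 26.59)$rounded, 44)
  expect_equal(round(percent_change(38.38, 26.59)$raw, 2), 44.34)
  expect_equal(percent_change(26.59, 26.59)$rounded, 0)
  expect_equal(percent_change(37.91, 26.88)$rounded, 41)
  expect_equal(round(percent_change(37.91, 26.88)$raw, 2), 41.03)
  expect_equal(percent_change(20, 40)$rounded, -50)
  expect_error(percent_change(10, 0), "reference")
})

test_that("univalent bookkeeping converts chromosome means to pair fractions", {
  expect_equal(round(100 * univalent_fraction(26.90, 38), 2), 70.79)
  expect_equal(univalent_fraction(0, 38), 0)
  expect_equal(univalent_fraction(38, 38), 1)
  expect_error(univalent_fraction(39, 38), "\\[0, 38\\]")
})
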