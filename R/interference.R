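# Statistical machinery for interference inference: the constructed Poisson
# null on foci-per-bivalent counts (two explicit binning policies, because
# spreadsheet-style chi-square layouts and the textbook estimated-parameter
# convention give different degrees of freedom), two-sample homogeneity,
# spacing summaries, a gamma-shape estimator for parameter recovery, and
# Games-Howell pairwise comparisons.

#' Poisson goodness-of-fit on a foci-per-bivalent distribution
#'
#' Tests whether per-bivalent focus counts are Poisson (the no-interference
#' null). The Poisson mean is estimated by the sample mean (maximum
#' likelihood); expected counts are `n * dpois(k, lambda_hat)` under the
#' chosen binning policy:
#'
#' * `"excel_k_minus_1"` (default): categories 0 .. max observed plus one
#'   extra empty category, expected counts NOT renormalized, df = number of
#'   categories - 1 — the layout a spreadsheet chi-square comparison
#'   produces.
#' * `"folded_k_minus_2"`: the right tail is folded (top category takes the
#'   whole tail mass `n * P(X >= k)`) until every expected count is >= 5;
#'   df = categories - 2, accounting for the estimated mean — the
#'   statistically standard convention, and the calibrated one.
#'
#' @param dist A `foci_distribution` ([foci_distribution()] or
#'   [foci_distribution_from_counts()]).
#' @param policy Binning policy (see above).
#' @return An object of class `poisson_gof`: `lambda_hat`, `categories`,
#'   `observed`, `expected`, `chi2`, `df`, `p_value`, `policy`.
#' @export
poisson_gof <- function(dist, policy = c("excel_k_minus_1",
                                         "folded_k_minus_2")) {
  policy <- match.arg(policy)
  stopifnot(inherits(dist, "foci_distribution"))
  n <- dist$n_bivalents
  if (n < 20)
    ms_stop("Poisson goodness-of-fit needs >= 20 bivalents (got %d)", n)
  if (length(dist$categories) < 2)
    ms_stop("distribution must span >= 2 categories")
  obs <- dist$counts
  lambda_hat <- sum(dist$categories * obs) / n
  if (lambda_hat <= 0) ms_stop("sample mean is 0; no Poisson fit possible")

  if (policy == "excel_k_minus_1") {
    k_max <- max(dist$categories)
    cats <- 0:(k_max + 1L)
    observed <- c(obs, 0L)
    expected <- n * dpois(cats, lambda_hat)
    if (any(expected == 0))
      ms_stop("expected count of 0 in category %d; fold the tail (policy 'folded_k_minus_2')",
              cats[which(expected == 0)[1]])
    df <- length(cats) - 1L
    labels <- as.character(cats)
  } else {
    # fold the right tail until every expected count >= 5
    k_max <- max(dist$categories)
    repeat {
      cats <- 0:k_max
      expected <- n * dpois(cats, lambda_hat)
      expected[k_max + 1L] <- n * ppois(k_max - 1L, lambda_hat,
                                        lower.tail = FALSE) # tail mass
      if (all(expected >= 5) || k_max <= 1L) break
      k_max <- k_max - 1L
    }
    if (any(expected < 5))
      ms_stop("cannot reach expected counts >= 5 in every category; too few bivalents")
    observed <- c(obs[seq_len(k_max)],
                  sum(obs[(k_max + 1L):length(obs)]))
    df <- length(cats) - 2L
    if (df < 1)
      ms_stop("folded table leaves no degrees of freedom")
    labels <- c(as.character(0:(k_max - 1L)), paste0(k_max, "+"))
  }

  chi2 <- sum((observed - expected)^2 / expected)
  structure(
    list(lambda_hat = lambda_hat, categories = labels,
         observed = observed, expected = expected,
         chi2 = chi2, df = df,
         p_value = pchisq(chi2, df, lower.tail = FALSE),
         policy = policy, n_bivalents = n),
    class = "poisson_gof"
  )
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf(
    "<poisson_gof> policy=%s  lambda_hat=%.4f  n=%d\n  chi2=%.4g  df=%d  p=%.4g\n",
    x$policy, x$lambda_hat, x$n_bivalents, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.poisson_gof <- function(x, ...) {
  data.frame(policy = x$policy, lambda_hat = x$lambda_hat,
             category = x$categories, observed = x$observed,
             expected = x$expected, chi2 = x$chi2, df = x$df,
             p_value = x$p_value, n_bivalents = x$n_bivalents,
             stringsAsFactors = FALSE)
}

#' Two-sample chi-square homogeneity test on foci distributions
#'
#' Pearson chi-square on the 2 x K contingency table of the two
#' distributions, after padding both to a shared category range and folding
#' right-tail categories whose combined expected count (under homogeneity)
#' falls below 5. df = K - 1.
#'
#' @param dist_a,dist_b `foci_distribution` objects, each with n >= 20.
#' @return List with `chi2`, `df`, `p_value`, `table` (the folded 2 x K
#'   table), of class `chisq_homogeneity`.
#' @export
chisq_homogeneity <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "foci_distribution"),
            inherits(dist_b, "foci_distribution"))
  if (dist_a$n_bivalents < 20 || dist_b$n_bivalents < 20)
    ms_stop("both samples need >= 20 bivalents")
  k_max <- max(max(dist_a$categories), max(dist_b$categories))
  pad <- function(d) c(d$counts, rep(0L, k_max + 1L - length(d$counts)))
  a <- pad(dist_a); b <- pad(dist_b)
  n_a <- sum(a); n_b <- sum(b); n <- n_a + n_b

  # fold right tail while the combined expected count of the top category
  # (column total scaled by either row share, take the smaller) is < 5
  repeat {
    k <- length(a)
    col_tot <- a + b
    exp_min <- min(n_a, n_b) / n * col_tot[k]
    if (exp_min >= 5 || k <= 2) break
    a <- c(a[seq_len(k - 2)], a[k - 1] + a[k])
    b <- c(b[seq_len(k - 2)], b[k - 1] + b[k])
  }
  if (length(a) < 2)
    ms_stop("degenerate single-category table; homogeneity test undefined")

  tab <- rbind(a = a, b = b)
  col_tot <- colSums(tab)
  expected <- outer(c(n_a, n_b) / n, col_tot)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  structure(
    list(chi2 = chi2, df = df,
         p_value = pchisq(chi2, df, lower.tail = FALSE),
         table = tab),
    class = "chisq_homogeneity"
  )
}

#' @export
print.chisq_homogeneity <- function(x, ...) {
  cat(sprintf("<chisq_homogeneity> chi2=%.4g df=%d p=%.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Coefficient of variation of inter-focus spacings
#'
#' SD/mean of the pooled normalized spacing sample — the standard
#' interference-strength summary: a gamma-renewal process of shape `nu` has
#' interval CV `1/sqrt(nu)`, so smaller CV means stronger interference.
#'
#' @param distances Numeric vector of >= 2 spacings.
#' @return CV (numeric scalar).
#' @export
spacing_cv <- function(distances) {
  if (length(distances) < 2)
    ms_stop("spacing CV needs >= 2 spacings (got %d)", length(distances))
  if (any(!is.finite(distances)) || any(distances < 0))
    ms_stop("spacings must be finite and nonnegative")
  sd(distances) / mean(distances)
}

#' Interference-strength estimate from pooled spacings
#'
#' Maximum-likelihood estimate of the gamma shape `nu` of the inter-focus
#' spacing distribution: method-of-moments initialization, then Newton
#' iteration on the profile score equation
#' `log(nu) - digamma(nu) = log(mean(x)) - mean(log(x))` to tolerance 1e-8.
#' An optional seeded percentile bootstrap gives a 95% interval.
#'
#' Spacings observed inside finite bivalents are edge-censored (a gap is
#' only observed if both foci fit on the bivalent), which biases the
#' estimate when the window holds few foci; see the methods vignette.
#'
#' @param spacings Numeric vector of >= 30 positive spacings.
#' @param n_boot Bootstrap resamples for the interval (default 1000; 0
#'   disables the interval).
#' @param seed Seed for the bootstrap resampling (recorded in the result).
#' @param conf Interval coverage (default 0.95).
#' @return Object of class `nu_estimate`: `nu_hat`, `ci` (or `NULL`),
#'   `n`, `n_boot`, `seed`, `iterations`.
#' @export
estimate_nu <- function(spacings, n_boot = 1000, seed = 1L, conf = 0.95) {
  x <- spacings[is.finite(spacings)]
  if (length(x) < 30)
    ms_stop("estimate_nu needs >= 30 spacings (got %d)", length(x))
  if (any(x <= 0))
    ms_stop("spacings must be strictly positive for the gamma model")

  nu_hat <- gamma_shape_mle(x)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    boots <- numeric(n_boot)
    n <- length(x)
    for (b in seq_len(n_boot)) {
      boots[b] <- gamma_shape_mle(x[sample.int(n, n, replace = TRUE)])$shape
    }
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  structure(
    list(nu_hat = nu_hat$shape, ci = ci, n = length(x),
         n_boot = n_boot, seed = if (n_boot > 0) seed else NULL,
         conf = conf, iterations = nu_hat$iterations),
    class = "nu_estimate"
  )
}

# Newton solver for the gamma-shape MLE on positive data.
gamma_shape_mle <- function(x, tol = 1e-8, max_iter = 100L) {
  m <- mean(x)
  s <- log(m) - mean(log(x)) # always > 0 unless x constant
  if (s <= 0) ms_stop("spacings are (numerically) constant; shape is unbounded")
  nu <- m^2 / var(x) # method-of-moments start
  if (!is.finite(nu) || nu <= 0) nu <- 1
  for (it in seq_len(max_iter)) {
    h <- log(nu) - digamma(nu) - s
    hp <- 1 / nu - trigamma(nu)
    step <- h / hp
    nu_new <- nu - step
    if (nu_new <= 0) nu_new <- nu / 2 # guard: stay in the domain
    if (abs(nu_new - nu) < tol * max(1, nu)) {
      return(list(shape = nu_new, iterations = it))
    }
    nu <- nu_new
  }
  ms_stop("gamma shape MLE did not converge in %d iterations (last nu = %g)",
          max_iter, nu)
}

#' @export
print.nu_estimate <- function(x, ...) {
  cat(sprintf("<nu_estimate> nu_hat=%.4f (n=%d spacings)\n", x$nu_hat, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  %.0f%% bootstrap CI [%.4f, %.4f] (%d resamples, seed %d)\n",
                100 * x$conf, x$ci[1], x$ci[2], x$n_boot, x$seed))
  invisible(x)
}

#' Games-Howell pairwise multiple comparisons
#'
#' Pairwise comparisons robust to unequal variances and sample sizes: each
#' pair uses the Welch standard error `sqrt(s1^2/n1 + s2^2/n2)` and
#' Welch-Satterthwaite degrees of freedom, and the statistic
#' `q = |mean difference| * sqrt(2) / SE` is referred to the studentized
#' range distribution with `k` (the number of groups) means. Adjustment is
#' within the one family formed by the supplied groups.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels, same length as `values`; >= 2 groups, each
#'   with n >= 2 and positive variance.
#' @return Data frame of class `games_howell`: one row per pair with
#'   `group_a`, `group_b`, `mean_diff`, `standard_error`, `df`, `statistic`,
#'   `p_adjusted`.
#' @export
games_howell <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    ms_stop("values and groups must have equal length")
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  labs <- unique(groups)
  k <- length(labs)
  if (k < 2) ms_stop("Games-Howell needs >= 2 groups")
  n <- vapply(labs, function(g) sum(groups == g), numeric(1))
  if (any(n < 2)) ms_stop("every group needs n >= 2")
  m <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  v <- vapply(labs, function(g) var(values[groups == g]), numeric(1))
  if (any(v <= 0))
    ms_stop("group '%s' has zero variance", labs[which(v <= 0)[1]])

  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
    mean_diff = NA_real_, standard_error = NA_real_, df = NA_real_,
    statistic = NA_real_, p_adjusted = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v[a] / n[a] + v[b] / n[b])
    df <- (v[a] / n[a] + v[b] / n[b])^2 /
      ((v[a] / n[a])^2 / (n[a] - 1) + (v[b] / n[b])^2 / (n[b] - 1))
    diff <- m[a] - m[b]
    q <- abs(diff) * sqrt(2) / se
    out$mean_diff[j] <- diff
    out$standard_error[j] <- se
    out$df[j] <- df
    out$statistic[j] <- q
    out$p_adjusted[j] <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  class(out) <- c("games_howell", "data.frame")
  out
}

#' @export
print.games_howell <- function(x, ...) {
  cat(sprintf("<games_howell> %d pairwise comparisons\n", nrow(x)))
  y <- x
  class(y) <- "data.frame"
  y$mean_diff <- round(y$mean_diff, 4)
  y$standard_error <- round(y$standard_error, 4)
  y$df <- round(y$df, 1)
  y$statistic <- round(y$statistic, 3)
  y$p_adjusted <- signif(y$p_adjusted, 3)
  print(y)
  invisible(x)
}
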