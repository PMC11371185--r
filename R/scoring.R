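# Configuration-based scoring rules used on chromosome spreads: a ring
# bivalent carries at least 2 chiasmata, a rod exactly 1 scoreable chiasma,
# a univalent pair none; so the per-cell sum 2*rings + rods is a minimum
# (conservative) estimate of the crossover number.

#' Minimum chiasma estimate per cell from bivalent configurations
#'
#' Scores each cell's diakinesis/metaphase I configurations: every ring
#' bivalent contributes 2, every rod 1, every univalent pair 0. The total is
#' a minimum bound on the true crossover number (a bivalent with more than
#' two crossovers, or with several crossovers confined to one arm, is
#' undercounted).
#'
#' @param df Per-bivalent data frame ([read_bivalents()] layout).
#' @return Data frame with one row per cell: `genotype`, `cell_id`, `n_ring`,
#'   `n_rod`, `n_univalent_pairs`, `min_chiasmata`.
#' @export
score_min_chiasmata <- function(df) {
  bad <- which(df$config == "unknown")
  if (length(bad) > 0)
    ms_stop("cannot score cell '%s': pair %d has config 'unknown'",
            df$cell_id[bad[1]], df$pair_index[bad[1]])
  key <- interaction(df$genotype, df$cell_id, drop = TRUE, lex.order = TRUE)
  split_rows <- split(seq_len(nrow(df)), key)
  out <- do.call(rbind, lapply(split_rows, function(rows) {
    cfg <- df$config[rows]
    n_ring <- sum(cfg == "ring")
    n_rod <- sum(cfg == "rod")
    n_uni <- sum(cfg == "univalent_pair")
    data.frame(genotype = df$genotype[rows[1]],
               cell_id = df$cell_id[rows[1]],
               n_ring = n_ring, n_rod = n_rod, n_univalent_pairs = n_uni,
               min_chiasmata = 2L * n_ring + n_rod,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expected minimum chiasmata per cell from configuration proportions
#'
#' Population-level version of the configuration scoring rule: with
#' proportions `p_ring`, `p_rod`, `p_univalent` of the `n_pairs` homolog
#' pairs, the expected per-cell minimum chiasma count is
#' `n_pairs * (2 * p_ring + p_rod)`.
#'
#' @param p_ring,p_rod,p_univalent Configuration proportions; must sum to 1
#'   within 1e-6.
#' @param n_pairs Number of homolog pairs (default 19).
#' @return Expected chiasmata per cell (numeric scalar).
#' @examples
#' expected_min_chiasmata(0.6595, 0.3405, 0) # 31.5305
#' @export
expected_min_chiasmata <- function(p_ring, p_rod, p_univalent = 0,
                                   n_pairs = 19) {
  s <- p_ring + p_rod + p_univalent
  if (!is.finite(s) || abs(s - 1) > 1e-6)
    ms_stop("configuration proportions must sum to 1 (got %.8f)", s)
  if (p_ring < 0 || p_rod < 0 || p_univalent < 0)
    ms_stop("configuration proportions must be nonnegative")
  n_pairs * (2 * p_ring + p_rod)
}

#' Class I / class II crossover accounting per cell
#'
#' Partitions each diakinesis cell's chiasmata by HEI10 label: labelled
#' chiasmata are class I crossovers, unlabelled chiasmata are treated as
#' class II, and the estimated total is their sum.
#'
#' @param df Per-bivalent data frame; every row must be at stage
#'   `"diakinesis"` and carry `n_chiasmata` and `n_labeled_chiasmata`.
#' @return Data frame with one row per cell: `genotype`, `cell_id`,
#'   `n_class1`, `n_class2`, `n_total` (always `n_class1 + n_class2`).
#' @export
account_crossovers <- function(df) {
  if (any(df$stage != "diakinesis"))
    ms_stop("crossover accounting is defined at diakinesis only")
  if (anyNA(df$n_chiasmata) || anyNA(df$n_labeled_chiasmata))
    ms_stop("row %d: n_chiasmata and n_labeled_chiasmata must be present on every bivalent",
            which(is.na(df$n_chiasmata) | is.na(df$n_labeled_chiasmata))[1])
  if (any(df$n_labeled_chiasmata > df$n_chiasmata))
    ms_stop("row %d: labelled chiasmata exceed total chiasmata",
            which(df$n_labeled_chiasmata > df$n_chiasmata)[1])
  key <- interaction(df$genotype, df$cell_id, drop = TRUE, lex.order = TRUE)
  split_rows <- split(seq_len(nrow(df)), key)
  out <- do.call(rbind, lapply(split_rows, function(rows) {
    n1 <- sum(df$n_labeled_chiasmata[rows])
    n2 <- sum(df$n_chiasmata[rows] - df$n_labeled_chiasmata[rows])
    data.frame(genotype = df$genotype[rows[1]],
               cell_id = df$cell_id[rows[1]],
               n_class1 = n1, n_class2 = n2, n_total = n1 + n2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Foci-per-bivalent distribution
#'
#' Tabulates the number of class I (HEI10) foci per bivalent at one stage,
#' over categories 0 .. max observed. Univalent pairs are excluded by
#' default — the distribution describes bivalents — but can be counted as
#' zero-focus entries with `count_univalents_as_zero = TRUE` (this shifts
#' category-0 mass; see the methods vignette).
#'
#' @param df Per-bivalent data frame.
#' @param stage Stage to select.
#' @param genotype Optional genotype to select (default: all rows pooled).
#' @param count_univalents_as_zero Include univalent pairs as zero-focus
#'   records (default `FALSE`).
#' @return An object of class `foci_distribution`: list with `genotype`,
#'   `stage`, `categories` (0..K), `counts`, `n_bivalents`, `proportions`.
#' @export
foci_distribution <- function(df, stage = "diakinesis", genotype = NULL,
                              count_univalents_as_zero = FALSE) {
  sel <- df$stage == stage
  if (!is.null(genotype)) sel <- sel & df$genotype %in% genotype
  if (!count_univalents_as_zero) sel <- sel & df$config != "univalent_pair"
  sub <- df[sel, , drop = FALSE]
  if (nrow(sub) == 0)
    ms_stop("no bivalents selected at stage '%s'%s", stage,
            if (is.null(genotype)) "" else sprintf(" for genotype '%s'",
                                                   paste(genotype, collapse = "/")))
  if (anyNA(sub$n_class1_foci))
    ms_stop("n_class1_foci missing on %d selected record(s)",
            sum(is.na(sub$n_class1_foci)))
  k_max <- max(sub$n_class1_foci)
  counts <- tabulate(sub$n_class1_foci + 1L, nbins = k_max + 1L)
  new_foci_distribution(
    genotype = if (is.null(genotype)) unique(sub$genotype) else genotype,
    stage = stage, counts = counts)
}

# Construct a foci_distribution from raw category counts (category k has
# `counts[k+1]` bivalents). Used for worked examples given as count tables.
new_foci_distribution <- function(counts, genotype = "unspecified",
                                  stage = "diakinesis") {
  counts <- as.integer(counts)
  if (any(counts < 0)) ms_stop("category counts must be nonnegative")
  n <- sum(counts)
  if (n == 0) ms_stop("distribution has no bivalents")
  structure(
    list(genotype = genotype, stage = stage,
         categories = seq_along(counts) - 1L,
         counts = counts, n_bivalents = n, proportions = counts / n),
    class = "foci_distribution"
  )
}

#' Build a foci distribution directly from category counts
#'
#' For worked examples where a published count (or percentage) table is the
#' input rather than per-bivalent records: element `k+1` of `counts` is the
#' number of bivalents carrying `k` foci.
#'
#' @param counts Integer vector of category counts for foci 0, 1, 2, ...
#' @param genotype,stage Labels carried on the result.
#' @return A `foci_distribution` object.
#' @export
foci_distribution_from_counts <- function(counts, genotype = "unspecified",
                                          stage = "diakinesis") {
  new_foci_distribution(counts, genotype, stage)
}

#' @export
print.foci_distribution <- function(x, ...) {
  cat(sprintf("<foci_distribution> %s, %s: %d bivalents\n",
              paste(x$genotype, collapse = "/"), x$stage, x$n_bivalents))
  tab <- rbind(count = x$counts,
               proportion = round(x$proportions, 4))
  colnames(tab) <- x$categories
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.foci_distribution <- function(x, ...) {
  data.frame(genotype = paste(x$genotype, collapse = "/"), stage = x$stage,
             category = x$categories, count = x$counts,
             proportion = x$proportions, stringsAsFactors = FALSE)
}

#' Distances between adjacent foci on one bivalent
#'
#' Consecutive differences of the sorted focus positions (positions are
#' already fractions of bivalent length, so the result is the normalized
#' inter-focus spacing). A bivalent with 0 or 1 focus yields an empty
#' vector, not a zero.
#'
#' @param positions Sorted numeric vector of focus positions in \[0, 1\].
#' @return Numeric vector of adjacent spacings (possibly empty).
#' @examples
#' adjacent_relative_distances(c(0.2, 0.7)) # 0.5
#' @export
adjacent_relative_distances <- function(positions) {
  if (length(positions) < 2) return(numeric(0))
  diff(sort(positions))
}

#' Pooled normalized inter-focus spacings across bivalents
#'
#' Applies [adjacent_relative_distances()] to every record and either pools
#' all spacings (default, matching how spacing distributions are summarized
#' across meiocytes) or averages per bivalent first.
#'
#' @param df Per-bivalent data frame.
#' @param stage,genotype Optional selection.
#' @param per_bivalent_average If `TRUE`, return one mean spacing per
#'   bivalent with >= 2 foci instead of the pooled spacings.
#' @return Numeric vector of spacings.
#' @export
relative_spacings <- function(df, stage = NULL, genotype = NULL,
                              per_bivalent_average = FALSE) {
  sel <- rep(TRUE, nrow(df))
  if (!is.null(stage)) sel <- sel & df$stage == stage
  if (!is.null(genotype)) sel <- sel & df$genotype %in% genotype
  gaps <- lapply(df$focus_positions[sel], adjacent_relative_distances)
  if (per_bivalent_average) {
    means <- vapply(gaps, function(g) if (length(g) == 0) NA_real_ else mean(g),
                    numeric(1))
    means[!is.na(means)]
  } else {
    unlist(gaps, use.names = FALSE)
  }
}

#' Background-subtracted, reference-normalized intensities
#'
#' Subtracts each record's background from its raw intensity and divides by
#' the mean background-subtracted intensity of the reference genotype, so the
#' reference group has normalized mean 1 by construction. The percent
#' decrease reported for a mutant group is `100 * (1 - mean normalized
#' value)`.
#'
#' @param df Intensity data frame ([read_intensity()] layout).
#' @param reference_genotype Genotype whose mean defines the unit.
#' @return `df` with columns `net_intensity` and `normalized` appended, plus
#'   attribute `reference_mean`.
#' @export
normalize_intensity <- function(df, reference_genotype) {
  if (!any(df$genotype == reference_genotype))
    ms_stop("reference genotype '%s' has no records", reference_genotype)
  net <- df$raw_intensity - df$background
  ref_mean <- mean(net[df$genotype == reference_genotype])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    ms_stop("reference mean net intensity must be > 0 (got %g)", ref_mean)
  df$net_intensity <- net
  df$normalized <- net / ref_mean
  attr(df, "reference_mean") <- ref_mean
  df
}

#' Percent change of a mutant mean against a reference mean
#'
#' `100 * (mutant - reference) / reference`, reported raw and rounded to the
#' nearest integer (half away from zero, the convention behind reported
#' whole-percent increases).
#'
#' @param mean_mutant,mean_reference Group means; the reference must be > 0.
#' @return List with `raw` and `rounded`.
#' @examples
#' percent_change(38.38, 26.59)$rounded # 44
#' @export
percent_change <- function(mean_mutant, mean_reference) {
  if (!is.finite(mean_reference) || mean_reference <= 0)
    ms_stop("reference mean must be finite and > 0")
  raw <- 100 * (mean_mutant - mean_reference) / mean_reference
  list(raw = raw, rounded = sign(raw) * floor(abs(raw) + 0.5))
}

#' Fraction of homolog pairs present as univalents
#'
#' Converts a mean count of univalent chromosomes per cell into the fraction
#' of pairs lacking a crossover: `mean / n_chromosomes` (univalent
#' chromosomes over total chromosomes equals univalent pairs over total
#' pairs).
#'
#' @param mean_univalent_chromosomes Mean univalent chromosomes per cell.
#' @param n_chromosomes Total chromosome number (2 * n_pairs; default 38).
#' @return Fraction in \[0, 1\].
#' @examples
#' univalent_fraction(26.90, 38) # 0.7079
#' @export
univalent_fraction <- function(mean_univalent_chromosomes, n_chromosomes = 38) {
  if (!is.finite(mean_univalent_chromosomes) ||
      mean_univalent_chromosomes < 0 ||
      mean_univalent_chromosomes > n_chromosomes)
    ms_stop("mean univalent chromosomes must lie in [0, %d]", n_chromosomes)
  mean_univalent_chromosomes / n_chromosomes
}
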