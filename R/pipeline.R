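# Pipeline orchestration: simulate -> score -> test -> report, driven by a
# single config object so runs are reproducible end to end.

#' Build a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. Recognized fields: `n_cells`
#' (single count or named per-genotype), `genotypes` (subset of preset
#' labels), `stage`, `gof_policy` (`"excel"`, `"folded"` or `"both"`),
#' `reference` (reference genotype for homogeneity tests),
#' `count_univalents_as_zero` (score univalent pairs as zero-focus entries in
#' distributions; default `FALSE`), `seed`,
#' `output_dir`, `genome` (n_pairs/lengths/centromere_fractions), and
#' `presets` (per-genotype parameter overrides as in [genotype_presets()]).
#'
#' @param config YAML path or named list (default: all defaults).
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  genome <- if (is.null(cfg$genome)) genome_spec() else do.call(genome_spec, cfg$genome)
  presets <- genotype_presets(cfg$presets, genome = genome)
  genotypes <- cfg$genotypes %||% names(presets)
  unknown <- setdiff(genotypes, names(presets))
  if (length(unknown) > 0)
    ms_stop("unknown genotype(s) in config: %s", paste(unknown, collapse = ", "))
  n_cells <- cfg$n_cells %||% 50L
  if (is.null(names(n_cells))) {
    n_cells <- setNames(rep(as.integer(n_cells), length(genotypes)), genotypes)
  } else {
    missing_n <- setdiff(genotypes, names(n_cells))
    if (length(missing_n) > 0)
      ms_stop("n_cells missing for genotype(s): %s", paste(missing_n, collapse = ", "))
    n_cells <- setNames(as.integer(n_cells[genotypes]), genotypes)
  }
  gof_policy <- match.arg(cfg$gof_policy %||% "both", c("both", "excel", "folded"))
  reference <- cfg$reference %||% "AACC_wt"
  structure(
    list(genome = genome, presets = presets, genotypes = genotypes,
         n_cells = n_cells, stage = cfg$stage %||% "diakinesis",
         gof_policy = gof_policy, reference = reference,
         count_univalents_as_zero = isTRUE(cfg$count_univalents_as_zero),
         seed = as.integer(cfg$seed %||% 1L),
         output_dir = cfg$output_dir %||% "meioscope_out"),
    class = "run_config"
  )
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[meioscope] ", fmt), ...))
}

#' Simulate a dataset from a run configuration
#'
#' Writes `bivalents.csv` (canonical schema) and `manifest.json` (parameters,
#' seeds, row counts, package version) into the configured output directory.
#' Deterministic per seed: per-genotype seeds are derived as `seed + index`.
#'
#' @param config A [run_config()].
#' @param force Overwrite existing outputs (default `FALSE`: refuse).
#' @param verbose Log one line per stage.
#' @return Invisibly, the simulated per-bivalent data frame.
#' @export
pipeline_simulate <- function(config, force = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(config$output_dir, "bivalents.csv")
  if (file.exists(data_path) && !force)
    ms_stop("output %s exists; pass force = TRUE to overwrite", data_path)

  parts <- list()
  for (i in seq_along(config$genotypes)) {
    g <- config$genotypes[i]
    parts[[g]] <- simulate_experiment(
      config$presets[[g]], config$n_cells[[g]], genome = config$genome,
      stage = config$stage, seed = config$seed + i)
    log_stage(verbose, "simulate %-8s n_cells=%d rows=%d seed=%d",
              g, config$n_cells[[g]], nrow(parts[[g]]), config$seed + i)
  }
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  write_bivalents(df, data_path)

  manifest <- list(
    package = "meioscope",
    version = as.character(packageVersion("meioscope")),
    seed = config$seed,
    stage = config$stage,
    genome = unclass(config$genome),
    genotypes = lapply(seq_along(config$genotypes), function(i) {
      g <- config$genotypes[i]
      c(list(label = g, n_cells = unname(config$n_cells[[g]]),
             seed = config$seed + i),
        unclass(config$presets[[g]]$params))
    }),
    n_rows = nrow(df)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(verbose, "wrote %s (%d rows) + manifest.json", data_path, nrow(df))
  invisible(df)
}

#' Analyze a per-bivalent dataset
#'
#' Runs the full scoring and testing battery and writes a report bundle:
#' per-genotype summaries (`summary_per_genotype.csv`: chiasma, focus, total
#' and class II crossover means with SD and n), the foci-per-bivalent
#' distribution long table (`distributions.csv`), Poisson goodness-of-fit
#' results under the configured policies (`gof.json`/`gof.csv`), homogeneity
#' tests of every genotype against the reference, Games-Howell comparisons of
#' per-cell focus counts and minimum chiasmata, spacing summaries, and a
#' human-readable `report.txt`. Every number in the report is taken from one
#' of these serialized results; the report does no arithmetic of its own
#' beyond formatting.
#'
#' When both policies are run, a genotype's Poisson verdict is emitted only
#' if they agree (at alpha = 0.05); otherwise it is flagged
#' `"policy-sensitive"`.
#'
#' @param data Per-bivalent data frame or path to a `bivalents.csv`.
#' @param config A [run_config()].
#' @param verbose Log one line per stage.
#' @return Invisibly, a list with all result objects (`summary`,
#'   `distributions`, `gof`, `verdicts`, `homogeneity`, `games_howell`,
#'   `spacings`).
#' @export
pipeline_analyze <- function(data, config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  df <- if (is.character(data)) read_bivalents(data, config$genome) else data
  genotypes <- intersect(config$genotypes, unique(df$genotype))
  if (length(genotypes) == 0) ms_stop("no configured genotype present in data")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  policies <- switch(config$gof_policy,
                     both = c("excel_k_minus_1", "folded_k_minus_2"),
                     excel = "excel_k_minus_1",
                     folded = "folded_k_minus_2")

  # per-genotype summaries ------------------------------------------------
  summarize <- function(x) c(mean = mean(x), sd = sd(x), n = length(x))
  rows <- list()
  spacing_rows <- list()
  dists <- list()
  gof_rows <- list()
  verdicts <- list()
  for (g in genotypes) {
    sub <- df[df$genotype == g, , drop = FALSE]
    chi <- score_min_chiasmata(sub)
    foci_cell <- tapply(sub$n_class1_foci,
                        interaction(sub$genotype, sub$cell_id, drop = TRUE),
                        sum)
    s_chi <- summarize(chi$min_chiasmata)
    s_foci <- summarize(as.numeric(foci_cell))
    acct <- if (!anyNA(sub$n_chiasmata) && !anyNA(sub$n_labeled_chiasmata) &&
                all(sub$stage == "diakinesis")) account_crossovers(sub) else NULL
    rows[[g]] <- data.frame(
      genotype = g,
      chiasmata_mean = s_chi["mean"], chiasmata_sd = s_chi["sd"],
      foci_mean = s_foci["mean"], foci_sd = s_foci["sd"],
      total_co_mean = if (is.null(acct)) NA_real_ else mean(acct$n_total),
      class2_mean = if (is.null(acct)) NA_real_ else mean(acct$n_class2),
      n_cells = unname(s_chi["n"]),
      stringsAsFactors = FALSE
    )
    sp <- relative_spacings(sub, stage = config$stage)
    spacing_rows[[g]] <- data.frame(
      genotype = g,
      spacing_mean = if (length(sp) > 0) mean(sp) else NA_real_,
      spacing_sd = if (length(sp) > 1) sd(sp) else NA_real_,
      spacing_cv = if (length(sp) > 1) spacing_cv(sp) else NA_real_,
      n_spacings = length(sp),
      stringsAsFactors = FALSE
    )
    dists[[g]] <- foci_distribution(
      sub, stage = config$stage, genotype = g,
      count_univalents_as_zero = config$count_univalents_as_zero)
    p_vals <- c()
    for (pol in policies) {
      fit <- tryCatch(poisson_gof(dists[[g]], pol), meioscope_error = identity)
      if (inherits(fit, "condition")) {
        # e.g. a 2-category table leaves the folded policy no df to test
        p_vals[pol] <- NA_real_
        next
      }
      gof_rows[[paste(g, pol)]] <- cbind(genotype = g, as.data.frame(fit))
      p_vals[pol] <- fit$p_value
    }
    verdict <- if (anyNA(p_vals)) {
      "not testable"
    } else if (length(p_vals) == 1) {
      if (p_vals < 0.05) "reject Poisson" else "consistent with Poisson"
    } else {
      agree <- (p_vals[1] < 0.05) == (p_vals[2] < 0.05)
      if (!agree) "policy-sensitive"
      else if (p_vals[1] < 0.05) "reject Poisson" else "consistent with Poisson"
    }
    verdicts[[g]] <- list(genotype = g, p_values = as.list(p_vals),
                          verdict = verdict)
    log_stage(verbose, "analyze %-8s cells=%d bivalents=%d verdict='%s'",
              g, nrow(chi), dists[[g]]$n_bivalents, verdict)
  }
  summary_df <- do.call(rbind, rows); rownames(summary_df) <- NULL
  spacing_df <- do.call(rbind, spacing_rows); rownames(spacing_df) <- NULL
  dist_long <- do.call(rbind, lapply(dists, as.data.frame))
  rownames(dist_long) <- NULL

  # homogeneity vs reference ----------------------------------------------
  homog <- NULL
  if (config$reference %in% genotypes && length(genotypes) > 1) {
    ref_dist <- dists[[config$reference]]
    others <- setdiff(genotypes, config$reference)
    homog <- do.call(rbind, lapply(others, function(g) {
      h <- chisq_homogeneity(dists[[g]], ref_dist)
      data.frame(genotype = g, reference = config$reference,
                 chi2 = h$chi2, df = h$df, p_value = h$p_value,
                 stringsAsFactors = FALSE)
    }))
  } else if (!(config$reference %in% genotypes) && length(genotypes) > 1) {
    ms_stop("reference genotype '%s' absent from data", config$reference)
  }

  # Games-Howell across genotypes ------------------------------------------
  gh <- NULL
  if (length(genotypes) > 1) {
    chi_all <- score_min_chiasmata(df[df$genotype %in% genotypes, ])
    foci_cell_all <- stats::aggregate(
      n_class1_foci ~ genotype + cell_id,
      data = df[df$genotype %in% genotypes, ], FUN = sum)
    gh <- list(
      min_chiasmata = games_howell(chi_all$min_chiasmata, chi_all$genotype),
      foci_per_cell = games_howell(foci_cell_all$n_class1_foci,
                                   foci_cell_all$genotype)
    )
  }

  # write bundle ------------------------------------------------------------
  out <- config$output_dir
  write.csv(summary_df, file.path(out, "summary_per_genotype.csv"),
            row.names = FALSE)
  write.csv(dist_long, file.path(out, "distributions.csv"), row.names = FALSE)
  write.csv(spacing_df, file.path(out, "spacings.csv"), row.names = FALSE)
  gof_df <- do.call(rbind, gof_rows); rownames(gof_df) <- NULL
  write.csv(gof_df, file.path(out, "gof.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, policies = policies, verdicts = verdicts),
    file.path(out, "gof.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(homog))
    write.csv(homog, file.path(out, "homogeneity.csv"), row.names = FALSE)
  if (!is.null(gh)) {
    write.csv(as.data.frame(gh$min_chiasmata),
              file.path(out, "games_howell_chiasmata.csv"), row.names = FALSE)
    write.csv(as.data.frame(gh$foci_per_cell),
              file.path(out, "games_howell_foci.csv"), row.names = FALSE)
  }

  results <- list(summary = summary_df, distributions = dist_long,
                  spacings = spacing_df, gof = gof_df, verdicts = verdicts,
                  homogeneity = homog, games_howell = gh)
  writeLines(format_report(results, config), file.path(out, "report.txt"))
  log_stage(verbose, "report bundle written to %s", out)
  invisible(results)
}

fmt_p <- function(p) ifelse(p < 0.001, sprintf("%.2E", p), sprintf("%.3f", p))

# Text report: formatting only, every number comes from a serialized result.
format_report <- function(res, config) {
  lines <- c("meioscope analysis report",
             strrep("=", 60),
             sprintf("seed: %d   stage: %s   gof policy: %s",
                     config$seed, config$stage, config$gof_policy),
             "",
             "Per-genotype summaries (mean ± SD, n cells)")
  for (i in seq_len(nrow(res$summary))) {
    r <- res$summary[i, ]
    lines <- c(lines, sprintf(
      "  %-8s chiasmata %.2f ± %.2f | foci/cell %.2f ± %.2f | total CO %s | class II %s | n=%d",
      r$genotype, r$chiasmata_mean, r$chiasmata_sd, r$foci_mean, r$foci_sd,
      ifelse(is.na(r$total_co_mean), "-", sprintf("%.2f", r$total_co_mean)),
      ifelse(is.na(r$class2_mean), "-", sprintf("%.2f", r$class2_mean)),
      r$n_cells))
  }
  lines <- c(lines, "", "Poisson goodness-of-fit verdicts")
  for (v in res$verdicts) {
    ps <- paste(sprintf("%s p=%s", names(v$p_values),
                        fmt_p(unlist(v$p_values))), collapse = "; ")
    lines <- c(lines, sprintf("  %-8s %s (%s)", v$genotype, v$verdict, ps))
  }
  if (!is.null(res$homogeneity)) {
    lines <- c(lines, "", sprintf("Homogeneity vs %s", res$homogeneity$reference[1]))
    for (i in seq_len(nrow(res$homogeneity))) {
      h <- res$homogeneity[i, ]
      lines <- c(lines, sprintf("  %-8s chi2=%.2f df=%d p=%s",
                                h$genotype, h$chi2, h$df, fmt_p(h$p_value)))
    }
  }
  if (!is.null(res$spacings)) {
    lines <- c(lines, "", "Inter-focus spacings (relative units)")
    for (i in seq_len(nrow(res$spacings))) {
      s <- res$spacings[i, ]
      if (is.na(s$spacing_mean)) next
      lines <- c(lines, sprintf("  %-8s %.2f ± %.2f (CV %.2f, n=%d)",
                                s$genotype, s$spacing_mean, s$spacing_sd,
                                s$spacing_cv, s$n_spacings))
    }
  }
  lines
}
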