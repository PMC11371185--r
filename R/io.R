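# Canonical CSV exchange schema: one row per bivalent.
bivalent_columns <- function() {
  c("genotype", "cell_id", "pair_index", "stage", "config",
    "n_class1_foci", "focus_positions", "n_chiasmata",
    "n_labeled_chiasmata", "length_um")
}

parse_positions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  v <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
  if (anyNA(v)) return(NULL) # signal malformed to caller
  sort(v)
}

format_positions <- function(v) {
  if (length(v) == 0) return("")
  paste(formatC(v, digits = 6, format = "f"), collapse = ";")
}

#' Read a per-bivalent cytology table
#'
#' Reads the canonical `bivalents.csv` schema (columns `genotype`, `cell_id`,
#' `pair_index`, `stage`, `config`, `n_class1_foci`, `focus_positions`,
#' `n_chiasmata`, `n_labeled_chiasmata`, `length_um`; focus positions
#' `;`-separated in one column), validates every record invariant, and returns
#' one row per bivalent with `focus_positions` as a sorted numeric
#' list-column. Positions are fractions of bivalent length in \[0, 1\]; when
#' `length_um` is given and positions exceed 1 they are treated as raw
#' micrometre coordinates and divided by `length_um` on ingest.
#'
#' A "cell" is the set of rows sharing `genotype` and `cell_id`; a complete
#' cell carries one row per homolog pair (`pair_index` 0 .. n_pairs-1). Empty
#' strings encode missing optional fields.
#'
#' @param path CSV file path.
#' @param genome A [genome_spec()]; defines the expected number of pairs.
#' @param on_incomplete What to do with cells missing pairs: `"error"`
#'   (default), `"drop"` the whole cell, or `"pad"` with `config = "unknown"`
#'   zero-focus rows.
#' @return A `data.frame`, one row per bivalent, validated.
#' @export
read_bivalents <- function(path, genome = genome_spec(),
                           on_incomplete = c("error", "drop", "pad")) {
  on_incomplete <- match.arg(on_incomplete)
  if (!file.exists(path)) ms_stop("bivalent table not found: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(bivalent_columns(), names(raw))
  if (length(missing_cols) > 0)
    ms_stop("bivalent table is missing required columns: %s",
            paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  to_int <- function(s) ifelse(nzchar(s), suppressWarnings(as.integer(s)), NA_integer_)
  to_num <- function(s) ifelse(nzchar(s), suppressWarnings(as.numeric(s)), NA_real_)

  df <- data.frame(
    genotype = raw$genotype,
    cell_id = raw$cell_id,
    pair_index = to_int(raw$pair_index),
    stage = raw$stage,
    config = raw$config,
    n_class1_foci = to_int(raw$n_class1_foci),
    n_chiasmata = to_int(raw$n_chiasmata),
    n_labeled_chiasmata = to_int(raw$n_labeled_chiasmata),
    length_um = to_num(raw$length_um),
    stringsAsFactors = FALSE
  )
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parse_positions(raw$focus_positions[i])
    if (is.null(p))
      ms_stop("row %d: focus_positions '%s' is not a ';'-separated numeric list",
              i, raw$focus_positions[i])
    # raw micrometre coordinates -> fractions of bivalent length
    if (length(p) > 0 && max(p) > 1 + 1e-9) {
      if (is.na(df$length_um[i]))
        ms_stop("row %d: focus_positions exceed 1 but length_um is missing", i)
      p <- p / df$length_um[i]
    }
    pos[[i]] <- p
  }
  df$focus_positions <- pos
  df <- validate_bivalents(df, genome, check_cells = FALSE)
  complete_cells(df, genome, on_incomplete)
}

#' Validate a per-bivalent table
#'
#' Checks every record-level invariant of the bivalent data model and
#' (optionally) cell completeness. Called by [read_bivalents()]; exported so
#' programmatically built tables can be validated too.
#'
#' @param df Data frame in the canonical layout (list-column
#'   `focus_positions`).
#' @param genome A [genome_spec()].
#' @param check_cells If `TRUE`, also require each cell to carry exactly
#'   `n_pairs` rows with pair indices 0 .. n_pairs-1 and a single stage.
#' @return `df`, invisibly unchanged, if valid; otherwise an error naming the
#'   first offending row and the violated invariant.
#' @export
validate_bivalents <- function(df, genome = genome_spec(), check_cells = TRUE) {
  req <- function(cond, i, what) {
    bad <- which(!cond)
    if (length(bad) > 0) ms_stop("row %d: %s", i[bad[1]], what)
  }
  idx <- seq_len(nrow(df))
  req(!is.na(df$pair_index) & df$pair_index >= 0 &
        df$pair_index < genome$n_pairs, idx,
      sprintf("pair_index must lie in [0, %d)", genome$n_pairs))
  bad_stage <- !(df$stage %in% stage_levels())
  if (any(bad_stage))
    ms_stop("row %d: unknown stage '%s'; allowed: %s",
            which(bad_stage)[1], df$stage[which(bad_stage)[1]],
            paste(stage_levels(), collapse = ", "))
  bad_config <- !(df$config %in% config_levels())
  if (any(bad_config))
    ms_stop("row %d: unknown config '%s'; allowed: %s",
            which(bad_config)[1], df$config[which(bad_config)[1]],
            paste(config_levels(), collapse = ", "))
  req(is.na(df$n_class1_foci) | df$n_class1_foci >= 0, idx,
      "n_class1_foci must be a nonnegative count")
  req(is.na(df$length_um) | df$length_um > 0, idx,
      "length_um must be strictly positive when present")

  for (i in idx) {
    p <- df$focus_positions[[i]]
    if (length(p) > 0) {
      if (any(p < -1e-9) || any(p > 1 + 1e-9))
        ms_stop("row %d: focus positions must be fractions in [0, 1]", i)
      if (is.unsorted(p))
        ms_stop("row %d: focus positions must be sorted ascending", i)
      if (!is.na(df$n_class1_foci[i]) && length(p) != df$n_class1_foci[i])
        ms_stop("row %d: %d focus positions but n_class1_foci = %d",
                i, length(p), df$n_class1_foci[i])
    }
    nc <- df$n_chiasmata[i]
    nl <- df$n_labeled_chiasmata[i]
    if (!is.na(nc) && !is.na(nl) && nl > nc)
      ms_stop("row %d: n_labeled_chiasmata (%d) exceeds n_chiasmata (%d)",
              i, nl, nc)
    if (!is.na(nc)) {
      cfg <- df$config[i]
      if (cfg == "ring" && nc < 2)
        ms_stop("row %d: ring bivalent requires n_chiasmata >= 2, got %d", i, nc)
      if (cfg == "rod" && nc < 1)
        ms_stop("row %d: rod bivalent requires n_chiasmata >= 1, got %d", i, nc)
      if (cfg == "univalent_pair" && nc != 0)
        ms_stop("row %d: univalent pair requires n_chiasmata = 0, got %d", i, nc)
    }
  }

  if (check_cells) {
    key <- paste(df$genotype, df$cell_id, sep = "\r")
    for (k in unique(key)) {
      rows <- which(key == k)
      if (length(unique(df$stage[rows])) != 1L)
        ms_stop("cell '%s' mixes stages", df$cell_id[rows[1]])
      if (!setequal(df$pair_index[rows], 0:(genome$n_pairs - 1)))
        ms_stop("cell '%s' does not carry exactly one row per pair 0..%d",
                df$cell_id[rows[1]], genome$n_pairs - 1)
    }
  }
  invisible(df)
}

complete_cells <- function(df, genome, on_incomplete) {
  key <- paste(df$genotype, df$cell_id, sep = "\r")
  keep <- rep(TRUE, nrow(df))
  pads <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    have <- df$pair_index[rows]
    if (anyDuplicated(have))
      ms_stop("cell '%s' has duplicated pair_index entries", df$cell_id[rows[1]])
    missing <- setdiff(0:(genome$n_pairs - 1), have)
    if (length(missing) == 0) next
    if (on_incomplete == "error")
      ms_stop("cell '%s' is missing %d pair(s); use on_incomplete = 'drop' or 'pad'",
              df$cell_id[rows[1]], length(missing))
    if (on_incomplete == "drop") {
      keep[rows] <- FALSE
    } else { # pad
      r <- df[rows[1], , drop = FALSE]
      pad <- r[rep(1, length(missing)), , drop = FALSE]
      pad$pair_index <- missing
      pad$config <- "unknown"
      pad$n_class1_foci <- 0L
      pad$focus_positions <- replicate(length(missing), numeric(0), simplify = FALSE)
      pad$n_chiasmata <- NA_integer_
      pad$n_labeled_chiasmata <- NA_integer_
      pad$length_um <- NA_real_
      pads[[length(pads) + 1]] <- pad
    }
  }
  df <- df[keep, , drop = FALSE]
  if (length(pads) > 0) df <- do.call(rbind, c(list(df), pads))
  df <- df[order(df$genotype, df$cell_id, df$pair_index), , drop = FALSE]
  rownames(df) <- NULL
  validate_bivalents(df, genome, check_cells = TRUE)
  df
}

#' Write a per-bivalent table to the canonical CSV schema
#'
#' Inverse of [read_bivalents()]: focus positions are serialized as a
#' `;`-separated list at 6 decimal places; missing optional fields become
#' empty strings.
#'
#' @param df Validated per-bivalent data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bivalents <- function(df, path) {
  if (nrow(df) == 0) ms_stop("refusing to write an empty bivalent table")
  out <- data.frame(
    genotype = df$genotype,
    cell_id = df$cell_id,
    pair_index = df$pair_index,
    stage = df$stage,
    config = df$config,
    n_class1_foci = ifelse(is.na(df$n_class1_foci), "", df$n_class1_foci),
    focus_positions = vapply(df$focus_positions, format_positions, character(1)),
    n_chiasmata = ifelse(is.na(df$n_chiasmata), "", df$n_chiasmata),
    n_labeled_chiasmata = ifelse(is.na(df$n_labeled_chiasmata), "",
                                 df$n_labeled_chiasmata),
    length_um = ifelse(is.na(df$length_um), "", format(df$length_um)),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an immunofluorescence intensity table
#'
#' Schema: `genotype, cell_id, stage, raw_intensity, background`. Both
#' measurements must be nonnegative.
#'
#' @param path CSV file path.
#' @return Data frame with numeric `raw_intensity` and `background`.
#' @export
read_intensity <- function(path) {
  if (!file.exists(path)) ms_stop("intensity table not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "cell_id", "stage", "raw_intensity", "background")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    ms_stop("intensity table is missing columns: %s",
            paste(missing_cols, collapse = ", "))
  bad_stage <- !(df$stage %in% stage_levels())
  if (any(bad_stage))
    ms_stop("row %d: unknown stage '%s'; allowed: %s",
            which(bad_stage)[1], df$stage[which(bad_stage)[1]],
            paste(stage_levels(), collapse = ", "))
  if (any(!is.finite(df$raw_intensity)) || any(df$raw_intensity < 0))
    ms_stop("raw_intensity must be finite and nonnegative")
  if (any(!is.finite(df$background)) || any(df$background < 0))
    ms_stop("background must be finite and nonnegative")
  df
}

#' Write a result object as twin JSON and CSV files
#'
#' Serializes any flat result (a data frame, or a result object with an
#' `as.data.frame` method such as [poisson_gof()] output) to `<path>.json`
#' (nested, full precision) and `<path>.csv` (flat), carrying identical
#' numbers.
#'
#' @param x Result object; must be non-empty.
#' @param path Output path without extension.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_results <- function(x, path) {
  df <- as.data.frame(x)
  if (nrow(df) == 0) ms_stop("refusing to write an empty result set")
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  payload <- if (is.data.frame(x)) x else unclass(x)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(df, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
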