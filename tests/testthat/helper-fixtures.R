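# Shared fixtures: small bivalent tables built in code.

# A minimal valid per-bivalent data frame for `n_cells` cells of `n_pairs`
# pairs; every pair a rod with 1 labelled chiasma and one focus at 0.5.
make_rod_cells <- function(n_cells = 2, n_pairs = 19, genotype = "AACC_wt",
                           stage = "diakinesis") {
  n <- n_cells * n_pairs
  df <- data.frame(
    genotype = rep(genotype, n),
    cell_id = rep(sprintf("c%02d", seq_len(n_cells)), each = n_pairs),
    pair_index = rep(0:(n_pairs - 1), times = n_cells),
    stage = stage,
    config = "rod",
    n_class1_foci = 1L,
    n_chiasmata = 1L,
    n_labeled_chiasmata = 1L,
    length_um = NA_real_,
    stringsAsFactors = FALSE
  )
  df$focus_positions <- replicate(n, 0.5, simplify = FALSE)
  df
}

# Write a bivalent CSV from raw character rows (to exercise the reader's
# parsing and validation paths directly).
write_raw_bivalent_csv <- function(rows, path) {
  header <- paste(meioscope:::bivalent_columns(), collapse = ",")
  writeLines(c(header, rows), path)
  path
}

# One raw CSV row with overridable fields.
raw_row <- function(genotype = "wt", cell_id = "c1", pair_index = 0,
                    stage = "diakinesis", config = "rod",
                    n_class1_foci = "1", focus_positions = "0.5",
                    n_chiasmata = "1", n_labeled_chiasmata = "1",
                    length_um = "") {
  paste(genotype, cell_id, pair_index, stage, config, n_class1_foci,
        focus_positions, n_chiasmata, n_labeled_chiasmata, length_um,
        sep = ",")
}

# A full cell of `n_pairs` raw rows (pair 0 configurable via ...).
raw_cell_rows <- function(cell_id, n_pairs = 19, ...) {
  first <- raw_row(cell_id = cell_id, pair_index = 0, ...)
  rest <- vapply(seq_len(n_pairs - 1), function(i) {
    raw_row(cell_id = cell_id, pair_index = i)
  }, character(1))
  c(first, rest)
}

small_genome <- function(n_pairs = 3) {
  genome_spec(n_pairs, lengths = rep(1, n_pairs),
              centromere_fractions = rep(0.45, n_pairs))
}
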