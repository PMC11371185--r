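#' Karyotype specification for a meiocyte
#'
#' Describes the chromosome complement the scoring and simulation code assumes:
#' the number of homolog pairs, their relative lengths (arbitrary units; the
#' default treats all pairs as unit length) and the centromere position of each
#' pair as a fraction of its length. *Brassica napus* meiocytes display 19
#' bivalents at diakinesis, which is the default.
#'
#' @param n_pairs Number of homologous chromosome pairs (default 19).
#' @param lengths Numeric vector of strictly positive relative lengths, one per
#'   pair. Default: all pairs of length 1.
#' @param centromere_fractions Numeric vector of centromere positions, each
#'   strictly inside (0, 1), one per pair. Default 0.45 for every pair.
#'
#' @return An object of class `genome_spec`: a list with elements `n_pairs`,
#'   `lengths`, `centromere_fractions`.
#' @examples
#' g <- genome_spec()
#' g$n_pairs
#' @export
genome_spec <- function(n_pairs = 19L,
                        lengths = rep(1, n_pairs),
                        centromere_fractions = rep(0.45, n_pairs)) {
  n_pairs <- as.integer(n_pairs)
  if (length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1L)
    ms_stop("n_pairs must be a single integer >= 1")
  if (length(lengths) != n_pairs)
    ms_stop("lengths must have exactly n_pairs (%d) entries, got %d",
            n_pairs, length(lengths))
  if (length(centromere_fractions) != n_pairs)
    ms_stop("centromere_fractions must have exactly n_pairs (%d) entries, got %d",
            n_pairs, length(centromere_fractions))
  if (!all(is.finite(lengths)) || any(lengths <= 0))
    ms_stop("all relative lengths must be finite and strictly positive")
  if (!all(is.finite(centromere_fractions)) ||
      any(centromere_fractions <= 0) || any(centromere_fractions >= 1))
    ms_stop("centromere fractions must lie strictly inside (0, 1)")
  structure(
    list(n_pairs = n_pairs,
         lengths = as.numeric(lengths),
         centromere_fractions = as.numeric(centromere_fractions)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d homolog pairs\n", x$n_pairs))
  cat(sprintf("  relative lengths: %s\n",
              paste(format(unique(x$lengths)), collapse = ", ")))
  cat(sprintf("  centromere fractions: %s\n",
              paste(format(unique(x$centromere_fractions)), collapse = ", ")))
  invisible(x)
}

#' Read a genome specification from YAML
#'
#' The YAML file may define `n_pairs`, `lengths` and `centromere_fractions`;
#' omitted fields fall back to the [genome_spec()] defaults. Scalar `lengths`
#' or `centromere_fractions` are recycled across pairs.
#'
#' @param path Path to a YAML file.
#' @return A `genome_spec` object.
#' @export
read_genome_yaml <- function(path) {
  if (!file.exists(path)) ms_stop("genome YAML not found: %s", path)
  y <- yaml::read_yaml(path)
  n <- as.integer(y$n_pairs %||% 19L)
  lens <- y$lengths %||% 1
  cents <- y$centromere_fractions %||% 0.45
  if (length(lens) == 1L) lens <- rep(lens, n)
  if (length(cents) == 1L) cents <- rep(cents, n)
  genome_spec(n, lens, cents)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
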