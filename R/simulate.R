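# Synthetic meiocyte simulator.
#
# Class I crossovers are placed by a stationary gamma-renewal process whose
# shape nu sets interference strength (nu = 1 is the Poisson, no-interference
# case); class II crossovers are an independent homogeneous Poisson overlay.
# An obligate-crossover mechanism and a focus-detection layer sit on top, and
# the observation layer emits the same fields a cytologist scores from
# spreads: configuration, labelled focus counts and positions, chiasmata.

#' Generative parameters for one genotype
#'
#' @param nu Interference shape of the gamma-renewal process for class I
#'   crossovers; `nu = 1` means no interference, larger values spread
#'   crossovers more evenly. Must be > 0.
#' @param class1_rate Expected class I crossovers per unit relative length.
#' @param class2_rate Expected class II crossovers per unit relative length.
#' @param obligate_mechanism Crossover-assurance rule applied to the union of
#'   both classes on each pair: `"none"`, `"resample_until_nonempty"` (redraw
#'   the pair until at least one crossover exists), or `"forced_extra"` (add
#'   one uniformly placed class I crossover to an empty pair).
#' @param detection_prob Probability that a class I crossover is observed as a
#'   focus; applies to focus observation only, never to chiasma existence or
#'   configuration. In (0, 1].
#' @param asy3_dosage Annotation only: functional-allele dosage in \[0, 1\].
#' @param seed Optional RNG seed recorded with the parameters.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(nu = 1,
                              class1_rate = 1,
                              class2_rate = 0,
                              obligate_mechanism = c("none",
                                                     "resample_until_nonempty",
                                                     "forced_extra"),
                              detection_prob = 1,
                              asy3_dosage = 1,
                              seed = NULL) {
  obligate_mechanism <- match.arg(obligate_mechanism)
  if (!is.finite(nu) || nu <= 0) ms_stop("nu must be finite and > 0")
  if (!is.finite(class1_rate) || class1_rate < 0)
    ms_stop("class1_rate must be finite and >= 0")
  if (!is.finite(class2_rate) || class2_rate < 0)
    ms_stop("class2_rate must be finite and >= 0")
  if (!is.finite(detection_prob) || detection_prob <= 0 || detection_prob > 1)
    ms_stop("detection_prob must lie in (0, 1]")
  if (!is.finite(asy3_dosage) || asy3_dosage < 0 || asy3_dosage > 1)
    ms_stop("asy3_dosage must lie in [0, 1]")
  structure(
    list(nu = nu, class1_rate = class1_rate, class2_rate = class2_rate,
         obligate_mechanism = obligate_mechanism,
         detection_prob = detection_prob, asy3_dosage = asy3_dosage,
         seed = seed),
    class = "simulation_params"
  )
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf(
    "<simulation_params> nu=%.3g class1_rate=%.4g class2_rate=%.4g\n  obligate=%s detection=%.3g dosage=%.2g seed=%s\n",
    x$nu, x$class1_rate, x$class2_rate, x$obligate_mechanism,
    x$detection_prob, x$asy3_dosage,
    if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

# Stationary-excess (equilibrium) CDF of a gamma(nu, beta) renewal process:
# F_e(x) = (1/mu) * Int_0^x S(t) dt = x*S(x)/mu + F_{nu+1,beta}(x),
# with mu = nu/beta the mean interval. Gives the void probability
# P(no event in a window of length L) = 1 - F_e(L) in closed form.
equilibrium_cdf <- function(x, rate, nu) {
  beta <- nu * rate
  s <- pgamma(x, shape = nu, rate = beta, lower.tail = FALSE)
  x * s * rate + pgamma(x, shape = nu + 1, rate = beta)
}

#' Void probability of the stationary class I crossover process
#'
#' Closed-form probability that a stationary gamma-renewal process with the
#' given rate and shape places no event in a window of length `length`.
#' Used for analytic preset calibration and as an independent check of the
#' sampler's stationarity.
#'
#' @param rate Events per unit length (>= 0).
#' @param nu Gamma shape (> 0).
#' @param length Window length (> 0).
#' @return A probability.
#' @export
renewal_void_prob <- function(rate, nu, length = 1) {
  if (rate == 0) return(1)
  1 - equilibrium_cdf(length, rate, nu)
}

# Inverse-CDF draw from the equilibrium first-interval law.
sample_equilibrium_interval <- function(rate, nu) {
  u <- runif(1)
  mu <- 1 / rate
  upper <- mu * (nu + 10) / max(nu, 1) + 10 * mu
  while (equilibrium_cdf(upper, rate, nu) < u) upper <- upper * 2
  uniroot(function(x) equilibrium_cdf(x, rate, nu) - u,
          lower = 0, upper = upper, tol = 1e-12)$root
}

#' Sample a stationary gamma-renewal point process
#'
#' Draws event positions on `[0, length]` from a stationary renewal process
#' whose inter-event intervals are gamma with shape `nu` and mean `1/rate`.
#' For integer `nu` the thinning construction is used (a homogeneous Poisson
#' process at rate `nu * rate`, keeping every `nu`-th event from a uniformly
#' random phase), which is exact; otherwise events are laid down
#' sequentially, the first from the equilibrium (integrated-tail) interval
#' law so the process is stationary. Expected event count is
#' `rate * length`.
#'
#' @param length Interval length (> 0).
#' @param rate Events per unit length; `rate = 0` yields no events.
#' @param nu Gamma shape (> 0); `nu = 1` reduces to a Poisson process.
#' @return Sorted numeric vector of event positions in `[0, length]`.
#' @export
sample_gamma_renewal <- function(length, rate, nu) {
  if (!is.finite(length) || length <= 0) ms_stop("length must be finite and > 0")
  if (!is.finite(rate) || rate < 0) ms_stop("rate must be finite and >= 0")
  if (!is.finite(nu) || nu <= 0) ms_stop("nu must be finite and > 0")
  if (rate == 0) return(numeric(0))

  if (abs(nu - round(nu)) < 1e-9) {
    k <- as.integer(round(nu))
    n <- rpois(1, k * rate * length)
    if (n == 0) return(numeric(0))
    ev <- sort(runif(n, 0, length))
    if (k == 1L) return(ev)
    phase <- sample.int(k, 1L) # uniformly random phase offset
    keep <- seq_along(ev) %% k == phase %% k
    return(ev[keep])
  }

  first <- sample_equilibrium_interval(rate, nu)
  if (first > length) return(numeric(0))
  out <- first
  beta <- nu * rate
  repeat {
    nxt <- out[base::length(out)] + rgamma(1, shape = nu, rate = beta)
    if (nxt > length) break
    out <- c(out, nxt)
  }
  out
}

# Configuration from the arm-wise placement of ALL crossovers:
# >=1 on each side of the centromere -> ring; >=1 all on one side -> rod;
# none -> univalent pair. Positions exactly at the centromere count as
# left-arm (tie-break; measure-zero under the continuous model).
config_from_positions <- function(positions, centromere_abs) {
  if (length(positions) == 0) return("univalent_pair")
  left <- any(positions <= centromere_abs)
  right <- any(positions > centromere_abs)
  if (left && right) "ring" else "rod"
}

# Core single-pair draw; returns a plain list (no data.frame overhead) so
# simulate_experiment can run hundreds of thousands of pairs.
simulate_bivalent_core <- function(params, pair_length, centromere) {
  draw <- function() {
    c1 <- sample_gamma_renewal(pair_length, params$class1_rate, params$nu)
    n2 <- rpois(1, params$class2_rate * pair_length)
    c2 <- if (n2 > 0) sort(runif(n2, 0, pair_length)) else numeric(0)
    list(c1 = c1, c2 = c2)
  }
  d <- draw()
  if (params$obligate_mechanism == "resample_until_nonempty") {
    tries <- 1L
    while (length(d$c1) + length(d$c2) == 0) {
      if (tries >= 100000L)
        ms_stop("resample_until_nonempty failed after 1e5 draws; rates too low")
      d <- draw()
      tries <- tries + 1L
    }
  } else if (params$obligate_mechanism == "forced_extra" &&
             length(d$c1) + length(d$c2) == 0) {
    d$c1 <- runif(1, 0, pair_length) # the assured crossover is class I
  }

  n1 <- length(d$c1)
  n2 <- length(d$c2)
  detected <- if (n1 > 0 && params$detection_prob < 1) {
    d$c1[runif(n1) < params$detection_prob]
  } else d$c1

  all_pos <- c(d$c1, d$c2)
  list(
    config = config_from_positions(all_pos, centromere * pair_length),
    n_class1_foci = length(detected),
    focus_positions = detected / pair_length,
    n_chiasmata = n1 + n2,
    n_labeled_chiasmata = length(detected),
    n_class1_true = n1,
    n_class2_true = n2
  )
}

#' Simulate one bivalent
#'
#' Draws class I crossovers from the stationary gamma-renewal process and
#' class II crossovers from an independent Poisson overlay, applies the
#' obligate-crossover mechanism to their union, then emits the observed
#' record: configuration scored arm-wise from all true crossovers relative to
#' the centromere, chiasma count = total crossovers, and focus
#' count/positions = detected class I crossovers only (each kept with
#' `detection_prob`). Positions are returned as fractions of pair length.
#'
#' @param params A [simulation_params()] object.
#' @param pair_length Relative length of the pair (> 0).
#' @param centromere Centromere position as a fraction of length, in (0, 1).
#' @return A list with fields `config`, `n_class1_foci`, `focus_positions`,
#'   `n_chiasmata`, `n_labeled_chiasmata`, plus ground truth `n_class1_true`
#'   and `n_class2_true`.
#' @export
simulate_bivalent <- function(params, pair_length = 1, centromere = 0.45) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.finite(pair_length) || pair_length <= 0)
    ms_stop("pair_length must be finite and > 0")
  if (!is.finite(centromere) || centromere <= 0 || centromere >= 1)
    ms_stop("centromere must lie strictly inside (0, 1)")
  simulate_bivalent_core(params, pair_length, centromere)
}

#' Simulate a cytology experiment for one genotype
#'
#' Generates `n_cells` meiocytes, each with one record per homolog pair of
#' `genome`, in the canonical per-bivalent layout of [read_bivalents()].
#' Reproducible: the same preset and seed give identical output.
#'
#' @param preset A genotype preset (element of [genotype_presets()]), or any
#'   list with fields `label` and `params`.
#' @param n_cells Number of meiocytes (>= 1).
#' @param genome A [genome_spec()].
#' @param stage Stage label stamped on every record.
#' @param seed RNG seed; defaults to the preset's `params$seed` (if `NULL`,
#'   the current RNG stream is used).
#' @param keep_truth If `TRUE`, append the simulator's ground-truth columns
#'   `n_class1_true` and `n_class2_true`.
#' @return A validated per-bivalent data frame.
#' @export
simulate_experiment <- function(preset, n_cells, genome = genome_spec(),
                                stage = "diakinesis",
                                seed = preset$params$seed,
                                keep_truth = FALSE) {
  stopifnot(inherits(preset$params, "simulation_params"))
  if (!is.numeric(n_cells) || n_cells < 1) ms_stop("n_cells must be >= 1")
  if (!(stage %in% stage_levels()))
    ms_stop("unknown stage '%s'; allowed: %s", stage,
            paste(stage_levels(), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  n_cells <- as.integer(n_cells)
  np <- genome$n_pairs
  n <- n_cells * np
  cfg <- character(n); nf <- integer(n); nch <- integer(n); nlab <- integer(n)
  nt1 <- integer(n); nt2 <- integer(n)
  pos <- vector("list", n)
  params <- preset$params
  i <- 0L
  for (cell in seq_len(n_cells)) {
    for (p in seq_len(np)) {
      i <- i + 1L
      b <- simulate_bivalent_core(params, genome$lengths[p],
                                  genome$centromere_fractions[p])
      cfg[i] <- b$config
      nf[i] <- b$n_class1_foci
      pos[[i]] <- b$focus_positions
      nch[i] <- b$n_chiasmata
      nlab[i] <- b$n_labeled_chiasmata
      nt1[i] <- b$n_class1_true
      nt2[i] <- b$n_class2_true
    }
  }
  df <- data.frame(
    genotype = rep(preset$label, n),
    cell_id = rep(sprintf("cell%04d", seq_len(n_cells)), each = np),
    pair_index = rep(0:(np - 1), times = n_cells),
    stage = rep(stage, n),
    config = cfg,
    n_class1_foci = nf,
    n_chiasmata = nch,
    n_labeled_chiasmata = nlab,
    length_um = NA_real_,
    stringsAsFactors = FALSE
  )
  df$focus_positions <- pos
  if (keep_truth) {
    df$n_class1_true <- nt1
    df$n_class2_true <- nt2
  }
  df
}

# Study conditions: printed diakinesis focus means, class II means per cell,
# and interference regime per genotype of the ASY3 dosage series. Presets are
# calibrated analytically against these at construction time.
preset_conditions <- function() {
  data.frame(
    label = c("AACC_wt", "aaCC", "AAcc", "aaCc", "Aacc", "aacc"),
    foci_mean = c(26.88, 29.76, 29.40, 37.91, 36.67, 5.48),
    class2_mean = c(6.55, 6.55, 6.55, 6.00, 6.50, 0.56),
    nu = c(8, 8, 8, 1, 1, 8),
    obligate = c("resample_until_nonempty", "resample_until_nonempty",
                 "resample_until_nonempty", "none", "none", "none"),
    asy3_dosage = c(1, 0.5, 0.5, 0.25, 0.25, 0),
    stringsAsFactors = FALSE
  )
}

# Solve class1_rate so that the post-obligate expected focus count per pair
# hits the target. Under resample-until-nonempty,
# E[N1 | union nonempty] = lambda1 * L / (1 - p0_union), with
# p0_union = void(lambda1, nu) * exp(-lambda2 * L); monotone in lambda1.
calibrate_class1_rate <- function(target_per_pair, class2_rate, nu, obligate,
                                  pair_length = 1) {
  if (obligate != "resample_until_nonempty") return(target_per_pair / pair_length)
  f <- function(l1) {
    p0 <- renewal_void_prob(l1, nu, pair_length) * exp(-class2_rate * pair_length)
    l1 * pair_length / (1 - p0) - target_per_pair
  }
  uniroot(f, lower = 1e-8, upper = target_per_pair / pair_length + 1e-6,
          tol = 1e-10)$root
}

#' Genotype presets for the ASY3 dosage series
#'
#' Returns the six default genotype presets (`AACC_wt`, `aaCC`, `AAcc`,
#' `aaCc`, `Aacc`, `aacc`). Class I rates are calibrated analytically so the
#' expected number of detected diakinesis foci per cell matches the study's
#' printed genotype means (26.88, 29.76, 29.40, 37.91, 36.67 and 5.48 over 19
#' pairs); interference is strong (`nu = 8`) for wild type and the
#' two-functional-allele genotypes, absent (`nu = 1`) for the
#' single-functional-allele genotypes whose focus counts are Poisson-like,
#' and the null mutant combines a strongly reduced class I rate with no
#' crossover assurance.
#'
#' @param config Optional YAML file path or named list of per-genotype
#'   overrides, e.g. `list(AACC_wt = list(nu = 4))`. Unknown genotype labels
#'   are an error.
#' @param genome A [genome_spec()]; calibration divides per-cell targets over
#'   its pairs.
#' @return Named list of presets, each `list(label =, params =
#'   simulation_params)`, of class `genotype_presets`.
#' @export
genotype_presets <- function(config = NULL, genome = genome_spec()) {
  cond <- preset_conditions()
  total_len <- sum(genome$lengths)
  presets <- list()
  for (i in seq_len(nrow(cond))) {
    class2_rate <- cond$class2_mean[i] / total_len
    target_per_pair <- cond$foci_mean[i] / genome$n_pairs
    # calibrate on the mean pair length (default genome: all pairs length 1)
    mean_len <- mean(genome$lengths)
    class1_rate <- calibrate_class1_rate(target_per_pair, class2_rate,
                                         cond$nu[i], cond$obligate[i],
                                         pair_length = mean_len)
    presets[[cond$label[i]]] <- list(
      label = cond$label[i],
      params = simulation_params(
        nu = cond$nu[i],
        class1_rate = class1_rate,
        class2_rate = class2_rate,
        obligate_mechanism = cond$obligate[i],
        detection_prob = 1,
        asy3_dosage = cond$asy3_dosage[i]
      )
    )
  }

  if (!is.null(config)) {
    overrides <- if (is.character(config)) yaml::read_yaml(config) else config
    unknown <- setdiff(names(overrides), names(presets))
    if (length(unknown) > 0)
      ms_stop("unknown genotype label(s) in override: %s; allowed: %s",
              paste(unknown, collapse = ", "),
              paste(names(presets), collapse = ", "))
    for (lab in names(overrides)) {
      p <- presets[[lab]]$params
      fields <- overrides[[lab]]
      bad <- setdiff(names(fields), c("nu", "class1_rate", "class2_rate",
                                      "obligate_mechanism", "detection_prob",
                                      "asy3_dosage", "seed"))
      if (length(bad) > 0)
        ms_stop("unknown parameter(s) for %s: %s", lab,
                paste(bad, collapse = ", "))
      merged <- utils::modifyList(unclass(p), fields)
      presets[[lab]]$params <- do.call(simulation_params, merged)
    }
  }
  structure(presets, class = "genotype_presets")
}

#' @export
print.genotype_presets <- function(x, ...) {
  cat(sprintf("<genotype_presets> %d genotypes\n", length(x)))
  for (p in x) {
    cat(sprintf(
      "  %-8s nu=%-4.3g class1_rate=%-7.4f class2_rate=%-7.4f obligate=%s\n",
      p$label, p$params$nu, p$params$class1_rate, p$params$class2_rate,
      p$params$obligate_mechanism))
  }
  invisible(x)
}
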