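---
title: "Crossover patterning from meiotic cytology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover patterning from meiotic cytology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscope)
```

## The scientific setting

During meiosis each pair of homologous chromosomes must receive at least one
crossover (CO) — the obligate CO — and additional COs are spaced out along the
bivalent by crossover interference. Cytologically, class I (interference-
sensitive) COs are marked by HEI10 foci in late prophase I, while the chiasma
configuration of a bivalent at diakinesis/metaphase I records the outcome of
all COs: a *ring* bivalent has a chiasma on both chromosome arms (hence at
least 2 COs), a *rod* bivalent has chiasmata on one arm only (scored as 1),
and a *univalent pair* has none. Unlabelled chiasmata — chiasmata without a
HEI10 focus — are attributed to the class II (interference-insensitive)
pathway.

`meioscope` implements the statistics a cytology study builds on these
observations, for allotetraploid material with 19 bivalents per meiocyte
(*Brassica napus*), together with a generative simulator used to calibrate
and validate the inference.

## Scoring rules

* **Minimum chiasmata.** `score_min_chiasmata()` applies ring = 2, rod = 1,
  univalent pair = 0 and sums over the 19 pairs.
  `expected_min_chiasmata(p_ring, p_rod, p_univalent, n_pairs)` is its
  population form, `n_pairs (2 p_ring + p_rod)`. The estimate is
  deliberately conservative: a bivalent with three COs, or with two COs on
  the same arm, is undercounted. On simulated data with full detection the
  package asserts `min_chiasmata <= true CO count` on every cell.
* **Class partition.** At diakinesis, `account_crossovers()` computes per
  cell: class I = labelled chiasmata, class II = unlabelled chiasmata, and
  total = their sum. The identity `n_total = n_class1 + n_class2` is enforced
  within each cell.
* **Spacings.** Focus positions are stored as fractions of bivalent length
  (unit interval; the orientation of each bivalent is arbitrary and the
  package adopts the convention that position 0 is one designated end).
  `adjacent_relative_distances()` returns consecutive differences; bivalents
  with 0 foci contribute nothing and bivalents with 1 focus contribute an
  empty set — not a zero, which would fabricate spurious short spacings.
  Pooling across bivalents is the default; `per_bivalent_average = TRUE`
  averages within bivalents first.
* **Intensities.** `normalize_intensity()` subtracts per-record background
  and divides by the reference genotype's mean net intensity, so the
  reference mean is 1 by construction and a mutant mean of, say, 0.3423
  reads directly as a 65.77% decrease. The operation is invariant to uniform
  rescaling of raw values.
* **Percent changes** are rounded half away from zero to whole percents,
  matching how such increases are conventionally reported.

## The Poisson null and its two binning policies

Without interference, per-bivalent class I CO counts are Poisson. The test
constructs the null from the data: lambda is the sample mean (the Poisson
MLE), expected counts are `n * dpois(k, lambda_hat)`, and the statistic is
Pearson's chi-square. Because the exact spreadsheet convention behind
published chi-square comparisons of this kind is not recoverable, both
defensible layouts are implemented and reported side by side:

* `excel_k_minus_1`: categories 0..max observed plus one extra empty
  category, expected counts not renormalized, df = categories − 1. This
  mirrors a spreadsheet layout in which the tail mass is represented by an
  explicit extra cell.
* `folded_k_minus_2`: the right tail is folded (the top category takes the
  entire tail mass) until every expected count is at least 5, and df =
  categories − 2, accounting for the estimated mean. This is the policy
  whose type-I error the package calibrates (rejection rate 5% ± 2% at
  alpha = 0.05 over 1000 replicates of n = 551 Poisson counts, and p-values
  uniform by Kolmogorov–Smirnov).

When both policies run, the pipeline emits a verdict only if they agree at
alpha = 0.05; otherwise the genotype is flagged *policy-sensitive*. A
degenerate case is handled explicitly: if folding leaves only two categories
(as happens for very sparse counts, e.g. a null-mutant-like genotype whose
bivalents rarely carry more than one focus), the folded policy has zero
degrees of freedom once the mean is estimated, and the verdict is *not
testable* rather than a number. Exact published p magnitudes for this family
of tests are not reproducible without knowing the original category range
and df choice; the package reproduces threshold conclusions, not those exact
magnitudes.

`chisq_homogeneity()` compares two focus-count distributions with the
standard two-sample Pearson chi-square on the 2 × K table, padding to a
common category range and folding right-tail categories whose expected count
under homogeneity falls below 5.

## Games–Howell comparisons

Group comparisons of per-cell quantities (chiasmata, foci, seed counts, and
similar) use the Games–Howell procedure: Welch standard errors
`sqrt(s1^2/n1 + s2^2/n2)`, Welch–Satterthwaite df, and the statistic
`q = |mean difference| * sqrt(2) / SE` referred to the studentized range
distribution with k means (`ptukey`). It is robust to unequal variances and
unequal group sizes, which is the regime cytological counts are usually in.
Adjustment is within the one family formed by the supplied groups; there is
no cross-family correction. Validation: under equal variances and equal
(large) n it agrees with a classical Tukey HSD computation within 5%
relative p, and its family-wise error under the global null is 5% ± 2% over
1000 replicates.

## The synthetic meiocyte generator

`simulate_experiment()` draws cells of 19 bivalents under a genotype preset:

* **Class I COs** follow a stationary gamma-renewal process along the unit
  interval: inter-CO distances are gamma with shape `nu` and mean
  `1/class1_rate`. `nu = 1` is the Poisson (no interference) case; larger
  `nu` spreads COs more evenly (interval CV is `1/sqrt(nu)`). For integer
  `nu` the sampler uses the exact thinning construction — a Poisson process
  at rate `nu * rate`, keeping every `nu`-th event from a uniformly random
  phase; for non-integer `nu` it samples sequentially with the first
  interval drawn from the equilibrium (integrated-tail) law by closed-form
  CDF inversion, so the process is stationary either way. The closed-form
  void probability (`renewal_void_prob()`) doubles as an independent check
  of stationarity in the test suite.
* **Class II COs** are an independent homogeneous Poisson overlay
  (`class2_rate`). Interference acts within bivalents only and only on
  class I; both choices reflect how the two pathways behave
  observationally: class II COs are interference-insensitive and all the
  statistics of interest are per-bivalent.
* **Obligate CO.** Three mechanisms are exposed:
  `resample_until_nonempty` (redraw the pair until the union of both
  classes is nonempty), `forced_extra` (add one uniform class I CO to an
  empty pair; the assured CO is class I because CO assurance runs through
  the ZMM pathway), and `none`.
* **Observation layer.** Configurations are scored arm-wise from all true
  COs against the centromere position (a CO exactly at the centromere
  counts as left-arm; this tie has probability zero under the continuous
  model). `n_chiasmata` counts all true COs; focus counts and positions
  reflect detected class I COs only, each kept with `detection_prob` —
  detection applies to focus observation, never to chiasma existence, since
  chiasmata are visible in spreads independently of immunolabelling. With
  `detection_prob = 1`, foci + class II = chiasmata on every record
  (asserted in the tests).

### Genotype presets and calibration

`genotype_presets()` encodes the six-genotype dosage series. The study
conditions are the printed diakinesis statistics: per-cell focus means
26.88 (wild type), 29.76, 29.40 (two functional alleles), 37.91, 36.67 (one
functional allele) and 5.48 (null), and per-cell class II means 6.55, 6.00,
6.50 and 0.56. Interference is strong (`nu = 8`) for wild type and the
two-allele genotypes, absent (`nu = 1`) for the one-allele genotypes whose
focus counts are Poisson-like, and `nu = 8` is retained for the null mutant
(its few COs make the choice nearly inconsequential). All presets are
calibrated to the diakinesis stage for internal consistency.

Calibration is analytic, not iterative tuning: for presets with
resample-until-nonempty assurance the class I rate solves

```
lambda1 / (1 - p0_union(lambda1)) = target foci per pair,
```

where `p0_union = renewal_void_prob(lambda1, nu) * exp(-lambda2)` uses the
closed-form stationary void probability; `uniroot` on a monotone function
makes the preset table deterministic. Simulated per-cell focus means land
within 10% of the printed genotype means (asserted in the tests with 400
cells per genotype).

Obligate-mechanism defaults are a modelling decision worth stating plainly.
For the one-functional-allele genotypes the default is `none`, not
resampling: conditioning the union on being nonempty suppresses the
zero-focus category so strongly (analytically, P(no focus | at least one
CO) ≈ 0.054 against a Poisson prediction of 0.136 at the calibrated rates)
that a `nu = 1` genotype would spuriously *reject* the Poisson null — the
opposite of what weak-interference genotypes show, and these genotypes do
exhibit partially compromised CO assurance (univalents in 13–17% of cells).
The trade-off is that the simulator then produces more univalent pairs than
real one-allele meiocytes show; neither simple mechanism reproduces both
the univalent frequency and the Poisson-type focus distribution, because
real CO assurance is not an all-or-nothing redraw. The null-mutant preset
also uses `none` (massive univalence is its phenotype); wild type and the
two-allele genotypes use resampling.

### Univalents in focus-count distributions

`foci_distribution()` describes *bivalents*, so univalent pairs are excluded
by default. This matters for the simulator's Poisson validation: a
zero-CO pair is an outcome of the same generative process, and excluding it
truncates part of the zero-focus class. With `obligate = none` and `nu = 1`
the class I counts over all pairs are exactly Poisson, so
calibration and power checks on simulated data set
`count_univalents_as_zero = TRUE`; on real data the default (off) matches
how published distributions count bivalents, and univalents are rare enough
there for the difference to be negligible. Both behaviors are exposed
because the choice shifts category-0 mass.

## Interference-strength estimation

`estimate_nu()` fits the gamma shape to pooled spacings by maximum
likelihood: method-of-moments start, Newton iteration on
`log(nu) - digamma(nu) = log(mean x) - mean(log x)` to tolerance 1e-8 (at
most 100 iterations, domain-guarded), with a seeded percentile bootstrap
(default 1000 resamples) for the 95% interval. Against
`MASS::fitdistr` it agrees to ~1e-3 on large gamma samples.

Spacings observed inside a finite bivalent are edge-censored: a gap can
only be observed when both foci fit on the bivalent, which under-samples
long gaps, shrinks the apparent spacing CV, and biases the shape estimate
*upward* when the window holds few foci (at ~2 foci per bivalent the median
estimate for a true shape of 5 is roughly 6). Parameter-recovery
validation therefore runs in a focus-dense regime — rate 5 per unit length,
1000 bivalents, shapes 2 and 5 — where the analytic length-bias is small
and the median estimate recovers the truth within 25% (asserted over 200
seeded replicates). Estimates from sparse, realistic bivalents should be
read as qualitative (interference present/absent), not as unbiased
measurements.

## Pipeline and reproducibility

`run_config()` + `pipeline_simulate()` + `pipeline_analyze()` (and the
`inst/exec/meioscope` script) orchestrate simulate → score → test → report.
Every output records the seed; per-genotype simulation seeds are derived as
`seed + genotype index`, so a run is byte-reproducible. Reports round means
and SDs to 2 decimals and print p-values below 0.001 in scientific
notation; every number in `report.txt` is lifted from a serialized result
file, never recomputed. `pipeline_simulate()` refuses to overwrite an
existing dataset unless forced.

## Validation problem sizes

The shipped test suite validates: sampler stationarity and the Poisson
limit (2500–5000 replicates of short windows; one 4000-length window for
interval CVs), type-I calibration of the folded policy (1000 replicates of
n = 551), power (200 replicates each of wild-type-like and
no-interference-like datasets of 551 bivalents: the former rejects with
p < 1e-6 in ≥ 99% of replicates, the latter fails to reject in ≈ 95%),
parameter recovery (200 replicates × 1000 bivalents at shapes 2 and 5),
Games–Howell calibration (1000 replicates, 4 groups of 50), and the exact
worked examples with printed inputs (expected chiasmata 31.53; percent
increases 44/41/55; univalent fraction 70.79%; the n = 551 wild-type
distribution rejecting Poisson at p < 1e-20 under both policies). These
sizes make the whole suite run in about a minute while keeping Monte-Carlo
error well inside the asserted bands.

## What the simulator does and does not emulate

It reproduces: per-bivalent count distributions under tunable interference,
dosage-dependent rates, obligate-CO behavior, detection loss, configuration
scoring (including its conservatism), and labelled/unlabelled chiasma
bookkeeping. It does not model: chromosome-specific CO landscapes
(telomere/centromere bias), cross-bivalent interference, synaptonemal-
complex dynamics or HEI10 coarsening, stage progression within one cell, or
measurement error in focus positions. Passing tests on synthetic data
therefore validate the statistical machinery and its calibration — not the
biological fidelity of any particular parameter value — and real-data
conclusions should rest on the scoring and testing functions, with the
simulator as a power/calibration harness.
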