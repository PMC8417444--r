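---
title: "Cross-cohort correlation meta-analysis with vote filtering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort correlation meta-analysis with vote filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corvote)
```

## The statistical model

`corvote` asks whether a gene's transcriptome-wide correlation pattern
opposes a clinical phenotype's, replicated across independent tumour
cohorts. The unit of evidence is a per-cohort correlation:

* **Gene–anchor**: Pearson product-moment correlation between each gene's
  log2 expression and the anchor gene's log2 expression. Expression is
  analysed on log2 scale because fold-change noise on microarray and
  RNA-seq intensities is approximately multiplicative; linear-scale
  cohorts are transformed as `log2(x + pseudocount)` (default
  pseudocount 1, so zero stays zero).
* **Gene–status**: the same machinery applied to a 0/1 coding of a binary
  clinical status (negative = 0, positive = 1), i.e. the point-biserial
  correlation. A negative sign means higher expression in status-negative
  samples. This keeps one estimator and one significance rule for both
  tracks and makes the two signed lists directly comparable.

Significance uses the exact null relationship between a correlation and
Student's t:

$$t = r\sqrt{\frac{n-2}{1-r^2}}, \qquad t \sim t_{n-2}$$

two-sided, with `n` the pairwise-complete sample count for that gene.
Missing expression or clinical values are excluded pairwise, per gene and
per analysis, because annotation coverage is heterogeneous across public
cohorts. Genes with constant expression (or fewer than 3 complete pairs)
are *skipped and listed*, never silently assigned r = 0. Degenerate
perfect correlations (|r| = 1) are flagged with a warning and a
smallest-positive-double p rather than 0, so downstream ranking still
works.

No per-cohort multiple-testing correction is applied to the genome-wide
correlation p-values: robustness is delegated to the cross-cohort filter,
which is the analysis's replication mechanism. The per-test level stays
at the conventional α = 0.05.

## The vote filter

A gene enters the meta-list when it is significantly correlated *with a
consistent sign* in at least `min_votes` of the cohorts (default K = 6 of
D = 12, i.e. half the benchmark cohorts). Conflicts are penalised. The
default penalty — each significant opposite-sign cohort cancels one
supporting cohort, `net_votes = |n_pos − n_neg|`, consensus = the
majority sign, ties fail — is the simplest rule in which conflicting
evidence subtracts rather than merely failing to add. A stricter variant
(`vote_penalty = "strict"`: any conflicting cohort disqualifies) is
provided because the penalty's exact form is a genuine design freedom;
both satisfy the key invariants (order invariance, monotonicity in
same-sign support). Vote counting deliberately ignores effect sizes: the
cohorts differ in platform and dynamic range, so pooling r values
(Fisher-z, random effects) would impose comparability the inputs do not
have. Genes measured in fewer than `min_votes` cohorts can never pass;
they are reported with `passes = FALSE` rather than dropped, for audit.

## Overlap statistics

The signed anchor list and signed status list are intersected. A shared
gene is *inverse* when its two signs differ. All percentages are computed
at full precision and on the 0–100 scale, with both one- and two-decimal
renderings in reports, since conventions differ by venue; when no genes
are shared, shared-based percentages are undefined and reported as
missing, not zero. The implicit universe of each percentage is the
corresponding list's own total — the only convention under which the
counts and percentages of a two-set Venn are mutually consistent.

## Enrichment

Over-representation of a signed-overlap class is tested per term by the
hypergeometric upper tail — the one-sided Fisher exact test on the 2×2
table. One-sided was chosen because the scientific question is
over-representation; depletion is not interpreted. The default universe
is every gene tested in at least one cohort (configurable), since an
enrichment universe should be the set of genes that *could* have entered
the query. Term sets are intersected with the universe before testing;
odds ratios use a 0.5 continuity correction only when a table cell is
zero. BH FDR is applied across terms. Note the BH step-up is not
idempotent: re-adjusting q-values inflates them whenever ranks shift, so
`bh_fdr()` must be applied once, to raw p-values.

## Survival analysis

Kaplan–Meier estimation and the k-group logrank test are delegated to the
`survival` package; the package-specific machinery is built on top:

* **Kaplan scan.** Every cut between consecutive distinct sorted
  expression values leaving at least `kaplan_min_group` samples per side
  (default 8 — guards against degenerate splits in cohorts of ~100) is
  scored by the 2-group logrank p; the minimum wins, ties going to the
  more balanced split. The scan statistic is computed incrementally
  (risk/event counts per distinct event time updated as one sample at a
  time crosses the cutoff), so a full scan is O(samples × event times);
  it is verified against `survival::survdiff` at matched splits in the
  test suite.
* **Multiplicity.** The minimal p over ~n cutoffs is anti-conservative
  (the test suite demonstrates this empirically under the null), so the
  result carries both `p_raw` and a clearly labelled Bonferroni-style
  `p_adjusted` (`p_raw` × number of scanned cutoffs, capped at 1), which
  holds the null rejection rate at or below nominal.
* **Estimator behaviour worth knowing.** The arg-min cutoff is a noisy
  estimator of a planted group boundary: in simulations with two
  expression groups of disjoint supports and a 3-fold hazard difference
  (n = 200), the minimal-p split drifts a few boundary samples into one
  group in most replicates, placing the numeric cutoff just outside the
  support gap even though the recovered *grouping* agrees with the
  planted grouping for ≥ 95% of samples. Recovery should therefore be
  judged — as the tests do — by group agreement and the adjusted p, not
  by strict containment of the cutoff value.
* **Combined tracks.** Two binary high/low tracks (typically two Kaplan
  scans) are crossed into a 4-level track; samples missing either track
  are dropped with a log message, and a track constant on the common
  samples is an error because the combination degenerates. The 4-group
  logrank is followed by all pairwise 2-group logranks, Holm-adjusted.
* Ties in the logrank use the standard pooled hypergeometric variance at
  each distinct event time. Which endpoint (overall vs relapse-free
  survival) the times represent is a property of the clinical table, not
  of the pipeline.

## Subtype association

Anchor expression across molecular subtypes is tested twice per cohort:
Kruskal–Wallis (midranks with tie correction, χ² reference with g − 1 df)
as the primary nonparametric test, and Welch's heteroscedastic ANOVA —
subtype groups have visibly unequal spreads — with pairwise Welch t
post-hoc contrasts against a reference subtype (default basal),
Holm-adjusted. The post-hoc method is a design choice: with a natural
reference group, all-pairs testing wastes power. Box-plot summaries use
type-7 (linear interpolation) quartiles — stated explicitly because
quartile conventions differ — and the conventional 1.5·IQR fences for
outlier flagging.

## The synthetic generator

`generate_cohorts()` emulates exactly the structure the meta-analysis
assumes, with analytic control of every planted parameter:

| parameter | default | rationale |
|---|---|---|
| `n_datasets` | 12 | benchmark width at which a 6-vote filter is meaningful |
| `samples_per_dataset` | 100–500 | the size range of public breast-cancer cohorts passing a ≥100-sample rule |
| `n_genes` | 2,000 | enough background for stable specificity, small enough for fast tests |
| `frac_status_positive` | 0.7 | the approximate prevalence of ER-positive breast tumours |
| `anchor_shift` | 1.5 log2 units | a strong (~2.8-fold) but realistic status-linked shift |
| `module_sizes` | 100 + 100 | planted antagonistic modules |
| `coupling_strength` | 0.5 | target \|r\| with the anchor: clearly detectable per cohort at n ≥ 100 without being trivial |
| `noise_sd` | 1 | typical log2 residual spread |
| hazards | 0.05 × (3, 2, 1.5, 1) | worst outcome in anchor-high/status-negative, mirroring an aggressive-subtype gradient |
| censoring | uniform(0, 40) | ~40–55% events depending on group |

Expression is Gaussian on log2 scale. Module genes are generated as
`±ρ·z + sqrt(1−ρ²)·ε` around the standardised anchor signal, so their
expected correlation with the anchor is exactly ±ρ, and — because the
anchor is shifted in status-negative samples — their status correlation
is automatically the *opposite* sign: the planted antagonism. A
receptor-like gene (`ESR1L`) is shifted up in status-positive samples to
serve as the second survival track. Subtypes are basal for
status-negative samples (flipped with probability 0.15), so the anchor is
highest in basal tumours. All randomness flows from one master seed;
cohort i uses a deterministically derived child seed, so any cohort is
reproducible in isolation.

What the generator does **not** emulate: platform-specific probe noise,
batch effects, normalisation artefacts, correlated background genes,
non-exponential hazards, informative censoring. Passing tests therefore
demonstrate that the pipeline recovers the assumed structure when it is
present — not that real cohorts satisfy those assumptions.

## Numerical and scope choices

* Expression TSVs are written with 17 significant digits so write → read
  round-trips are bitwise exact.
* Strict parsing: ragged rows, non-numeric cells, duplicate identifiers
  and `NA` expression values are errors naming the offending location;
  imputation is deliberately out of scope.
* Clinical status tokens (`pos/neg`, `+/−`, `1/0`, case-insensitive) are
  normalised at read time; unknown tokens are errors, not missings.
* Input rows are assumed gene-level; probe-to-gene collapsing and
  normalisation are upstream of this package.
* The pipeline is deterministic given inputs and configuration: repeated
  runs produce identical reports (no timestamps in provenance).

## Problem sizes used in the shipped tests

The test suite and acceptance script run the default 12-cohort benchmark
(2,000 genes, 100–500 samples), 1,000-replicate null calibrations for the
correlation, logrank and vote-filter type-I rates, a 400-replicate null
for the scan-multiplicity property, and exhaustive small-n enumeration
oracles (permutation tests at n ≤ 6, hypergeometric sums at N ≤ 30).
These sizes give Monte-Carlo standard errors small enough for ±3 s.e.
calibration bands while keeping a full run in the tens of seconds.

## Known limitations

* Vote counting discards effect-size information by design; it cannot
  distinguish 6 marginal cohorts from 6 overwhelming ones.
* The Bonferroni-style scan adjustment is conservative; permutation-based
  adjustment would be tighter but orders of magnitude slower.
* The point-biserial correlation inherits Pearson's sensitivity to heavy
  tails; no robust variant is provided.
* Enrichment treats gene sets as flat (no ontology topology, no
  inter-term redundancy correction).
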