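---
title: "Methods: enrichment statistics for air–sea microbial transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment statistics for air-sea microbial transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroflux)
```

## The model

`aeroflux` analyses the transfer of bacteria and viruses from seawater
into sea spray aerosol in a mesocosm setting: three compartments (bulk
seawater, the sea surface microlayer SSML, and aerosol) sampled on a set
of experiment days, with each sample size-fractionated (0.2–3 µm for
bacterial cells, 0.025–0.2 µm for free viruses) and sequenced. The data
unit is a taxon-by-sample table of read counts, normalised per sample to
population fractions.

For a taxon with fractions A (aerosol), B (bulk) and S (SSML) in the same
day and size fraction, the aerosolization factor is AF = A/B (A:B) or A/S
(A:S), and the surface-enrichment factor is S:B = S/B. Wherever all three
are defined and positive, A:B = (A:S)·(S:B) exactly; the test suite
verifies this identity to 1e-12 relative tolerance. Because fractions are
per-sample compositions, all three ratios are invariant to per-sample
sequencing depth — the property that makes them comparable across
compartments sequenced at different depths.

Key assumptions worth stating explicitly:

- **Compositionality.** Fractions within a sample sum to 1, so one
  taxon's enrichment is always relative to its community. A global change
  affecting every taxon equally is invisible to AF. This is why the
  analysis of domain-wide effects (bacteria versus viruses) needs the
  unannotated read mass in the denominators (see the generator section).
- **No pseudocounts.** A zero denominator yields a flagged undefined
  ratio (`zero_denominator` when the numerator is positive, `absent` when
  both are zero) rather than a smoothed value. The published strategy this
  mirrors controls zero-driven artefacts by abundance filtering instead of
  smoothing, and we follow it: filters run before enrichment.
- **Non-renormalising filters.** Removing a taxon does not renormalise
  the remaining fractions, so filtering never changes the AF of a
  surviving taxon (verified by test).

## Filters

Two exclusion procedures run on fractions-mode tables:

- **Abundance-threshold filter.** A taxon is removed if any sample holds
  less than `min_fraction_any_sample` of the population, or if at least
  `max_low_samples` samples hold less than `low_fraction`. Two published
  variants are provided: `"methods"` (0.001% any sample; 10-of-18 samples
  below 0.01%) — the default, being the procedural description — and
  `"results"` (0.01% any sample; more than half of samples below 0.1%).
  For designs with N ≠ 18 samples the 10-of-18 count scales as
  `ceiling(10 N / 18)` and "more than half" as `floor(N/2) + 1`; both are
  overridable. Thresholds are expressed on [0, 1] throughout (0.01% =
  1e-4), converted once at configuration time, to preclude percent/fraction
  confusion. The low-sample count is evaluated over all samples in the
  table; whether it should instead run per size fraction is not specified
  by the source analysis, and the grouping can be arranged by subsetting
  the table first.
- **Spatial-coverage filter.** For taxa with a reference genome, the
  coverage fraction is the proportion of concatenated assembly positions
  covered by at least one mapped read, computed from bedgraph intervals
  (0-based half-open; depth values are reduced to covered/uncovered since
  only the proportion of mapped positions matters). Taxa strictly below
  the threshold (default 0.1%) are removed — a taxon at exactly 0.1% is
  retained, matching a rule phrased as "below". Taxa without a reference
  are retained and flagged `no_reference`: they cannot be coverage-tested,
  and silently dropping them would conflate missing references with bad
  annotations.

Both rules are per-taxon and independent of other taxa, so the two
filters commute (tested). Exclusion reports name the rule that fired and
the statistic that triggered it.

## Enrichment, quadrants, summaries

`compute_enrichment()` emits one record per taxon per (day, size
fraction) with at least two compartments sampled. `classify_quadrant()`
applies the standard scheme: aerosol-enriched (A:B and A:S > 1),
waterborne (both < 1), and the two mixed quadrants. The boundary is
handled by a `tie_epsilon` half-width (default 0: exact comparison, a
ratio equal to 1 is `neutral`), because the source analysis never states
boundary behaviour and an explicit parameter is better than a hidden
convention.

`enrichment_summary()` pools defined A:B and A:S values by default; a
single-ratio mode exists because it is genuinely ambiguous whether
published summary statistics pool both ratios, and the choice is exposed
rather than guessed. Reported statistics: count, mean, s.d., adjusted
Fisher–Pearson skewness (the common bias-corrected standardized third
moment; a degenerate distribution reports 0), Shapiro–Wilk normality
p-value (the test is configurable and recorded in the output — the source
says only "normality analysis"), fraction of values below 1, and the
per-taxon extremes: mean per-taxon maximum and minimum AF with the
amplitude ratio mean|max − 1| / mean|1 − min|, which captures whether
enrichment extends farther from neutrality than depletion.

## Temporal classification and groups

A taxon is a *constitutive* aerosolizer when at least a proportion
`q = 0.8` of its observed (defined) AF values lie on one side of 1 —
inclusive comparison, so 4 of 5 qualifies. Values exactly 1 count toward
the number observed but to neither side; the constitutive side must also
be the strict majority (relevant only for q ≤ 0.5). `min_obs = 3` guards
taxa observed once or twice from being called constitutive; the source
states no minimum, and 3 is the smallest count for which "80% on one
side" differs from "all on one side" being trivially satisfiable.
By default both A:B and A:S contribute to a taxon's series (the published
temporal displays show both ratios); single-ratio mode is available. The
implementation is verified against exhaustive enumeration of all
three-level AF patterns (below/at/above 1) up to length 6 for
q ∈ {0.5, 0.8, 1.0}.

Group summaries (by class, order, family, domain, or viral-envelope
status) average per-taxon means rather than pooling observations, so
long-observed taxa do not dominate; pooled mode is available. Taxa
lacking the annotation go to an `unannotated` bucket, and a day-exclusion
list allows removing days of global surface enrichment before averaging
S:B. `compare_domains()` reports per-domain summaries, the difference of
means on both the AF scale and the log scale (AF is a ratio; the log
scale is robust to its right skew), a Wilcoxon rank-sum p-value, and
per-day mean AF series that expose day-wise clustering.

## Count-ratio analysis

Compartment concentration series (cells or VLP, on a common ×10⁷ per-mL
scale) support per-day ratios and two averaging conventions:
mean-of-ratios over shared days, and ratio-of-means with each series over
its own days (or restricted to shared days). The conventions answer
different questions and generally differ; both are exposed because
published averages use both. Uncertainty is propagated to first order:
sd_r = r·sqrt((sd_n/n)² + (sd_d/d)² + flow²), with flow = 0.10 applied
only when the numerator compartment is aerosol — the aerosol sampler's
system flow variance. Comparisons against printed two-decimal values use
round-half-away-from-zero, which matches every checkable printed entry;
base R's round-half-even does not. The packaged VLP table's printed
average aerosol:bulk row is not recoverable from the printed per-day
entries under either convention (it evidently used unprinted raw data);
the per-day entries and the SSML:bulk average are, and those are what the
acceptance script recomputes.

## The synthetic mesocosm generator

`simulate_mesocosm()` generates the statistical structure the analysis
assumes, with exported ground truth:

- **Bulk dynamics.** Per-taxon baseline log abundance (s.d. 1) plus a
  per-taxon bloom response (s.d. 0.5) times a two-Gaussian bloom pulse
  (default peaks at days 13 and 28, widths 4, the second bloom stronger),
  softmax-normalised to bulk fractions per day. Six sampling days
  (8, 13, 18, 23, 28, 34) span the two blooms, matching a 3-compartment ×
  6-day, two-size-fraction design of 36 libraries.
- **Partitioning chain.** SSML fractions are bulk fractions reweighted by
  a per-taxon surface-partition coefficient σ (log-normal, sdlog 0.5) and
  renormalised; aerosol fractions are SSML fractions reweighted by the
  aerosolization coefficient α (log-normal, sdlog 0.8, spanning roughly
  0.2–5) and renormalised. This encodes the inference that surface
  accumulation feeds aerosolization; a bulk→aerosol mode emulates
  jet-drop transfer instead. Enveloped viruses get a 2× α boost by
  default; optional per-class multipliers plant class-structured effects.
- **Temporal structure.** A fraction (default 0.7) of taxa are
  constitutive; the rest are intermittent, with α inverted (α → 1/α) on a
  random subset of days. The subset size is binomial
  (`intermittent_flip_prob = 0.5`) but clamped to [2, n_days − 2] so that
  an intended-intermittent taxon is observable on both sides of AF = 1 in
  the latent signal — otherwise "intermittent" would be unverifiable
  ground truth.
- **Unannotated background.** Half of each community's population
  (`background_fraction = 0.5`) is a single background pseudo-taxon with
  α = σ = 1, standing for the reads a taxonomic classifier cannot
  annotate — typically the majority in environmental samples. This is not
  decorative: in a fully annotated (closed) community a domain-wide
  multiplier on α cancels exactly in the compositional renormalisation,
  so planted domain-level effects would be undetectable in principle. The
  unannotated mass is what carries them, exactly as in real fraction-of-
  total-population data.
- **Observation.** Counts are multinomial draws per sample at
  `read_depth` (default 1e5); compartments may differ in depth, which is
  how depth invariance is exercised. Count series for the particle-count
  module are derived from the same latent compartment masses with
  log-normal observation noise plus the 10% aerosol flow variance.
  `simulate_coverage()` places reads uniformly on a genome; its coverage
  fraction follows the occupancy form 1 − (1 − L_read/L_genome)^n, used
  as an independent oracle in tests. All randomness flows from one seeded
  stream; a fixed seed gives bit-identical output.

### Validation experiments and their design

The recovery experiments in the tests and the acceptance script are
designed, not tuned; their problem sizes are the package's own choice:

- **α recovery** (50 bacteria + 20 viruses, depth 1e5, 6 days, all
  constitutive): Spearman correlation between planted log α and recovered
  per-taxon mean log A:S. The A:S route isolates α; A:B compounds σ with
  α, so the A:B recovery property is tested separately with surface
  partitioning held mild (sdlog 0.2). All-constitutive communities are
  used because an intermittent taxon's mean log AF deliberately does not
  estimate its log α.
- **Temporal-label recovery** (defaults, strong effects α ≥ 2 or ≤ 0.5):
  fraction of taxa whose constitutive/intermittent label is recovered by
  `classify_temporal()`.
- **Domain-deficit detection** (40 taxa per domain, planted 0.6× viral α
  multiplier): the experiment sets the envelope boost to 1 — otherwise the
  enveloped-virus α boost partially offsets the planted deficit and the
  experiment would confound two effects — and uses moderate α
  heterogeneity (sdlog 0.3), so that the test exercises the detection
  statistic rather than the luck of 40 taxon draws; with the full 0.2–5 α
  span, between-taxon variance dominates a 0.6× domain shift at this
  sample size and detection would hinge on the seed. The assertion is on
  the log-scale mean difference and the rank-sum p-value.

## What the generator does not emulate

Real mesocosm metagenomes have features the generator omits: taxonomic
misassignment and database incompleteness beyond a single background
bucket; correlated day-to-day community autocorrelation (days are
conditionally independent given the bloom curve); ecological
interactions (predation, lysis, succession); within-taxon strain
variation; and compositional coupling between the two size fractions
(cell-associated viruses). Passing recovery tests therefore shows the
statistics recover planted structure under realistic sampling noise — not
that the biological model of any particular mesocosm is correct.

## Numerical and degenerate-input choices

- Fractions mode requires columns summing to 1 ± 1e-9; all-zero columns
  are tolerated and flagged rather than erroring, since empty libraries
  occur.
- `normalize_abundance()` refuses fractions-mode input instead of
  silently renormalising (idempotence violations are bugs upstream).
- Abundance tables are written with 17 significant digits and re-read
  with a correctly-rounded parser, so write→read is value-identical.
- Coverage intervals are stored merged and sorted; merging treats
  touching intervals as one (identical coverage).
- The coverage threshold comparison is strict (`<`), the constitutive
  proportion inclusive (`>=`), both stated above with their rationale.
- Ratios at AF = 1 are neutral at `tie_epsilon = 0` by exact floating
  comparison; simulated AFs are continuous so exact ties occur only in
  hand-built data, where exactness is wanted.

## Known limitations

- The two published abundance-filter variants disagree by a factor of 10
  in their thresholds; both are implemented, the procedural variant is
  the default, and results should state which was used.
- Published headline values from the original deposited reads (mean AFs,
  constitutive percentages, group S:B means) depend on a specific read
  classifier and database snapshot and are not recomputable from tables
  alone; the package validates the statistics by synthetic recovery
  instead.
- Wilcoxon on pooled AF observations treats repeated observations of a
  taxon as independent; with few days and strong day effects it is
  anticonservative. The per-day series in `compare_domains()` output is
  provided so users can judge day structure; a hierarchical model is out
  of scope.
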