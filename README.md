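# aeroflux

Taxon-specific aerosolization analysis for ocean–atmosphere mesocosm
experiments.

When waves break, bubbles burst through the sea surface microlayer (SSML)
and eject sea spray aerosol (SSA) carrying bacteria and viruses into the
air. Transfer across the air–sea interface is not uniform: some taxa are
strongly over-represented in aerosol relative to the water they came from,
others stay waterborne. `aeroflux` quantifies this from size-fractionated
metagenomic abundance tables sampled in three compartments — bulk seawater,
SSML, and aerosol — over the days of a mesocosm bloom experiment, and from
parallel cell / virus-like-particle (VLP) count series.

## The statistics at its core

For a taxon with relative abundance (population fraction) A in aerosol,
B in bulk seawater, and S in the SSML, all within the same size fraction
and day:

- **Aerosolization factor**: AF = A / B (written A:B) or A / S (A:S).
  AF > 1 means the taxon is enriched in aerosol.
- **Surface-enrichment factor**: S:B = S / B, the analogous SSML:bulk
  ratio. The chain identity A:B = (A:S) × (S:B) holds wherever all three
  are defined.

Because AFs are ratios of within-sample fractions, they are invariant to
sequencing depth. Ratios are plain quotients — no pseudocounts; zero
denominators yield flagged undefined values that are excluded from
summaries. Before computing AFs, low-abundance taxa are removed by a
two-clause threshold filter, and taxa whose reference-genome spatial
coverage (fraction of positions with a mapped read) falls below 0.1% can
be removed as likely spurious annotations. Taxa are classified as
*constitutive* aerosolizers when ≥ 80% of their observed AF values fall on
one side of 1, else *intermittent*; group summaries aggregate by class,
order, viral family, or viral-envelope status.

A built-in synthetic mesocosm generator plants known per-taxon
aerosolization (α) and surface-partitioning (σ) coefficients, bloom
dynamics, and multinomial sequencing noise, so the whole pipeline can be
validated by parameter recovery without any external data.

## Worked example

The packaged VLP count table (epifluorescence microscopy counts from a
34-day wave-channel bloom, on a common ×10⁷ per-mL scale) supports per-day
and averaged compartment ratios with first-order uncertainty propagation —
aerosol numerators carry an extra 10% relative flow-variance term:

```r
library(aeroflux)
counts <- vlp_counts()
day_ratio(counts, "virus_particles", "aerosol", "bulk", day = 4)
#>   day   numerator denominator ratio    sd convention
#> 1 4     aerosol   bulk        0.543 0.142 per_day
average_ratio(counts, "virus_particles", "ssml", "bulk", "mean_of_ratios")
#>   day     numerator denominator ratio     sd convention
#> 1 average ssml      bulk         1.02 0.0750 mean_of_ratios
```

Day 4 viruses are about half as concentrated in aerosol as in bulk water
(ratio 0.54), while on average the SSML holds virtually the same VLP
concentration as the underlying water (1.02).

A synthetic community run end to end:

```r
cfg <- simulation_config(seed = 42, n_bacteria = 20, n_viruses = 8,
                         read_depth = 1e5)
sim <- simulate_mesocosm(cfg)
rec <- sim$abundance |>
  normalize_abundance() |>
  compute_enrichment() |>
  classify_quadrant()
head(rec[rec$af_bulk_flag == "ok",
         c("taxon_id", "day", "af_bulk", "af_ssml", "sb", "quadrant")], 4)
#>   taxon_id           day af_bulk af_ssml    sb quadrant
#> 1 b000_unannotated     8   0.523   0.574 0.911 waterborne
#> 2 b000_unannotated    13   0.544   0.590 0.921 waterborne
#> 3 b000_unannotated    18   0.424   0.463 0.915 waterborne
#> 4 b000_unannotated    23   0.552   0.605 0.911 waterborne

enrichment_summary(rec)[, c("n", "mean", "sd", "skewness", "frac_below_1")]
#>       n  mean    sd skewness frac_below_1
#> 1   360  1.25  2.13     5.74        0.667
dplyr::count(classify_temporal(rec), label)
#>   label                     n
#> 1 constitutive_depleted    16
#> 2 constitutive_enriched     5
#> 3 intermittent              9
```

The AF distribution shows the expected shape: most observations sit below
1 (two-thirds here) yet the distribution is strongly right-skewed —
aerosol enrichment, when it happens, is larger in amplitude than
depletion. `sim$truth` carries the planted α, σ and intended temporal
labels for recovery checks, and `plot_quadrants(rec)`,
`plot_af_timecourse(rec)` and `plot_count_series(counts)` give the
standard displays.

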