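# Independent brute-force oracles, deliberately naive implementations.

# Abundance filter: literal per-taxon loop over both clauses.
oracle_abundance_removed <- function(values, min_any, low, max_low) {
  removed <- character(0)
  for (tx in rownames(values)) {
    f <- values[tx, ]
    if (min(f) < min_any || sum(f < low) >= max_low) {
      removed <- c(removed, tx)
    }
  }
  removed
}

# Coverage fraction: per-position membership count over the whole genome.
oracle_coverage_fraction <- function(genome_length, starts, ends) {
  covered <- logical(genome_length)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      covered[(starts[i] + 1):ends[i]] <- TRUE  # 0-based half-open -> 1-based
    }
  }
  mean(covered)
}

# Temporal classification: literal restatement of the constitutive rule.
oracle_temporal_label <- function(af, q, min_obs) {
  n <- length(af)
  if (n < min_obs) return("insufficient")
  up <- sum(af > 1); down <- sum(af < 1)
  if (up / n >= q && up > down) return("constitutive_enriched")
  if (down / n >= q && down > up) return("constitutive_depleted")
  "intermittent"
}
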