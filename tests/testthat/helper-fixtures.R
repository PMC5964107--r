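# Small in-code fixtures shared across tests.

# Sample metadata for a generic n-column design: days 1..n on one
# compartment/fraction won't do (enrichment needs compartments), so cycle
# compartments within days.
toy_design <- function(n, size_fraction = "f3000_200") {
  comp <- rep(c("bulk", "ssml", "aerosol"), length.out = n)
  day <- rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)]
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    day = day, compartment = comp, size_fraction = size_fraction
  )
}

# The classic 18-sample design: 3 compartments x 6 days, one size fraction.
mesocosm_design <- function(days = c(8, 13, 18, 23, 28, 34),
                            size_fraction = "f3000_200") {
  tidyr::expand_grid(day = days,
                     compartment = c("bulk", "ssml", "aerosol")) |>
    dplyr::mutate(sample_id = sprintf("d%02d_%s", day, compartment),
                  size_fraction = size_fraction) |>
    dplyr::select(sample_id, day, compartment, size_fraction)
}

counts_matrix <- function(values, samples = NULL) {
  if (is.null(samples)) samples <- toy_design(ncol(values))
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("t%03d", seq_len(nrow(values)))
  }
  abundance_matrix(values, samples, mode = "counts")
}

# Fractions-mode matrix from arbitrary sub-unity rows: a filler taxon
# absorbs the remainder of each column so columns sum to 1 exactly.
fractions_matrix <- function(values, samples = NULL) {
  if (is.null(samples)) samples <- toy_design(ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("t%03d", seq_len(nrow(values)))
  }
  filler <- 1 - colSums(values)
  stopifnot(all(filler >= 0))
  values <- rbind(values, filler = filler)
  colnames(values) <- samples$sample_id
  abundance_matrix(values, samples, mode = "fractions")
}

# Hand-built enrichment records (as produced by compute_enrichment) from AF
# series; NA values get the missing_sample flag and are excluded downstream.
make_records <- function(taxon_id, af_bulk = NULL, af_ssml = NULL, sb = NULL,
                         day = NULL, size_fraction = "f3000_200") {
  n <- max(length(af_bulk), length(af_ssml), length(sb))
  pad <- function(x) if (is.null(x)) rep(NA_real_, n) else x
  af_bulk <- pad(af_bulk); af_ssml <- pad(af_ssml); sb <- pad(sb)
  if (is.null(day)) day <- seq_len(n)
  flag <- function(x) ifelse(is.na(x), "missing_sample", "ok")
  tibble::tibble(
    taxon_id = taxon_id, day = as.integer(day),
    size_fraction = size_fraction,
    A = NA_real_, B = NA_real_, S = NA_real_,
    af_bulk = af_bulk, af_ssml = af_ssml, sb = sb,
    af_bulk_flag = flag(af_bulk), af_ssml_flag = flag(af_ssml),
    sb_flag = flag(sb)
  )
}
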