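#' Compute aerosolization and surface-enrichment factors
#'
#' For every taxon and every (day, size fraction) group with at least two
#' compartments sampled, computes the three enrichment ratios from per-sample
#' population fractions:
#' \describe{
#'   \item{`af_bulk` (A:B)}{aerosol fraction / bulk fraction}
#'   \item{`af_ssml` (A:S)}{aerosol fraction / SSML fraction}
#'   \item{`sb` (S:B)}{SSML fraction / bulk fraction — surface enrichment}
#' }
#' Ratios are plain quotients with no pseudocounts. A ratio is flagged
#' `"zero_denominator"` when the denominator fraction is 0 and the numerator
#' positive, `"absent"` when both are 0, and `"missing_sample"` when a needed
#' compartment was not sampled in that group; flagged ratios are `NA` and are
#' excluded from every downstream summary. Wherever all three ratios are
#' defined, `af_bulk == af_ssml * sb` holds to floating precision.
#'
#' @param x An `abund_matrix` in fractions mode (typically filtered first).
#' @return A tibble with columns `taxon_id`, `day`, `size_fraction`,
#'   `A`, `B`, `S`, `af_bulk`, `af_ssml`, `sb`, and the three
#'   `*_flag` columns (`"ok"` or the undefined-reason).
#' @export
compute_enrichment <- function(x) {
  stopifnot(inherits(x, "abund_matrix"))
  if (x$mode != "fractions") {
    abort("enrichment requires fractions mode; run normalize_abundance() first.")
  }
  dup <- x$samples |>
    dplyr::count(.data$day, .data$size_fraction, .data$compartment) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate compartment within a (day, size_fraction) group.")
  }
  long <- tidy(x)
  wide <- long |>
    dplyr::select("taxon_id", "day", "size_fraction", "compartment", "value") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "value")
  for (comp in COMPARTMENTS) {
    if (!comp %in% names(wide)) wide[[comp]] <- NA_real_
  }
  n_comp <- x$samples |>
    dplyr::distinct(.data$day, .data$size_fraction, .data$compartment) |>
    dplyr::count(.data$day, .data$size_fraction, name = "n_compartments")
  wide <- wide |>
    dplyr::inner_join(n_comp, by = c("day", "size_fraction")) |>
    dplyr::filter(.data$n_compartments >= 2)

  ratio <- function(num, den) {
    dplyr::case_when(
      is.na(num) | is.na(den) ~ NA_real_,
      den > 0 ~ num / den,
      TRUE ~ NA_real_
    )
  }
  flag <- function(num, den) {
    dplyr::case_when(
      is.na(num) | is.na(den) ~ "missing_sample",
      den > 0 ~ "ok",
      num > 0 ~ "zero_denominator",
      TRUE ~ "absent"
    )
  }
  wide |>
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      day = .data$day,
      size_fraction = .data$size_fraction,
      A = .data$aerosol, B = .data$bulk, S = .data$ssml,
      af_bulk = ratio(.data$aerosol, .data$bulk),
      af_ssml = ratio(.data$aerosol, .data$ssml),
      sb = ratio(.data$ssml, .data$bulk),
      af_bulk_flag = flag(.data$aerosol, .data$bulk),
      af_ssml_flag = flag(.data$aerosol, .data$ssml),
      sb_flag = flag(.data$ssml, .data$bulk)
    ) |>
    dplyr::arrange(.data$taxon_id, .data$day, .data$size_fraction)
}

#' Classify enrichment records into quadrants
#'
#' The quadrant scheme partitions taxa by whether A:B and A:S exceed 1:
#' `aerosol_enriched` (both > 1), `waterborne` (both < 1),
#' `bulk_only_enriched` (A:B > 1, A:S < 1), `ssml_only_enriched`
#' (A:B < 1, A:S > 1). With `tie_epsilon = 0` (exact comparison) a ratio
#' equal to 1 is `neutral`; a positive epsilon widens the neutral band to
#' `[1 - eps, 1 + eps]`. Records with either ratio undefined are `undefined`.
#'
#' @param records Tibble from [compute_enrichment()].
#' @param tie_epsilon Half-width of the neutral band around 1 (default 0).
#' @return `records` with an added `quadrant` character column.
#' @export
classify_quadrant <- function(records, tie_epsilon = 0) {
  stopifnot(tie_epsilon >= 0)
  lo <- 1 - tie_epsilon; hi <- 1 + tie_epsilon
  records |>
    dplyr::mutate(quadrant = dplyr::case_when(
      is.na(.data$af_bulk) | is.na(.data$af_ssml) ~ "undefined",
      .data$af_bulk > hi & .data$af_ssml > hi ~ "aerosol_enriched",
      .data$af_bulk < lo & .data$af_ssml < lo ~ "waterborne",
      .data$af_bulk > hi & .data$af_ssml < lo ~ "bulk_only_enriched",
      .data$af_bulk < lo & .data$af_ssml > hi ~ "ssml_only_enriched",
      TRUE ~ "neutral"
    ))
}

collect_af_values <- function(records,
                              ratios = c("both", "af_bulk", "af_ssml")) {
  ratios <- match.arg(ratios)
  pieces <- list()
  if (ratios %in% c("both", "af_bulk")) {
    pieces$af_bulk <- records |>
      dplyr::filter(.data$af_bulk_flag == "ok") |>
      dplyr::transmute(.data$taxon_id, .data$day, ratio = "af_bulk",
                       af = .data$af_bulk)
  }
  if (ratios %in% c("both", "af_ssml")) {
    pieces$af_ssml <- records |>
      dplyr::filter(.data$af_ssml_flag == "ok") |>
      dplyr::transmute(.data$taxon_id, .data$day, ratio = "af_ssml",
                       af = .data$af_ssml)
  }
  dplyr::bind_rows(pieces)
}

#' Adjusted Fisher-Pearson standardized skewness
#'
#' Thin wrapper over [e1071::skewness()] type 2 (the bias-adjusted
#' standardized third moment used by most statistical software).
#'
#' @param x Numeric vector (length >= 3).
#' @return Skewness coefficient.
#' @export
adjusted_skewness <- function(x) {
  if (sd(x) == 0) return(0)  # degenerate distribution is symmetric
  e1071::skewness(x, type = 2)
}

#' Summarise an aerosolization-factor distribution
#'
#' Pools the defined AF values (by default both A:B and A:S, configurable)
#' and reports distributional statistics: count, mean, s.d., adjusted
#' Fisher-Pearson skewness, a normality-test p-value (Shapiro-Wilk by
#' default), the fraction of values below 1 (waterborne share), and the
#' per-taxon extreme statistics: mean per-taxon maximum AF, mean per-taxon
#' minimum AF, and the amplitude ratio `mean(|max - 1|) / mean(|1 - min|)`,
#' which measures whether aerosol enrichment extends farther from neutrality
#' than depletion does.
#'
#' @param records Tibble from [compute_enrichment()].
#' @param lineage Optional lineage tibble (needed if `domains` is given).
#' @param domains Optional character vector restricting to lineage domains
#'   (e.g. `"bacteria"`).
#' @param ratios Which ratios to pool: `"both"` (default), `"af_bulk"`,
#'   `"af_ssml"`.
#' @param normality_test `"shapiro"` or `"none"`.
#' @return A one-row tibble: `n`, `n_taxa`, `mean`, `sd`, `skewness`,
#'   `normality_p`, `frac_below_1`, `mean_taxon_max`, `mean_taxon_min`,
#'   `amplitude_ratio`. The normality test used is recorded in the
#'   `normality_test` column.
#' @export
enrichment_summary <- function(records, lineage = NULL, domains = NULL,
                               ratios = c("both", "af_bulk", "af_ssml"),
                               normality_test = c("shapiro", "none")) {
  ratios <- match.arg(ratios)
  normality_test <- match.arg(normality_test)
  if (!is.null(domains)) {
    if (is.null(lineage)) abort("`domains` filtering needs a lineage table.")
    keep <- lineage$taxon_id[lineage$domain %in% domains]
    records <- dplyr::filter(records, .data$taxon_id %in% keep)
  }
  vals <- collect_af_values(records, ratios)
  if (nrow(vals) == 0) abort("no defined AF values to summarise.")
  per_taxon <- vals |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(af_max = max(.data$af), af_min = min(.data$af),
                     .groups = "drop")
  p <- if (normality_test == "shapiro" && nrow(vals) >= 3) {
    shapiro.test(vals$af)$p.value
  } else {
    NA_real_
  }
  tibble::tibble(
    n = nrow(vals),
    n_taxa = nrow(per_taxon),
    mean = mean(vals$af),
    sd = if (nrow(vals) > 1) sd(vals$af) else NA_real_,
    skewness = if (nrow(vals) >= 3) adjusted_skewness(vals$af) else NA_real_,
    normality_p = p,
    normality_test = normality_test,
    frac_below_1 = mean(vals$af < 1),
    mean_taxon_max = mean(per_taxon$af_max),
    mean_taxon_min = mean(per_taxon$af_min),
    amplitude_ratio = mean(abs(per_taxon$af_max - 1)) /
      mean(abs(1 - per_taxon$af_min))
  )
}
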