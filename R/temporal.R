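#' Classify taxa as constitutive or intermittent aerosolizers
#'
#' A taxon is a constitutive aerosolizer when at least a proportion `q`
#' (default 80%) of its observed (defined) AF values lie on one side of 1 —
#' `constitutive_enriched` when that side is above 1, `constitutive_depleted`
#' below. AF values exactly equal to 1 count toward the number observed but
#' toward neither side. Ties between sides (possible only for `q <= 0.5`)
#' are `intermittent`: the constitutive side must be the strict majority.
#' Taxa with fewer than `min_obs` defined values are `insufficient`.
#'
#' @param records Tibble from [compute_enrichment()].
#' @param q Constitutive proportion threshold in `(0, 1]`; inclusive
#'   comparison (`>= q`). Default 0.8.
#' @param min_obs Minimum number of defined AF values (default 3).
#' @param ratios Which ratios form a taxon's AF series: `"both"` (default:
#'   A:B and A:S pooled), `"af_bulk"`, or `"af_ssml"`.
#' @return A tibble with `taxon_id`, `n_observed`, `n_above`, `n_below`,
#'   `label`.
#' @export
classify_temporal <- function(records, q = 0.8, min_obs = 3,
                              ratios = c("both", "af_bulk", "af_ssml")) {
  stopifnot(q > 0, q <= 1, min_obs >= 1)
  vals <- collect_af_values(records, match.arg(ratios))
  all_taxa <- unique(records$taxon_id)
  counts <- vals |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(
      n_observed = dplyr::n(),
      n_above = sum(.data$af > 1),
      n_below = sum(.data$af < 1),
      .groups = "drop"
    )
  counts <- dplyr::left_join(tibble::tibble(taxon_id = all_taxa), counts,
                             by = "taxon_id") |>
    dplyr::mutate(dplyr::across(c("n_observed", "n_above", "n_below"),
                                ~ tidyr::replace_na(.x, 0L)))
  counts |>
    dplyr::mutate(label = temporal_label(.data$n_observed, .data$n_above,
                                         .data$n_below, q, min_obs))
}

temporal_label <- function(n_observed, n_above, n_below, q, min_obs) {
  dplyr::case_when(
    n_observed < min_obs ~ "insufficient",
    n_above / n_observed >= q & n_above > n_below ~ "constitutive_enriched",
    n_below / n_observed >= q & n_below > n_above ~ "constitutive_depleted",
    TRUE ~ "intermittent"
  )
}

#' Aggregate enrichment and temporal statistics by lineage group
#'
#' Averages per-taxon mean AF and mean S:B within taxonomic classes, orders,
#' domains, or viral-envelope status. Group means average per-taxon means
#' (each taxon contributes once regardless of how often it was observed);
#' `pooled = TRUE` averages all observations directly. Taxa without the
#' grouping annotation fall into an `"unannotated"` bucket. `exclude_days`
#' drops the stated experiment days from the records before averaging (used
#' e.g. to remove days of global SSML enrichment from an S:B average).
#'
#' @param records Tibble from [compute_enrichment()].
#' @param lineage Lineage tibble (`taxon_id`, `domain`, `class`, `order`,
#'   `family`, `enveloped`).
#' @param group_by One of `"class"`, `"order"`, `"family"`, `"domain"`,
#'   `"envelope"`.
#' @param classifications Optional tibble from [classify_temporal()]; adds a
#'   `frac_constitutive` column.
#' @param exclude_days Optional integer vector of days dropped before
#'   averaging.
#' @param ratios Which ratios contribute to the AF mean (default `"both"`).
#' @param pooled If `TRUE`, pool observations instead of averaging per-taxon
#'   means.
#' @return A tibble with `group`, `n_taxa`, `mean_af`, `mean_sb`, and (when
#'   classifications are supplied) `frac_constitutive`.
#' @export
group_aggregate <- function(records, lineage,
                            group_by = c("class", "order", "family",
                                         "domain", "envelope"),
                            classifications = NULL, exclude_days = NULL,
                            ratios = c("both", "af_bulk", "af_ssml"),
                            pooled = FALSE) {
  group_by <- match.arg(group_by)
  ratios <- match.arg(ratios)
  if (!is.null(exclude_days)) {
    records <- dplyr::filter(records, !.data$day %in% exclude_days)
  }
  grp <- if (group_by == "envelope") {
    if (!"enveloped" %in% names(lineage)) {
      abort("envelope grouping needs an `enveloped` column in the lineage table.")
    }
    lineage |>
      dplyr::transmute(.data$taxon_id, group = dplyr::case_when(
        is.na(.data$enveloped) ~ NA_character_,
        .data$enveloped ~ "enveloped",
        TRUE ~ "non_enveloped"
      ))
  } else {
    lineage |> dplyr::transmute(.data$taxon_id, group = .data[[group_by]])
  }
  af <- collect_af_values(records, ratios) |>
    dplyr::select("taxon_id", "af")
  sb <- records |>
    dplyr::filter(.data$sb_flag == "ok") |>
    dplyr::transmute(.data$taxon_id, sb = .data$sb)
  if (!pooled) {
    af <- af |> dplyr::group_by(.data$taxon_id) |>
      dplyr::summarise(af = mean(.data$af), .groups = "drop")
    sb <- sb |> dplyr::group_by(.data$taxon_id) |>
      dplyr::summarise(sb = mean(.data$sb), .groups = "drop")
  }
  taxa <- tibble::tibble(taxon_id = unique(records$taxon_id)) |>
    dplyr::left_join(grp, by = "taxon_id") |>
    dplyr::mutate(group = dplyr::coalesce(.data$group, "unannotated"))
  out <- taxa |>
    dplyr::left_join(
      af |> dplyr::group_by(.data$taxon_id) |>
        dplyr::summarise(taxon_af = mean(.data$af), .groups = "drop"),
      by = "taxon_id") |>
    dplyr::left_join(
      sb |> dplyr::group_by(.data$taxon_id) |>
        dplyr::summarise(taxon_sb = mean(.data$sb), .groups = "drop"),
      by = "taxon_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_taxa = dplyr::n(),
      mean_af = mean(.data$taxon_af, na.rm = TRUE),
      mean_sb = mean(.data$taxon_sb, na.rm = TRUE),
      .groups = "drop"
    )
  if (!is.null(classifications)) {
    fc <- taxa |>
      dplyr::inner_join(classifications, by = "taxon_id") |>
      dplyr::filter(.data$label != "insufficient") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        frac_constitutive = mean(.data$label %in%
          c("constitutive_enriched", "constitutive_depleted")),
        .groups = "drop")
    out <- dplyr::left_join(out, fc, by = "group")
  }
  out
}

#' Compare bacterial and viral aerosolization-factor distributions
#'
#' Pools the defined AF values of each domain and reports per-domain
#' distribution summaries, the difference of means (virus minus bacteria), a
#' rank-based two-sample (Wilcoxon rank-sum) test of the two AF
#' distributions, and the per-day mean AF series of each domain — the latter
#' exposes day-wise clustering of viral AFs driven by shared environmental
#' conditions.
#'
#' @param records Tibble from [compute_enrichment()].
#' @param lineage Lineage tibble with a `domain` column.
#' @param ratios Which ratios to pool (default `"both"`).
#' @return An object of class `domain_comparison` with [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @export
compare_domains <- function(records, lineage,
                            ratios = c("both", "af_bulk", "af_ssml")) {
  ratios <- match.arg(ratios)
  dom <- lineage |> dplyr::select("taxon_id", "domain")
  vals <- collect_af_values(records, ratios) |>
    dplyr::inner_join(dom, by = "taxon_id") |>
    dplyr::filter(.data$domain %in% c("bacteria", "virus"))
  af_b <- vals$af[vals$domain == "bacteria"]
  af_v <- vals$af[vals$domain == "virus"]
  if (length(af_b) == 0 || length(af_v) == 0) {
    abort("both domains must contribute at least one defined AF value.")
  }
  summaries <- dplyr::bind_rows(
    bacteria = enrichment_summary(
      dplyr::semi_join(records, dom[dom$domain == "bacteria", ], by = "taxon_id"),
      ratios = ratios, normality_test = "none"),
    virus = enrichment_summary(
      dplyr::semi_join(records, dom[dom$domain == "virus", ], by = "taxon_id"),
      ratios = ratios, normality_test = "none"),
    .id = "domain")
  wt <- wilcox.test(af_v, af_b, exact = FALSE)
  per_day <- vals |>
    dplyr::group_by(.data$domain, .data$day) |>
    dplyr::summarise(mean_af = mean(.data$af), n = dplyr::n(),
                     .groups = "drop")
  # arithmetic difference on the AF scale, plus the log-scale difference,
  # which is robust to the right skew of ratio data (zeros excluded)
  structure(
    list(summaries = summaries,
         diff_means = mean(af_v) - mean(af_b),
         diff_log_means = mean(log(af_v[af_v > 0])) -
           mean(log(af_b[af_b > 0])),
         statistic = unname(wt$statistic),
         p_value = wt$p.value,
         per_day = per_day,
         ratios = ratios),
    class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat("<domain_comparison> bacterial vs viral aerosolization factors\n")
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s n = %4d (%d taxa)  mean AF = %.3f  sd = %.3f\n",
                s$domain[i], s$n[i], s$n_taxa[i], s$mean[i], s$sd[i]))
  }
  cat(sprintf("  difference of means (virus - bacteria): %.3f\n", x$diff_means))
  cat(sprintf("  Wilcoxon rank-sum: W = %.1f, p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' @rdname compare_domains
#' @param x A `domain_comparison`.
#' @param ... Unused.
#' @export
tidy.domain_comparison <- function(x, ...) {
  x$summaries
}

#' @rdname compare_domains
#' @export
glance.domain_comparison <- function(x, ...) {
  tibble::tibble(diff_means = x$diff_means,
                 diff_log_means = x$diff_log_means,
                 statistic = x$statistic, p_value = x$p_value)
}
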