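#' Read a compartment particle/cell count table
#'
#' Comma- or tab-separated (detected from the header line) with columns
#' `entity` (`bacteria_cells` or `virus_particles`), `compartment` (`bulk`,
#' `ssml`, `aerosol`), `day`, `value` (concentration on a common x1e7 per-mL
#' scale), and optional `sd` on the same scale. One observation per
#' (entity, compartment, day).
#'
#' @param path Path to the counts file.
#' @return A tibble sorted by entity, compartment, day; empty files yield an
#'   empty tibble.
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    return(tibble::tibble(entity = character(), compartment = character(),
                          day = integer(), value = numeric(), sd = numeric()))
  }
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("entity", "compartment", "day", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("counts table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  df$day <- as.integer(df$day)
  if (any(df$value < 0, na.rm = TRUE)) abort("negative count value.")
  key <- paste(df$entity, df$compartment, df$day)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (entity, compartment, day): ",
                 key[duplicated(key)][1]))
  }
  bad_comp <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad_comp) > 0) {
    abort(paste0("unknown compartment(s): ", paste(bad_comp, collapse = ", ")))
  }
  df |>
    dplyr::select("entity", "compartment", "day", "value", "sd") |>
    dplyr::arrange(.data$entity, .data$compartment, .data$day)
}

#' Packaged virus-like-particle count fixture
#'
#' Loads the VLP microscopy counts (bulk, SSML and aerosol compartments over
#' a 36-day wave-channel bloom experiment, x1e7 vlp per mL) shipped with the
#' package.
#'
#' @return A counts tibble as from [read_counts()].
#' @export
vlp_counts <- function() {
  read_counts(system.file("extdata", "table1_vlp.csv", package = "aeroflux"))
}

lookup_obs <- function(counts, entity, compartment, day) {
  row <- counts[counts$entity == entity & counts$compartment == compartment &
                  counts$day == day, ]
  if (nrow(row) == 0) {
    abort(sprintf("no %s observation for %s on day %d", entity, compartment, day))
  }
  row
}

ratio_sd <- function(r, num_val, num_sd, den_val, den_sd, flow) {
  terms <- flow^2
  if (!is.na(num_sd) && !is.na(den_sd)) {
    terms <- terms + (num_sd / num_val)^2 + (den_sd / den_val)^2
  } else if (flow == 0) {
    return(NA_real_)
  }
  abs(r) * sqrt(terms)
}

#' Per-day compartment count ratio
#'
#' Divides the numerator compartment's concentration by the denominator's on
#' their common x1e7 per-mL scale. Uncertainty is propagated to first order
#' (delta method): `sd_r = r * sqrt((sd_n/n)^2 + (sd_d/d)^2 + flow^2)`, where
#' the extra relative `flow` term (default 10%) accounts for the aerosol
#' sampler's system flow variance and is applied only when the numerator
#' compartment is aerosol.
#'
#' @param counts Counts tibble from [read_counts()].
#' @param entity `"bacteria_cells"` or `"virus_particles"`.
#' @param numerator,denominator Compartment names.
#' @param day Experiment day (must be present in both series).
#' @param flow_variance Relative flow variance for aerosol numerators
#'   (default 0.10).
#' @return A one-row tibble: `day`, `numerator`, `denominator`, `ratio`,
#'   `sd`, `convention = "per_day"`.
#' @export
day_ratio <- function(counts, entity, numerator, denominator, day,
                      flow_variance = 0.10) {
  num <- lookup_obs(counts, entity, numerator, day)
  den <- lookup_obs(counts, entity, denominator, day)
  if (den$value == 0) abort("zero denominator count.")
  r <- num$value / den$value
  flow <- if (numerator == "aerosol") flow_variance else 0
  tibble::tibble(
    day = as.character(day), numerator = numerator, denominator = denominator,
    ratio = r,
    sd = ratio_sd(r, num$value, num$sd, den$value, den$sd, flow),
    convention = "per_day"
  )
}

#' Average compartment count ratio under two conventions
#'
#' `mean_of_ratios` averages the per-day ratios over days present in both
#' series (its s.d. is the propagated s.d. of that mean). `ratio_of_means`
#' divides the mean numerator concentration by the mean denominator
#' concentration, by default each over all of its own observed days
#' (`days = "all"`); `days = "common"` restricts both means to shared days.
#' The two conventions answer different questions and generally differ; they
#' coincide when the series are proportional.
#'
#' @inheritParams day_ratio
#' @param convention `"mean_of_ratios"` or `"ratio_of_means"`.
#' @param days For `ratio_of_means`: `"all"` (default) or `"common"`.
#' @return A one-row tibble with `day = "average"`.
#' @export
average_ratio <- function(counts, entity, numerator, denominator,
                          convention = c("mean_of_ratios", "ratio_of_means"),
                          days = c("all", "common"), flow_variance = 0.10) {
  convention <- match.arg(convention)
  days <- match.arg(days)
  num <- counts[counts$entity == entity & counts$compartment == numerator, ]
  den <- counts[counts$entity == entity & counts$compartment == denominator, ]
  if (nrow(num) == 0 || nrow(den) == 0) abort("empty count series.")
  common <- intersect(num$day, den$day)
  flow <- if (numerator == "aerosol") flow_variance else 0
  if (convention == "mean_of_ratios") {
    if (length(common) == 0) abort("no common day between the series.")
    per <- purrr::map_dfr(sort(common), function(d) {
      day_ratio(counts, entity, numerator, denominator, d, flow_variance)
    })
    sd_out <- if (all(!is.na(per$sd))) {
      sqrt(sum(per$sd^2)) / nrow(per)
    } else {
      NA_real_
    }
    tibble::tibble(day = "average", numerator = numerator,
                   denominator = denominator, ratio = mean(per$ratio),
                   sd = sd_out, convention = convention)
  } else {
    if (days == "common") {
      if (length(common) == 0) abort("no common day between the series.")
      num <- num[num$day %in% common, ]
      den <- den[den$day %in% common, ]
    }
    m_num <- mean(num$value); m_den <- mean(den$value)
    if (m_den == 0) abort("zero denominator mean.")
    r <- m_num / m_den
    sd_num <- if (all(!is.na(num$sd))) sqrt(sum(num$sd^2)) / nrow(num) else NA_real_
    sd_den <- if (all(!is.na(den$sd))) sqrt(sum(den$sd^2)) / nrow(den) else NA_real_
    tibble::tibble(day = "average", numerator = numerator,
                   denominator = denominator, ratio = r,
                   sd = ratio_sd(r, m_num, sd_num, m_den, sd_den, flow),
                   convention = convention)
  }
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of the
#' printed count-ratio tables), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
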