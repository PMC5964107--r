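#' Abundance-threshold filter configuration
#'
#' Two published variants of the low-abundance exclusion rule are supported.
#' A taxon is removed when either clause fires:
#' (1) any sample holds less than `min_fraction_any_sample` of the population,
#' or (2) at least `max_low_samples` samples hold less than `low_fraction`.
#'
#' The `"methods"` variant uses 0.001% / 0.01% with a 10-of-18-sample count;
#' the `"results"` variant uses 0.01% / 0.1% with "more than half of samples".
#' For studies with `n_samples != 18` the methods count scales as
#' `ceiling(10 * n / 18)` and the results count is `floor(n / 2) + 1`; both
#' can be overridden.
#'
#' @param variant `"methods"` (default) or `"results"`.
#' @param n_samples Number of samples the rule is evaluated over (default 18).
#' @param min_fraction_any_sample,low_fraction,max_low_samples Override the
#'   variant's thresholds. Fractions are on `[0, 1]` (0.01% = 1e-4).
#' @return A list of class `af_filter_config`.
#' @export
abundance_filter_config <- function(variant = c("methods", "results"),
                                    n_samples = 18,
                                    min_fraction_any_sample = NULL,
                                    low_fraction = NULL,
                                    max_low_samples = NULL) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    methods = list(min = 1e-5, low = 1e-4,
                   nlow = as.integer(ceiling(10 * n_samples / 18))),
    results = list(min = 1e-4, low = 1e-3,
                   nlow = as.integer(floor(n_samples / 2) + 1))
  )
  cfg <- list(
    variant = variant,
    n_samples = as.integer(n_samples),
    min_fraction_any_sample = min_fraction_any_sample %||% defaults$min,
    low_fraction = low_fraction %||% defaults$low,
    max_low_samples = as.integer(max_low_samples %||% defaults$nlow)
  )
  if (cfg$min_fraction_any_sample > cfg$low_fraction) {
    abort("min_fraction_any_sample must be <= low_fraction.")
  }
  if (cfg$min_fraction_any_sample < 0 || cfg$low_fraction > 1 ||
      cfg$max_low_samples < 0) {
    abort("filter thresholds out of range.")
  }
  structure(cfg, class = "af_filter_config")
}

#' Apply the abundance-threshold filter
#'
#' Removes taxa whose relative abundance falls below the configured
#' thresholds; see [abundance_filter_config()]. The retained matrix is NOT
#' renormalised: fractions keep their original per-sample denominators so the
#' removal of one taxon never changes another's enrichment ratios.
#'
#' @param x An `abund_matrix` in fractions mode.
#' @param config An `af_filter_config`; defaults to the methods variant sized
#'   to `ncol(x$values)`.
#' @return A list with `matrix` (retained `abund_matrix`) and `report`, a
#'   tibble with one row per (removed taxon, fired rule): `taxon_id`, `rule`
#'   (`"any_sample"` or `"low_samples"`), `statistic` (the minimum fraction,
#'   or the number of low samples).
#' @export
apply_abundance_filter <- function(x, config = NULL) {
  stopifnot(inherits(x, "abund_matrix"))
  if (x$mode != "fractions") {
    abort("abundance filter requires a fractions-mode matrix; run normalize_abundance() first.")
  }
  config <- config %||% abundance_filter_config(n_samples = ncol(x$values))
  stopifnot(inherits(config, "af_filter_config"))
  min_frac <- apply(x$values, 1, min)
  n_low <- rowSums(x$values < config$low_fraction)
  fire_any <- min_frac < config$min_fraction_any_sample
  fire_low <- n_low >= config$max_low_samples
  report <- dplyr::bind_rows(
    tibble::tibble(taxon_id = rownames(x$values)[fire_any],
                   rule = "any_sample",
                   statistic = unname(min_frac[fire_any])),
    tibble::tibble(taxon_id = rownames(x$values)[fire_low],
                   rule = "low_samples",
                   statistic = unname(as.numeric(n_low[fire_low])))
  )
  keep <- rownames(x$values)[!(fire_any | fire_low)]
  list(matrix = keep_taxa(x, keep), report = report)
}

#' Construct a genome coverage profile
#'
#' Intervals are 0-based half-open `[start, end)` positions on the
#' concatenated genome assembly; they are stored merged, sorted and
#' non-overlapping.
#'
#' @param taxon_id Taxon identifier the profile belongs to.
#' @param genome_length Total assembly length in bp (> 0).
#' @param starts,ends Integer vectors of interval bounds with
#'   `0 <= start < end <= genome_length`.
#' @return A list of class `coverage_profile`.
#' @export
coverage_profile <- function(taxon_id, genome_length, starts = integer(),
                             ends = integer()) {
  genome_length <- as.numeric(genome_length)
  if (length(genome_length) != 1 || genome_length <= 0) {
    abort("genome_length must be a single positive number.")
  }
  if (length(starts) != length(ends)) abort("starts/ends length mismatch.")
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (any(starts >= ends)) abort("intervals must satisfy start < end.")
  if (any(starts < 0) || any(ends > genome_length)) {
    abort("interval out of genome bounds.")
  }
  m <- merge_intervals(starts, ends)
  structure(list(taxon_id = taxon_id, genome_length = genome_length,
                 starts = m$starts, ends = m$ends),
            class = "coverage_profile")
}

merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) return(list(starts = numeric(), ends = numeric()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

#' Spatial coverage fraction of a genome
#'
#' The proportion of assembly positions covered by at least one mapped read:
#' total merged interval length over genome length.
#'
#' @param profile A `coverage_profile`.
#' @return A number in `[0, 1]`.
#' @export
coverage_fraction <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  sum(profile$ends - profile$starts) / profile$genome_length
}

#' Read a bedgraph file into a coverage profile
#'
#' Four whitespace-separated columns `chrom start end value`, 0-based
#' half-open. Intervals with `value > 0` are kept (depth is reduced to
#' covered/uncovered, since only the proportion of mapped positions is used)
#' and merged. Multi-sequence assemblies are concatenated with cumulative
#' offsets: pass `genome_length` as a named vector of per-sequence lengths in
#' concatenation order. A single unnamed length is accepted for single-chrom
#' files.
#'
#' @param path Path to the bedgraph file.
#' @param genome_length Single total length, or named vector of per-chrom
#'   lengths.
#' @param taxon_id Taxon id for the resulting profile (default: file name).
#' @return A `coverage_profile` over the concatenated assembly.
#' @export
read_bedgraph <- function(path, genome_length, taxon_id = NULL) {
  taxon_id <- taxon_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(
    read.table(path, header = FALSE,
               col.names = c("chrom", "start", "end", "value"),
               colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) NULL)
  if (is.null(df)) {  # empty file -> empty profile
    return(coverage_profile(taxon_id, sum(genome_length)))
  }
  if (any(df$start >= df$end)) abort("bedgraph interval with start >= end.")
  chroms <- unique(df$chrom)
  if (is.null(names(genome_length))) {
    if (length(genome_length) != 1 || length(chroms) > 1) {
      abort("multi-chrom bedgraph needs a named vector of per-chrom lengths.")
    }
    lengths <- setNames(genome_length, chroms)
  } else {
    missing <- setdiff(chroms, names(genome_length))
    if (length(missing) > 0) {
      abort(paste0("bedgraph chrom(s) without declared length: ",
                   paste(missing, collapse = ", ")))
    }
    lengths <- genome_length
  }
  offsets <- setNames(cumsum(c(0, as.numeric(lengths)))[seq_along(lengths)],
                      names(lengths))
  too_long <- df$end > lengths[df$chrom]
  if (any(too_long)) abort("bedgraph interval beyond declared chrom length.")
  cov <- df[df$value > 0, , drop = FALSE]
  coverage_profile(taxon_id, sum(lengths),
                   starts = cov$start + offsets[cov$chrom],
                   ends = cov$end + offsets[cov$chrom])
}

#' Apply the genome spatial-coverage filter
#'
#' Removes taxa whose reference genome has spatial coverage strictly below
#' `threshold` (default 0.1%): a genome at exactly the threshold is retained.
#' Taxa with no coverage profile cannot be coverage-tested; they are retained
#' and flagged `"no_reference"` in the report.
#'
#' @param x An `abund_matrix` (either mode).
#' @param profiles Named list of `coverage_profile`s (names = taxon ids), or a
#'   list whose elements carry their own `taxon_id`.
#' @param threshold Spatial-coverage cutoff in `(0, 1)`; default `0.001`.
#' @return A list with `matrix` (retained `abund_matrix`) and `report`
#'   (tibble: `taxon_id`, `rule` in `"low_coverage"`/`"no_reference"`,
#'   `statistic` = coverage fraction or NA).
#' @export
apply_coverage_filter <- function(x, profiles, threshold = 0.001) {
  stopifnot(inherits(x, "abund_matrix"))
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1).")
  if (is.null(names(profiles)) && length(profiles) > 0) {
    names(profiles) <- vapply(profiles, function(p) p$taxon_id, character(1))
  }
  ids <- rownames(x$values)
  has_profile <- ids %in% names(profiles)
  covfrac <- rep(NA_real_, length(ids))
  covfrac[has_profile] <- vapply(profiles[ids[has_profile]],
                                 coverage_fraction, numeric(1))
  removed <- has_profile & covfrac < threshold
  report <- dplyr::bind_rows(
    tibble::tibble(taxon_id = ids[removed], rule = "low_coverage",
                   statistic = covfrac[removed]),
    tibble::tibble(taxon_id = ids[!has_profile], rule = "no_reference",
                   statistic = NA_real_)
  )
  list(matrix = keep_taxa(x, ids[!removed]), report = report)
}
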