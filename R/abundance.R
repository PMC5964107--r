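#' Construct a taxon-by-sample abundance matrix
#'
#' The central data container: a non-negative taxon x sample matrix of read
#' counts or per-sample population fractions, together with a sample metadata
#' table locating each column in the study design (experiment day, compartment,
#' size fraction). Each sample column is one sequenced library, so a column is
#' always a single size fraction of a single compartment on a single day.
#'
#' @param values Numeric matrix, taxa in rows and samples in columns, with
#'   rownames giving taxon ids and colnames giving sample ids. No negative
#'   values.
#' @param samples Data frame with columns `sample_id`, `day` (integer >= 0),
#'   `compartment` (one of `"bulk"`, `"ssml"`, `"aerosol"`), `size_fraction`
#'   (one of `"f3000_200"` = 0.2-3 um, `"f200_25"` = 0.025-0.2 um). One row
#'   per column of `values`; `(day, compartment, size_fraction)` must be
#'   unique.
#' @param mode `"counts"` (raw reads) or `"fractions"` (columns sum to 1, or
#'   are all-zero and flagged).
#' @param taxa Optional data frame of taxon annotations with a `taxon_id`
#'   column covering the rownames of `values`.
#'
#' @return An object of class `abund_matrix`: a list with elements `values`,
#'   `samples` (tibble), `taxa` (tibble or NULL), `mode`, and `zero_samples`
#'   (character vector of all-zero sample ids, only meaningful in fractions
#'   mode).
#' @export
abundance_matrix <- function(values, samples, mode = c("counts", "fractions"),
                             taxa = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have taxon rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0("duplicate taxon_id: ",
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", ")))
  }
  if (any(values < 0)) abort("abundance values must be non-negative.")
  samples <- validate_sample_metadata(samples)
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("no metadata for sample(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  extra_meta <- setdiff(samples$sample_id, colnames(values))
  if (length(extra_meta) > 0) {
    abort(paste0("metadata names sample(s) absent from the table: ",
                 paste(extra_meta, collapse = ", ")))
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  zero_samples <- colnames(values)[colSums(values) == 0]
  if (mode == "fractions") {
    sums <- colSums(values)
    bad <- abs(sums - 1) > 1e-9 & sums != 0
    if (any(bad)) {
      abort(paste0("fractions-mode columns must sum to 1 (or be all-zero); ",
                   "offending sample(s): ",
                   paste(colnames(values)[bad], collapse = ", ")))
    }
  }
  if (!is.null(taxa)) {
    taxa <- tibble::as_tibble(taxa)
    if (!"taxon_id" %in% names(taxa)) abort("`taxa` needs a `taxon_id` column.")
    missing_tax <- setdiff(rownames(values), taxa$taxon_id)
    if (length(missing_tax) > 0) {
      abort(paste0("taxa table misses: ", paste(head(missing_tax, 5), collapse = ", ")))
    }
    taxa <- taxa[match(rownames(values), taxa$taxon_id), ]
  }
  structure(
    list(values = values, samples = samples, taxa = taxa, mode = mode,
         zero_samples = zero_samples),
    class = "abund_matrix"
  )
}

validate_sample_metadata <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "day", "compartment", "size_fraction")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample metadata missing column(s): ", paste(miss, collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$day <- as.integer(samples$day)
  if (any(is.na(samples$day)) || any(samples$day < 0)) {
    abort("`day` must be a non-negative integer.")
  }
  bad_comp <- setdiff(unique(samples$compartment), COMPARTMENTS)
  if (length(bad_comp) > 0) {
    abort(paste0("unknown compartment(s): ", paste(bad_comp, collapse = ", ")))
  }
  bad_sf <- setdiff(unique(samples$size_fraction), SIZE_FRACTIONS)
  if (length(bad_sf) > 0) {
    abort(paste0("unknown size_fraction(s): ", paste(bad_sf, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in metadata.")
  key <- paste(samples$day, samples$compartment, samples$size_fraction)
  if (anyDuplicated(key)) {
    abort("duplicate (day, compartment, size_fraction) in metadata.")
  }
  samples
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("<abund_matrix> %d taxa x %d samples (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat(sprintf("  days: %s\n", paste(sort(unique(x$samples$day)), collapse = ", ")))
  cat(sprintf("  compartments: %s; size fractions: %s\n",
              paste(unique(x$samples$compartment), collapse = "/"),
              paste(unique(x$samples$size_fraction), collapse = "/")))
  if (length(x$zero_samples) > 0) {
    cat(sprintf("  all-zero samples: %s\n", paste(x$zero_samples, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an abundance matrix into long format
#'
#' @param x An `abund_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (taxon, sample): `taxon_id`, `sample_id`,
#'   `day`, `compartment`, `size_fraction`, `value`.
#' @export
tidy.abund_matrix <- function(x, ...) {
  long <- tibble::tibble(
    taxon_id = rep(rownames(x$values) %||% character(0),
                   times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Read a taxon abundance table and its sample metadata
#'
#' The abundance table is tab-separated with a `taxon_id` first column and one
#' column per sample; the metadata table is tab-separated with columns
#' `sample_id`, `day`, `compartment`, `size_fraction`. Sample ids present in
#' one file but not the other are an error.
#'
#' @param path Path to the abundance TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An `abund_matrix` in counts mode, taxa in file order.
#' @export
read_abundance_table <- function(path, metadata_path) {
  # base parser: correctly rounded at full double precision, so the
  # write -> read cycle is value-identical
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character"))
  if (names(tab)[1] != "taxon_id") {
    abort("abundance table must have `taxon_id` as its first column.")
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  values <- vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  if (nrow(tab) == 1) values <- matrix(values, nrow = 1, dimnames = list(NULL, names(tab)[-1]))
  if (anyNA(values)) abort("abundance values must be numeric.")
  rownames(values) <- tab$taxon_id
  abundance_matrix(values, meta, mode = "counts")
}

#' Write an abundance table to TSV
#'
#' Values are written with 17 significant digits so that a written table
#' re-read with [read_abundance_table()] is value-identical (exact decimal
#' round trip of doubles).
#'
#' @param x An `abund_matrix`.
#' @param path Output path for the abundance TSV.
#' @param metadata_path Optional output path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "abund_matrix"))
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    ifelse(v == round(v) & abs(v) < 1e15, sprintf("%.0f", v), out)
  }
  df <- tibble::as_tibble(apply(x$values, 2, fmt, simplify = FALSE))
  df <- dplyr::bind_cols(tibble::tibble(taxon_id = rownames(x$values)), df)
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_tsv(x$samples, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a taxon lineage table
#'
#' Tab-separated with columns `taxon_id`, `name`, `domain` (bacteria, virus,
#' other), `class`, `order`, `family`, and `enveloped` (logical, viruses
#' only; empty elsewhere).
#'
#' @param path Path to the lineage TSV.
#' @return A tibble.
#' @export
read_lineage <- function(path) {
  lin <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           enveloped = readr::col_logical(),
                           .default = readr::col_character()))
  if (anyDuplicated(lin$taxon_id)) abort("duplicate taxon_id in lineage table.")
  if ("enveloped" %in% names(lin) && "domain" %in% names(lin)) {
    bad <- !is.na(lin$enveloped) & lin$domain != "virus"
    if (any(bad)) abort("`enveloped` may only be set for viruses.")
  }
  lin
}

#' Normalise counts to per-sample population fractions
#'
#' Divides each sample column by its total so that fractions are relative
#' abundances on `[0, 1]`. Because every sample column is one size fraction of
#' one compartment, per-column normalisation is normalisation within size
#' fraction — the convention under which aerosolization factors are defined.
#' Set `group = "day_compartment"` to normalise against the combined total of
#' both size fractions of the same (day, compartment) instead.
#'
#' All-zero columns are left at zero and flagged in `zero_samples`. Fractions
#' are invariant to rescaling any column's counts (sequencing-depth
#' invariance), which is what makes downstream enrichment ratios depth-free.
#'
#' @param x An `abund_matrix` in counts mode.
#' @param group `"sample"` (default: each column by its own total) or
#'   `"day_compartment"` (columns sharing day and compartment by their joint
#'   total).
#' @return An `abund_matrix` in fractions mode.
#' @export
normalize_abundance <- function(x, group = c("sample", "day_compartment")) {
  stopifnot(inherits(x, "abund_matrix"))
  group <- match.arg(group)
  if (x$mode == "fractions") {
    abort("matrix is already in fractions mode; refusing to renormalise.")
  }
  values <- x$values
  if (group == "sample") {
    totals <- colSums(values)
  } else {
    key <- paste(x$samples$day, x$samples$compartment)
    totals <- stats::ave(colSums(values), key, FUN = sum)
  }
  nz <- totals > 0
  values[, nz] <- sweep(values[, nz, drop = FALSE], 2, totals[nz], `/`)
  out <- abundance_matrix(values, x$samples, mode = "counts", taxa = x$taxa)
  out$mode <- "fractions"
  out$zero_samples <- colnames(values)[colSums(x$values) == 0]
  if (group == "day_compartment") {
    # columns are fractions of the pooled (day, compartment) total, so a
    # single column need not sum to 1; keep the container honest
    attr(out, "fraction_group") <- "day_compartment"
  } else {
    sums <- colSums(values)
    stopifnot(all(abs(sums[sums != 0] - 1) <= 1e-9))
  }
  out
}

#' Subset an abundance matrix by taxa
#'
#' Keeps the stated taxa without renormalising columns: fractions keep their
#' original denominators, so remaining taxa's values (and hence their
#' enrichment ratios) are unchanged by the removal of others.
#'
#' @param x An `abund_matrix`.
#' @param taxon_ids Character vector of taxa to keep, in `x`'s row order.
#' @return An `abund_matrix` with the same mode.
#' @export
keep_taxa <- function(x, taxon_ids) {
  stopifnot(inherits(x, "abund_matrix"))
  keep <- rownames(x$values) %in% taxon_ids
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  if (!is.null(x$taxa)) out$taxa <- x$taxa[keep, , drop = FALSE]
  out
}
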