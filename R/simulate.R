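#' Configuration for the synthetic mesocosm generator
#'
#' Defines a simulated bloom experiment with the statistical structure the
#' enrichment analysis assumes: a bacterial and a viral community observed in
#' three compartments (bulk, SSML, aerosol) on a set of sampling days, two
#' size fractions (bacteria in 0.2-3 um, viruses in 0.025-0.2 um), taxon-
#' specific aerosolization (`alpha`) and surface-partitioning (`sigma`)
#' coefficients, bloom dynamics, and multinomial sequencing noise.
#'
#' The latent chain mirrors the enrichment model: SSML fractions are bulk
#' fractions reweighted by `sigma` and renormalised; aerosol fractions are
#' SSML fractions reweighted by the day's effective `alpha` and renormalised
#' (`aerosol_mode = "bulk"` reweights bulk fractions instead, emulating
#' jet-drop transfer of subsurface water). Intermittent taxa have `alpha`
#' inverted (log-flipped) on a random subset of days; the subset size is
#' binomial with success probability `intermittent_flip_prob`, clamped so
#' both states occur at least twice, making intended intermittency observable
#' in the latent signal.
#'
#' @param n_bacteria,n_viruses Community sizes (default 50 and 20).
#' @param days Sampling days, strictly increasing (default
#'   `c(8, 13, 18, 23, 28, 34)`: six time points across two bloom peaks).
#' @param read_depth Reads per sample for multinomial sampling (default 1e5).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param alpha_meanlog,alpha_sdlog Log-normal hyperparameters of the
#'   aerosolization coefficient (default meanlog 0, sdlog 0.8, spanning
#'   roughly 0.2-5).
#' @param sigma_meanlog,sigma_sdlog Log-normal hyperparameters of the SSML
#'   partition coefficient (default 0, 0.5).
#' @param constitutive_fraction Probability a taxon is a constitutive (rather
#'   than intermittent) aerosolizer (default 0.7).
#' @param intermittent_flip_prob Per-day probability of the alpha inversion
#'   for intermittent taxa (default 0.5).
#' @param bloom_centers,bloom_widths,bloom_amplitudes Two-pulse Gaussian
#'   bloom shape on log abundance (defaults: peaks at days 13 and 28).
#' @param bloom_response_sd S.d. of per-taxon bloom responsiveness.
#' @param base_abund_sdlog S.d. of per-taxon baseline log abundance.
#' @param envelope_effect Multiplier on `alpha` for lipid-enveloped viruses
#'   (default 2: enveloped viruses aerosolize more readily).
#' @param enveloped_fraction Fraction of viruses drawn from enveloped
#'   families (default 0.4).
#' @param viral_alpha_multiplier Global multiplier on viral `alpha` (default
#'   1; values < 1 plant domain-level depressed viral aerosolization).
#' @param class_effects Optional named multipliers on `alpha` by bacterial
#'   class, planting class-structured aerosolization.
#' @param background_fraction Fraction of each community's bulk population
#'   made of a single unannotated background pseudo-taxon (domain `"other"`,
#'   `alpha = sigma = 1`); default 0.5. Metagenomic classifiers annotate only
#'   a minority of environmental reads, and this unannotated mass is what
#'   keeps domain-wide aerosolization shifts identifiable: in a fully
#'   annotated (closed) community a global multiplier on `alpha` cancels in
#'   the compositional renormalisation. Set to 0 for a closed community.
#' @param aerosol_mode `"ssml"` (default; film-drop pathway) or `"bulk"`
#'   (jet-drop pathway).
#' @param count_bulk_base Named baseline bulk concentrations (x1e7 per mL)
#'   for `bacteria_cells` and `virus_particles` used by [simulate_counts()].
#' @param count_noise_sdlog Log-normal observation noise of simulated counts.
#' @param aerosol_transfer Bulk-water-equivalent transfer factor from SSML
#'   mass to aerosol mass for simulated counts.
#' @param flow_variance Relative aerosol flow variance (default 0.10).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_bacteria = 50, n_viruses = 20,
                              days = c(8L, 13L, 18L, 23L, 28L, 34L),
                              read_depth = 1e5, seed = 1,
                              alpha_meanlog = 0, alpha_sdlog = 0.8,
                              sigma_meanlog = 0, sigma_sdlog = 0.5,
                              constitutive_fraction = 0.7,
                              intermittent_flip_prob = 0.5,
                              bloom_centers = c(13, 28),
                              bloom_widths = c(4, 4),
                              bloom_amplitudes = c(1, 1.5),
                              bloom_response_sd = 0.5,
                              base_abund_sdlog = 1,
                              envelope_effect = 2,
                              enveloped_fraction = 0.4,
                              viral_alpha_multiplier = 1,
                              class_effects = NULL,
                              background_fraction = 0.5,
                              aerosol_mode = c("ssml", "bulk"),
                              count_bulk_base = c(bacteria_cells = 0.1,
                                                  virus_particles = 2),
                              count_noise_sdlog = 0.1,
                              aerosol_transfer = 1,
                              flow_variance = 0.10) {
  aerosol_mode <- match.arg(aerosol_mode)
  days <- as.integer(days)
  if (length(days) < 1 || any(diff(days) <= 0)) {
    abort("`days` must be strictly increasing.")
  }
  if (n_bacteria + n_viruses < 1) abort("need at least one taxon.")
  if (read_depth < 1) abort("read_depth must be positive.")
  stopifnot(alpha_sdlog >= 0, sigma_sdlog >= 0,
            background_fraction >= 0, background_fraction < 1,
            constitutive_fraction >= 0, constitutive_fraction <= 1,
            intermittent_flip_prob >= 0, intermittent_flip_prob <= 1,
            length(bloom_centers) == length(bloom_widths),
            length(bloom_centers) == length(bloom_amplitudes))
  structure(as.list(environment()), class = "sim_config")
}

bloom_shape <- function(days, config) {
  out <- numeric(length(days))
  for (k in seq_along(config$bloom_centers)) {
    out <- out + config$bloom_amplitudes[k] *
      exp(-(days - config$bloom_centers[k])^2 / (2 * config$bloom_widths[k]^2))
  }
  out
}

BACTERIAL_CLASSES <- list(
  Actinobacteria = c("Corynebacteriales", "Micrococcales"),
  Flavobacteriia = "Flavobacteriales",
  Gammaproteobacteria = c("Alteromonadales", "Pseudomonadales"),
  Alphaproteobacteria = c("Rhodobacterales", "Sphingomonadales")
)
VIRAL_FAMILIES <- list(
  non_enveloped = c("Myoviridae", "Podoviridae", "Siphoviridae"),
  enveloped = c("Herpesviridae", "Polydnaviridae")
)

draw_taxa <- function(config) {
  nb <- config$n_bacteria; nv <- config$n_viruses
  n <- nb + nv
  domain <- rep(c("bacteria", "virus"), c(nb, nv))
  taxon_id <- c(sprintf("b%03d", seq_len(nb)), sprintf("v%03d", seq_len(nv)))

  cls <- ord <- fam <- rep(NA_character_, n)
  env <- rep(NA, n)
  if (nb > 0) {
    cls[1:nb] <- sample(names(BACTERIAL_CLASSES), nb, replace = TRUE)
    ord[1:nb] <- vapply(cls[1:nb], function(cl) {
      ords <- BACTERIAL_CLASSES[[cl]]
      ords[sample.int(length(ords), 1)]
    }, character(1))
  }
  if (nv > 0) {
    env[nb + seq_len(nv)] <- stats::runif(nv) < config$enveloped_fraction
    fam[nb + seq_len(nv)] <- vapply(env[nb + seq_len(nv)], function(e) {
      pool <- if (e) VIRAL_FAMILIES$enveloped else VIRAL_FAMILIES$non_enveloped
      pool[sample.int(length(pool), 1)]
    }, character(1))
    cls[nb + seq_len(nv)] <- "Viruses"
    ord[nb + seq_len(nv)] <- ifelse(
      fam[nb + seq_len(nv)] %in% VIRAL_FAMILIES$non_enveloped,
      "Caudovirales", "Herpesvirales")
  }

  alpha <- rlnorm(n, config$alpha_meanlog, config$alpha_sdlog)
  sigma <- rlnorm(n, config$sigma_meanlog, config$sigma_sdlog)
  alpha[domain == "virus"] <- alpha[domain == "virus"] *
    config$viral_alpha_multiplier
  alpha[which(env)] <- alpha[which(env)] * config$envelope_effect
  if (!is.null(config$class_effects)) {
    hit <- cls %in% names(config$class_effects) & domain == "bacteria"
    alpha[hit] <- alpha[hit] * unlist(config$class_effects)[cls[hit]]
  }

  constitutive <- stats::runif(n) < config$constitutive_fraction
  intended_label <- ifelse(constitutive,
                           ifelse(alpha > 1, "constitutive_enriched",
                                  "constitutive_depleted"),
                           "intermittent")
  n_days <- length(config$days)
  flip_days <- lapply(seq_len(n), function(i) {
    if (constitutive[i]) return(integer(0))
    k <- rbinom(1, n_days, config$intermittent_flip_prob)
    k <- max(min(k, max(n_days - 2, 1)), min(2, n_days - 1))
    sort(sample(config$days, k))
  })

  out <- tibble::tibble(
    taxon_id = taxon_id,
    name = paste0("Synthetic ", ifelse(domain == "bacteria", "bacterium ",
                                       "virus "), taxon_id),
    domain = domain, class = cls, order = ord, family = fam, enveloped = env,
    community = ifelse(domain == "bacteria", "f3000_200", "f200_25"),
    background = FALSE,
    alpha = alpha, sigma = sigma, intended_label = intended_label,
    flip_days = flip_days,
    base_log_abund = rnorm(n, 0, config$base_abund_sdlog),
    bloom_response = rnorm(n, 0, config$bloom_response_sd)
  )
  if (config$background_fraction > 0) {
    bg <- tibble::tibble(
      taxon_id = c(if (nb > 0) "b000_unannotated",
                   if (nv > 0) "v000_unannotated"),
      name = "Unannotated background",
      domain = "other", class = NA_character_, order = NA_character_,
      family = NA_character_, enveloped = NA,
      community = c(if (nb > 0) "f3000_200", if (nv > 0) "f200_25"),
      background = TRUE,
      alpha = 1, sigma = 1, intended_label = "background",
      flip_days = list(integer(0))[rep(1, (nb > 0) + (nv > 0))],
      base_log_abund = 0, bloom_response = 0
    )
    out <- dplyr::bind_rows(out, bg)
  }
  out
}

latent_fractions <- function(taxa, config) {
  shape <- bloom_shape(config$days, config)
  communities <- split(seq_len(nrow(taxa)), taxa$community)
  lat <- list()
  masses <- list()
  for (com in names(communities)) {
    idx <- communities[[com]]
    sub <- taxa[idx, ]
    entity <- if (com == "f3000_200") "bacteria_cells" else "virus_particles"
    bulk_base <- unname(config$count_bulk_base[entity])
    bf <- config$background_fraction
    for (j in seq_along(config$days)) {
      d <- config$days[j]
      w <- exp(sub$base_log_abund + sub$bloom_response * shape[j])
      if (any(sub$background) && sum(!sub$background) > 0) {
        # background holds a fixed share of the bulk population each day
        w[sub$background] <- bf / (1 - bf) * sum(w[!sub$background])
      }
      bulk <- w / sum(w)
      s_un <- bulk * sub$sigma
      ssml <- s_un / sum(s_un)
      flipped <- vapply(sub$flip_days, function(f) d %in% f, logical(1))
      a_eff <- ifelse(flipped, 1 / sub$alpha, sub$alpha)
      src <- if (config$aerosol_mode == "ssml") ssml else bulk
      a_un <- src * a_eff
      aero <- a_un / sum(a_un)
      lat[[length(lat) + 1]] <- tibble::tibble(
        taxon_id = rep(sub$taxon_id, 3),
        day = d,
        compartment = rep(COMPARTMENTS, each = nrow(sub)),
        fraction = c(bulk, ssml, aero),
        alpha_eff = rep(a_eff, 3)
      )
      bulk_mass <- bulk_base * exp(0.3 * shape[j])
      ssml_mass <- bulk_mass * sum(bulk * sub$sigma)
      aero_mass <- config$aerosol_transfer * bulk_mass *
        sum(bulk * sub$sigma * a_eff)
      masses[[length(masses) + 1]] <- tibble::tibble(
        entity = entity, day = d, compartment = COMPARTMENTS,
        mass = c(bulk_mass, ssml_mass, aero_mass)
      )
    }
  }
  list(latent = dplyr::bind_rows(lat), masses = dplyr::bind_rows(masses))
}

#' Simulate a synthetic mesocosm metagenomic data set
#'
#' Generates a counts-mode abundance matrix over 3 compartments x `days` x 2
#' size fractions (bacteria in the 0.2-3 um fraction, viruses in the
#' 0.025-0.2 um fraction), a lineage table, and the ground truth used to
#' build it. Observed counts are multinomial draws of `read_depth` reads per
#' sample from the latent compartment fractions, modelling compositional
#' sequencing; all randomness comes from a single stream seeded with
#' `config$seed`, so output is bit-identical for a fixed seed.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list: `abundance` (`abund_matrix`, counts mode), `lineage`
#'   (tibble), `truth` (list with per-taxon parameters `taxa`, latent
#'   per-day compartment `fractions`, and compartment `masses`).
#' @export
simulate_mesocosm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  taxa <- draw_taxa(config)
  lat <- latent_fractions(taxa, config)

  samples <- tidyr::expand_grid(
    day = config$days, compartment = COMPARTMENTS,
    size_fraction = sort(unique(taxa$community), decreasing = TRUE)
  ) |>
    dplyr::mutate(sample_id = sprintf("d%02d_%s_%s", .data$day,
                                      .data$compartment, .data$size_fraction))
  values <- matrix(0, nrow = nrow(taxa), ncol = nrow(samples),
                   dimnames = list(taxa$taxon_id, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    sf <- samples$size_fraction[i]
    ids <- taxa$taxon_id[taxa$community == sf]
    pr <- lat$latent |>
      dplyr::filter(.data$day == samples$day[i],
                    .data$compartment == samples$compartment[i],
                    .data$taxon_id %in% ids)
    pr <- pr[match(ids, pr$taxon_id), ]
    values[ids, i] <- rmultinom(1, size = config$read_depth,
                                prob = pr$fraction)[, 1]
  }
  lineage <- taxa |>
    dplyr::select("taxon_id", "name", "domain", "class", "order", "family",
                  "enveloped")
  abundance <- abundance_matrix(values, samples, mode = "counts",
                                taxa = lineage)
  list(abundance = abundance, lineage = lineage,
       truth = list(taxa = taxa, fractions = lat$latent, masses = lat$masses))
}

#' Simulate compartment particle/cell count series
#'
#' Produces per-day bulk, SSML and aerosol total concentrations consistent
#' with the latent compartment masses underlying [simulate_mesocosm()] for
#' the same configuration, with multiplicative log-normal observation noise
#' and an extra aerosol flow-variance term. The reported `sd` column carries
#' the relative noise level on the value scale.
#'
#' @param config A `sim_config`.
#' @return A counts tibble as from [read_counts()].
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  taxa <- draw_taxa(config)
  lat <- latent_fractions(taxa, config)
  lat$masses |>
    dplyr::mutate(
      rel_sd = sqrt(config$count_noise_sdlog^2 +
                      ifelse(.data$compartment == "aerosol",
                             config$flow_variance^2, 0)),
      value = .data$mass * rlnorm(dplyr::n(), 0, config$count_noise_sdlog) *
        ifelse(.data$compartment == "aerosol",
               rlnorm(dplyr::n(), 0, config$flow_variance), 1),
      sd = .data$value * .data$rel_sd
    ) |>
    dplyr::select("entity", "compartment", "day", "value", "sd") |>
    dplyr::arrange(.data$entity, .data$compartment, .data$day)
}

#' Simulate a read-coverage profile for one genome
#'
#' Places `round(fraction * read_depth)` reads of length `read_length`
#' uniformly on a genome of `genome_length` bp and returns the merged
#' covered intervals. The expected coverage fraction follows the occupancy
#' approximation `1 - (1 - read_length / genome_length)^n`.
#'
#' @param fraction Taxon abundance fraction in `[0, 1]`.
#' @param genome_length Genome length in bp.
#' @param read_depth Total reads in the sample.
#' @param read_length Read length in bp (default 150).
#' @param seed Optional seed (omit to use the current RNG stream).
#' @param taxon_id Id for the profile.
#' @return A `coverage_profile`.
#' @export
simulate_coverage <- function(fraction, genome_length, read_depth,
                              read_length = 150, seed = NULL,
                              taxon_id = "sim") {
  stopifnot(fraction >= 0, fraction <= 1)
  if (read_length > genome_length) abort("read_length exceeds genome_length.")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fraction * read_depth)
  if (n == 0) return(coverage_profile(taxon_id, genome_length))
  starts <- sample.int(genome_length - read_length + 1, n, replace = TRUE) - 1
  coverage_profile(taxon_id, genome_length, starts, starts + read_length)
}

#' Write a simulated data set to plain-text files
#'
#' Writes the abundance TSV, sample metadata TSV, lineage TSV, counts CSV
#' and ground-truth TSV for a simulated mesocosm into a directory.
#'
#' @param sim Result of [simulate_mesocosm()].
#' @param dir Output directory (created if missing).
#' @param counts Optional counts tibble from [simulate_counts()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, counts = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_table(sim$abundance, file.path(dir, "abundance.tsv"),
                        file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$lineage, file.path(dir, "lineage.tsv"), progress = FALSE)
  truth <- sim$truth$taxa |>
    dplyr::mutate(flip_days = vapply(.data$flip_days, paste,
                                     character(1), collapse = ","))
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  if (!is.null(counts)) {
    readr::write_csv(counts, file.path(dir, "counts.csv"), progress = FALSE)
  }
  invisible(dir)
}
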