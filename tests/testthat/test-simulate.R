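test_that("simulation is bit-identical for a fixed seed", {
  cfg <- simulation_config(n_bacteria = 10, n_viruses = 5, read_depth = 1e4,
                           seed = 13)
  a <- simulate_mesocosm(cfg)
  b <- simulate_mesocosm(cfg)
  expect_identical(a$abundance$values, b$abundance$values)
  expect_equal(a$truth$taxa, b$truth$taxa)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  # and different for a different seed
  c_ <- simulate_mesocosm(simulation_config(n_bacteria = 10, n_viruses = 5,
                                            read_depth = 1e4, seed = 14))
  expect_false(identical(a$abundance$values, c_$abundance$values))
})

test_that("sample design covers compartments, days, and size fractions", {
  cfg <- simulation_config(n_bacteria = 5, n_viruses = 5, read_depth = 1000,
                           seed = 1)
  sim <- simulate_mesocosm(cfg)
  s <- sim$abundance$samples
  expect_identical(nrow(s), 3L * 6L * 2L)
  expect_setequal(unique(s$compartment), c("bulk", "ssml", "aerosol"))
  expect_setequal(unique(s$size_fraction), c("f3000_200", "f200_25"))
  # every sample carries exactly read_depth reads
  expect_true(all(colSums(sim$abundance$values) == cfg$read_depth))
  # bacteria live in the large fraction, viruses in the small one
  lin <- sim$lineage
  bact <- lin$taxon_id[lin$domain == "bacteria"]
  small_cols <- s$sample_id[s$size_fraction == "f200_25"]
  expect_true(all(sim$abundance$values[bact, small_cols] == 0))
})

test_that("latent compartment fractions are proper distributions", {
  cfg <- simulation_config(n_bacteria = 8, n_viruses = 4, read_depth = 1000,
                           seed = 3)
  sim <- simulate_mesocosm(cfg)
  sums <- sim$truth$fractions |>
    dplyr::group_by(.data$day, .data$compartment,
                    in_small = grepl("^v", .data$taxon_id)) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("a single-taxon community has unit fractions and unit AFs", {
  cfg <- simulation_config(n_bacteria = 1, n_viruses = 0,
                           background_fraction = 0, read_depth = 1000,
                           seed = 2)
  sim <- simulate_mesocosm(cfg)
  fr <- normalize_abundance(sim$abundance)
  expect_true(all(fr$values == 1))
  rec <- compute_enrichment(fr)
  expect_true(all(rec$af_bulk == 1 & rec$af_ssml == 1 & rec$sb == 1))
})

test_that("a neutral community yields AFs centred on 1", {
  # all alpha and sigma exactly 1: no envelope boost either
  cfg <- simulation_config(n_bacteria = 30, n_viruses = 10,
                           alpha_sdlog = 0, sigma_sdlog = 0,
                           envelope_effect = 1,
                           read_depth = 1e6, seed = 5)
  sim <- simulate_mesocosm(cfg)
  # all latent compartment fractions coincide
  wide <- tidyr::pivot_wider(sim$truth$fractions |>
                               dplyr::select(-"alpha_eff"),
                             names_from = "compartment",
                             values_from = "fraction")
  expect_equal(wide$ssml, wide$bulk, tolerance = 1e-12)
  expect_equal(wide$aerosol, wide$bulk, tolerance = 1e-12)
  rec <- compute_enrichment(normalize_abundance(sim$abundance))
  af <- c(rec$af_bulk[rec$af_bulk_flag == "ok"],
          rec$af_ssml[rec$af_ssml_flag == "ok"])
  expect_lt(abs(mean(log(af[af > 0]))), 0.05)
})

test_that("planted envelope and class effects are recovered in group means", {
  cfg <- simulation_config(n_bacteria = 30, n_viruses = 30, seed = 17,
                           envelope_effect = 3,
                           constitutive_fraction = 1,
                           class_effects = c(Actinobacteria = 4,
                                             Flavobacteriia = 0.25))
  sim <- simulate_mesocosm(cfg)
  rec <- compute_enrichment(normalize_abundance(sim$abundance))
  ge <- group_aggregate(rec, sim$lineage, group_by = "envelope")
  expect_gt(ge$mean_af[ge$group == "enveloped"],
            ge$mean_af[ge$group == "non_enveloped"])
  gc <- group_aggregate(rec, sim$lineage, group_by = "class")
  expect_gt(gc$mean_af[gc$group == "Actinobacteria"],
            gc$mean_af[gc$group == "Flavobacteriia"])
})

test_that("intended temporal labels are observable in the latent alphas", {
  cfg <- simulation_config(n_bacteria = 20, n_viruses = 10, seed = 23,
                           constitutive_fraction = 0.5)
  sim <- simulate_mesocosm(cfg)
  truth <- sim$truth$taxa
  inter <- truth$taxon_id[truth$intended_label == "intermittent"]
  expect_gt(length(inter), 0)
  # every intermittent taxon flips on 2..4 of the 6 days
  nflips <- lengths(truth$flip_days[match(inter, truth$taxon_id)])
  expect_true(all(nflips >= 2 & nflips <= 4))
  # constitutive taxa never flip
  cons <- truth$intended_label != "intermittent"
  expect_true(all(lengths(truth$flip_days[cons]) == 0))
})

test_that("simulated counts reproduce latent compartment ratios when noiseless", {
  cfg <- simulation_config(n_bacteria = 10, n_viruses = 5, seed = 7,
                           count_noise_sdlog = 0, flow_variance = 0)
  counts <- simulate_counts(cfg)
  sim <- simulate_mesocosm(cfg)
  masses <- sim$truth$masses
  d <- cfg$days[3]
  latent <- masses$mass[masses$entity == "virus_particles" &
                          masses$compartment == "aerosol" & masses$day == d] /
    masses$mass[masses$entity == "virus_particles" &
                  masses$compartment == "bulk" & masses$day == d]
  got <- day_ratio(counts, "virus_particles", "aerosol", "bulk", d,
                   flow_variance = 0)
  expect_equal(got$ratio, latent)
  # neutral community: SSML enrichment of counts is exactly 1
  cfg_n <- simulation_config(n_bacteria = 10, n_viruses = 5, seed = 7,
                             alpha_sdlog = 0, sigma_sdlog = 0,
                             count_noise_sdlog = 0, flow_variance = 0)
  cn <- simulate_counts(cfg_n)
  expect_equal(average_ratio(cn, "bacteria_cells", "ssml", "bulk",
                             "mean_of_ratios")$ratio, 1)
})

test_that("noisy simulated counts stay near the latent ratio", {
  cfg <- simulation_config(n_bacteria = 10, n_viruses = 5, seed = 19,
                           count_noise_sdlog = 0.1)
  counts <- simulate_counts(cfg)
  sim <- simulate_mesocosm(cfg)
  m <- sim$truth$masses |>
    dplyr::filter(.data$entity == "bacteria_cells") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "mass")
  latent_avg <- mean(m$ssml / m$bulk)
  got <- average_ratio(counts, "bacteria_cells", "ssml", "bulk",
                       "mean_of_ratios")
  # ~0.14 relative noise per day ratio, averaged over 6 days
  expect_lt(abs(got$ratio - latent_avg), 3 * latent_avg * 0.14 / sqrt(6))
})

test_that("simulated read coverage matches the occupancy approximation", {
  expect_equal(coverage_fraction(
    simulate_coverage(0, 1000, 1e4, seed = 1)), 0)
  expect_equal(coverage_fraction(
    simulate_coverage(1e-4, 10000, 1e4, read_length = 150, seed = 1)), 0.015)
  expect_error(simulate_coverage(0.5, 100, 1000, read_length = 150), "exceeds")

  set.seed(33)
  L <- 5000; n_reads <- 40; rl <- 100
  cf <- replicate(200, {
    coverage_fraction(simulate_coverage(n_reads / 1e4, L, 1e4,
                                        read_length = rl))
  })
  expected <- 1 - (1 - rl / L)^n_reads
  expect_lt(abs(mean(cf) - expected), 0.02)
})

test_that("written simulation files are faithful plain text", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_bacteria = 6, n_viruses = 3, read_depth = 5000,
                           seed = 29)
  sim <- simulate_mesocosm(cfg)
  write_simulation(sim, dir, counts = simulate_counts(cfg))
  back <- read_abundance_table(file.path(dir, "abundance.tsv"),
                               file.path(dir, "metadata.tsv"))
  expect_identical(back$values, sim$abundance$values)
  lin <- read_lineage(file.path(dir, "lineage.tsv"))
  expect_identical(lin$taxon_id, sim$lineage$taxon_id)
  expect_identical(nrow(read_counts(file.path(dir, "counts.csv"))), 36L)
})
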