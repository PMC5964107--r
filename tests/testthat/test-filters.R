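test_that("filter configs encode both published rule variants", {
  m <- abundance_filter_config("methods")
  expect_equal(m$min_fraction_any_sample, 1e-5)
  expect_equal(m$low_fraction, 1e-4)
  expect_equal(m$max_low_samples, 10L)
  r <- abundance_filter_config("results")
  expect_equal(r$min_fraction_any_sample, 1e-4)
  expect_equal(r$low_fraction, 1e-3)
  expect_equal(r$max_low_samples, 10L)  # "more than half" of 18
  # scaling to other designs
  expect_equal(abundance_filter_config("methods", n_samples = 36)$max_low_samples, 20L)
  expect_equal(abundance_filter_config("results", n_samples = 11)$max_low_samples, 6L)
  expect_error(abundance_filter_config(min_fraction_any_sample = 0.5,
                                       low_fraction = 0.1), "<=")
})

test_that("abundance filter applies both clauses and reports the firing rule", {
  cfg <- abundance_filter_config("methods")
  v <- rbind(
    dips_once   = c(5e-6, rep(1e-3, 17)),          # any-sample clause
    often_low   = c(rep(5e-5, 10), rep(1e-3, 8)),  # low-samples clause (10 >= 10)
    nine_low    = c(rep(5e-5, 9), rep(1e-3, 9)),   # 9 low samples: retained
    healthy     = rep(2e-3, 18)
  )
  fr <- fractions_matrix(v, mesocosm_design())
  res <- apply_abundance_filter(fr, cfg)
  expect_setequal(setdiff(rownames(v), rownames(res$matrix$values)),
                  c("dips_once", "often_low"))
  expect_equal(res$report$rule[res$report$taxon_id == "dips_once"], "any_sample")
  expect_equal(res$report$rule[res$report$taxon_id == "often_low"], "low_samples")
  expect_false("nine_low" %in% res$report$taxon_id)
  # counts-mode input refused
  expect_error(apply_abundance_filter(counts_matrix(v * 1e4, mesocosm_design())),
               "fractions")
  # retained matrix keeps original denominators (no renormalisation)
  expect_equal(res$matrix$values["healthy", ], fr$values["healthy", ])
})

test_that("abundance filter agrees with the per-clause brute-force oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n_tax <- sample(5:12, 1)
    v <- matrix(10^stats::runif(n_tax * 18, -6, -2), nrow = n_tax)
    rownames(v) <- sprintf("t%02d", seq_len(n_tax))
    fr <- fractions_matrix(v, mesocosm_design())
    for (variant in c("methods", "results")) {
      cfg <- abundance_filter_config(variant)
      res <- apply_abundance_filter(fr, cfg)
      expected <- oracle_abundance_removed(
        fr$values, cfg$min_fraction_any_sample, cfg$low_fraction,
        cfg$max_low_samples)
      expect_setequal(setdiff(rownames(fr$values), rownames(res$matrix$values)),
                      expected)
    }
  }
})

test_that("degenerate thresholds behave as limits", {
  set.seed(5)
  v <- matrix(10^stats::runif(8 * 18, -6, -2), nrow = 8)
  fr <- fractions_matrix(v, mesocosm_design())
  keep_all <- apply_abundance_filter(
    fr, abundance_filter_config(min_fraction_any_sample = 0, low_fraction = 0,
                                max_low_samples = 19))
  expect_identical(nrow(keep_all$matrix$values), nrow(fr$values))
  drop_all <- apply_abundance_filter(
    fr, abundance_filter_config(min_fraction_any_sample = 1, low_fraction = 1,
                                max_low_samples = 19))
  expect_identical(nrow(drop_all$matrix$values), 0L)
})

test_that("coverage fraction merges intervals and matches per-position count", {
  p <- coverage_profile("g", 1000, 0, 100)
  expect_equal(coverage_fraction(p), 0.10)
  # overlapping raw intervals are merged
  p2 <- coverage_profile("g", 100, c(0, 25), c(50, 75))
  expect_equal(coverage_fraction(p2), 0.75)
  expect_equal(p2$starts, 0)
  expect_equal(p2$ends, 75)
  expect_equal(coverage_fraction(coverage_profile("g", 200000, 1000, 1100)),
               0.0005)
  expect_error(coverage_profile("g", 100, 50, 40), "start < end")
  expect_error(coverage_profile("g", 100, 50, 150), "bounds")
  # invariance under splitting/permutation of an equivalent covering
  set.seed(7)
  for (rep in 1:20) {
    L <- 500
    s <- sort(sample(0:(L - 2), 6)); e <- pmin(s + sample(1:80, 6, TRUE), L)
    cf <- coverage_fraction(coverage_profile("g", L, s, e))
    o <- sample(6)
    expect_equal(coverage_fraction(coverage_profile("g", L, s[o], e[o])), cf)
    expect_equal(cf, oracle_coverage_fraction(L, s, e))
  }
})

test_that("bedgraph parsing handles zero runs, offsets, and bad input", {
  dir <- withr::local_tempdir()
  bg <- file.path(dir, "x.bedgraph")

  writeLines("g1\t0\t100\t5", bg)
  p <- read_bedgraph(bg, 1000)
  expect_equal(p$starts, 0); expect_equal(p$ends, 100)

  writeLines(c("g1\t0\t50\t1", "g1\t50\t80\t0", "g1\t80\t90\t2"), bg)
  p <- read_bedgraph(bg, 1000)
  expect_equal(p$starts, c(0, 80))
  expect_equal(p$ends, c(50, 90))

  # two chroms concatenated with cumulative offsets
  writeLines(c("c1\t10\t40\t3", "c2\t0\t20\t1"), bg)
  p <- read_bedgraph(bg, c(c1 = 100, c2 = 200))
  expect_equal(p$genome_length, 300)
  expect_equal(p$starts, c(10, 100))
  expect_equal(p$ends, c(40, 120))
  expect_equal(coverage_fraction(p), oracle_coverage_fraction(300, p$starts, p$ends))

  writeLines("c1\t40\t10\t1", bg)
  expect_error(read_bedgraph(bg, 100), "start >= end")
  writeLines("c1\t0\t150\t1", bg)
  expect_error(read_bedgraph(bg, c(c1 = 100)), "beyond")
  writeLines(c("c1\t0\t10\t1", "c2\t0\t10\t1"), bg)
  expect_error(read_bedgraph(bg, 100), "named")
})

test_that("coverage filter removes low-coverage genomes, keeps unreferenced", {
  v <- matrix(0.2, nrow = 3, ncol = 3,
              dimnames = list(c("lowcov", "at_thresh", "no_ref"), NULL))
  fr <- fractions_matrix(v, toy_design(3))
  profiles <- list(
    lowcov = coverage_profile("lowcov", 200000, 0, 100),      # 0.0005
    at_thresh = coverage_profile("at_thresh", 100000, 0, 100) # exactly 0.001
  )
  res <- apply_coverage_filter(fr, profiles, threshold = 0.001)
  expect_setequal(rownames(res$matrix$values),
                  c("at_thresh", "no_ref", "filler"))
  expect_equal(res$report$rule[res$report$taxon_id == "lowcov"], "low_coverage")
  expect_true("no_ref" %in%
                res$report$taxon_id[res$report$rule == "no_reference"])
  expect_false("filler" %in% res$report$taxon_id[res$report$rule == "low_coverage"])
})

test_that("coverage filter matches the per-position oracle on random profiles", {
  set.seed(31)
  n_tax <- 30
  v <- matrix(1 / (n_tax + 1), nrow = n_tax, ncol = 3)
  rownames(v) <- sprintf("t%02d", seq_len(n_tax))
  fr <- fractions_matrix(v, toy_design(3))
  profiles <- lapply(rownames(v), function(tx) {
    L <- sample(5000:20000, 1)
    k <- sample(0:5, 1)
    if (k == 0) return(coverage_profile(tx, L))
    s <- sample(0:(L - 30), k, replace = TRUE)
    e <- pmin(s + sample(c(2, 5, 10, 200), k, replace = TRUE), L)
    coverage_profile(tx, L, s, e)
  })
  names(profiles) <- rownames(v)
  thr <- 0.002
  res <- apply_coverage_filter(fr, profiles, threshold = thr)
  expected_removed <- names(profiles)[vapply(profiles, function(p) {
    oracle_coverage_fraction(p$genome_length, p$starts, p$ends) < thr
  }, logical(1))]
  expect_setequal(setdiff(rownames(fr$values), rownames(res$matrix$values)),
                  expected_removed)
})

test_that("abundance and coverage filters commute on the retained taxon set", {
  set.seed(77)
  v <- matrix(10^stats::runif(10 * 18, -6, -2), nrow = 10)
  rownames(v) <- sprintf("t%02d", 1:10)
  fr <- fractions_matrix(v, mesocosm_design())
  profiles <- lapply(rownames(v), function(tx) {
    L <- 10000
    s <- sample(0:(L - 20), 2)
    coverage_profile(tx, L, s, s + sample(c(4, 50), 2, replace = TRUE))
  })
  names(profiles) <- rownames(v)
  cfg <- abundance_filter_config("methods")
  ab_then_cov <- apply_coverage_filter(
    apply_abundance_filter(fr, cfg)$matrix, profiles, 0.002)$matrix
  cov_then_ab <- apply_abundance_filter(
    apply_coverage_filter(fr, profiles, 0.002)$matrix, cfg)$matrix
  expect_setequal(rownames(ab_then_cov$values), rownames(cov_then_ab$values))
})
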