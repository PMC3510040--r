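test_that("degenerate generator settings produce degenerate data", {
  spec0 <- sim_spec(chrom_lengths = c(chr1 = 2e5), theta = 0, tract_lambda = 0)
  sim0 <- simulate_individual(spec0, seed = 1)
  expect_equal(nrow(sim0$variants), 0)
  expect_equal(nrow(sim0$truth), 0)
  # depth track still tiles the chromosome
  expect_equal(max(sim0$depth$end), 2e5)
})

test_that("fixed tracts land verbatim in the truth set", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 5e6),
                   fixed_tracts = tibble::tibble(chrom = "chr1",
                                                 start = 2e6, end = 3e6))
  sim <- simulate_individual(spec, seed = 2)
  expect_equal(sim$truth,
               tibble::tibble(chrom = "chr1", start = 2e6, end = 3e6))
  # residual heterozygosity inside the tract is strongly depleted
  inside <- sum(sim$variants$pos > 2e6 & sim$variants$pos <= 3e6)
  outside <- nrow(sim$variants) - inside
  expect_lt(inside / 1e6, 0.2 * outside / 4e6)
  # and matches the configured residual rate within Poisson noise
  lam <- 1e6 * spec$theta * spec$tract_residual_frac
  expect_lt(abs(inside - lam), 4 * sqrt(lam))
  # tract mass larger than the chromosome fails
  bad <- sim_spec(chrom_lengths = c(chr1 = 5e6),
                  fixed_tracts = tibble::tibble(chrom = "chr1",
                                                start = 0, end = 6e6))
  expect_error(simulate_individual(bad, seed = 1), "exceeds")
})

test_that("marginal SNV density matches theta within Poisson error", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 1e8), tract_lambda = 0)
  sim <- simulate_individual(spec, seed = 3)
  lam <- 1e8 * 1.7e-3
  expect_lt(abs(nrow(sim$variants) - lam), 3 * sqrt(lam))
})

test_that("the generator is byte-identical under a fixed seed", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 1e6, chr2 = 5e5),
                   tract_lambda = 2, tract_meanlog = log(5e4))
  a <- simulate_individual(spec, seed = 4)
  b <- simulate_individual(spec, seed = 4)
  expect_identical(a$variants, b$variants)
  expect_identical(a$depth, b$depth)
  expect_identical(a$truth, b$truth)
  d <- simulate_individual(spec, seed = 5)
  expect_false(identical(a$variants, d$variants))
})

test_that("depth model centres near the configured mean with dropout holes", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 2e6),
                   tract_lambda = 2, tract_meanlog = log(5e4))
  sim <- simulate_individual(spec, seed = 6)
  w <- sim$depth$end - sim$depth$start
  mean_depth <- sum(sim$depth$depth * w) / sum(w)
  expect_equal(mean_depth, 8, tolerance = 0.1)
  expect_true(any(sim$depth$depth == 0))
})

test_that("an undisturbed uniform genome recovers theta through the whole binning stage", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 1e7), tract_lambda = 0,
                   depth_mean = 30, depth_size = 50, dropout_rate_per_mb = 0)
  sim <- simulate_individual(spec, seed = 8)
  grid <- bin_variants(sim$variants, sim$depth,
                       chrom_lengths = spec$chrom_lengths,
                       filter = depth_filter(min_dp = 7, max_dp = 60))
  avg <- genomic_average(grid)
  expect_equal(avg, spec$theta * 1e4, tolerance = 0.02)
})

test_that("tract-rich groups call more ROHs than tract-poor groups", {
  lens <- c(chr1 = 1e7, chr2 = 1e7)
  many <- sim_spec(chrom_lengths = lens, tract_lambda = 40,
                   tract_meanlog = log(3e5))
  few <- sim_spec(chrom_lengths = lens, tract_lambda = 4,
                  tract_meanlog = log(3e5))
  cohort <- simulate_cohort(list(many = many, few = few), n_per_group = 2,
                            seed = 7, chrom_lengths = lens)
  counts <- vapply(names(cohort$individuals), function(id) {
    sim <- cohort$individuals[[id]]
    grid <- bin_variants(sim$variants, sim$depth, chrom_lengths = lens,
                         individual_id = id)
    nrow(call_rohs(grid)$rohs)
  }, numeric(1))
  grp <- cohort$groups$group[match(names(counts), cohort$groups$individual_id)]
  expect_gt(mean(counts[grp == "many"]), mean(counts[grp == "few"]))
})

test_that("an empty cohort request yields an empty cohort", {
  cohort <- simulate_cohort(presets = "as-wild", n_per_group = 0, seed = 1,
                            chrom_lengths = c(chr1 = 2e5))
  expect_length(cohort$individuals, 0)
  expect_equal(nrow(cohort$groups), 0)
})

test_that("cohorts are reproducible and carry shared genome resources", {
  lens <- c(chr1 = 3e5, chr2 = 3e5)
  specs <- list(
    g1 = sim_spec(chrom_lengths = lens, tract_lambda = 3,
                  tract_meanlog = log(3e4)),
    g2 = sim_spec(chrom_lengths = lens, theta = 2.2e-3, tract_lambda = 1,
                  tract_meanlog = log(3e4)))
  a <- simulate_cohort(presets = specs, n_per_group = 1, seed = 31,
                       chrom_lengths = lens, include_reference = TRUE)
  b <- simulate_cohort(presets = specs, n_per_group = 1, seed = 31,
                       chrom_lengths = lens, include_reference = TRUE)
  expect_identical(lapply(a$individuals, `[[`, "variants"),
                   lapply(b$individuals, `[[`, "variants"))
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_equal(unname(Biostrings::width(a$reference)), unname(lens))
  expect_equal(sort(unique(a$map$chrom)), names(lens))
  expect_true(all(a$genes$end <= lens[a$genes$chrom]))
})

test_that("recovery scoring matches a per-bp bitmap oracle", {
  truth <- tibble::tibble(chrom = "chr1", start = c(1e5, 5e5), end = c(2e5, 8e5))
  # perfect calls
  perfect <- recovery_report(truth, truth)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$boundary_error_bins, 0)
  # no calls at all
  none <- recovery_report(truth, truth[0, ])
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))

  # seeded scenario scored independently at bp resolution
  set.seed(59)
  called <- tibble::tibble(
    chrom = "chr1",
    start = c(0.9e5, 5.6e5, 9e5),
    end = c(1.6e5, 7.9e5, 9.3e5))
  got <- recovery_report(truth, called, min_overlap_frac = 0.5)
  bitmap <- function(df, n) {
    v <- rep(FALSE, n)
    for (k in seq_len(nrow(df))) v[(df$start[k] + 1):df$end[k]] <- TRUE
    v
  }
  tb <- bitmap(truth, 1e6); cb <- bitmap(called, 1e6)
  rec <- mean(vapply(seq_len(nrow(truth)), function(k) {
    idx <- (truth$start[k] + 1):truth$end[k]
    mean(cb[idx]) >= 0.5
  }, logical(1)))
  prec <- mean(vapply(seq_len(nrow(called)), function(k) {
    idx <- (called$start[k] + 1):called$end[k]
    mean(tb[idx]) >= 0.5
  }, logical(1)))
  expect_equal(got$recall, rec)
  expect_equal(got$precision, prec)
})

test_that("simulated VCF output is consumable by an independent VCF parser", {
  spec <- sim_spec(chrom_lengths = c(chr7 = 2e5),
                   tract_lambda = 1, tract_meanlog = log(2e4))
  sim <- simulate_individual(spec, seed = 12, individual_id = "vcfcheck")
  dir <- withr::local_tempdir()
  paths <- write_sim_individual(sim, dir)
  v <- vcfR::read.vcfR(paths[["vcf"]], verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(sim$variants))
  expect_equal(colnames(v@gt)[2], "vcfcheck")
})
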