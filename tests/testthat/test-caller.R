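# A worked example grid mirroring the caller's documentation: two low-SNP
# stretches, one containing a single high (but relaxable) bin, separated by
# bins far above the relaxation caps; background tuned so that the genomic
# average is exactly 10.
worked_example_grid <- function() {
  low1 <- rep(2.5, 20); low1[10] <- 20     # relaxable: 20 <= 2 x avg
  sep <- rep(50, 3)                        # 50 > 2 x avg: splits/kills
  low2 <- rep(2.5, 15)
  used <- sum(low1) + sum(sep) + sum(low2)
  n_bg <- 62
  bg <- rep((10 * (38 + n_bg) - used) / n_bg, n_bg)
  make_grid(c(bg[1:31], low1, sep, low2, bg[32:62]))
}

worked_params <- function() detection_params(mu_per_bin = 0.0025)

test_that("the stretch ceiling is the max of the relative threshold and the FDR + mu floor", {
  p <- worked_params()
  expect_equal(roh_bin_threshold(10, p), 2.5)        # 0.25*10 beats 2.0025
  expect_equal(roh_bin_threshold(4, p), 2.0025)      # floor takes over
  p0 <- detection_params(fdr_per_bin = 0, mu_per_bin = 0)
  expect_equal(roh_bin_threshold(10, p0), 2.5)       # floor inactive
  # default per-bin mutation expectation derives from the per-bp rate
  expect_equal(mu_per_bin(detection_params()), 2.5e-8 * 1e4)
  expect_error(roh_bin_threshold(0, p))
})

test_that("candidate bins require a strictly below-average anchored window", {
  p <- detection_params()
  const <- make_grid(rep(8, 50))
  expect_false(any(candidate_bins(const, 8, p)))

  sb <- rep(20, 40); sb[16:25] <- 0
  grid <- make_grid(sb)
  mask <- candidate_bins(grid, genomic_average(grid), p)
  expect_true(all(mask[16:25]))

  # brute-force window enumeration oracle, both orientations and modes
  for (seed in 1:5) {
    grid <- random_grid(seed, n_bins = 500)
    avg <- genomic_average(grid)
    for (mode in c("anchored", "any")) {
      pm <- detection_params(window_mode = mode)
      expect_equal(candidate_bins(grid, avg, pm),
                   oracle_candidate_mask(grid$snpbin, grid$covered, avg,
                                         pm$window_len, mode),
                   info = paste("seed", seed, mode))
    }
  }
})

test_that("chromosomes shorter than the window yield no candidates", {
  short <- make_grid(rep(0, 5))
  expect_equal(candidate_bins(short, 10, detection_params()), rep(FALSE, 5))
})

test_that("neighbour concatenation produces maximal runs", {
  st <- concatenate_stretches(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(st$first, c(1, 6))
  expect_equal(st$n_bins, c(3, 2))
  expect_equal(nrow(concatenate_stretches(logical(10))), 0)
  alt <- rep(c(TRUE, FALSE), 10)
  st2 <- concatenate_stretches(alt)
  expect_equal(nrow(st2), sum(alt))
  expect_true(all(st2$n_bins == 1))
})

test_that("a single high bin is relaxed when caps allow and splits the stretch otherwise", {
  p <- worked_params()
  # 10-bin stretch at 2.5 with one bin at 20, genomic average 10:
  # bin cap 20 holds, window mean (9*2.5 + 20)/10 = 4.25 <= 6.67 holds
  sb <- c(rep(2.5, 4), 20, rep(2.5, 5))
  grid <- make_grid(sb)
  kept <- apply_threshold_and_relaxation(
    tibble::tibble(first = 1L, last = 10L, n_bins = 10L), grid, 10, p)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$idx, 1:10)
  expect_equal(kept[[1]]$relaxed, 5L)

  # same stretch with the aberrant bin at 21 > 2 x avg: split at that bin
  grid2 <- make_grid(c(rep(2.5, 4), 21, rep(2.5, 5)))
  kept2 <- apply_threshold_and_relaxation(
    tibble::tibble(first = 1L, last = 10L, n_bins = 10L), grid2, 10, p)
  expect_length(kept2, 2)
  expect_equal(kept2[[1]]$idx, 1:4)
  expect_equal(kept2[[2]]$idx, 6:10)

  # randomized stretches match the literal-rule oracle
  for (seed in 6:10) {
    grid <- random_grid(seed, n_bins = 120)
    avg <- genomic_average(grid)
    st <- tibble::tibble(first = 11L, last = 90L, n_bins = 80L)
    got <- apply_threshold_and_relaxation(st, grid, avg, p)
    want <- oracle_threshold_relax(11:90, grid$snpbin, grid$covered, avg, p)
    expect_equal(lapply(got, `[[`, "idx"), lapply(want, `[[`, "idx"),
                 info = paste("seed", seed))
    expect_equal(lapply(got, `[[`, "relaxed"), lapply(want, `[[`, "relaxed"),
                 info = paste("seed", seed))
  }
})

test_that("coverage rules trim uncovered ends and bound the uncovered fraction", {
  p <- detection_params()
  # covered,5x uncovered,covered,covered: fraction 5/8 <= 2/3, size 80 kb
  g1 <- make_grid(rep(0, 8), covered = c(TRUE, rep(FALSE, 5), TRUE, TRUE))
  r1 <- apply_coverage_rules(list(idx = 1:8, relaxed = integer()), g1, p)
  expect_equal(r1$start, 0)
  expect_equal(r1$end, 80000)
  expect_equal(r1$n_uncovered, 5)

  # 7 uncovered interior bins of 9: 7/9 > 2/3, rejected
  g2 <- make_grid(rep(0, 9), covered = c(TRUE, rep(FALSE, 7), TRUE))
  expect_null(apply_coverage_rules(list(idx = 1:9, relaxed = integer()), g2, p))

  # leading uncovered bins are trimmed off
  g3 <- make_grid(rep(0, 6), covered = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  r3 <- apply_coverage_rules(list(idx = 1:6, relaxed = integer()), g3, p)
  expect_equal(r3$start, 20000)
  expect_equal(r3$n_bins, 4)

  # below the minimum ROH size
  g4 <- make_grid(rep(0, 3), bin_size = 1000)
  expect_null(apply_coverage_rules(list(idx = 1:3, relaxed = integer()), g4, p))
})

test_that("size classes split at 100 kb and 5 Mb with strict outer bounds", {
  expect_equal(as.character(classify_roh(c(5e4, 1e5, 5e6, 6e6))),
               c("small", "medium", "medium", "large"))
})

test_that("a uniformly heterozygous genome contains no ROHs", {
  set.seed(3)
  grid <- make_grid(rpois(800, 17) + 1)
  calls <- call_rohs(grid)
  expect_equal(nrow(calls$rohs), 0)
  g <- glance(calls)
  expect_equal(g$n_roh, 0)
  expect_equal(g$cum_roh_bp, 0)
})

test_that("the worked-example grid yields exactly two ROHs with the high bin relaxed", {
  grid <- worked_example_grid()
  expect_equal(genomic_average(grid), 10)
  calls <- call_rohs(grid, worked_params())
  expect_equal(nrow(calls$rohs), 2)
  r <- calls$rohs
  # the relaxed 20-SNP bin sits inside the first ROH, not between ROHs
  bin20_start <- grid$bin_start[which(grid$snpbin == 20)]
  expect_true(r$start[1] <= bin20_start && r$end[1] > bin20_start)
  expect_equal(r$n_relaxed, c(1, 0))
  # separator bins at 50 belong to neither ROH
  sep_starts <- grid$bin_start[which(grid$snpbin == 50)]
  expect_true(all(sep_starts >= r$end[1] & sep_starts < r$start[2]))
})

test_that("the optimized caller matches the literal bin-by-bin oracle", {
  p <- detection_params()
  for (seed in 21:32) {
    grid <- random_grid(seed, n_bins = sample(c(150, 400, 900), 1))
    got <- call_rohs(grid, p)$rohs
    want <- oracle_call_rohs(grid, p)
    expect_equal(got[, c("chrom", "start", "end")],
                 want, ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("called ROHs satisfy their structural invariants", {
  p <- detection_params()
  for (seed in 41:45) {
    grid <- random_grid(seed, n_bins = 600)
    calls <- call_rohs(grid, p)
    r <- calls$rohs
    if (nrow(r) == 0) next
    # disjoint, sorted, in bounds
    expect_true(all(diff(r$start) > 0))
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    expect_true(all(r$start >= 0 & r$end <= max(grid$bin_end)))
    expect_true(all(r$end - r$start >= p$min_roh_bp))
    # class accounting conserves totals
    g <- glance(calls)
    expect_equal(g$n_small + g$n_medium + g$n_large, g$n_roh)
    expect_equal(g$cum_small_bp + g$cum_medium_bp + g$cum_large_bp,
                 g$cum_roh_bp)
    # every covered bin inside a ROH respects the relaxation cap; the
    # non-relaxed mean respects the stretch ceiling
    for (k in seq_len(nrow(r))) {
      idx <- which(grid$bin_start >= r$start[k] & grid$bin_end <= r$end[k])
      inside <- grid$snpbin[idx][grid$covered[idx]]
      expect_true(all(inside <= p$relax_bin_cap_factor * calls$genome_avg))
      expect_true(r$mean_snpbin[k] <= calls$threshold + 1e-12)
    }
  }
})

test_that("raising the relative threshold never shrinks total ROH coverage", {
  for (seed in 51:53) {
    grid <- random_grid(seed, n_bins = 500)
    cov <- vapply(c(0.1, 0.25, 0.4), function(rt) {
      sum(call_rohs(grid, detection_params(rel_threshold = rt))$rohs$size_bp)
    }, numeric(1))
    expect_true(all(diff(cov) >= 0), info = paste("seed", seed))
  }
})

test_that("planted low-heterozygosity tracts are recovered end to end", {
  spec <- sim_spec(
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    fixed_tracts = tibble::tibble(chrom = c("chr1", "chr2"),
                                  start = c(1e6, 2e6), end = c(2e6, 4.5e6))
  )
  sim <- simulate_individual(spec, seed = 77)
  grid <- bin_variants(sim$variants, sim$depth,
                       chrom_lengths = spec$chrom_lengths)
  calls <- call_rohs(grid)
  rep <- recovery_report(sim$truth, calls, min_overlap_frac = 0.5)
  expect_equal(rep$recall, 1)
  # every planted tract is overlapped by a called ROH covering >= half of it
  expect_true(nrow(calls$rohs) >= 2)
})
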