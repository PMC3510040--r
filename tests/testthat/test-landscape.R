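test_that("GC fractions per bin match a naive per-base count", {
  gc_all <- Biostrings::DNAStringSet(c(chrG = paste(rep("GC", 5000), collapse = "")))
  expect_true(all(gc_content_bins(gc_all)$gc == 1))
  at_all <- Biostrings::DNAStringSet(c(chrA = paste(rep("AT", 5000), collapse = "")))
  expect_true(all(gc_content_bins(at_all)$gc == 0))

  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 25000, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.25, 0.05)), collapse = "")
  bins <- gc_content_bins(Biostrings::DNAStringSet(c(chr1 = s)))
  chars <- strsplit(s, "")[[1]]
  for (k in seq_len(nrow(bins))) {
    piece <- chars[(bins$start[k] + 1):bins$end[k]]
    expect_equal(bins$gc[k],
                 sum(piece %in% c("G", "C")) / sum(piece != "N"))
  }
  # an all-N bin is excluded, not zero
  nbin <- gc_content_bins(Biostrings::DNAStringSet(
    c(chrN = paste(rep("N", 10000), collapse = ""))))
  expect_true(is.na(nbin$gc))
})

test_that("two markers at 1 cM / 1 Mb give a flat 1 cM/Mb profile", {
  map <- tibble::tibble(chrom = "chr1", bp = c(0, 1e6), cm = c(0, 1))
  prof <- recombination_profile(map, c(chr1 = 1e6))
  expect_true(all(prof$value[prof$n > 0] == 1))
})

test_that("the simulated map's profile recovers the U-shaped rate function", {
  spec <- sim_spec(chrom_lengths = c(chr1 = 2e7, chr2 = 2e7))
  map <- simulate_genetic_map(spec)
  prof <- recombination_profile(map, spec$chrom_lengths)
  rate <- recomb_rate_fun(spec)
  mid <- (prof$rel_lower + prof$rel_upper) / 2
  expect_true(all(abs(prof$value - rate(mid)) / rate(mid) < 0.05))
  # U shape: ends well above the middle
  expect_gt(prof$value[1], 2 * prof$value[10])
})

test_that("degenerate genetic maps are guarded", {
  dup <- tibble::tibble(chrom = "chr1", bp = c(0, 0, 1e6), cm = c(0, 0, 1))
  prof <- recombination_profile(dup, c(chr1 = 1e6))
  expect_true(all(is.finite(prof$value[prof$n > 0])))
  bad <- tibble::tibble(chrom = "chr1", bp = c(1e6, 0), cm = c(0, 1))
  expect_error(recombination_profile(bad, c(chr1 = 1e6)), "sorted")
  single <- tibble::tibble(chrom = "chr1", bp = 5e5, cm = 1)
  prof1 <- recombination_profile(single, c(chr1 = 1e6))
  expect_true(all(is.na(prof1$value)))
})

test_that("ROH positional densities count constituent bins and normalise per class", {
  lens <- c(chr1 = 1e6)
  # one ROH spanning exactly the first 5% of the chromosome
  first <- tibble::tibble(chrom = "chr1", start = 0, end = 5e4)
  prof <- roh_positional_distribution(first, lens, bin_size = 1e4)
  expect_equal(prof$density[1], 1)
  expect_equal(sum(prof$density), 1)

  # ROHs tiled uniformly: flat profile
  tiled <- tibble::tibble(chrom = "chr1",
                          start = seq(0, 9.5e5, 5e4), end = seq(5e4, 1e6, 5e4))
  ptile <- roh_positional_distribution(tiled, lens, bin_size = 1e4)
  expect_true(all(abs(ptile$density - 0.05) < 1e-12))

  # seeded set against a direct per-bin counting oracle
  set.seed(55)
  starts <- sort(sample(seq(0, 9e5, 1e4), 12))
  rohs <- tibble::tibble(chrom = "chr1", start = starts,
                         end = pmin(starts + sample(1:6, 12, TRUE) * 1e4, 1e6))
  rohs <- rohs[!duplicated(rohs$start), ]
  got <- roh_positional_distribution(rohs, lens, bin_size = 1e4)
  counts <- numeric(20)
  for (k in seq_len(nrow(rohs))) {
    for (b in seq(rohs$start[k], rohs$end[k] - 1, 1e4)) {
      seg <- min(floor(((b + min(b + 1e4, rohs$end[k])) / 2 / 1e6) * 20) + 1, 20)
      counts[seg] <- counts[seg] + 1
    }
  }
  expect_equal(got$density, counts / sum(counts))

  # an empty class is flagged, not zero-filled
  empty <- roh_positional_distribution(
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                   size_class = character()),
    lens, size_class = "large")
  expect_true(all(is.na(empty$density)))
})

test_that("profile correlation matches the hand sum-of-products formula", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(correlate_profiles(x, x)$estimate, 1)
  expect_equal(correlate_profiles(x, -x)$estimate, -1)

  set.seed(77)
  a <- runif(20); b <- a * 0.5 + rnorm(20, sd = 0.2)
  n <- 20
  r_hand <- (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  out <- correlate_profiles(a, b)
  expect_equal(out$estimate, r_hand)
  expect_equal(out$n, 20)

  expect_error(correlate_profiles(rep(1, 5), 1:5), "variance")
  expect_error(correlate_profiles(c(1, NA, NA, NA), c(1, 2, NA, NA)), "pairs")
})

test_that("gene-density segments are per-chromosome fractions", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  g1 <- tibble::tibble(chrom = "chr1", start = seq(0, 4e4, 1e4),
                       end = seq(0, 4e4, 1e4) + 5e3,
                       gene_id = paste0("g", 1:5))
  seg <- gene_density_segments(g1, lens)
  s1 <- seg[seg$chrom == "chr1", ]
  expect_equal(s1$frac, c(1, rep(0, 19)))
  expect_true(all(is.na(seg$frac[seg$chrom == "chr2"])))

  # uniform genes: roughly 0.05 per segment; exact counting oracle
  set.seed(13)
  gu <- tibble::tibble(chrom = "chr1", start = floor(runif(400, 0, 1e6)),
                       end = NA_real_, gene_id = paste0("u", 1:400))
  gu$end <- gu$start + 1000
  segu <- gene_density_segments(gu, c(chr1 = 1e6))
  expect_equal(mean(segu$frac), 0.05)
  oracle_counts <- tabulate(pmin(gu$start %/% 5e4 + 1, 20), 20)
  expect_equal(segu$n_genes, oracle_counts)
  expect_equal(segu$frac, oracle_counts / 400)
})

test_that("GFF3 annotations round-trip through the reader", {
  genes <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                          start = c(100, 5000, 0), end = c(900, 8000, 1200),
                          gene_id = c("gA", "gB", "gC"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  back <- read_gene_annotation(path)
  expect_equal(back$chrom, genes$chrom)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$gene_id, genes$gene_id)
})

test_that("diversity and GC profiles feed the correlation machinery", {
  set.seed(91)
  grid <- dplyr::bind_rows(
    make_grid(rpois(500, 17), chrom = "chr1"),
    make_grid(rpois(500, 17), chrom = "chr2"))
  lens <- c(chr1 = 5e6, chr2 = 5e6)
  prof <- pi_profile(grid, lens)
  expect_equal(nrow(prof), 20)
  expect_true(all(prof$n > 0))
  # flat-heterozygosity genome: profile variation stays within noise
  expect_lt(stats::sd(prof$value) / mean(prof$value), 0.05)
})
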