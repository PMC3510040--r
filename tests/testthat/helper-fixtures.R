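# Bin-grid and random-grid builders shared across test files.

# build a one-chromosome bin grid from snpbin values and a coverage mask
make_grid <- function(snpbin, covered = rep(TRUE, length(snpbin)),
                      chrom = "chr1", bin_size = 10000, id = "ind") {
  n <- length(snpbin)
  tibble::tibble(
    individual_id = id,
    chrom = chrom,
    bin_start = (seq_len(n) - 1) * bin_size,
    bin_end = seq_len(n) * bin_size,
    snp_count = round(snpbin),
    covered_bp = ifelse(covered, bin_size, floor(0.05 * bin_size)),
    snpbin = as.numeric(snpbin),
    covered = covered
  )
}

# random grid with planted low-het runs, aberrant spikes and coverage holes:
# exercises candidate windows, relaxation and uncovered-bin rules
random_grid <- function(seed, n_bins = 300, background = 15,
                        n_tracts = 3, chrom = "chr1") {
  set.seed(seed)
  snpbin <- as.numeric(rpois(n_bins, background))
  for (k in seq_len(n_tracts)) {
    len <- sample(5:40, 1)
    s <- sample(seq_len(max(n_bins - len, 1)), 1)
    snpbin[s:(s + len - 1)] <- rpois(len, background * 0.05)
  }
  # sprinkle spikes: some relaxable (< 2x avg), some killers
  spikes <- sample(n_bins, max(2, n_bins %/% 50))
  snpbin[spikes] <- rpois(length(spikes), background * sample(c(1.5, 3), 1))
  covered <- runif(n_bins) > 0.08
  make_grid(snpbin, covered, chrom = chrom)
}

# tiny two-group summary table for group-comparison tests
toy_summaries <- function(values_by_group) {
  out <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    tibble::tibble(
      individual_id = paste0(g, seq_along(v)), group = g, pi_out = v,
      n_small = 2L, n_medium = 1L, n_large = 0L
    )
  })
  dplyr::bind_rows(out)
}
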