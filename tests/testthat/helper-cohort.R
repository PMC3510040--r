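# The default synthetic study cohort (4 group presets x 3 individuals on
# five 20-Mb autosomes, seed 1) is expensive enough to build once and share
# across test blocks.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_results <- function() {
  if (!is.null(.cohort_cache$default)) return(.cohort_cache$default)
  cohort <- simulate_cohort(seed = 1)
  results <- lapply(names(cohort$individuals), function(id) {
    sim <- cohort$individuals[[id]]
    grid <- bin_variants(sim$variants, sim$depth,
                         chrom_lengths = cohort$chrom_lengths,
                         individual_id = id)
    list(id = id, sim = sim, grid = grid, calls = call_rohs(grid))
  })
  names(results) <- names(cohort$individuals)
  .cohort_cache$default <- list(cohort = cohort, results = results)
  .cohort_cache$default
}
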