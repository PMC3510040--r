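# two-sample Kolmogorov-Smirnov distance (sup |ECDF_a - ECDF_b|);
# 0 when both samples are empty, NA when exactly one is
ks_distance <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 && length(b) == 0) return(0)
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  x <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(x)
  Fb <- stats::ecdf(b)(x)
  max(abs(Fa - Fb))
}

# candidate stretches of a grid: length in bins and mean snpbin of covered
# bins relative to the genomic average. Candidate runs are additionally
# broken at covered bins that are not themselves below the genomic average:
# a bin at or above the average cannot belong to a homozygous stretch, and
# keeping such flanking bins would dilute every stretch mean toward 1.
calibration_stretches <- function(bins, genome_avg, params) {
  out <- lapply(split(bins, bins$chrom), function(grid) {
    grid <- dplyr::arrange(grid, .data$bin_start)
    mask <- candidate_bins(grid, genome_avg, params) &
      (!grid$covered | grid$snpbin < genome_avg)
    st <- concatenate_stretches(mask)
    if (nrow(st) == 0) {
      return(tibble(length_bins = integer(), rel_mean = numeric()))
    }
    rel <- vapply(seq_len(nrow(st)), function(k) {
      idx <- seq.int(st$first[k], st$last[k])
      m <- stretch_mean(grid$snpbin, grid$covered, idx)
      m / genome_avg
    }, numeric(1))
    tibble(length_bins = st$n_bins, rel_mean = rel)
  })
  dplyr::bind_rows(out)
}

#' Permutation calibration of the relative ROH threshold
#'
#' Verifies the choice of `rel_threshold` by comparing the observed
#' candidate-stretch population against a null in which the individual's
#' snpbin values are randomly shuffled across all covered autosomal bins
#' (the coverage mask stays in place). Genuine autozygosity produces long
#' candidate stretches at low relative SNP counts that the shuffled genome
#' cannot reproduce; above the threshold the two populations should look
#' alike. Divergence is measured per 0.05-wide level of the stretch mean
#' relative to the genomic average, as the two-sample Kolmogorov-Smirnov
#' distance between observed and permuted stretch-length distributions.
#'
#' @param bins Bin grid tibble of one individual.
#' @param params A [detection_params()].
#' @param n_perm Number of genome-wide permutations (>= 1).
#' @param seed Integer seed; the calibration is deterministic given it.
#' @return An object of class `roh_calibration`: `stretches` (tibble with
#'   `rep` 0 for observed, 1..n_perm for permutations, `length_bins`,
#'   `rel_mean`) and `divergence` (tibble `level_lower, level_upper, n_obs,
#'   n_perm_stretches, ks_distance`).
#' @export
permutation_calibration <- function(bins, params = detection_params(),
                                    n_perm = 20, seed = 1) {
  stopifnot(n_perm >= 1)
  bins <- dplyr::arrange(as_tibble(bins), .data$chrom, .data$bin_start)
  genome_avg <- genomic_average(bins)

  obs <- calibration_stretches(bins, genome_avg, params)
  obs$rep <- 0L

  cov_idx <- which(bins$covered)
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(r) {
    shuffled <- bins
    shuffled$snpbin[cov_idx] <- bins$snpbin[sample(cov_idx)]
    p <- calibration_stretches(shuffled, genome_avg, params)
    p$rep <- r
    p
  })
  stretches <- dplyr::bind_rows(c(list(obs), perms))

  breaks <- c(seq(0, 1, by = 0.05), Inf)
  lev <- function(x) findInterval(x, breaks, rightmost.closed = FALSE)
  div <- lapply(seq_len(length(breaks) - 1), function(k) {
    o <- obs$length_bins[!is.na(obs$rel_mean) & lev(obs$rel_mean) == k]
    pm <- dplyr::bind_rows(perms)
    p <- pm$length_bins[!is.na(pm$rel_mean) & lev(pm$rel_mean) == k]
    tibble(level_lower = breaks[k], level_upper = breaks[k + 1],
           n_obs = length(o), n_perm_stretches = length(p),
           ks_distance = ks_distance(o, p))
  })

  structure(
    list(stretches = stretches, divergence = dplyr::bind_rows(div),
         genome_avg = genome_avg, n_perm = n_perm, seed = seed,
         params = params),
    class = "roh_calibration"
  )
}

#' @export
print.roh_calibration <- function(x, ...) {
  cat(sprintf("ROH threshold calibration: %d permutation(s), seed %d\n",
              x$n_perm, x$seed))
  d <- x$divergence[x$divergence$n_obs + x$divergence$n_perm_stretches > 0, ]
  print(as.data.frame(d), row.names = FALSE)
  invisible(x)
}
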