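#' Per-bin SNP ceiling for ROH stretches
#'
#' The ceiling a candidate stretch must stay under is the larger of
#' `rel_threshold *` the individual's genomic average and an absolute floor,
#' the expected spurious heterozygous calls per bin (`fdr_per_bin`) plus the
#' per-bin mutation expectation. The floor matters for low-heterozygosity
#' individuals, where a quarter of the genomic average would undercut the
#' noise level of the calls themselves.
#'
#' @param genome_avg Genomic average snpbin of the individual (> 0).
#' @param params A [detection_params()].
#' @return Threshold in SNPs per bin.
#' @export
#' @examples
#' p <- detection_params(mu_per_bin = 0.0025)
#' roh_bin_threshold(10, p)  # 2.5: 0.25 * 10 > 2 + 0.0025
#' roh_bin_threshold(4, p)   # 2.0025: the floor takes over
roh_bin_threshold <- function(genome_avg, params = detection_params()) {
  stopifnot(genome_avg > 0)
  max(params$rel_threshold * genome_avg, params$fdr_per_bin + mu_per_bin(params))
}

#' All caller thresholds for a given genomic average
#'
#' @inheritParams roh_bin_threshold
#' @return A list with `threshold` (stretch ceiling from
#'   [roh_bin_threshold()]), `relax_bin_cap` (maximum snpbin a relaxed bin
#'   may carry) and `relax_window_cap` (maximum local window mean around a
#'   relaxed bin).
#' @export
roh_thresholds <- function(genome_avg, params = detection_params()) {
  list(
    threshold = roh_bin_threshold(genome_avg, params),
    relax_bin_cap = params$relax_bin_cap_factor * genome_avg,
    relax_window_cap = params$relax_window_cap_factor * genome_avg
  )
}

# mean snpbin of each window of L consecutive bins, by window start;
# uncovered bins contribute to neither numerator nor denominator
window_means_by_start <- function(snpbin, covered, window_len) {
  n <- length(snpbin)
  if (n < window_len) return(numeric(0))
  val <- ifelse(covered, snpbin, 0)
  cn <- c(0, cumsum(val))
  cd <- c(0, cumsum(as.numeric(covered)))
  i <- seq_len(n - window_len + 1)
  num <- cn[i + window_len] - cn[i]
  den <- cd[i + window_len] - cd[i]
  ifelse(den > 0, num / den, NaN)
}

#' Candidate ROH bins from the sliding window
#'
#' A bin is a candidate when a `window_len`-bin window anchored at it —
#' starting at it (forward orientation) or ending at it (reverse
#' orientation) — has mean snpbin strictly below the genomic average
#' (`window_mode = "anchored"`, the default). With `window_mode = "any"`,
#' any window containing the bin qualifies it. Window means ignore
#' uncovered bins; windows never extend past the chromosome.
#'
#' @param grid One chromosome's bin tibble (columns `snpbin`, `covered`),
#'   sorted by `bin_start`.
#' @param genome_avg Genomic average snpbin.
#' @param params A [detection_params()].
#' @return Logical mask over the chromosome's bins. Chromosomes shorter
#'   than `window_len` bins yield an all-`FALSE` mask.
#' @export
candidate_bins <- function(grid, genome_avg, params = detection_params()) {
  n <- nrow(grid)
  L <- params$window_len
  mask <- logical(n)
  if (n < L) return(mask)
  wm <- window_means_by_start(grid$snpbin, grid$covered, L)
  below <- !is.nan(wm) & wm < genome_avg
  starts <- seq_len(n - L + 1)
  if (params$window_mode == "anchored") {
    mask[starts] <- below
    ends <- starts + L - 1
    mask[ends] <- mask[ends] | below
  } else {
    S <- c(0, cumsum(below))
    a <- pmax(1L, seq_len(n) - L + 1L)
    b <- pmin(seq_len(n), n - L + 1L)
    mask <- b >= a & (S[b + 1] - S[a]) > 0
  }
  mask
}

#' Concatenate adjacent candidate bins into stretches
#'
#' @param mask Logical candidate mask over one chromosome's bins.
#' @return Tibble `first, last, n_bins` of maximal runs of `TRUE`, in
#'   coordinate order (1-based bin indices into the mask).
#' @export
concatenate_stretches <- function(mask) {
  if (length(mask) == 0 || !any(mask)) {
    return(tibble(first = integer(), last = integer(), n_bins = integer()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(first = starts[keep], last = ends[keep],
         n_bins = r$lengths[keep])
}

# mean over covered bins of a stretch, excluding `drop` (absolute indices);
# NA when no covered bins remain
stretch_mean <- function(snpbin, covered, idx, drop = integer()) {
  use <- setdiff(idx[covered[idx]], drop)
  if (length(use) == 0) return(NA_real_)
  mean(snpbin[use])
}

# windows of window_len consecutive stretch bins that contain any of `hit`;
# a stretch shorter than window_len is itself the single window
stretch_windows_containing <- function(idx, hit, window_len) {
  n <- length(idx)
  if (n <= window_len) return(list(idx))
  first <- idx[1]
  starts <- seq.int(first, idx[n] - window_len + 1)
  keep <- starts <= max(hit) & (starts + window_len - 1) >= min(hit)
  lapply(starts[keep], function(s) seq.int(s, s + window_len - 1))
}

#' Enforce the stretch threshold with single-bin relaxation
#'
#' Within each candidate stretch, covered bins must stay at or below the
#' stretch ceiling ([roh_bin_threshold()]). A run of aberrant bins — likely
#' local assembly or alignment errors — is retained (relaxed) rather than
#' splitting the stretch when (a) each of its bins is at most
#' `relax_bin_cap_factor` times the genomic average, (b) every
#' `window_len`-bin window of the stretch containing it averages at most
#' `relax_window_cap_factor` times the genomic average, and (c) the stretch
#' mean of the surrounding conforming bins (all aberrant bins excluded)
#' still respects the ceiling. Aberrant runs
#' failing any condition split the stretch; the parts are re-evaluated and
#' surviving stretches must average at or below the ceiling.
#'
#' @param stretches Tibble from [concatenate_stretches()].
#' @param grid The chromosome's bin tibble the stretches index into.
#' @param genome_avg Genomic average snpbin.
#' @param params A [detection_params()].
#' @return A list of surviving stretches, each
#'   `list(idx = <bin indices>, relaxed = <relaxed bin indices>)`.
#' @export
apply_threshold_and_relaxation <- function(stretches, grid, genome_avg,
                                           params = detection_params()) {
  th <- roh_thresholds(genome_avg, params)
  snpbin <- grid$snpbin
  covered <- grid$covered
  L <- params$window_len

  process <- function(idx) {
    if (length(idx) == 0) return(list())
    nonconf <- idx[covered[idx] & snpbin[idx] > th$threshold]
    if (length(nonconf) == 0) {
      m <- stretch_mean(snpbin, covered, idx)
      if (is.na(m) || m > th$threshold) return(list())
      return(list(list(idx = idx, relaxed = integer())))
    }
    runs <- split(nonconf, cumsum(c(1, diff(nonconf) != 1)))
    # the "surrounding" stretch mean excludes every aberrant bin, so the
    # decision for one run does not depend on other runs' fates
    m_excl <- stretch_mean(snpbin, covered, idx, drop = nonconf)
    relaxed <- integer()
    for (run in runs) {
      ok_bin <- all(snpbin[run] <= th$relax_bin_cap)
      ok_win <- ok_bin && all(vapply(
        stretch_windows_containing(idx, run, L),
        function(w) {
          m <- stretch_mean(snpbin, covered, w)
          !is.na(m) && m <= th$relax_window_cap
        }, logical(1)))
      ok_mean <- !is.na(m_excl) && m_excl <= th$threshold
      if (ok_bin && ok_win && ok_mean) {
        relaxed <- c(relaxed, run)
      } else {
        left <- idx[idx < min(run)]
        right <- idx[idx > max(run)]
        return(c(process(left), process(right)))
      }
    }
    m_final <- stretch_mean(snpbin, covered, idx, drop = relaxed)
    if (is.na(m_final) || m_final > th$threshold) return(list())
    list(list(idx = idx, relaxed = relaxed))
  }

  out <- list()
  for (k in seq_len(nrow(stretches))) {
    out <- c(out, process(seq.int(stretches$first[k], stretches$last[k])))
  }
  out
}

#' Uncovered-bin rules and minimum size
#'
#' Trims uncovered bins off both ends of a surviving stretch (an accepted
#' ROH must begin and end in covered sequence), then accepts it as a ROH iff
#' the uncovered fraction of its bins is at most `max_uncovered_frac` and
#' its genomic span is at least `min_roh_bp`. Uncovered interior bins still
#' count toward the ROH's size.
#'
#' @param stretch A `list(idx, relaxed)` entry from
#'   [apply_threshold_and_relaxation()].
#' @param grid The chromosome's bin tibble.
#' @param params A [detection_params()].
#' @return A one-row ROH tibble, or `NULL` if rejected.
#' @export
apply_coverage_rules <- function(stretch, grid, params = detection_params()) {
  idx <- stretch$idx
  cov <- grid$covered[idx]
  if (!any(cov)) return(NULL)
  idx <- idx[seq.int(which(cov)[1], which(cov)[sum(cov)])]
  n <- length(idx)
  n_unc <- sum(!grid$covered[idx])
  if (n_unc / n > params$max_uncovered_frac) return(NULL)
  start <- grid$bin_start[idx[1]]
  end <- grid$bin_end[idx[n]]
  if (end - start < params$min_roh_bp) return(NULL)
  relaxed <- intersect(stretch$relaxed, idx)
  tibble(
    chrom = grid$chrom[idx[1]],
    start = start, end = end,
    n_bins = n, n_uncovered = n_unc, n_relaxed = length(relaxed),
    mean_snpbin = stretch_mean(grid$snpbin, grid$covered, idx, drop = relaxed)
  )
}

#' Size class of a ROH
#'
#' @param size_bp ROH span(s) in bp.
#' @param params A [detection_params()].
#' @return Factor with levels `small` (strictly below 100 kb), `medium`
#'   (100 kb to 5 Mb inclusive) and `large` (strictly above 5 Mb), under
#'   default boundaries.
#' @export
#' @examples
#' classify_roh(c(5e4, 1e5, 6e6))
classify_roh <- function(size_bp, params = detection_params()) {
  cls <- ifelse(size_bp < params$size_small_upper, "small",
                ifelse(size_bp > params$size_large_lower, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Call regions of homozygosity on a binned individual
#'
#' Runs the full sliding-window pipeline on one individual's bin grid:
#' candidate bins (forward and reverse windows below the genomic average),
#' concatenation into stretches, the stretch ceiling with single-bin
#' relaxation, uncovered-bin rules, and size classification.
#'
#' @param bins Bin grid tibble from [bin_variants()] (one individual, all
#'   autosomes).
#' @param params A [detection_params()].
#' @return An object of class `roh_calls`: list with `rohs` (tibble of
#'   called regions: `individual_id, chrom, start, end, size_bp, n_bins,
#'   n_uncovered, n_relaxed, mean_snpbin, size_class`), `genome_avg`,
#'   `threshold`, `params` and `individual_id`. Use [tidy()] for the ROH
#'   table and [glance()] for the one-row call summary.
#' @export
call_rohs <- function(bins, params = detection_params()) {
  bins <- dplyr::arrange(as_tibble(bins), .data$chrom, .data$bin_start)
  genome_avg <- genomic_average(bins)
  threshold <- roh_bin_threshold(genome_avg, params)
  individual_id <- if ("individual_id" %in% names(bins) && nrow(bins) > 0) {
    bins$individual_id[1]
  } else "ind"

  rows <- lapply(split(bins, bins$chrom), function(grid) {
    grid <- dplyr::arrange(grid, .data$bin_start)
    mask <- candidate_bins(grid, genome_avg, params)
    stretches <- concatenate_stretches(mask)
    kept <- apply_threshold_and_relaxation(stretches, grid, genome_avg, params)
    dplyr::bind_rows(lapply(kept, apply_coverage_rules, grid = grid,
                            params = params))
  })
  rohs <- dplyr::bind_rows(rows)
  if (nrow(rohs) == 0) {
    rohs <- tibble(chrom = character(), start = numeric(), end = numeric(),
                   n_bins = integer(), n_uncovered = integer(),
                   n_relaxed = integer(), mean_snpbin = numeric())
  }
  rohs <- rohs %>%
    dplyr::mutate(individual_id = individual_id,
                  size_bp = .data$end - .data$start,
                  size_class = classify_roh(.data$size_bp, params)) %>%
    dplyr::select("individual_id", "chrom", "start", "end", "size_bp",
                  "n_bins", "n_uncovered", "n_relaxed", "mean_snpbin",
                  "size_class") %>%
    dplyr::arrange(.data$chrom, .data$start)

  structure(
    list(rohs = rohs, genome_avg = genome_avg, threshold = threshold,
         params = params, individual_id = individual_id),
    class = "roh_calls"
  )
}

#' @export
print.roh_calls <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("ROH calls for %s\n", x$individual_id))
  cat(sprintf("  genomic average : %.4g SNPs/bin\n", x$genome_avg))
  cat(sprintf("  stretch ceiling : %.4g SNPs/bin\n", x$threshold))
  cat(sprintf("  ROHs            : %d (small %d, medium %d, large %d)\n",
              g$n_roh, g$n_small, g$n_medium, g$n_large))
  cat(sprintf("  cumulative size : %.4g Mb\n", g$cum_roh_bp / 1e6))
  invisible(x)
}

#' @rdname call_rohs
#' @param x A `roh_calls` object.
#' @param ... Unused.
#' @method tidy roh_calls
#' @export
tidy.roh_calls <- function(x, ...) x$rohs

#' @rdname call_rohs
#' @method glance roh_calls
#' @export
glance.roh_calls <- function(x, ...) {
  r <- x$rohs
  lv <- c("small", "medium", "large")
  cnt <- table(factor(r$size_class, levels = lv))
  cum <- vapply(lv, function(l) sum(r$size_bp[r$size_class == l]), numeric(1))
  tibble(
    individual_id = x$individual_id,
    genome_avg = x$genome_avg,
    threshold = x$threshold,
    n_roh = nrow(r),
    n_small = as.integer(cnt[["small"]]),
    n_medium = as.integer(cnt[["medium"]]),
    n_large = as.integer(cnt[["large"]]),
    cum_small_bp = cum[["small"]],
    cum_medium_bp = cum[["medium"]],
    cum_large_bp = cum[["large"]],
    cum_roh_bp = sum(r$size_bp),
    mean_roh_bp = if (nrow(r) > 0) mean(r$size_bp) else NA_real_
  )
}
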