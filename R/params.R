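#' Per-base depth filter for variant and coverage accounting
#'
#' Sites (and bases) are only used when their read depth lies in
#' `[min_dp, max_dp]`. The upper bound guards against collapsed repeats and
#' copy-number artefacts; by convention it is about twice the individual's
#' mean coverage and is computed from the depth track when left `NULL`.
#'
#' @param min_dp Minimum read depth for a base to count as covered and for a
#'   heterozygous call to be trusted. Default 7.
#' @param max_dp Maximum read depth, same role. `NULL` (default) means
#'   "compute as `2 *` mean depth of the individual's depth track".
#' @param exclude_indels Drop non-SNV records. Default `TRUE`.
#' @return An object of class `depth_filter`.
#' @export
#' @examples
#' depth_filter()
#' depth_filter(min_dp = 5, max_dp = 40)
depth_filter <- function(min_dp = 7, max_dp = NULL, exclude_indels = TRUE) {
  stopifnot(is.numeric(min_dp), length(min_dp) == 1, min_dp >= 1)
  if (!is.null(max_dp)) {
    stopifnot(is.numeric(max_dp), length(max_dp) == 1, max_dp > min_dp)
  }
  structure(
    list(min_dp = min_dp, max_dp = max_dp, exclude_indels = isTRUE(exclude_indels)),
    class = "depth_filter"
  )
}

#' Tunable parameters of the ROH caller
#'
#' Every knob of the sliding-window caller in one validated object. All
#' thresholds are expressed in units of SNPs per bin (the coverage-corrected
#' `snpbin` scale) or as multiples of the individual's genomic average.
#'
#' @param bin_size Bin width in bp (default 10000).
#' @param window_len Sliding-window length in bins (default 10).
#' @param rel_threshold ROH stretches must average at most this multiple of
#'   the genomic mean snpbin (default 0.25).
#' @param fdr_per_bin Expected spurious heterozygous calls per bin, the
#'   "false discovery" floor added to the mutation expectation (default 2).
#' @param mu_per_bp Per-base mutation rate used for the threshold floor
#'   (default 2.5e-8, i.e. 2.5e-4 SNPs per 10-kb bin).
#' @param mu_per_bin Explicit per-bin mutation expectation; overrides
#'   `mu_per_bp * bin_size` when non-`NULL`.
#' @param relax_bin_cap_factor A single aberrant bin inside a stretch may be
#'   retained if its snpbin is at most this multiple of the genomic average
#'   (default 2).
#' @param relax_window_cap_factor ... and if every `window_len`-bin window of
#'   the stretch containing it averages at most this multiple of the genomic
#'   average (default 2/3).
#' @param max_uncovered_frac Maximum fraction of uncovered bins an accepted
#'   ROH may contain after terminal trimming (default 2/3).
#' @param cov_frac A bin is "covered" when at least this fraction of its
#'   bases passes the depth window (default 0.10).
#' @param min_roh_bp Minimum ROH size in bp (default 10000, one bin).
#' @param size_small_upper,size_large_lower Size-class boundaries: small
#'   strictly below 100 kb, large strictly above 5 Mb, medium in between
#'   (both boundaries inclusive to medium).
#' @param window_mode `"anchored"` flags a bin when the window starting or
#'   ending at it is below the genomic average (forward and reverse
#'   orientation); `"any"` uses every window containing the bin.
#' @return An object of class `detection_params`.
#' @export
#' @examples
#' p <- detection_params()
#' mu_per_bin(p)  # 2.5e-4
detection_params <- function(bin_size = 10000,
                             window_len = 10,
                             rel_threshold = 0.25,
                             fdr_per_bin = 2.0,
                             mu_per_bp = 2.5e-8,
                             mu_per_bin = NULL,
                             relax_bin_cap_factor = 2.0,
                             relax_window_cap_factor = 2 / 3,
                             max_uncovered_frac = 2 / 3,
                             cov_frac = 0.10,
                             min_roh_bp = 10000,
                             size_small_upper = 1e5,
                             size_large_lower = 5e6,
                             window_mode = c("anchored", "any")) {
  window_mode <- match.arg(window_mode)
  stopifnot(
    bin_size >= 1,
    window_len >= 2,
    rel_threshold > 0, rel_threshold < 1,
    fdr_per_bin >= 0, mu_per_bp >= 0,
    relax_bin_cap_factor > 0, relax_window_cap_factor > 0,
    max_uncovered_frac >= 0, max_uncovered_frac < 1,
    cov_frac > 0, cov_frac <= 1,
    min_roh_bp >= 1,
    size_small_upper < size_large_lower
  )
  if (!is.null(mu_per_bin)) stopifnot(mu_per_bin >= 0)
  structure(
    list(
      bin_size = bin_size, window_len = window_len,
      rel_threshold = rel_threshold, fdr_per_bin = fdr_per_bin,
      mu_per_bp = mu_per_bp, mu_per_bin = mu_per_bin,
      relax_bin_cap_factor = relax_bin_cap_factor,
      relax_window_cap_factor = relax_window_cap_factor,
      max_uncovered_frac = max_uncovered_frac,
      cov_frac = cov_frac, min_roh_bp = min_roh_bp,
      size_small_upper = size_small_upper,
      size_large_lower = size_large_lower,
      window_mode = window_mode
    ),
    class = "detection_params"
  )
}

#' Effective per-bin mutation expectation
#'
#' @param params A [detection_params()] object.
#' @return `mu_per_bin` if explicitly set, else `mu_per_bp * bin_size`.
#' @export
mu_per_bin <- function(params) {
  if (!is.null(params$mu_per_bin)) params$mu_per_bin else params$mu_per_bp * params$bin_size
}

#' @export
print.detection_params <- function(x, ...) {
  cat("ROH detection parameters\n")
  cat(sprintf("  bin size            : %d bp\n", as.integer(x$bin_size)))
  cat(sprintf("  window length       : %d bins (%s)\n", as.integer(x$window_len), x$window_mode))
  cat(sprintf("  relative threshold  : %.3g x genomic average\n", x$rel_threshold))
  cat(sprintf("  threshold floor     : fdr %.3g + mu %.3g SNPs/bin\n", x$fdr_per_bin, mu_per_bin(x)))
  cat(sprintf("  relaxation caps     : bin %.3g x avg, window %.3g x avg\n",
              x$relax_bin_cap_factor, x$relax_window_cap_factor))
  cat(sprintf("  uncovered bins      : <= %.3g of ROH, covered if covered_bp >= %.3g x width\n",
              x$max_uncovered_frac, x$cov_frac))
  cat(sprintf("  min ROH / classes   : %g bp; small < %g, large > %g\n",
              x$min_roh_bp, x$size_small_upper, x$size_large_lower))
  invisible(x)
}

# round half away from zero, the display convention used for reporting
# window means (e.g. 4.25 -> 4.3 at one decimal)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
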