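#' Per-individual nucleotide diversity
#'
#' Within one diploid individual, nucleotide diversity is the density of
#' heterozygous sites: the mean coverage-corrected snpbin over covered bins,
#' rescaled from SNPs per bin to SNPs per kb.
#'
#' @param bins Bin grid tibble of one individual.
#' @param bin_size Bin width in bp (default 10000).
#' @return Diversity in SNPs per kb.
#' @export
pi_total <- function(bins, bin_size = 10000) {
  cov <- bins$snpbin[bins$covered]
  if (length(cov) == 0) stop("no covered bins: nucleotide diversity undefined")
  mean(cov) / (bin_size / 1000)
}

#' Nucleotide diversity outside ROHs
#'
#' Mean snpbin over covered bins that do not intersect any called ROH
#' (overlap of one bp or more puts a bin inside), rescaled to SNPs per kb.
#' Because ROHs collect the below-average bins, this is never below
#' [pi_total()] and approximates the diversity of the non-autozygous
#' (ancestral-haplotype) fraction of the genome.
#'
#' @param bins Bin grid tibble of one individual.
#' @param rohs ROH tibble (`chrom, start, end`) or a `roh_calls` object
#'   from [call_rohs()] on the same grid.
#' @param bin_size Bin width in bp (default 10000).
#' @return Diversity in SNPs per kb; `NA` (with a warning) when every
#'   covered bin lies inside a ROH.
#' @export
pi_outside <- function(bins, rohs, bin_size = 10000) {
  if (inherits(rohs, "roh_calls")) rohs <- rohs$rohs
  out <- bins$snpbin[bins$covered & !bins_in_rohs(bins, rohs)]
  if (length(out) == 0) {
    warning("all covered bins lie inside ROHs; pi_outside is undefined")
    return(NA_real_)
  }
  mean(out) / (bin_size / 1000)
}

# logical: does each bin overlap (>= 1 bp) any ROH interval?
bins_in_rohs <- function(bins, rohs) {
  inside <- logical(nrow(bins))
  if (is.null(rohs) || nrow(rohs) == 0) return(inside)
  for (ch in unique(rohs$chrom)) {
    r <- rohs[rohs$chrom == ch, ]
    b <- which(bins$chrom == ch)
    if (length(b) == 0) next
    ir_b <- IRanges::IRanges(bins$bin_start[b] + 1, bins$bin_end[b])
    ir_r <- IRanges::IRanges(r$start + 1, r$end)
    inside[b] <- IRanges::overlapsAny(ir_b, ir_r)
  }
  inside
}

#' Per-individual ROH and diversity summary
#'
#' Assembles the three statistics the group comparisons run on — diversity
#' outside ROHs, ROH count and mean ROH size — together with per-class
#' counts, cumulative sizes and the autozygous genome fraction FROH.
#'
#' @param bins Bin grid tibble of one individual.
#' @param calls `roh_calls` object from [call_rohs()] on the same grid.
#' @param group Group label for downstream comparisons.
#' @param froh_denominator `"total"` (default) divides cumulative ROH bp by
#'   the full autosomal length; `"covered"` divides by the depth-covered
#'   length only.
#' @param bin_size Bin width in bp.
#' @return One-row tibble: `individual_id, group, pi_total, pi_out, n_roh,
#'   n_small, n_medium, n_large, cum_small_bp, cum_medium_bp, cum_large_bp,
#'   cum_roh_bp, mean_roh_bp, froh`.
#' @export
summarize_individual <- function(bins, calls, group = NA_character_,
                                 froh_denominator = c("total", "covered"),
                                 bin_size = 10000) {
  froh_denominator <- match.arg(froh_denominator)
  stopifnot(inherits(calls, "roh_calls"))
  g <- glance(calls)
  denom <- if (froh_denominator == "total") {
    sum(bins$bin_end - bins$bin_start)
  } else {
    sum(bins$covered_bp)
  }
  suppressWarnings(pi_out <- pi_outside(bins, calls, bin_size = bin_size))
  tibble(
    individual_id = g$individual_id, group = group,
    pi_total = pi_total(bins, bin_size = bin_size), pi_out = pi_out,
    n_roh = g$n_roh,
    n_small = g$n_small, n_medium = g$n_medium, n_large = g$n_large,
    cum_small_bp = g$cum_small_bp, cum_medium_bp = g$cum_medium_bp,
    cum_large_bp = g$cum_large_bp, cum_roh_bp = g$cum_roh_bp,
    mean_roh_bp = g$mean_roh_bp,
    froh = g$cum_roh_bp / denom
  )
}

#' Between-group tests on individual summaries
#'
#' Continuous summaries (diversity, ROH count, mean size, FROH) are
#' compared with one-way analysis of variance on the per-individual values;
#' ROH size-class composition is compared with a chi-squared test on the
#' group-by-class count table.
#'
#' @param summaries Tibble of rows from [summarize_individual()] with a
#'   `group` column.
#' @param response Column to test (ANOVA only).
#' @param statistic `"anova"` or `"chisq"`.
#' @return One-row tibble: `method, response, statistic, df1, df2, p.value`
#'   (`df2` is `NA` for the chi-squared test).
#' @export
compare_groups <- function(summaries, response = "pi_out",
                           statistic = c("anova", "chisq")) {
  statistic <- match.arg(statistic)
  s <- as_tibble(summaries)
  if (statistic == "anova") {
    stopifnot(response %in% names(s))
    sizes <- table(s$group)
    if (length(sizes) < 2) stop("ANOVA needs at least two groups")
    if (any(sizes < 2)) {
      stop("ANOVA needs at least two members per group; singleton group(s): ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    }
    fit <- aov(s[[response]] ~ factor(s$group))
    a <- summary(fit)[[1]]
    tibble(method = "one-way ANOVA", response = response,
           statistic = a[["F value"]][1], df1 = a[["Df"]][1],
           df2 = a[["Df"]][2], p.value = a[["Pr(>F)"]][1])
  } else {
    counts <- rbind(
      small = tapply(s$n_small, s$group, sum),
      medium = tapply(s$n_medium, s$group, sum),
      large = tapply(s$n_large, s$group, sum)
    )
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    ct <- suppressWarnings(chisq.test(counts))
    tibble(method = "chi-squared", response = "size-class proportions",
           statistic = unname(ct$statistic), df1 = unname(ct$parameter),
           df2 = NA_real_, p.value = unname(ct$p.value))
  }
}
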