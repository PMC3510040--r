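#' Read an array-based ROH table (PLINK `.hom` dialect)
#'
#' @param path Whitespace-delimited table with at least the columns `IID`
#'   (individual), `CHR`, `POS1`, `POS2` (1-based inclusive bp), as written
#'   by PLINK's runs-of-homozygosity scan.
#' @return Tibble `individual_id, chrom, start, end, size_bp` in 0-based
#'   half-open coordinates, sorted per individual.
#' @export
read_array_roh_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  needed <- c("IID", "CHR", "POS1", "POS2")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0) {
    stop(".hom table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tibble(
    individual_id = as.character(d$IID),
    chrom = as.character(d$CHR),
    start = as.numeric(d$POS1) - 1,
    end = as.numeric(d$POS2),
    size_bp = as.numeric(d$POS2) - as.numeric(d$POS1) + 1
  ) %>%
    dplyr::arrange(.data$individual_id, .data$chrom, .data$start)
}

#' Sequence-based versus array-based cumulative ROH size
#'
#' The array resolves only the largest ROHs, so the sequence-based calls
#' are filtered to regions strictly larger than `min_size` (default 5 Mb)
#' before comparing per-individual cumulative sizes. Agreement is scored as
#' the squared Pearson correlation of the paired cumulative sizes; flagged
#' outliers can be excluded from that statistic while staying in the table.
#'
#' @param seq_rohs Sequence-based ROH tibble
#'   (`individual_id, chrom, start, end`).
#' @param array_rohs Array-based ROH tibble from [read_array_roh_table()].
#' @param min_size Size filter in bp applied to the sequence calls
#'   (strictly greater than; default 5e6). Use 0 to compare totals.
#' @param exclude Individual ids left out of the R-squared (still listed in
#'   the table with `excluded = TRUE`).
#' @return List of class `method_comparison`: `by_individual` tibble
#'   (`individual_id, cum_seq_bp, cum_array_bp, excluded`) over the shared
#'   individuals, `r_squared`, `n_used`, `min_size`.
#' @export
compare_methods <- function(seq_rohs, array_rohs, min_size = 5e6,
                            exclude = character()) {
  s <- as_tibble(seq_rohs)
  a <- as_tibble(array_rohs)
  ids <- intersect(unique(s$individual_id), unique(a$individual_id))
  if (length(ids) == 0) stop("no shared individual ids between the two sets")
  s$size_bp <- s$end - s$start
  a$size_bp <- a$end - a$start
  by_ind <- tibble(individual_id = ids) %>%
    dplyr::mutate(
      cum_seq_bp = unname(vapply(ids, function(i) {
        sum(s$size_bp[s$individual_id == i & s$size_bp > min_size])
      }, numeric(1))),
      cum_array_bp = unname(vapply(ids, function(i) {
        sum(a$size_bp[a$individual_id == i])
      }, numeric(1))),
      excluded = ids %in% exclude
    )
  used <- by_ind[!by_ind$excluded, ]
  r2 <- if (nrow(used) >= 2 &&
            stats::sd(used$cum_seq_bp) > 0 && stats::sd(used$cum_array_bp) > 0) {
    stats::cor(used$cum_seq_bp, used$cum_array_bp)^2
  } else NA_real_
  structure(
    list(by_individual = by_ind, r_squared = r2, n_used = nrow(used),
         min_size = min_size),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Sequence vs array ROH comparison (sequence ROHs > %.3g Mb)\n",
              x$min_size / 1e6))
  cat(sprintf("  individuals: %d (%d in R^2)\n", nrow(x$by_individual), x$n_used))
  cat(sprintf("  R^2 = %s\n",
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared)))
  invisible(x)
}
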