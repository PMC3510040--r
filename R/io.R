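#' Write variants as a minimal VCF
#'
#' @param variants Tibble `chrom, pos, ref, alt, gt, dp` (1-based `pos`).
#' @param path Output file (plain text).
#' @param individual_id Sample column name.
#' @param chrom_lengths Optional named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, individual_id = "sim1",
                      chrom_lengths = NULL) {
  v <- dplyr::arrange(as_tibble(variants), .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rohscape",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individual_id), collapse = "\t")
  )
  body <- if (nrow(v) == 0) character(0) else {
    paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), ".",
          v$ref, v$alt, ".", "PASS", ".", "GT:DP",
          paste0(v$gt, ":", as.integer(v$dp)), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a depth track as BEDGRAPH
#'
#' @param depth Run tibble `chrom, start, end, depth` (0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path) {
  readr::write_tsv(as_tibble(depth)[, c("chrom", "start", "end", "depth")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write intervals as 3-column BED
#'
#' @param intervals Tibble `chrom, start, end` (0-based half-open); a
#'   `roh_calls` or `shared_regions` object is reduced to its intervals.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "roh_calls")) intervals <- intervals$rohs
  if (inherits(intervals, "shared_regions")) intervals <- intervals$regions
  readr::write_tsv(as_tibble(intervals)[, c("chrom", "start", "end")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a gene annotation as GFF3
#'
#' @param genes Tibble `chrom, start, end, gene_id` (0-based half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  g <- as_tibble(genes)
  lines <- c("##gff-version 3",
             paste(g$chrom, "rohscape", "gene",
                   format(g$start + 1, scientific = FALSE, trim = TRUE),
                   format(g$end, scientific = FALSE, trim = TRUE),
                   ".", "+", ".", paste0("ID=", g$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic individual's bundle to a directory
#'
#' Emits `<id>.vcf`, `<id>.depth.bedgraph` and `<id>.truth.bed`.
#'
#' @param sim A `sim_individual` from [simulate_individual()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim_individual <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_individual"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, paste0(sim$individual_id, ".vcf")),
    depth = file.path(dir, paste0(sim$individual_id, ".depth.bedgraph")),
    truth = file.path(dir, paste0(sim$individual_id, ".truth.bed"))
  )
  write_vcf(sim$variants, paths[["vcf"]], individual_id = sim$individual_id,
            chrom_lengths = sim$spec$chrom_lengths)
  write_bedgraph(sim$depth, paths[["depth"]])
  write_bed(sim$truth, paths[["truth"]])
  invisible(paths)
}
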