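#' Coverage-corrected heterozygosity per bin
#'
#' The correction rescales the raw heterozygous-SNP count of a bin to a full
#' bin's worth of sufficiently covered bases: `snp_count * bin_size /
#' covered_bp`. A bin half of whose bases pass the depth window therefore has
#' its count doubled, making bins with different coverage comparable.
#'
#' @param snp_count Heterozygous SNVs counted in the bin (depth-filtered).
#' @param covered_bp Bases of the bin whose depth lies in the accepted
#'   window. Must be positive wherever `snp_count > 0`.
#' @param bin_size Bin width in bp.
#' @return Corrected count per `bin_size` covered bases; 0 where
#'   `snp_count == 0`, `NA` where `covered_bp == 0` with a positive count.
#' @export
#' @examples
#' compute_snpbin(5, 5000, 10000)  # 10
compute_snpbin <- function(snp_count, covered_bp, bin_size = 10000) {
  out <- ifelse(snp_count == 0, 0,
                ifelse(covered_bp > 0, snp_count * bin_size / covered_bp, NA_real_))
  as.numeric(out)
}

is_het_gt <- function(gt) {
  a <- sub("[:].*$", "", gt)            # strip trailing FORMAT subfields
  parts <- strsplit(a, "[/|]")
  vapply(parts, function(p) {
    length(p) == 2 && !any(p == ".") && p[1] != p[2]
  }, logical(1))
}

is_snv <- function(ref, alt) {
  alt_ok <- vapply(strsplit(alt, ","), function(a) all(nchar(a) == 1 & a != "*"),
                   logical(1))
  nchar(ref) == 1 & alt_ok
}

# cumulative covered bases strictly before position x (0-based half-open
# runs), vectorised over x; runs must be sorted and disjoint per chromosome
cum_covered_before <- function(x, run_start, run_end) {
  if (length(run_start) == 0) return(numeric(length(x)))
  len <- run_end - run_start
  cum <- cumsum(len)
  idx <- findInterval(x, run_start)
  prev <- ifelse(idx >= 1, cum[pmax(idx, 1)] - len[pmax(idx, 1)], 0)
  inside <- ifelse(idx >= 1, pmin(pmax(x - run_start[pmax(idx, 1)], 0), len[pmax(idx, 1)]), 0)
  prev + inside
}

#' Read a depth-of-coverage track
#'
#' Accepts either BEDGRAPH (`chrom start end depth`, 0-based half-open) or
#' `samtools depth` 3-column output (`chrom pos depth`, 1-based per base).
#' The format is sniffed from the column count of the first data line.
#'
#' @param path Plain-text (optionally gzipped) track file.
#' @return Tibble `chrom, start, end, depth` in 0-based half-open
#'   coordinates, adjacent equal-depth runs merged.
#' @export
read_depth_track <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^(#|track|browser)", first)]
  if (length(first) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  depth = numeric()))
  }
  ncol <- length(strsplit(first[[1]], "[\t ]+")[[1]])
  if (ncol == 4) {
    d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                         comment = "#", show_col_types = FALSE, progress = FALSE)
  } else if (ncol == 3) {
    d <- readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                         comment = "#", show_col_types = FALSE, progress = FALSE)
    d <- dplyr::mutate(d, start = .data$pos - 1, end = .data$pos)
    d <- dplyr::select(d, "chrom", "start", "end", "depth")
  } else {
    stop("depth track must have 3 (samtools depth) or 4 (BEDGRAPH) columns, found ",
         ncol)
  }
  collapse_depth_runs(d)
}

# merge touching runs of identical depth (keeps tracks compact)
collapse_depth_runs <- function(d) {
  d <- dplyr::arrange(as_tibble(d), .data$chrom, .data$start)
  n <- nrow(d)
  if (n == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  depth = numeric()))
  }
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-n] |
                 d$depth[-1] != d$depth[-n] |
                 d$start[-1] != d$end[-n])
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  tibble(chrom = d$chrom[first], start = d$start[first],
         end = d$end[last], depth = d$depth[first])
}

#' Read called variants from a VCF
#'
#' Extracts chromosome, position, alleles, the first sample's genotype and a
#' per-site depth (FORMAT `DP` when present, else INFO `DP`).
#'
#' @param path VCF file (v4.x, plain or gzipped).
#' @param sample Sample column to use; defaults to the first.
#' @return Tibble `chrom, pos, ref, alt, gt, dp` with `pos` 1-based.
#' @export
read_vcf_variants <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = numeric(), ref = character(),
                  alt = character(), gt = character(), dp = numeric()))
  }
  gt_mat <- vcfR::extract.gt(v, element = "GT")
  if (is.null(sample)) sample <- colnames(gt_mat)[1]
  gt <- gt_mat[, sample]
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, sample],
                 error = function(e) rep(NA_real_, nrow(fix)))
  if (all(is.na(dp))) {
    info_dp <- vcfR::extract.info(v, element = "DP", as.numeric = TRUE)
    if (!is.null(info_dp)) dp <- info_dp
  }
  tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    gt = unname(gt), dp = unname(dp)
  )
}

#' Bin heterozygous variants into a coverage-corrected grid
#'
#' The workhorse of the binning stage: counts depth-filtered heterozygous
#' SNVs per fixed-width bin, measures how many bases of each bin pass the
#' per-base depth window, and computes the coverage-corrected `snpbin`.
#'
#' @param variants Tibble with columns `chrom, pos` (1-based), `ref, alt,
#'   gt, dp` as returned by [read_vcf_variants()] or the simulator.
#' @param depth Depth runs `chrom, start, end, depth` (0-based half-open),
#'   as from [read_depth_track()].
#' @param chrom_lengths Named vector of chromosome lengths in bp. `NULL`
#'   infers each length from the end of its depth track.
#' @param filter A [depth_filter()]. A `NULL` `max_dp` is resolved to twice
#'   the track's length-weighted mean depth.
#' @param bin_size Bin width in bp (default 10000).
#' @param cov_frac Covered-bin fraction threshold (default 0.10).
#' @param individual_id Label stored in the result.
#' @return Tibble `individual_id, chrom, bin_start, bin_end, snp_count,
#'   covered_bp, snpbin, covered`, one row per bin, sorted.
#' @export
bin_variants <- function(variants, depth, chrom_lengths = NULL,
                         filter = depth_filter(), bin_size = 10000,
                         cov_frac = 0.10, individual_id = "ind") {
  stopifnot(inherits(filter, "depth_filter"))
  depth <- dplyr::arrange(as_tibble(depth), .data$chrom, .data$start)

  vcf_chroms <- unique(as.character(variants$chrom))
  depth_chroms <- unique(as.character(depth$chrom))
  missing_chr <- setdiff(vcf_chroms, depth_chroms)
  if (length(missing_chr) > 0) {
    stop("chromosomes present in the VCF but absent from the depth track: ",
         paste(missing_chr, collapse = ", "),
         " (depth track has: ", paste(depth_chroms, collapse = ", "), ")")
  }

  if (is.null(chrom_lengths)) {
    cl <- depth %>% dplyr::group_by(.data$chrom) %>%
      dplyr::summarise(len = max(.data$end), .groups = "drop")
    chrom_lengths <- setNames(cl$len, cl$chrom)
  }

  max_dp <- filter$max_dp
  if (is.null(max_dp)) {
    w <- (depth$end - depth$start)
    max_dp <- 2 * sum(depth$depth * w) / sum(w)
  }

  ok_depth <- depth[depth$depth >= filter$min_dp & depth$depth <= max_dp, ]

  v <- as_tibble(variants)
  if (nrow(v) > 0) {
    keep <- is_het_gt(v$gt) & !is.na(v$dp) &
      v$dp >= filter$min_dp & v$dp <= max_dp
    if (filter$exclude_indels) keep <- keep & is_snv(v$ref, v$alt)
    v <- v[keep, ]
  }

  grids <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    bin_start <- seq(0, len - 1, by = bin_size)
    bin_end <- pmin(bin_start + bin_size, len)
    runs <- ok_depth[ok_depth$chrom == ch, ]
    cb <- cum_covered_before(c(bin_start, len), runs$start, runs$end)
    covered_bp <- cb[-1] - cb[-length(cb)]
    pos0 <- v$pos[v$chrom == ch] - 1
    snp_count <- tabulate(findInterval(pos0, bin_start), nbins = length(bin_start))
    tibble(
      individual_id = individual_id, chrom = ch,
      bin_start = bin_start, bin_end = bin_end,
      snp_count = snp_count, covered_bp = covered_bp,
      snpbin = compute_snpbin(snp_count, covered_bp, bin_size),
      covered = covered_bp >= cov_frac * (bin_end - bin_start)
    )
  })
  dplyr::bind_rows(grids)
}

#' Read, filter, and bin variants from files
#'
#' Convenience composition of [read_vcf_variants()], [read_depth_track()]
#' and [bin_variants()].
#'
#' @inheritParams bin_variants
#' @param vcf_path,depth_path Input files.
#' @param sample VCF sample column (default first).
#' @return The bin grid tibble of [bin_variants()].
#' @export
read_filtered_variants <- function(vcf_path, depth_path, chrom_lengths = NULL,
                                   filter = depth_filter(), bin_size = 10000,
                                   cov_frac = 0.10, individual_id = "ind",
                                   sample = NULL) {
  bin_variants(read_vcf_variants(vcf_path, sample = sample),
               read_depth_track(depth_path),
               chrom_lengths = chrom_lengths, filter = filter,
               bin_size = bin_size, cov_frac = cov_frac,
               individual_id = individual_id)
}

#' Genomic average heterozygosity per bin
#'
#' Mean `snpbin` over sufficiently covered autosomal bins of one individual.
#' This is the unit in which all caller thresholds are expressed.
#'
#' @param bins Bin grid tibble from [bin_variants()].
#' @return A single number, the mean snpbin over covered bins.
#' @export
genomic_average <- function(bins) {
  cov <- bins$snpbin[bins$covered]
  if (length(cov) == 0) {
    stop("no covered bins: cannot compute a genomic average")
  }
  avg <- mean(cov)
  if (avg == 0) {
    stop("genomic average is 0 (no heterozygosity at all); ",
         "ROH thresholds would be degenerate")
  }
  avg
}
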