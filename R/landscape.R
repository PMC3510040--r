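# index of the relative-position bin (1..n_bins) for relative positions in
# [0, 1]; bins are half-open with the final bin closed at 1.0
relative_bin_index <- function(relpos, n_bins = 20) {
  pmin(floor(relpos * n_bins) + 1L, n_bins)
}

relative_bin_edges <- function(n_bins = 20) {
  tibble(segment = seq_len(n_bins),
         rel_lower = (seq_len(n_bins) - 1) / n_bins,
         rel_upper = seq_len(n_bins) / n_bins)
}

#' Average a per-bin value over relative chromosomal position
#'
#' Maps each genomic bin to its relative position (midpoint divided by
#' chromosome length), averages the value within each of `n_bins` equal
#' relative-position bins per chromosome, then averages those profiles
#' across chromosomes so that chromosomes of different sizes contribute
#' equally. Position 0 is the left chromosome end, 1 the right.
#'
#' @param df Tibble with columns `chrom, start, end` (0-based half-open)
#'   and the value column.
#' @param value Name of the value column.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_bins Number of relative-position bins (default 20, step 0.05).
#' @return Tibble `segment, rel_lower, rel_upper, value, n` where `n` is
#'   the number of contributing genomic bins and `value` is `NA` for empty
#'   positional bins.
#' @export
relative_profile <- function(df, value, chrom_lengths, n_bins = 20) {
  df <- as_tibble(df)
  stopifnot(all(df$chrom %in% names(chrom_lengths)))
  mid <- (df$start + df$end) / 2
  rel <- mid / chrom_lengths[as.character(df$chrom)]
  seg <- relative_bin_index(rel, n_bins)
  per_chrom <- tibble(chrom = df$chrom, segment = seg, v = df[[value]]) %>%
    dplyr::filter(!is.na(.data$v)) %>%
    dplyr::group_by(.data$chrom, .data$segment) %>%
    dplyr::summarise(v = mean(.data$v), n = dplyr::n(), .groups = "drop")
  prof <- per_chrom %>%
    dplyr::group_by(.data$segment) %>%
    dplyr::summarise(value = mean(.data$v), n = sum(.data$n), .groups = "drop")
  relative_bin_edges(n_bins) %>%
    dplyr::left_join(prof, by = "segment") %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' GC fraction per genomic bin
#'
#' @param fasta Path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @param bin_size Bin width in bp (default 10000).
#' @return Tibble `chrom, start, end, gc` with `gc` the fraction of G/C
#'   among unambiguous bases; `NA` where a bin is all-N.
#' @export
gc_content_bins <- function(fasta, bin_size = 10000) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else {
    Biostrings::readDNAStringSet(fasta)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    len <- length(s)
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    v <- Biostrings::Views(s, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
    tibble(chrom = ch, start = starts - 1, end = ends, gc = gc)
  })
  dplyr::bind_rows(out)
}

#' GC-content profile over relative chromosomal position
#'
#' @inheritParams gc_content_bins
#' @param n_bins Relative-position bins (default 20).
#' @return A [relative_profile()] tibble of mean GC fraction.
#' @export
gc_profile <- function(fasta, bin_size = 10000, n_bins = 20) {
  bins <- gc_content_bins(fasta, bin_size = bin_size)
  lens <- tapply(bins$end, bins$chrom, max)
  relative_profile(dplyr::rename(bins, value = "gc"), "value",
                   setNames(as.numeric(lens), names(lens)), n_bins = n_bins)
}

#' Read a genetic map table
#'
#' @param path TSV with columns `chrom, bp, cm` (header optional in that
#'   order): marker chromosome, physical position and genetic position.
#' @return Sorted tibble `chrom, bp, cm`.
#' @export
read_genetic_map <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("chrom", "bp", "cm") %in% names(d))) {
    d <- readr::read_tsv(path, col_names = c("chrom", "bp", "cm"),
                         show_col_types = FALSE, progress = FALSE)
  }
  dplyr::arrange(d[, c("chrom", "bp", "cm")], .data$chrom, .data$bp)
}

#' Recombination-rate profile over relative chromosomal position
#'
#' Each pair of neighbouring markers yields a local rate, the ratio of
#' genetic to physical distance (cM/Mb), assigned to both markers of the
#' pair. The profile is the mean rate over all markers falling in each
#' relative-position bin, pooled across chromosomes. Marker pairs at
#' identical physical positions are skipped.
#'
#' @param map Tibble `chrom, bp, cm` (sorted by `bp` within chromosome,
#'   `cm` non-decreasing), as from [read_genetic_map()].
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_bins Relative-position bins (default 20).
#' @return Tibble `segment, rel_lower, rel_upper, value, n` with `value`
#'   the mean cM/Mb and `n` the marker count; `NA` where no markers fall.
#' @export
recombination_profile <- function(map, chrom_lengths, n_bins = 20) {
  map <- as_tibble(map)
  recs <- lapply(split(map, map$chrom), function(m) {
    if (is.unsorted(m$bp)) stop("genetic map not sorted by bp within chromosome ",
                                m$chrom[1])
    if (is.unsorted(m$cm)) stop("genetic positions decrease within chromosome ",
                                m$chrom[1])
    if (nrow(m) < 2) return(NULL)
    dbp <- diff(m$bp); dcm <- diff(m$cm)
    keep <- dbp > 0
    rate <- dcm[keep] / (dbp[keep] / 1e6)
    left <- which(keep); right <- left + 1L
    tibble(chrom = m$chrom[1],
           bp = c(m$bp[left], m$bp[right]),
           rate = c(rate, rate))
  })
  recs <- dplyr::bind_rows(recs)
  if (nrow(recs) == 0) {
    return(dplyr::mutate(relative_bin_edges(n_bins), value = NA_real_, n = 0L))
  }
  rel <- recs$bp / chrom_lengths[as.character(recs$chrom)]
  seg <- relative_bin_index(pmin(pmax(rel, 0), 1), n_bins)
  prof <- tibble(segment = seg, rate = recs$rate) %>%
    dplyr::group_by(.data$segment) %>%
    dplyr::summarise(value = mean(.data$rate), n = dplyr::n(), .groups = "drop")
  relative_bin_edges(n_bins) %>%
    dplyr::left_join(prof, by = "segment") %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Nucleotide-diversity profile over relative chromosomal position
#'
#' Mean snpbin of covered bins per relative-position bin, averaged per
#' chromosome then across chromosomes.
#'
#' @param bins Bin grid tibble (one individual, or several row-bound).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_bins Relative-position bins (default 20).
#' @return A [relative_profile()] tibble of mean snpbin.
#' @export
pi_profile <- function(bins, chrom_lengths, n_bins = 20) {
  b <- as_tibble(bins)[bins$covered, ]
  relative_profile(
    tibble(chrom = b$chrom, start = b$bin_start, end = b$bin_end,
           value = b$snpbin),
    "value", chrom_lengths, n_bins = n_bins)
}

#' Positional distribution of ROHs of one size class
#'
#' Each ROH contributes its constituent bins' relative midpoint positions;
#' counts are normalised to the total number of ROH bins in that size
#' class, so each non-empty class's distribution sums to one.
#'
#' @param rohs ROH tibble (from `tidy()` on [call_rohs()] output, possibly
#'   row-bound over individuals) with `chrom, start, end` and, unless
#'   `size_class` is `NULL`, a `size_class` column.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param size_class Class to profile (`"small"`, `"medium"`, `"large"`),
#'   or `NULL` to use all ROHs as one class.
#' @param bin_size Bin width used for decomposition (default 10000).
#' @param n_bins Relative-position bins (default 20).
#' @return Tibble `segment, rel_lower, rel_upper, density, n`; densities
#'   are `NA` for an empty class and otherwise sum to one.
#' @export
roh_positional_distribution <- function(rohs, chrom_lengths,
                                        size_class = NULL, bin_size = 10000,
                                        n_bins = 20) {
  r <- as_tibble(rohs)
  if (!is.null(size_class)) r <- r[r$size_class == size_class, ]
  edges <- relative_bin_edges(n_bins)
  if (nrow(r) == 0) {
    return(dplyr::mutate(edges, density = NA_real_, n = 0L))
  }
  counts <- numeric(n_bins)
  for (k in seq_len(nrow(r))) {
    starts <- seq(r$start[k], r$end[k] - 1, by = bin_size)
    mids <- (starts + pmin(starts + bin_size, r$end[k])) / 2
    rel <- mids / chrom_lengths[[as.character(r$chrom[k])]]
    tab <- tabulate(relative_bin_index(rel, n_bins), nbins = n_bins)
    counts <- counts + tab
  }
  dplyr::mutate(edges, density = counts / sum(counts), n = as.integer(counts))
}

#' Pearson correlation between two landscape profiles
#'
#' @param a,b Equal-length numeric vectors, or profile tibbles carrying a
#'   `value` or `density` column.
#' @return Tibble `estimate, statistic, p.value, n` from a two-sided
#'   Pearson product-moment test on the complete pairs.
#' @export
correlate_profiles <- function(a, b) {
  pull_vec <- function(x) {
    if (is.data.frame(x)) {
      col <- intersect(c("value", "density"), names(x))[1]
      if (is.na(col)) stop("profile tibble must have a 'value' or 'density' column")
      x[[col]]
    } else as.numeric(x)
  }
  va <- pull_vec(a); vb <- pull_vec(b)
  stopifnot(length(va) == length(vb))
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3) stop("need at least 3 complete pairs to correlate")
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    stop("zero variance in a profile: correlation undefined")
  }
  ct <- cor.test(va[ok], vb[ok], method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p.value = ct$p.value, n = sum(ok))
}

#' Read a gene annotation (GFF3 or BED)
#'
#' @param path GFF3 or BED file. GFF3 records of type `gene` are used when
#'   present (all records otherwise).
#' @return Tibble `chrom, start, end, gene_id` in 0-based half-open
#'   coordinates.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    md <- md[md$type == "gene", ]
  }
  id <- if ("ID" %in% names(md)) md$ID
        else if ("Name" %in% names(md)) md$Name
        else if ("name" %in% names(md)) md$name
        else paste0("gene", seq_len(nrow(md)))
  tibble(chrom = as.character(md$seqnames), start = md$start - 1,
         end = md$end, gene_id = as.character(id))
}

#' Relative gene content per chromosome segment
#'
#' Divides each chromosome into `n_segments` equal parts and reports the
#' fraction of the chromosome's genes starting in each segment
#' (proportional to the chromosome's gene total). Genes spanning a segment
#' boundary are assigned once, by start coordinate.
#'
#' @param genes Tibble `chrom, start, end, gene_id` (0-based half-open),
#'   as from [read_gene_annotation()].
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_segments Number of segments (default 20).
#' @return Tibble `chrom, segment, rel_lower, rel_upper, n_genes, frac`;
#'   `frac` is `NA` for chromosomes with no genes.
#' @export
gene_density_segments <- function(genes, chrom_lengths, n_segments = 20) {
  g <- as_tibble(genes)
  edges <- relative_bin_edges(n_segments)
  out <- lapply(names(chrom_lengths), function(ch) {
    gs <- g$start[g$chrom == ch]
    counts <- if (length(gs) == 0) rep(0L, n_segments) else {
      tabulate(relative_bin_index(gs / chrom_lengths[[ch]], n_segments),
               nbins = n_segments)
    }
    dplyr::mutate(edges, chrom = ch, n_genes = as.integer(counts),
                  frac = if (sum(counts) > 0) counts / sum(counts) else NA_real_)
  })
  dplyr::bind_rows(out) %>%
    dplyr::select("chrom", "segment", "rel_lower", "rel_upper", "n_genes",
                  "frac")
}

#' Genome-wide gene-density profile
#'
#' Averages the per-chromosome segment fractions of
#' [gene_density_segments()] across chromosomes, yielding a profile
#' comparable (and correlatable) with [roh_positional_distribution()].
#'
#' @inheritParams gene_density_segments
#' @return Tibble `segment, rel_lower, rel_upper, value`.
#' @export
gene_density_profile <- function(genes, chrom_lengths, n_segments = 20) {
  gene_density_segments(genes, chrom_lengths, n_segments) %>%
    dplyr::group_by(.data$segment, .data$rel_lower, .data$rel_upper) %>%
    dplyr::summarise(value = mean(.data$frac, na.rm = TRUE), .groups = "drop")
}
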