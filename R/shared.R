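# interval tibble (chrom, start, end; 0-based half-open) -> per-chromosome
# IRanges list
intervals_to_iranges <- function(df) {
  lapply(split(df, df$chrom), function(d) {
    IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
  })
}

iranges_to_tibble <- function(ir_by_chrom) {
  rows <- lapply(names(ir_by_chrom), function(ch) {
    ir <- ir_by_chrom[[ch]]
    if (length(ir) == 0) return(NULL)
    tibble(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Regions homozygous in every member of a group
#'
#' Base-pair-level intersection of the ROH interval sets of several
#' individuals: the regions returned lie inside a ROH of every member (or,
#' with `min_members = k`, of at least k members).
#'
#' @param rohs ROH tibble with `individual_id, chrom, start, end` — e.g.
#'   row-bound `tidy()` outputs of [call_rohs()] for the group's members.
#' @param min_members Minimum number of members a base must be homozygous
#'   in; default `NULL` means all members (strict intersection).
#' @return List of class `shared_regions`: `regions` tibble
#'   (`chrom, start, end, size_bp`), `cumulative_bp`, `members`.
#' @export
intersect_rohs <- function(rohs, min_members = NULL) {
  r <- as_tibble(rohs)
  members <- unique(r$individual_id)
  k <- if (is.null(min_members)) length(members) else min_members
  stopifnot(k >= 1, k <= max(length(members), 1))
  regions <- if (length(members) == 0) {
    tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    chroms <- unique(r$chrom)
    rows <- lapply(chroms, function(ch) {
      W <- max(r$end[r$chrom == ch])
      per_member <- lapply(members, function(m) {
        d <- r[r$chrom == ch & r$individual_id == m, ]
        IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      })
      cov <- Reduce(`+`, lapply(per_member, IRanges::coverage, width = W))
      ir <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
      if (length(ir) == 0) return(NULL)
      tibble(chrom = ch, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      tibble(chrom = character(), start = numeric(), end = numeric())
    } else {
      dplyr::arrange(out, .data$chrom, .data$start)
    }
  }
  regions$size_bp <- regions$end - regions$start
  structure(
    list(regions = regions, cumulative_bp = sum(regions$size_bp),
         members = members, min_members = k),
    class = "shared_regions"
  )
}

#' @export
print.shared_regions <- function(x, ...) {
  cat(sprintf("%d shared region(s) across %d member(s) (>= %d required), %.4g Mbp cumulative\n",
              nrow(x$regions), length(x$members), x$min_members,
              x$cumulative_bp / 1e6))
  invisible(x)
}

#' Regions homozygous in one group and in no outsider
#'
#' Intersects the ROHs of the in-group members, then subtracts every base
#' covered by any ROH of any out-group individual, leaving regions
#' exclusively and jointly homozygous in the group.
#'
#' @param rohs_in ROH tibble of the group's members
#'   (`individual_id, chrom, start, end`).
#' @param rohs_out ROH tibble of all other individuals.
#' @return A `shared_regions` object (see [intersect_rohs()]).
#' @export
exclusive_shared_rohs <- function(rohs_in, rohs_out) {
  shared <- intersect_rohs(rohs_in)
  if (nrow(shared$regions) == 0 || nrow(rohs_out) == 0) return(shared)
  out_ir <- intervals_to_iranges(as_tibble(rohs_out))
  kept <- lapply(split(shared$regions, shared$regions$chrom), function(d) {
    ir <- IRanges::IRanges(d$start + 1, d$end)
    sub <- out_ir[[d$chrom[1]]]
    if (!is.null(sub)) ir <- IRanges::setdiff(ir, sub)
    ir
  })
  regions <- iranges_to_tibble(kept)
  regions$size_bp <- regions$end - regions$start
  structure(
    list(regions = regions, cumulative_bp = sum(regions$size_bp),
         members = shared$members, min_members = shared$min_members),
    class = "shared_regions"
  )
}

#' Genes overlapping shared regions
#'
#' @param regions Region tibble (`chrom, start, end`) or a
#'   `shared_regions` object.
#' @param genes Gene tibble `chrom, start, end, gene_id` (0-based
#'   half-open), as from [read_gene_annotation()].
#' @return Tibble `chrom, start, end, gene_id` with one row per
#'   (region, overlapping gene) pair; overlap of at least one bp counts,
#'   so a gene merely abutting a region end is excluded.
#' @export
genes_in_regions <- function(regions, genes) {
  if (inherits(regions, "shared_regions")) regions <- regions$regions
  r <- as_tibble(regions); g <- as_tibble(genes)
  if (nrow(r) == 0 || nrow(g) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  gene_id = character()))
  }
  rows <- lapply(seq_len(nrow(r)), function(k) {
    hit <- g$chrom == r$chrom[k] & g$start < r$end[k] & g$end > r$start[k]
    if (!any(hit)) return(NULL)
    tibble(chrom = r$chrom[k], start = r$start[k], end = r$end[k],
           gene_id = g$gene_id[hit])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  gene_id = character()))
  }
  out
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each term, tests whether the gene set drawn from the background is
#' enriched for the term's genes, with the one-sided hypergeometric
#' upper-tail probability; p-values are adjusted for multiple testing with
#' the Benjamini-Hochberg procedure.
#'
#' @param gene_set Character vector of genes of interest (must be a subset
#'   of the background).
#' @param background_set Character vector, the gene universe.
#' @param term_map Tibble or data frame with columns `term, gene` mapping
#'   each term to its annotated genes (genes outside the background are
#'   ignored).
#' @return Tibble `term, n_term, n_overlap, p.value, q.value`, sorted by
#'   p-value. Terms with no annotated gene in the set get `p = 1`.
#' @export
term_enrichment <- function(gene_set, background_set, term_map) {
  gene_set <- unique(gene_set)
  background_set <- unique(background_set)
  extra <- setdiff(gene_set, background_set)
  if (length(extra) > 0) {
    stop("gene_set contains genes absent from the background: ",
         paste(head(extra, 5), collapse = ", "))
  }
  tm <- as_tibble(term_map)
  stopifnot(all(c("term", "gene") %in% names(tm)))
  tm <- tm[tm$gene %in% background_set, ]
  N <- length(background_set)
  n <- length(gene_set)
  per_term <- split(unique(tm)$gene, unique(tm)$term)
  res <- lapply(names(per_term), function(t) {
    K <- length(per_term[[t]])
    x <- length(intersect(per_term[[t]], gene_set))
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = t, n_term = K, n_overlap = x, p.value = p)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(term = character(), n_term = integer(),
                  n_overlap = integer(), p.value = numeric(),
                  q.value = numeric()))
  }
  out$q.value <- p.adjust(out$p.value, method = "BH")
  dplyr::arrange(out, .data$p.value)
}
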