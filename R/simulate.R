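#' Specification of a synthetic diploid individual
#'
#' Describes the statistical structure the pipeline assumes: a background
#' heterozygosity of about 1.7 SNPs per kb, planted autozygous tracts with
#' a small residual mutation load, roughly 8x sequencing depth with
#' dropout, and U-shaped recombination-rate and GC profiles along each
#' chromosome (high near the ends, low mid-chromosome).
#'
#' @param chrom_lengths Named chromosome lengths in bp (default five 20-Mb
#'   autosomes).
#' @param theta Background heterozygosity in SNPs per bp (default 1.7e-3,
#'   i.e. 1.7 per kb).
#' @param tract_lambda Expected number of planted autozygous tracts per
#'   genome (Poisson; apportioned to chromosomes by length).
#' @param tract_meanlog,tract_sdlog Log-normal parameters of tract length
#'   in bp.
#' @param tract_min_len Minimum tract length in bp (default one 10-kb bin).
#' @param tract_residual_frac Residual heterozygosity inside tracts as a
#'   fraction of `theta` (default 0.05 — mutations accumulated since the
#'   common ancestor).
#' @param tract_bias_recomb If `TRUE`, tract placement is biased toward
#'   low-recombination regions (probability proportional to the inverse
#'   local rate); default `FALSE` (uniform).
#' @param depth_mean Mean sequencing depth (default 8).
#' @param depth_size Negative-binomial size (dispersion) of per-block depth
#'   (default 15; larger is closer to Poisson).
#' @param depth_block Depth is drawn per block of this many bases (default
#'   200 bp) — the granularity of the emitted BEDGRAPH track.
#' @param dropout_rate_per_mb Expected dropout segments per Mb (depth 0).
#' @param dropout_mean_len Mean dropout-segment length in bp (exponential).
#' @param recomb_min,recomb_amp Recombination rate in cM/Mb at relative
#'   position x is `recomb_min + recomb_amp * (2x - 1)^2`: U-shaped, high
#'   at chromosome ends.
#' @param gc_base,gc_amp GC fraction at relative position x is
#'   `gc_base + gc_amp * (2x - 1)^2`: elevated toward the ends.
#' @param marker_spacing Genetic-map marker spacing in bp (default 50 kb).
#' @param genes_per_chrom Genes per chromosome in the random annotation.
#' @param gene_mean_len Mean gene length in bp.
#' @param fixed_tracts Optional tibble `chrom, start, end` of tracts to
#'   plant verbatim instead of random placement (tract number and length
#'   parameters are then ignored).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(chrom_lengths = setNames(rep(20e6, 5), paste0("chr", 1:5)),
                     theta = 1.7e-3,
                     tract_lambda = 40,
                     tract_meanlog = log(6e5),
                     tract_sdlog = 0.8,
                     tract_min_len = 1e4,
                     tract_residual_frac = 0.05,
                     tract_bias_recomb = FALSE,
                     depth_mean = 8,
                     depth_size = 15,
                     depth_block = 200,
                     dropout_rate_per_mb = 0.5,
                     dropout_mean_len = 2000,
                     recomb_min = 0.3,
                     recomb_amp = 2.7,
                     gc_base = 0.38,
                     gc_amp = 0.06,
                     marker_spacing = 5e4,
                     genes_per_chrom = 200,
                     gene_mean_len = 2e4,
                     fixed_tracts = NULL) {
  stopifnot(
    length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
    all(chrom_lengths >= 1e5),
    theta >= 0, tract_lambda >= 0, tract_residual_frac >= 0,
    tract_min_len >= 1,
    depth_mean > 0, depth_size > 0, depth_block >= 1,
    dropout_rate_per_mb >= 0, dropout_mean_len > 0,
    recomb_min >= 0, recomb_amp >= 0,
    gc_base > 0, gc_base + gc_amp < 1,
    marker_spacing >= 1, genes_per_chrom >= 0, gene_mean_len > 0
  )
  if (!is.null(fixed_tracts)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(fixed_tracts)),
              all(fixed_tracts$end > fixed_tracts$start),
              all(fixed_tracts$chrom %in% names(chrom_lengths)))
  }
  structure(as.list(environment()), class = "sim_spec")
}

#' Recombination-rate function of a simulation spec
#'
#' @param spec A [sim_spec()].
#' @return Function mapping relative position in `[0, 1]` to cM/Mb.
#' @export
recomb_rate_fun <- function(spec) {
  force(spec)
  function(relpos) spec$recomb_min + spec$recomb_amp * (2 * relpos - 1)^2
}

gc_fun <- function(spec) {
  force(spec)
  function(relpos) spec$gc_base + spec$gc_amp * (2 * relpos - 1)^2
}

#' Group presets for cohort simulation
#'
#' Parameter presets emulating the qualitative ROH regimes of pig
#' populations: `"eu-wild"` (many moderately sized tracts, low background
#' diversity — long-standing small populations), `"eu-domestic"` (many
#' tracts, moderate diversity), `"as-domestic"` (few but large tracts —
#' recent bottlenecks on a large source population) and `"as-wild"` (few
#' tracts, highest diversity).
#'
#' @param preset One of `"eu-wild"`, `"eu-domestic"`, `"as-domestic"`,
#'   `"as-wild"`.
#' @param ... Overrides passed on to [sim_spec()] (e.g. `chrom_lengths`,
#'   `tract_bias_recomb`).
#' @return A [sim_spec()].
#' @export
group_preset <- function(preset = c("eu-wild", "eu-domestic", "as-domestic",
                                    "as-wild"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "eu-wild" = list(theta = 1.4e-3, tract_lambda = 60,
                     tract_meanlog = log(4e5), tract_sdlog = 0.8),
    "eu-domestic" = list(theta = 1.7e-3, tract_lambda = 40,
                         tract_meanlog = log(6e5), tract_sdlog = 0.9),
    "as-domestic" = list(theta = 1.9e-3, tract_lambda = 12,
                         tract_meanlog = log(2e6), tract_sdlog = 0.7),
    "as-wild" = list(theta = 2.2e-3, tract_lambda = 5,
                     tract_meanlog = log(3e5), tract_sdlog = 0.8)
  )
  do.call(sim_spec, utils::modifyList(args, list(...)))
}

# place n non-overlapping tracts of given lengths on [0, len); returns a
# sorted tibble(start, end); placement optionally biased by weights over a
# 10-kb grid of candidate start positions
place_tracts <- function(lengths, len, weight_fun = NULL) {
  if (sum(lengths) > len) {
    stop("planted tract mass (", sum(lengths), " bp) exceeds chromosome length (",
         len, " bp)")
  }
  placed_s <- numeric(0); placed_e <- numeric(0)
  for (L in sort(lengths, decreasing = TRUE)) {
    ok <- FALSE
    for (try in seq_len(200)) {
      if (is.null(weight_fun)) {
        s <- floor(runif(1, 0, len - L + 1))
      } else {
        grid <- seq(0, len - L, by = 1e4)
        w <- weight_fun((grid + L / 2) / len)
        s <- sample(grid, 1, prob = w)
      }
      e <- s + L
      if (!any(s < placed_e & e > placed_s)) { ok <- TRUE; break }
    }
    if (ok) { placed_s <- c(placed_s, s); placed_e <- c(placed_e, e) }
  }
  o <- order(placed_s)
  tibble(start = placed_s[o], end = placed_e[o])
}

# Poisson-process heterozygous sites over segments with per-segment rates
poisson_sites <- function(seg_start, seg_end, rate) {
  pos <- lapply(seq_along(seg_start), function(k) {
    w <- seg_end[k] - seg_start[k]
    if (w <= 0 || rate[k] <= 0) return(numeric(0))
    n <- rpois(1, w * rate[k])
    if (n == 0) return(numeric(0))
    unique(floor(runif(n, seg_start[k], seg_end[k])))
  })
  sort(unique(unlist(pos)))
}

#' Simulate one diploid individual
#'
#' Places autozygous tracts, scatters heterozygous sites as a Poisson
#' process (`theta` outside tracts, `tract_residual_frac * theta` inside),
#' and draws a block-wise negative-binomial depth track with dropout
#' segments of depth 0. Each variant's `DP` is read off the depth track at
#' its position. Deterministic given `(spec, seed)`.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @param individual_id Label for the individual.
#' @return Object of class `sim_individual`: `variants` (tibble `chrom,
#'   pos, ref, alt, gt, dp` with 1-based `pos`, all genotypes `0/1`),
#'   `depth` (run tibble `chrom, start, end, depth`), `truth` (planted
#'   tracts `chrom, start, end`), plus `individual_id`, `spec`, `seed`.
#' @export
simulate_individual <- function(spec, seed = 1, individual_id = "sim1") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  genome_len <- sum(spec$chrom_lengths)
  rate_fun <- recomb_rate_fun(spec)
  weight_fun <- if (spec$tract_bias_recomb) function(x) 1 / rate_fun(x) else NULL

  all_var <- list(); all_depth <- list(); all_truth <- list()
  for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]

    tracts <- if (!is.null(spec$fixed_tracts)) {
      ft <- spec$fixed_tracts[spec$fixed_tracts$chrom == ch, ]
      if (sum(ft$end - ft$start) > len) {
        stop("planted tract mass exceeds chromosome length on ", ch)
      }
      dplyr::arrange(tibble(start = ft$start, end = ft$end), start)
    } else {
      n_tr <- rpois(1, spec$tract_lambda * len / genome_len)
      if (n_tr > 0) {
        lens <- pmax(round(rlnorm(n_tr, spec$tract_meanlog, spec$tract_sdlog)),
                     spec$tract_min_len)
        # keep the genome placeable: drop the largest draws until the tract
        # mass fits in at most 90% of the chromosome
        lens <- sort(lens)
        while (length(lens) > 0 && sum(lens) > 0.9 * len) {
          lens <- lens[-length(lens)]
        }
        place_tracts(lens, len, weight_fun)
      } else tibble(start = numeric(0), end = numeric(0))
    }

    # segment the chromosome into tract / non-tract pieces with rates
    bounds <- sort(unique(c(0, tracts$start, tracts$end, len)))
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1]
    in_tract <- vapply(seg_start, function(s) {
      any(s >= tracts$start & s < tracts$end)
    }, logical(1))
    rates <- ifelse(in_tract, spec$theta * spec$tract_residual_frac, spec$theta)
    pos0 <- poisson_sites(seg_start, seg_end, rates)

    # block-wise depth with dropout
    nb <- ceiling(len / spec$depth_block)
    depth_b <- rnbinom(nb, size = spec$depth_size, mu = spec$depth_mean)
    n_drop <- rpois(1, len / 1e6 * spec$dropout_rate_per_mb)
    if (n_drop > 0) {
      ds <- floor(runif(n_drop, 0, len))
      dl <- pmax(ceiling(rexp(n_drop, 1 / spec$dropout_mean_len)), 1)
      for (k in seq_len(n_drop)) {
        b1 <- ds[k] %/% spec$depth_block + 1
        b2 <- min(nb, (ds[k] + dl[k] - 1) %/% spec$depth_block + 1)
        depth_b[b1:b2] <- 0L
      }
    }

    if (length(pos0) > 0) {
      dp <- depth_b[pos0 %/% spec$depth_block + 1]
      bases <- c("A", "C", "G", "T")
      ref_i <- sample.int(4, length(pos0), replace = TRUE)
      alt_i <- (ref_i - 1 + sample.int(3, length(pos0), replace = TRUE)) %% 4 + 1
      all_var[[ch]] <- tibble(chrom = ch, pos = pos0 + 1, ref = bases[ref_i],
                              alt = bases[alt_i], gt = "0/1", dp = dp)
    }
    all_depth[[ch]] <- tibble(
      chrom = ch,
      start = (seq_len(nb) - 1) * spec$depth_block,
      end = pmin(seq_len(nb) * spec$depth_block, len),
      depth = depth_b
    )
    if (nrow(tracts) > 0) {
      all_truth[[ch]] <- tibble(chrom = ch, start = tracts$start,
                                end = tracts$end)
    }
  }

  variants <- dplyr::bind_rows(all_var)
  if (nrow(variants) == 0) {
    variants <- tibble(chrom = character(), pos = numeric(), ref = character(),
                       alt = character(), gt = character(), dp = numeric())
  }
  truth <- dplyr::bind_rows(all_truth)
  if (nrow(truth) == 0) {
    truth <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  structure(
    list(individual_id = individual_id,
         variants = variants,
         depth = collapse_depth_runs(dplyr::bind_rows(all_depth)),
         truth = truth, spec = spec, seed = seed),
    class = "sim_individual"
  )
}

#' @export
print.sim_individual <- function(x, ...) {
  cat(sprintf("Synthetic individual %s: %d het sites, %d planted tract(s), %.4g Mb genome\n",
              x$individual_id, nrow(x$variants), nrow(x$truth),
              sum(x$spec$chrom_lengths) / 1e6))
  invisible(x)
}

#' Simulate a reference genome with a U-shaped GC gradient
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @param gc_block Block size in bp within which GC probability is held
#'   constant (default 10 kb).
#' @return A `Biostrings::DNAStringSet`, one sequence per chromosome.
#' @export
simulate_reference <- function(spec, seed = 1, gc_block = 1e4) {
  set.seed(seed)
  seqs <- lapply(names(spec$chrom_lengths), function(ch) {
    len <- spec$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = gc_block)
    widths <- pmin(starts + gc_block, len) - starts
    gc <- gc_fun(spec)((starts + widths / 2) / len)
    blocks <- vapply(seq_along(starts), function(k) {
      p <- c((1 - gc[k]) / 2, gc[k] / 2, gc[k] / 2, (1 - gc[k]) / 2)
      paste(sample(c("A", "C", "G", "T"), widths[k], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    paste(blocks, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(spec$chrom_lengths)
  out
}

#' Deterministic genetic map with the spec's U-shaped rate
#'
#' Markers are placed every `marker_spacing` bp; genetic positions are the
#' cumulative integral of the recombination-rate function, so the
#' marker-pair rates recover the U shape.
#'
#' @param spec A [sim_spec()].
#' @return Tibble `chrom, bp, cm`.
#' @export
simulate_genetic_map <- function(spec) {
  rate <- recomb_rate_fun(spec)
  out <- lapply(names(spec$chrom_lengths), function(ch) {
    len <- spec$chrom_lengths[[ch]]
    bp <- seq(0, len, by = spec$marker_spacing)
    mids <- (bp[-length(bp)] + bp[-1]) / 2 / len
    dcm <- rate(mids) * diff(bp) / 1e6
    tibble(chrom = ch, bp = bp, cm = c(0, cumsum(dcm)))
  })
  dplyr::bind_rows(out)
}

#' Random gene annotation
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @return Tibble `chrom, start, end, gene_id` (0-based half-open).
#' @export
simulate_annotation <- function(spec, seed = 1) {
  set.seed(seed)
  out <- lapply(names(spec$chrom_lengths), function(ch) {
    len <- spec$chrom_lengths[[ch]]
    n <- spec$genes_per_chrom
    if (n == 0) return(NULL)
    start <- sort(floor(runif(n, 0, len - 1000)))
    glen <- pmax(ceiling(rexp(n, 1 / spec$gene_mean_len)), 500)
    tibble(chrom = ch, start = start, end = pmin(start + glen, len),
           gene_id = sprintf("%s_g%04d", ch, seq_len(n)))
  })
  dplyr::bind_rows(out)
}

#' Simulate a cohort of groups of synthetic individuals
#'
#' Independent individuals drawn from per-group parameter presets, sharing
#' one genome (chromosome lengths, genetic map, gene annotation, and
#' optionally a reference sequence).
#'
#' @param presets Character vector of [group_preset()] names, or a named
#'   list of [sim_spec()] objects (one per group).
#' @param n_per_group Individuals per group (default 3).
#' @param seed Integer seed; every individual receives a seed derived from
#'   it, so the cohort is reproducible byte for byte.
#' @param chrom_lengths Shared chromosome lengths (default the
#'   [sim_spec()] default).
#' @param tract_bias_recomb Passed to every group's spec: bias tract
#'   placement toward low-recombination regions.
#' @param include_reference Also simulate the reference FASTA sequence
#'   (default `FALSE`; the binning and calling stages do not need it).
#' @return Object of class `sim_cohort`: `individuals` (list of
#'   [simulate_individual()] results), `groups` tibble
#'   (`individual_id, group`), `map`, `genes`, `chrom_lengths`,
#'   `reference` (or `NULL`), `seed`.
#' @export
simulate_cohort <- function(presets = c("eu-wild", "eu-domestic",
                                        "as-domestic", "as-wild"),
                            n_per_group = 3, seed = 1,
                            chrom_lengths = setNames(rep(20e6, 5),
                                                     paste0("chr", 1:5)),
                            tract_bias_recomb = FALSE,
                            include_reference = FALSE) {
  specs <- if (is.list(presets)) presets else {
    setNames(lapply(presets, function(p) {
      group_preset(p, chrom_lengths = chrom_lengths,
                   tract_bias_recomb = tract_bias_recomb)
    }), presets)
  }
  base <- specs[[1]] %||% sim_spec(chrom_lengths = chrom_lengths)
  individuals <- list(); rows <- list()
  i <- 0
  for (g in names(specs)) {
    for (j in seq_len(n_per_group)) {
      i <- i + 1
      id <- sprintf("%s_%d", g, j)
      ind_seed <- (as.numeric(seed) * 1009 + i * 7919) %% 2147483647
      individuals[[id]] <- simulate_individual(specs[[g]], seed = ind_seed,
                                               individual_id = id)
      rows[[id]] <- tibble(individual_id = id, group = g)
    }
  }
  structure(
    list(individuals = individuals, groups = dplyr::bind_rows(rows),
         map = simulate_genetic_map(base),
         genes = simulate_annotation(base, seed = seed),
         chrom_lengths = chrom_lengths,
         reference = if (include_reference) simulate_reference(base, seed = seed)
                     else NULL,
         seed = seed),
    class = "sim_cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individual(s) in %d group(s), %.4g Mb genome, seed %s\n",
              length(x$individuals), length(unique(x$groups$group)),
              sum(x$chrom_lengths) / 1e6, format(x$seed)))
  invisible(x)
}

# per-chromosome union IRanges of an interval tibble
interval_union <- function(df) intervals_to_iranges(as_tibble(df))

overlap_bp_with <- function(df, union_ir) {
  vapply(seq_len(nrow(df)), function(k) {
    u <- union_ir[[as.character(df$chrom[k])]]
    if (is.null(u)) return(0)
    sum(IRanges::width(IRanges::intersect(
      IRanges::IRanges(df$start[k] + 1, df$end[k]), u)))
  }, numeric(1))
}

#' Score called ROHs against planted truth tracts
#'
#' A truth tract counts as recovered when called ROHs cover at least
#' `min_overlap_frac` of it; a called ROH is a true positive when at least
#' that fraction of it lies inside truth. Boundary error is the mean
#' absolute offset between each recovered tract's breakpoints and those of
#' its best-overlapping call, in bins.
#'
#' @param truth Tract tibble `chrom, start, end` (e.g. a `sim_individual`'s
#'   `truth`), or a `sim_individual`.
#' @param called ROH tibble `chrom, start, end` or a `roh_calls` object.
#' @param min_overlap_frac Overlap fraction defining recovery (default
#'   0.5).
#' @param min_size Only truth tracts and calls at least this many bp enter
#'   the scoring (default 0 — everything).
#' @param bin_size Bin width for the boundary-error unit (default 10000).
#' @return One-row tibble: `n_truth, n_called, recall, precision,
#'   boundary_error_bins`. `precision` is `NA` when there are no calls,
#'   `recall` `NA` when there is no truth.
#' @export
recovery_report <- function(truth, called, min_overlap_frac = 0.5,
                            min_size = 0, bin_size = 10000) {
  if (inherits(truth, "sim_individual")) truth <- truth$truth
  if (inherits(called, "roh_calls")) called <- called$rohs
  truth <- as_tibble(truth); called <- as_tibble(called)
  truth <- truth[truth$end - truth$start >= min_size, ]
  called_f <- called[called$end - called$start >= min_size, ]

  call_union <- interval_union(called)
  truth_union <- interval_union(truth)

  recall <- if (nrow(truth) == 0) NA_real_ else {
    ov <- overlap_bp_with(truth, call_union)
    mean(ov / (truth$end - truth$start) >= min_overlap_frac)
  }
  precision <- if (nrow(called_f) == 0) NA_real_ else {
    ov <- overlap_bp_with(called_f, truth_union)
    mean(ov / (called_f$end - called_f$start) >= min_overlap_frac)
  }

  boundary <- NA_real_
  if (nrow(truth) > 0 && nrow(called) > 0) {
    errs <- unlist(lapply(seq_len(nrow(truth)), function(k) {
      cand <- called[called$chrom == truth$chrom[k] &
                       called$start < truth$end[k] &
                       called$end > truth$start[k], ]
      if (nrow(cand) == 0) return(NULL)
      ov <- pmin(cand$end, truth$end[k]) - pmax(cand$start, truth$start[k])
      best <- cand[which.max(ov), ]
      cov <- overlap_bp_with(truth[k, ], call_union)
      if (cov / (truth$end[k] - truth$start[k]) < min_overlap_frac) return(NULL)
      (abs(best$start - truth$start[k]) + abs(best$end - truth$end[k])) / 2
    }))
    if (length(errs) > 0) boundary <- mean(errs) / bin_size
  }

  tibble(n_truth = nrow(truth), n_called = nrow(called_f),
         recall = recall, precision = precision,
         boundary_error_bins = boundary)
}
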