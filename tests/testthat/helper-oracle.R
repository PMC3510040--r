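# Literal, unoptimized reference implementations used as oracles.
# Everything here works bin-by-bin with explicit loops and exhaustive window
# enumeration, independent of the package's vectorised code paths.

oracle_window_mean <- function(snpbin, covered, idx) {
  use <- idx[covered[idx]]
  if (length(use) == 0) return(NaN)
  mean(snpbin[use])
}

oracle_candidate_mask <- function(snpbin, covered, avg, L, mode = "anchored") {
  n <- length(snpbin)
  mask <- logical(n)
  if (n < L) return(mask)
  for (j in seq_len(n)) {
    if (mode == "anchored") {
      starts <- c(if (j + L - 1 <= n) j, if (j - L + 1 >= 1) j - L + 1)
    } else {
      lo <- max(1, j - L + 1); hi <- min(j, n - L + 1)
      starts <- if (lo <= hi) lo:hi else integer(0)
    }
    for (s in starts) {
      m <- oracle_window_mean(snpbin, covered, s:(s + L - 1))
      if (!is.nan(m) && m < avg) { mask[j] <- TRUE; break }
    }
  }
  mask
}

oracle_stretches <- function(mask) {
  out <- list()
  j <- 1
  while (j <= length(mask)) {
    if (mask[j]) {
      k <- j
      while (k < length(mask) && mask[k + 1]) k <- k + 1
      out[[length(out) + 1]] <- j:k
      j <- k + 1
    } else j <- j + 1
  }
  out
}

# literal evaluation of threshold + relaxation rules (a)-(c) on one stretch,
# splitting at failing aberrant runs, recursively
oracle_threshold_relax <- function(idx, snpbin, covered, avg, params) {
  th_stretch <- max(params$rel_threshold * avg,
                    params$fdr_per_bin + rohscape::mu_per_bin(params))
  bin_cap <- params$relax_bin_cap_factor * avg
  win_cap <- params$relax_window_cap_factor * avg
  L <- params$window_len

  recurse <- function(idx) {
    if (length(idx) == 0) return(list())
    bad <- idx[covered[idx] & snpbin[idx] > th_stretch]
    if (length(bad) == 0) {
      m <- oracle_window_mean(snpbin, covered, idx)
      if (is.nan(m) || m > th_stretch) return(list())
      return(list(list(idx = idx, relaxed = integer())))
    }
    # group adjacent aberrant bins
    runs <- list(); cur <- bad[1]
    for (b in bad[-1]) {
      if (b == cur[length(cur)] + 1) cur <- c(cur, b)
      else { runs[[length(runs) + 1]] <- cur; cur <- b }
    }
    runs[[length(runs) + 1]] <- cur

    relaxed <- integer()
    for (run in runs) {
      pass <- all(snpbin[run] <= bin_cap)
      if (pass) {
        # enumerate every L-window of the stretch containing the run
        if (length(idx) <= L) {
          wins <- list(idx)
        } else {
          wins <- list()
          for (s in idx[1]:(idx[length(idx)] - L + 1)) {
            w <- s:(s + L - 1)
            if (any(w %in% run)) wins[[length(wins) + 1]] <- w
          }
        }
        for (w in wins) {
          m <- oracle_window_mean(snpbin, covered, w)
          if (is.nan(m) || m > win_cap) { pass <- FALSE; break }
        }
      }
      if (pass) {
        rest <- setdiff(idx[covered[idx]], bad)
        pass <- length(rest) > 0 && mean(snpbin[rest]) <= th_stretch
      }
      if (pass) relaxed <- c(relaxed, run)
      else {
        return(c(recurse(idx[idx < min(run)]), recurse(idx[idx > max(run)])))
      }
    }
    rest <- setdiff(idx[covered[idx]], relaxed)
    if (length(rest) == 0 || mean(snpbin[rest]) > th_stretch) return(list())
    list(list(idx = idx, relaxed = relaxed))
  }
  recurse(idx)
}

oracle_coverage_rules <- function(idx, grid, params) {
  cov <- grid$covered[idx]
  if (!any(cov)) return(NULL)
  idx <- idx[min(which(cov)):max(which(cov))]
  if (sum(!grid$covered[idx]) / length(idx) > params$max_uncovered_frac) {
    return(NULL)
  }
  start <- grid$bin_start[idx[1]]
  end <- grid$bin_end[idx[length(idx)]]
  if (end - start < params$min_roh_bp) return(NULL)
  c(start = start, end = end)
}

# full literal caller on a (possibly multi-chromosome) grid
oracle_call_rohs <- function(bins, params = rohscape::detection_params()) {
  bins <- bins[order(bins$chrom, bins$bin_start), ]
  avg <- mean(bins$snpbin[bins$covered])
  rows <- list()
  for (ch in unique(bins$chrom)) {
    grid <- bins[bins$chrom == ch, ]
    mask <- oracle_candidate_mask(grid$snpbin, grid$covered, avg,
                                  params$window_len, params$window_mode)
    for (idx in oracle_stretches(mask)) {
      kept <- oracle_threshold_relax(idx, grid$snpbin, grid$covered, avg, params)
      for (st in kept) {
        r <- oracle_coverage_rules(st$idx, grid, params)
        if (!is.null(r)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            chrom = ch, start = r[["start"]], end = r[["end"]])
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  }
  out[order(out$chrom, out$start), ]
}

# exact hypergeometric upper-tail p by direct combinatorial summation
oracle_hyper_tail <- function(overlap, term_size, bg_size, set_size) {
  ks <- overlap:min(term_size, set_size)
  sum(choose(term_size, ks) * choose(bg_size - term_size, set_size - ks)) /
    choose(bg_size, set_size)
}

# Benjamini-Hochberg by the textbook step-up arithmetic
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# per-bp boolean-AND intersection of interval sets on a toy genome
oracle_bitmap_intersect <- function(sets, genome_len) {
  acc <- rep(TRUE, genome_len)
  for (s in sets) {
    cur <- rep(FALSE, genome_len)
    for (k in seq_len(nrow(s))) {
      if (s$end[k] > s$start[k]) cur[(s$start[k] + 1):s$end[k]] <- TRUE
    }
    acc <- acc & cur
  }
  # back to intervals
  r <- rle(acc)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# closed-form R^2 from the raw sums of a paired sample
oracle_r_squared <- function(x, y) {
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}
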