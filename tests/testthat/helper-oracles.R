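# Independent brute-force reference implementations.  These deliberately
# avoid the code paths of the package functions they check: percentiles are
# interpolated by hand from a sorted copy, peaks come from a scalar run
# scan, metagene windows from per-base accumulation, compartments from a
# per-bin priority scan over all genes, and overlaps from all-pairs
# comparison.

# plain data.frame comparison view (drops carried attributes like the
# threshold a PeakSet records)
plain_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  d
}

oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# single-chromosome peak scan
oracle_peaks <- function(score, bin_size, chrom, chrom_len,
                         percentile = 98, min_bins = 2L) {
  t <- oracle_percentile(score, percentile)
  res <- list()
  run_start <- NA_integer_
  flush <- function(run_start, i_end) {
    n <- i_end - run_start + 1L
    if (n < min_bins) return(NULL)
    sc <- score[run_start:i_end]
    data.table::data.table(
      chrom = chrom, start = (run_start - 1L) * bin_size,
      end = min(i_end * bin_size, chrom_len),
      n_bins = n, mean_score = mean(sc), max_score = max(sc))
  }
  for (i in seq_along(score)) {
    if (score[i] > t) {
      if (is.na(run_start)) run_start <- i
    } else if (!is.na(run_start)) {
      res[[length(res) + 1L]] <- flush(run_start, i - 1L)
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start))
    res[[length(res) + 1L]] <- flush(run_start, length(score))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_bins = integer(),
                                  mean_score = numeric(),
                                  max_score = numeric()))
  data.table::rbindlist(res)
}

# per-base metagene resampling for one track
oracle_metagene <- function(track, regions, n_interior,
                            flank_frac = NULL, flank_bp = NULL, n_flank = 0L) {
  grid <- track$grid
  base_score <- function(chrom, p) {
    ci <- match(chrom, names(grid$chrom_sizes))
    if (p < 0 || p >= grid$chrom_sizes[ci]) return(0)
    k <- min(p %/% grid$bin_size, grid$n_bins[ci] - 1L)
    track$score[grid$offset[ci] + k + 1L]
  }
  n_win <- n_interior + 2L * n_flank
  acc <- numeric(n_win)
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    f <- if (!is.null(flank_frac)) flank_frac * (e - s)
         else if (!is.null(flank_bp)) flank_bp else 0
    bounds <- c(if (n_flank) seq(s - f, s, length.out = n_flank + 1L)[-(n_flank + 1L)],
                seq(s, e, length.out = n_interior + 1L),
                if (n_flank) seq(e, e + f, length.out = n_flank + 1L)[-1L])
    v <- numeric(n_win)
    for (w in seq_len(n_win)) {
      a <- bounds[w]; b <- bounds[w + 1L]
      tot <- 0
      for (p in seq(floor(a), ceiling(b) - 1)) {
        ov <- min(p + 1, b) - max(p, a)
        if (ov > 0) tot <- tot + ov * base_score(regions$chrom[i], p)
      }
      v[w] <- tot / (b - a)
    }
    if (!is.null(regions$strand) && regions$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  acc / nrow(regions)
}

# per-bin priority scan over all genes
oracle_compartments <- function(genes, grid) {
  levs <- c("promoter_core", "promoter_proximal", "promoter_distal",
            "exonic", "intronic", "intergenic")
  bins <- grid_bins(grid)
  mid <- (bins$start + bins$end) / 2
  tss <- tss_positions(genes)
  lab <- rep("intergenic", nrow(bins))
  inside <- function(m, a, b) m >= a & m < b
  for (b in seq_len(nrow(bins))) {
    best <- 6L
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != bins$chrom[b]) next
      m <- mid[b]; t <- tss[g]; plus <- genes$strand[g] == "+"
      prox <- if (plus) c(t - 1000, t - 250) else c(t + 251, t + 1001)
      dist <- if (plus) c(t - 2000, t - 1000) else c(t + 1001, t + 2001)
      cand <- if (inside(m, t - 250, t + 250)) 1L
        else if (inside(m, prox[1], prox[2])) 2L
        else if (inside(m, dist[1], dist[2])) 3L
        else if (any(inside(m, genes$start[g] + genes$exon_starts[[g]],
                            genes$start[g] + genes$exon_starts[[g]] +
                              genes$exon_sizes[[g]]))) 4L
        else if (inside(m, genes$start[g], genes$end[g])) 5L
        else 6L
      best <- min(best, cand)
    }
    lab[b] <- levs[best]
  }
  factor(lab, levels = levs)
}

# all-pairs interval overlap counts
oracle_overlap <- function(a, b) {
  hits_a <- rep(FALSE, nrow(a))
  hits_b <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
      hits_a[i] <- TRUE
      hits_b[j] <- TRUE
    }
  }
  c(n_a_overlap = sum(hits_a), n_b_overlap = sum(hits_b))
}

# random peak-like interval set on one chromosome
random_intervals <- function(n, chrom_len, chrom = "chrT") {
  s <- sort(sample.int(chrom_len - 500L, n))
  data.table::data.table(chrom = chrom, start = s,
                         end = s + sample(50:400, n, replace = TRUE))
}
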