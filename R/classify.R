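#' Per-gene promoter-window score matrix
#'
#' Mean score over the bins intersecting `[TSS - half_window, TSS +
#' half_window)` for every gene and every track.
#'
#' @param tracks Named list of `BinnedTrack`s (one mark, all samples).
#' @param genes A `GeneSet`.
#' @param half_window Half-width of the promoter window in bp (default 250).
#' @return Numeric matrix genes x samples.
#' @export
promoter_scores <- function(tracks, genes, half_window = 250L) {
  grid <- tracks[[1L]]$grid
  tss <- tss_positions(genes)
  idx <- lapply(seq_len(nrow(genes)), function(g)
    window_bins(grid, genes$chrom[g], max(0L, tss[g] - half_window),
                tss[g] + half_window))
  if (any(!lengths(idx))) stop("gene with no overlapping bins")
  score_region_matrix(tracks, idx, genes$gene_id)
}

#' Per-gene gene-body score matrix
#'
#' Mean score of the bins whose midpoint lies in `[gene start, gene end)`,
#' i.e. the full gene body including introns.
#'
#' @inheritParams promoter_scores
#' @return Numeric matrix genes x samples.
#' @export
genic_scores <- function(tracks, genes) {
  grid <- tracks[[1L]]$grid
  idx <- lapply(seq_len(nrow(genes)), function(g)
    midpoint_bins(grid, genes$chrom[g], genes$start[g], genes$end[g]))
  if (any(!lengths(idx))) stop("gene with no overlapping bins")
  score_region_matrix(tracks, idx, genes$gene_id)
}

score_region_matrix <- function(tracks, idx, gene_ids) {
  m <- vapply(tracks, function(t)
    vapply(idx, function(i) mean(t$score[i]), numeric(1)),
    numeric(length(idx)))
  m <- matrix(m, nrow = length(idx),
              dimnames = list(gene_ids, names(tracks)))
  m
}

#' Classify promoters into modification groups
#'
#' Per gene and mark, using the mean normalized score over the promoter
#' window in every sample: group `i` if every sample is below the
#' threshold; `ii` if every sample is above it; `iii_sd` if all
#' Sprague-Dawley samples are above and all Wistar samples below;
#' `iv_wistar` symmetrically; otherwise `unclassified`.  The
#' strain-specific groups require the opposite strain to be uniformly below
#' threshold, so the four groups are mutually exclusive; set
#' `strict_strain_groups = FALSE` for the literal reading in which the
#' strain groups only constrain their own strain.
#'
#' @param tracks Named list of `BinnedTrack`s for one mark (all samples).
#' @param genes A `GeneSet`.
#' @param strains Character vector aligned with `tracks`; values `"sd"` /
#'   `"wistar"`.
#' @param threshold Absolute score threshold (default 5).
#' @param half_window Promoter half-width in bp (default 250).
#' @param strict_strain_groups See above.
#' @return `data.table`: `gene_id`, `group`, plus the per-sample score
#'   matrix as attribute `scores`.
#' @export
classify_promoters <- function(tracks, genes, strains, threshold = 5,
                               half_window = 250L,
                               strict_strain_groups = TRUE) {
  stopifnot(length(strains) == length(tracks))
  m <- promoter_scores(tracks, genes, half_window)
  sd_cols <- strains == "sd"
  wi_cols <- strains == "wistar"
  all_lo <- rowSums(m >= threshold) == 0L
  all_hi <- rowSums(m <= threshold) == 0L
  sd_hi <- rowSums(m[, sd_cols, drop = FALSE] <= threshold) == 0L
  wi_hi <- rowSums(m[, wi_cols, drop = FALSE] <= threshold) == 0L
  sd_lo <- rowSums(m[, sd_cols, drop = FALSE] >= threshold) == 0L
  wi_lo <- rowSums(m[, wi_cols, drop = FALSE] >= threshold) == 0L
  group <- rep("unclassified", nrow(m))
  if (strict_strain_groups) {
    group[sd_hi & wi_lo] <- "iii_sd"
    group[wi_hi & sd_lo] <- "iv_wistar"
  } else {
    group[sd_hi] <- "iii_sd"
    group[wi_hi] <- "iv_wistar"
  }
  group[all_hi] <- "ii"
  group[all_lo] <- "i"
  out <- data.table::data.table(gene_id = genes$gene_id, group = group)
  data.table::setattr(out, "scores", m)
  out[]
}

#' Call strain-differential gene bodies
#'
#' A gene is called up in strain A when, for every A individual,
#' `(score_A + pseudocount) >= fold x (mean over B individuals +
#' pseudocount)` on the gene-body mean score; both directions are tested.
#' With the default fivefold rule this is the "enriched in all individuals
#' of one strain over the other by fivefold" criterion; comparisons are
#' made within one gender.
#'
#' @param tracks_a,tracks_b Named lists of `BinnedTrack`s for the two
#'   strains (same mark, same gender).
#' @param genes A `GeneSet`.
#' @param fold Fold threshold (default 5).
#' @param pseudocount Added to both sides to stabilize near-zero means
#'   (default 1).
#' @param labels Length-2 character vector naming the directions (default
#'   `c("a_up", "b_up")`).
#' @return `data.table` of calls: `gene_id`, `direction`, `fold_achieved`
#'   (minimum individual-over-opposite-mean ratio), with the two genic
#'   score matrices as attributes `scores_a`, `scores_b`.
#' @export
call_differential_genes <- function(tracks_a, tracks_b, genes, fold = 5,
                                    pseudocount = 1,
                                    labels = c("a_up", "b_up")) {
  ma <- genic_scores(tracks_a, genes) + pseudocount
  mb <- genic_scores(tracks_b, genes) + pseudocount
  ratio_a <- ma / rowMeans(mb)   # each A individual vs B group mean
  ratio_b <- mb / rowMeans(ma)
  min_a <- apply(ratio_a, 1L, min)
  min_b <- apply(ratio_b, 1L, min)
  a_up <- min_a >= fold
  b_up <- min_b >= fold
  out <- data.table::rbindlist(list(
    data.table::data.table(gene_id = genes$gene_id[a_up],
                           direction = labels[1L],
                           fold_achieved = min_a[a_up]),
    data.table::data.table(gene_id = genes$gene_id[b_up],
                           direction = labels[2L],
                           fold_achieved = min_b[b_up])))
  data.table::setattr(out, "scores_a", ma - pseudocount)
  data.table::setattr(out, "scores_b", mb - pseudocount)
  out[]
}

#' Define poised and active enhancers from chromatin peaks
#'
#' Candidates are H3K4me1 peaks whose midpoint lies within `(far_excl,
#' near]` bp of the nearest TSS; distance is measured on either side of the
#' TSS by default (`upstream_only = TRUE` restricts to the 5' side).  A
#' candidate is `active` when it overlaps at least 1 bp of an H3K27ac peak
#' and `poised` otherwise.
#'
#' @param k4_peaks,k27_peaks `PeakSet`s for H3K4me1 and H3K27ac (typically
#'   from gender-averaged tracks).
#' @param genes A `GeneSet`.
#' @param near,far_excl Distance window from the TSS in bp (default 5000
#'   and 1000: "within 5-1 kb").
#' @param upstream_only Restrict candidates to the TSS's upstream side.
#' @return `data.table`: `element_id`, `chrom`, `start`, `end`,
#'   `nearest_gene`, `distance`, `state`.
#' @export
define_enhancers <- function(k4_peaks, k27_peaks, genes, near = 5000L,
                             far_excl = 1000L, upstream_only = FALSE) {
  if (nrow(k4_peaks) == 0L)
    return(data.table::data.table(element_id = character(),
                                  chrom = character(), start = numeric(),
                                  end = numeric(), nearest_gene = character(),
                                  distance = numeric(), state = character()))
  tss <- tss_positions(genes)
  mid <- (k4_peaks$start + k4_peaks$end) / 2
  nearest_gene <- character(nrow(k4_peaks))
  distance <- signed <- numeric(nrow(k4_peaks))
  for (i in seq_len(nrow(k4_peaks))) {
    same <- which(genes$chrom == k4_peaks$chrom[i])
    if (!length(same)) { distance[i] <- Inf; next }
    d <- abs(tss[same] - mid[i])
    j <- same[which.min(d)]
    nearest_gene[i] <- genes$gene_id[j]
    distance[i] <- min(d)
    # positive when the peak lies upstream of the nearest TSS
    signed[i] <- if (genes$strand[j] == "+") tss[j] - mid[i]
                 else mid[i] - tss[j]
  }
  cand <- distance > far_excl & distance <= near
  if (upstream_only) cand <- cand & signed > 0
  k4g <- peaks_to_granges(k4_peaks)
  hit <- IRanges::overlapsAny(k4g, peaks_to_granges(k27_peaks))
  out <- data.table::data.table(
    element_id = sprintf("enh_%d", seq_len(sum(cand))),
    chrom = k4_peaks$chrom[cand],
    start = k4_peaks$start[cand], end = k4_peaks$end[cand],
    nearest_gene = nearest_gene[cand], distance = distance[cand],
    state = ifelse(hit[cand], "active", "poised"))
  out[]
}

#' Call gender-biased genes from an expression matrix
#'
#' Strictest reading of the all-individuals rule: a gene is male-biased
#' when `min(male log2 values) - max(female log2 values) > log2fc`
#' (every male exceeds every female by the threshold), and symmetrically
#' for female bias.  `pairwise = FALSE` instead compares each individual to
#' the opposite-gender mean.
#'
#' @param expr Numeric matrix genes x samples (log2 scale).
#' @param gender Character vector aligned with columns; `"male"` /
#'   `"female"`.
#' @param log2fc Threshold (default 1.5).
#' @param pairwise Use the worst-case pairwise gap (default) or the
#'   per-individual-vs-opposite-mean rule.
#' @return `data.table`: `gene_id`, `direction`, `gap` (minimal log2
#'   separation achieved).
#' @export
call_gender_biased_genes <- function(expr, gender, log2fc = 1.5,
                                     pairwise = TRUE) {
  stopifnot(ncol(expr) == length(gender))
  male <- expr[, gender == "male", drop = FALSE]
  female <- expr[, gender == "female", drop = FALSE]
  if (ncol(male) < 2L || ncol(female) < 2L)
    stop("need at least 2 samples per gender")
  if (pairwise) {
    gap_m <- apply(male, 1L, min) - apply(female, 1L, max)
    gap_f <- apply(female, 1L, min) - apply(male, 1L, max)
  } else {
    gap_m <- apply(male - rowMeans(female), 1L, min)
    gap_f <- apply(female - rowMeans(male), 1L, min)
  }
  out <- data.table::rbindlist(list(
    data.table::data.table(gene_id = rownames(expr)[gap_m > log2fc],
                           direction = "male", gap = gap_m[gap_m > log2fc]),
    data.table::data.table(gene_id = rownames(expr)[gap_f > log2fc],
                           direction = "female", gap = gap_f[gap_f > log2fc])))
  out[]
}

#' Row-wise Z-score matrix
#'
#' Standardizes each gene across samples with the population (divide by n)
#' standard deviation; zero-variance rows become all zeros.
#'
#' @param values Numeric matrix genes x samples.
#' @return Matrix of the same shape.
#' @export
zscore_matrix <- function(values) {
  if (ncol(values) < 2L) stop("need at least 2 samples")
  mu <- rowMeans(values)
  sd_pop <- sqrt(rowMeans((values - mu)^2))
  z <- (values - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  z
}
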