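#' Pairwise Pearson correlation between tracks
#'
#' Correlation over all grid bins, zeros included.  A constant track has no
#' defined correlation; its pairs are reported as `NA` with a warning.
#'
#' @param tracks Named list of `BinnedTrack`s on a shared grid.
#' @return A `SampleSimilarity`: list with `cor` (symmetric matrix, unit
#'   diagonal) and `samples`.
#' @export
pearson_matrix <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least 2 tracks")
  grid <- tracks[[1L]]$grid
  for (t in tracks) if (!same_grid(t$grid, grid))
    stop("tracks are on different grids")
  X <- vapply(tracks, function(t) t$score, numeric(grid$total_bins))
  const <- apply(X, 2L, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(X))
  if (any(const)) {
    warning("constant track(s): ", paste(names(tracks)[const], collapse = ", "),
            "; correlations undefined for those pairs")
    cm[const, ] <- NA_real_
    cm[, const] <- NA_real_
  }
  diag(cm) <- 1
  structure(list(cor = cm, samples = names(tracks)),
            class = "SampleSimilarity")
}

#' Hierarchical clustering of samples
#'
#' Agglomerates samples by Euclidean distance between the rows of the
#' correlation matrix (each sample's vector of correlations to all
#' samples) with Ward linkage, the combination behind
#' correlation-heatmap dendrograms.  `on = "tracks"` clusters the raw bin
#' vectors instead.
#'
#' @param sim A `SampleSimilarity` from [pearson_matrix()].
#' @param tracks Track list, only needed for `on = "tracks"`.
#' @param on `"correlation"` (default) or `"tracks"`.
#' @return List of class `SampleClustering`: `hclust` (stats::hclust,
#'   Ward.D2), `merge_heights`, `order` (leaf order), `newick`.
#' @export
hcluster_samples <- function(sim, tracks = NULL, on = "correlation") {
  stopifnot(inherits(sim, "SampleSimilarity"))
  d <- if (on == "correlation") {
    stats::dist(sim$cor)
  } else {
    X <- t(vapply(tracks, function(t) t$score,
                  numeric(length(tracks[[1L]]$score))))
    rownames(X) <- names(tracks)
    stats::dist(X)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  structure(list(hclust = hc,
                 merge_heights = hc$height,
                 order = hc$labels[hc$order],
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "SampleClustering")
}

#' Replicate variance partitioned by coding status
#'
#' Per-bin population standard deviation across replicate tracks, split
#' into coding (exonic or intronic compartments, i.e. gene bodies) versus
#' noncoding bins, with quartile summaries per class.
#'
#' @param tracks List of replicate `BinnedTrack`s (>= 2).
#' @param compartments Compartment factor from [assign_compartments()].
#' @return List: `sd` (per-bin SD), `coding` (logical per bin), `summary`
#'   (`data.table` of quartiles per class).
#' @export
variance_partition <- function(tracks, compartments) {
  if (length(tracks) < 2L) stop("need at least 2 replicates")
  X <- vapply(tracks, function(t) t$score,
              numeric(length(tracks[[1L]]$score)))
  mu <- rowMeans(X)
  sd_pop <- sqrt(rowMeans((X - mu)^2))
  coding <- compartments %in% c("exonic", "intronic")
  summ <- data.table::rbindlist(lapply(c(TRUE, FALSE), function(cl) {
    x <- sd_pop[coding == cl]
    q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
    data.table::data.table(class = if (cl) "coding" else "noncoding",
                           n_bins = length(x), min = q[1], q1 = q[2],
                           median = q[3], q3 = q[4], max = q[5],
                           mean = mean(x))
  }))
  list(sd = sd_pop, coding = coding, summary = summ)
}
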