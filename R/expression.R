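#' Read an expression matrix from TSV
#'
#' First column `gene_id`, remaining columns one sample each (log2 scale).
#' Genes with missing entries are dropped with a message.
#'
#' @param path TSV file.
#' @return Numeric matrix genes x samples.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path)
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- dt[[1L]]
  bad <- rowSums(is.na(mat)) > 0L
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing entries dropped")
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}

#' Stratify genes into expression quintiles
#'
#' Genes ranked by expression (highest first) and split into five groups of
#' near-equal size; when sizes cannot be equal the extra genes go to the
#' lower-expression quintiles.  Ties are broken by gene id so the
#' assignment is deterministic.  Quintile 1 is the highest-expression
#' group.
#'
#' @param values Named numeric vector of per-gene expression.
#' @return List of five character vectors of gene ids (`Q1` .. `Q5`).
#' @export
expression_quintiles <- function(values) {
  n <- length(values)
  if (n < 5L) stop("need at least 5 genes")
  ord <- names(values)[order(-values, names(values))]
  base <- n %/% 5L
  rem <- n %% 5L
  sizes <- base + c(rep(0L, 5L - rem), rep(1L, rem))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  stats::setNames(lapply(1:5, function(q) ord[starts[q]:ends[q]]),
                  paste0("Q", 1:5))
}

#' Tissue-specific gene sets
#'
#' For each tissue, genes are scored by their expression margin: own-tissue
#' expression minus the maximum over all other tissues; only genes whose
#' unique maximum is in that tissue are eligible, and the `top_n` by margin
#' are kept.  Sets are disjoint by construction.  Columns of the same
#' tissue (e.g. the two genders) are averaged first.
#'
#' @param expr Matrix genes x samples (log2).
#' @param tissue Character vector aligned with columns.
#' @param top_n Set size (default 250); truncated with a warning when fewer
#'   genes qualify.
#' @return Named list of character vectors of gene ids, one per tissue.
#' @export
tissue_specific_sets <- function(expr, tissue, top_n = 250L) {
  stopifnot(ncol(expr) == length(tissue))
  tl <- unique(tissue)
  if (length(tl) < 2L) stop("need at least 2 tissues")
  tm <- vapply(tl, function(tt)
    rowMeans(expr[, tissue == tt, drop = FALSE]), numeric(nrow(expr)))
  out <- lapply(seq_along(tl), function(ti) {
    own <- tm[, ti]
    other <- apply(tm[, -ti, drop = FALSE], 1L, max)
    eligible <- own > other            # unique maximum in this tissue
    margin <- own - other
    ids <- rownames(expr)[eligible]
    ids <- ids[order(-margin[eligible], ids)]
    if (length(ids) < top_n)
      warning("only ", length(ids), " genes specific to ", tl[ti])
    utils::head(ids, top_n)
  })
  stats::setNames(out, tl)
}

#' Housekeeping gene set
#'
#' Genes exhibiting similarly high expression in all datasets: ranked by
#' their minimum expression across columns (descending), after excluding
#' genes whose across-column coefficient of variation exceeds the median CV
#' of the matrix (and genes with non-positive mean, for which the CV is
#' undefined).
#'
#' @param expr Matrix genes x samples (log2).
#' @param top_n Set size (default 250).
#' @return Character vector of gene ids.
#' @export
housekeeping_set <- function(expr, top_n = 250L) {
  if (ncol(expr) < 2L) stop("need at least 2 datasets")
  mu <- rowMeans(expr)
  cv <- apply(expr, 1L, stats::sd) / mu
  cv[mu <= 0] <- Inf
  keep <- cv <= stats::median(cv[is.finite(cv)])
  lo <- apply(expr, 1L, min)
  ids <- rownames(expr)[keep]
  ids <- ids[order(-lo[keep], ids)]
  if (length(ids) < top_n)
    warning("only ", length(ids), " genes pass the variability filter")
  utils::head(ids, top_n)
}
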