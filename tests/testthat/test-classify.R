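## constant-score track helper over the small cohort grid
const_track <- function(value, grid) binned_track(rep(value, grid$total_bins), grid)

test_that("promoter groups follow the all-samples threshold rules", {
  co <- small_cohort()
  grid <- co$grid
  strains <- c("sd", "sd", "wistar", "wistar")
  mk <- function(vals) {
    tr <- stats::setNames(lapply(vals, const_track, grid = grid),
                          paste0("s", seq_along(vals)))
    classify_promoters(tr, co$genes, strains)
  }
  expect_true(all(mk(c(0, 0, 0, 0))$group == "i"))
  expect_true(all(mk(c(10, 10, 10, 10))$group == "ii"))
  expect_true(all(mk(c(10, 10, 1, 1))$group == "iii_sd"))
  expect_true(all(mk(c(1, 1, 10, 10))$group == "iv_wistar"))
  expect_true(all(mk(c(10, 1, 10, 1))$group == "unclassified"))
  # exactly at the threshold counts as neither above nor below
  expect_true(all(mk(c(5, 5, 5, 5))$group == "unclassified"))
})

test_that("literal strain-group reading lets uniform enrichment pass as ii", {
  co <- small_cohort()
  grid <- co$grid
  tr <- stats::setNames(lapply(c(10, 10, 10, 10), const_track, grid = grid),
                        paste0("s", 1:4))
  strains <- c("sd", "sd", "wistar", "wistar")
  strict <- classify_promoters(tr, co$genes, strains)
  literal <- classify_promoters(tr, co$genes, strains,
                                strict_strain_groups = FALSE)
  expect_true(all(strict$group == "ii"))
  expect_true(all(literal$group == "ii"))  # ii takes precedence either way
})

test_that("differential calling applies the per-individual fold rule", {
  co <- small_cohort()
  grid <- co$grid
  a <- stats::setNames(lapply(c(60, 60), const_track, grid = grid), c("a1", "a2"))
  b <- stats::setNames(lapply(c(2, 2), const_track, grid = grid), c("b1", "b2"))
  dc <- call_differential_genes(a, b, co$genes)
  # 61 >= 5 x 3 for every A individual -> every gene called a_up
  expect_equal(nrow(dc), nrow(co$genes))
  expect_true(all(dc$direction == "a_up"))
  # identical groups -> no calls
  expect_equal(nrow(call_differential_genes(a, a, co$genes)), 0)
  # antisymmetry: swapping the strains swaps the direction labels
  swapped <- call_differential_genes(b, a, co$genes)
  expect_equal(nrow(swapped), nrow(dc))
  expect_true(all(swapped$direction == "b_up"))
  expect_identical(sort(swapped$gene_id), sort(dc$gene_id))
})

test_that("a single deviant individual blocks a differential call", {
  co <- small_cohort()
  grid <- co$grid
  a <- stats::setNames(lapply(c(60, 8), const_track, grid = grid), c("a1", "a2"))
  b <- stats::setNames(lapply(c(2, 2), const_track, grid = grid), c("b1", "b2"))
  dc <- call_differential_genes(a, b, co$genes)   # 9 < 5 x 3 for a2
  expect_equal(nrow(dc), 0)
})

test_that("enhancer candidates respect the TSS distance window and marks", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chrT", start = 50000L, end = 60000L,
    strand = "+", exon_starts = list(0L), exon_sizes = list(10000L))
  data.table::setattr(genes, "class", c("GeneSet", class(genes)))
  pk <- function(start, end)
    data.table::data.table(chrom = "chrT", start = start, end = end,
                           n_bins = (end - start) %/% 150L,
                           mean_score = 10, max_score = 12)
  none <- pk(integer(), integer())[0, ]
  # midpoint 3 kb upstream of the TSS, no H3K27ac -> poised
  k4 <- pk(46500L, 47500L)
  e <- define_enhancers(k4, none, genes)
  expect_equal(nrow(e), 1)
  expect_equal(e$state, "poised")
  expect_equal(e$nearest_gene, "g1")
  # the same peak overlapping an H3K27ac peak -> active
  e2 <- define_enhancers(k4, pk(47000L, 47600L), genes)
  expect_equal(e2$state, "active")
  # midpoint 500 bp from the TSS -> inside the exclusion zone
  e3 <- define_enhancers(pk(49350L, 49650L), none, genes)
  expect_equal(nrow(e3), 0)
  # beyond 5 kb -> not a candidate
  e4 <- define_enhancers(pk(43000L, 44000L), none, genes)
  expect_equal(nrow(e4), 0)
  # downstream side counts unless upstream_only is set
  e5 <- define_enhancers(pk(52500L, 53500L), none, genes)
  expect_equal(nrow(e5), 1)
  e6 <- define_enhancers(pk(52500L, 53500L), none, genes,
                         upstream_only = TRUE)
  expect_equal(nrow(e6), 0)
})

test_that("gender-bias calls demand the gap from every individual", {
  expr <- rbind(gA = c(10, 10, 10, 10, 8, 8, 8, 8),
                gB = c(10, 9.8, 10, 10, 8, 8, 8, 8.4),
                gC = c(8, 8, 8, 8, 10.2, 10.1, 10.3, 10.2))
  gender <- rep(c("male", "female"), each = 4)
  calls <- call_gender_biased_genes(expr, gender, log2fc = 1.5)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$direction[calls$gene_id == "gA"], "male")
  expect_equal(calls$direction[calls$gene_id == "gC"], "female")
  # worst pair (9.8 vs 8.4) gives gap 1.4, blocked by those two individuals
  expect_false("gB" %in% calls$gene_id)
  # per-individual-vs-opposite-mean reading is more permissive
  calls2 <- call_gender_biased_genes(expr, gender, log2fc = 1.5,
                                     pairwise = FALSE)
  expect_true("gB" %in% calls2$gene_id)
  expect_error(call_gender_biased_genes(expr[, 1:5], gender[1:5]), "2 samples")
})

test_that("z-scores standardize rows with the population SD", {
  expect_equal(unname(zscore_matrix(rbind(c(2, 2, 2)))), rbind(c(0, 0, 0)))
  expect_equal(unname(zscore_matrix(rbind(c(0, 10)))), rbind(c(-1, 1)))
  set.seed(17)
  m <- matrix(rnorm(200), 20)
  z <- zscore_matrix(m)
  expect_equal(rowMeans(z), rep(0, 20), tolerance = 1e-9)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 20), tolerance = 1e-9)
  expect_error(zscore_matrix(m[, 1, drop = FALSE]), "2 samples")
})
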