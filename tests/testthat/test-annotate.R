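## small deterministic gene fixture on one chromosome
fixture_genes <- function(n = 20, chrom_len = 6e5, seed = 13) {
  set.seed(seed)
  slot <- chrom_len %/% n
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(2000:8000, 1)
    s <- (i - 1) * slot + 10000
    n_ex <- sample(2:4, 1)
    cuts <- sort(sample.int(len - 1, 2 * n_ex - 2))
    bounds <- c(0L, cuts, len)
    ex <- seq(1, 2 * n_ex - 1, by = 2)
    data.table::data.table(
      gene_id = sprintf("f%02d", i), chrom = "chrF", start = s, end = s + len,
      strand = sample(c("+", "-"), 1),
      exon_starts = list(bounds[ex]),
      exon_sizes = list(diff(bounds)[ex]))
  })
  g <- data.table::rbindlist(rows)
  data.table::setattr(g, "class", c("GeneSet", class(g)))
  g
}

test_that("compartment assignment matches the per-bin priority oracle", {
  genes <- fixture_genes()
  grid <- bin_grid(c(chrF = 6e5), 150)
  got <- assign_compartments(genes, grid)
  expect_identical(got, oracle_compartments(genes, grid))
  # labels partition the grid
  expect_equal(sum(table(got)), grid$total_bins)
  # a bin 2 Mb from any gene is intergenic (use a bigger chromosome)
  grid2 <- bin_grid(c(chrF = 3e6), 150)
  got2 <- assign_compartments(genes, grid2)
  expect_equal(as.character(got2[grid2$total_bins]), "intergenic")
})

test_that("promoter-core bins sit within 250 bp of the TSS", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chrF", start = 10000L, end = 15000L,
    strand = "+", exon_starts = list(0L), exon_sizes = list(5000L))
  data.table::setattr(genes, "class", c("GeneSet", class(genes)))
  grid <- bin_grid(c(chrF = 1e5), 150)
  lab <- assign_compartments(genes, grid)
  bin_9900 <- 9900 %/% 150 + 1     # bin covering position 9,900
  expect_equal(as.character(lab[bin_9900]), "promoter_core")
})

test_that("compartment summaries reduce to the right degenerate stats", {
  genes <- fixture_genes(5)
  grid <- bin_grid(c(chrF = 6e5), 150)
  lab <- assign_compartments(genes, grid)
  const <- binned_track(rep(2.5, grid$total_bins), grid)
  s <- compartment_summary(const, lab)
  expect_true(all(s$median == 2.5 & s$min == 2.5 & s$max == 2.5))
  # one-bin compartment: all five stats equal that bin's score
  one <- binned_track(seq_len(10), toy_grid(10))
  lab1 <- factor(c("promoter_core", rep("intergenic", 9)),
                 levels = levels(lab))
  s1 <- compartment_summary(one, lab1)
  core <- s1[s1$compartment == "promoter_core", ]
  expect_true(all(unlist(core[, c("min", "q1", "median", "q3", "max")]) == 1))
})

test_that("metagene profiles are exact on identity and constant cases", {
  # constant track -> flat profile at that constant, exactly
  const <- toy_track(rep(4.2, 400))
  reg <- data.frame(chrom = "chrT", start = 3000, end = 12000, strand = "+")
  p <- metagene_profile(const, reg, n_interior = 25, flank_frac = 0.25)
  expect_equal(p$mean, rep(4.2, length(p$mean)))
  # one region of exactly 10 bins, 10 interior windows, no flank
  set.seed(3)
  tr <- toy_track(rpois(100, 5))
  reg10 <- data.frame(chrom = "chrT", start = 30 * 150, end = 40 * 150,
                      strand = "+")
  p10 <- metagene_profile(tr, reg10, n_interior = 10)
  expect_equal(p10$mean, tr$score[31:40])
})

test_that("metagene profiles match the per-base resampling oracle", {
  set.seed(91)
  tr <- toy_track(round(rexp(3000, 1 / 3), 4))
  n <- 20
  start <- sample.int(3000 * 150 - 9000, n)
  regions <- data.frame(chrom = "chrT", start = start,
                        end = start + sample(1500:6000, n, TRUE),
                        strand = sample(c("+", "-"), n, TRUE))
  for (spec in list(list(frac = 0.25), list(bp = 1000), list())) {
    p <- metagene_profile(tr, regions, n_interior = 30,
                          flank_frac = spec$frac, flank_bp = spec$bp)
    want <- oracle_metagene(tr, regions, 30, flank_frac = spec$frac,
                            flank_bp = spec$bp,
                            n_flank = attr(p, "n_flank"))
    expect_equal(p$mean, want, tolerance = 1e-9)
  }
})

test_that("strand reversal and linearity hold exactly", {
  set.seed(55)
  tr1 <- toy_track(rpois(500, 4))
  tr2 <- toy_track(rpois(500, 2))
  reg_p <- data.frame(chrom = "chrT", start = 9000, end = 24000, strand = "+")
  reg_m <- reg_p
  reg_m$strand <- "-"
  pp <- metagene_profile(tr1, reg_p, n_interior = 20, flank_frac = 0.5)
  pm <- metagene_profile(tr1, reg_m, n_interior = 20, flank_frac = 0.5)
  expect_equal(pm$mean, rev(pp$mean))
  # profile of a sum of tracks = sum of profiles
  sum_tr <- toy_track(tr1$score + tr2$score)
  ps <- metagene_profile(sum_tr, reg_p, n_interior = 20, flank_frac = 0.5)
  p2 <- metagene_profile(tr2, reg_p, n_interior = 20, flank_frac = 0.5)
  expect_equal(ps$mean, pp$mean + p2$mean)
})

test_that("regions shorter than one bin are skipped with a message", {
  tr <- toy_track(rep(1, 100))
  regions <- data.frame(chrom = "chrT", start = c(0, 500), end = c(100, 5000),
                        strand = "+")
  expect_message(p <- metagene_profile(tr, regions, n_interior = 5),
                 "skipped")
  expect_equal(attr(p, "n_regions"), 1)
  expect_error(metagene_profile(tr, regions[1, , drop = FALSE],
                                n_interior = 5), "no usable regions")
})

test_that("differential profiles subtract window-wise and are antisymmetric", {
  set.seed(8)
  tr_a <- toy_track(rpois(300, 3))
  tr_b <- toy_track(rpois(300, 3))
  reg <- data.frame(chrom = "chrT", start = 1500, end = 30000, strand = "+")
  a <- metagene_profile(tr_a, reg, n_interior = 10, flank_frac = 0.25)
  b <- metagene_profile(tr_b, reg, n_interior = 10, flank_frac = 0.25)
  expect_equal(differential_profile(a, a)$mean, rep(0, length(a$mean)))
  expect_equal(differential_profile(a, b)$mean,
               -differential_profile(b, a)$mean)
  c_other <- metagene_profile(tr_b, reg, n_interior = 12, flank_frac = 0.25)
  expect_error(differential_profile(a, c_other), "window spec")
})
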