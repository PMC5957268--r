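test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_chrom = 1, chrom_length = 1e6, n_genes = 30,
                    n_animals_dna = 2, n_animals_chip = 2)
  g1 <- build_toy_genome(cfg)
  g2 <- build_toy_genome(cfg)
  expect_identical(g1$genes$start, g2$genes$start)
  expect_identical(g1$genes$end, g2$genes$end)
  t1 <- plant_epigenome(g1$genes, cfg)
  t2 <- plant_epigenome(g2$genes, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  grid <- bin_grid(g1$chrom_sizes, cfg$bin_size)
  r1 <- simulate_sample_reads(t1, grid, cfg, "5mC", "wistar", "male", 3L)
  r2 <- simulate_sample_reads(t2, grid, cfg, "5mC", "wistar", "male", 3L)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("an empty gene request yields one chromosome and no genes", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 5e6, n_genes = 0)
  g <- build_toy_genome(cfg)
  expect_equal(length(g$chrom_sizes), 1)
  expect_equal(nrow(g$genes), 0)
})

test_that("genes are placed with disjoint flanked footprints", {
  g <- build_toy_genome(sim_config(seed = 3))
  genes <- g$genes
  for (ch in unique(genes$chrom)) {
    sub <- genes[genes$chrom == ch, ][order(start)]
    lo <- sub$start - 5000
    hi <- sub$end + 5000
    expect_true(all(hi[-nrow(sub)] <= lo[-1]))  # exhaustive pairwise on sorted
  }
  # gene bodies at least 10 bins
  expect_true(all(genes$end - genes$start >= 10 * 150))
  # exon blocks start at the gene start and end at the gene end
  expect_true(all(vapply(seq_len(nrow(genes)), function(i)
    genes$exon_starts[[i]][1] == 0, logical(1))))
  expect_true(all(vapply(seq_len(nrow(genes)), function(i) {
    k <- length(genes$exon_starts[[i]])
    genes$exon_starts[[i]][k] + genes$exon_sizes[[i]][k] ==
      genes$end[i] - genes$start[i]
  }, logical(1))))
})

test_that("planted class sizes follow the configured fractions exactly", {
  cfg <- sim_config(seed = 2)
  truth <- plant_epigenome(build_toy_genome(cfg)$genes, cfg)
  n <- nrow(truth)
  f <- cfg$fracs
  expect_equal(sum(truth$prom_group_5mc == "ii"), round(f$prom_ii_5mc * n))
  expect_equal(sum(truth$prom_group_5mc == "iii_sd"), round(f$prom_strain * n))
  expect_equal(sum(truth$prom_group_5hmc == "ii"), round(f$prom_ii_5hmc * n))
  expect_equal(sum(truth$genic_diff_5hmc == "wistar_up"),
               round(f$genic_diff * n))
  expect_equal(sum(truth$enh_state == "poised"), round(f$enh_poised * n))
  expect_equal(sum(truth$gender_bias == "male"), round(f$gender * n))

  zcfg <- sim_config(seed = 2, fracs = utils::modifyList(
    cfg$fracs, list(prom_ii_5hmc = 0, enh_active = 0)))
  ztruth <- plant_epigenome(build_toy_genome(zcfg)$genes, zcfg)
  expect_equal(sum(ztruth$prom_group_5hmc == "ii"), 0)
  expect_equal(sum(ztruth$enh_state == "active"), 0)
})

test_that("planted enhancers sit strand-aware 1-5 kb upstream of their TSS", {
  truth <- small_cohort()$truth
  enh <- truth[truth$enh_state != "none", ]
  expect_gt(nrow(enh), 0)
  plus <- enh$strand == "+"
  expect_true(all(enh$enh_start[plus] >= enh$tss[plus] - 5000))
  expect_true(all(enh$enh_end[plus] <= enh$tss[plus] - 1000))
  expect_true(all(enh$enh_start[!plus] >= enh$tss[!plus] + 1000))
  expect_true(all(enh$enh_end[!plus] <= enh$tss[!plus] + 5000))
  expect_true(all(enh$enh_end - enh$enh_start >= 600 &
                    enh$enh_end - enh$enh_start <= 1500))
})

test_that("per-bin counts are calibrated to the planted rates", {
  co <- small_cohort()
  cfg <- co$config
  # input: mean bin count ~ background_rate x depth factor, within 3 SE
  inp <- co$reads[["sd_male_1_input"]]
  f <- attr(inp, "depth_factor")
  tr <- bin_reads(inp, co$grid)
  rate <- cfg$background_rate * f
  se <- sqrt(rate / co$grid$total_bins)
  expect_lt(abs(mean(tr$score) - rate), 3 * se)
  # constitutively modified promoter bins: rate x enrich_promoter
  idx <- epibase:::plant_bin_index(co$truth, co$grid)
  pb <- unlist(idx$prom[co$truth$prom_group_5mc == "ii"])
  mc <- bin_reads(co$reads[["sd_male_1_5mC"]], co$grid)
  fmc <- attr(co$reads[["sd_male_1_5mC"]], "depth_factor")
  expected <- cfg$background_rate * fmc * cfg$enrich_promoter
  se <- sqrt(expected / length(pb))
  expect_lt(abs(mean(mc$score[pb]) - expected), 4 * se)
})

test_that("strain-differential gene bodies reach the planted fold", {
  co <- small_cohort()
  sheet <- co$samples
  up <- co$truth[co$truth$genic_diff_5hmc == "wistar_up", ]
  gb <- function(strain) {
    ids <- sheet$sample[sheet$mark == "5hmC" & sheet$strain == strain]
    tr <- lapply(ids, function(s) {
      t <- bin_reads(co$reads[[s]], co$grid)
      t$score <- t$score / attr(co$reads[[s]], "depth_factor")
      t
    })
    gm <- genic_scores(stats::setNames(tr, ids), co$genes)
    mean(gm[up$gene_id, ])
  }
  ratio <- gb("wistar") / gb("sd")
  expect_lt(abs(ratio - co$config$diff_fold), 0.2 * co$config$diff_fold)
})

test_that("expression matrix carries the planted gender structure", {
  co <- small_cohort()
  expr <- co$expr
  gender <- attr(expr, "gender")
  male <- expr[, gender == "male"]
  female <- expr[, gender == "female"]
  biased_m <- co$truth$gender_bias == "male"
  none <- co$truth$gender_bias == "none"
  # biased genes: every male exceeds every female by > 1.5 log2 units
  expect_true(all(apply(male[biased_m, ], 1, min) -
                    apply(female[biased_m, ], 1, max) > 1.5))
  # unbiased genes: means agree within noise
  expect_true(all(abs(rowMeans(male[none, ]) - rowMeans(female[none, ])) < 0.5))
  # degenerate config: no noise, no effect -> identical columns
  cfg0 <- sim_config(seed = 5, n_chrom = 1, chrom_length = 1.5e6,
                     n_genes = 50, expr_noise_sd = 0, expr_log2fc_gender = 2.5)
  t0 <- plant_epigenome(build_toy_genome(cfg0)$genes, cfg0)
  t0$gender_bias <- "none"
  e0 <- simulate_expression(t0, cfg0)
  expect_true(all(e0 == e0[, 1]))
})

test_that("unknown sample descriptors are rejected", {
  co <- small_cohort()
  expect_error(simulate_sample_reads(co$truth, co$grid, co$config,
                                     "H4K20me3", "wistar", "male"), "mark")
  expect_error(simulate_sample_reads(co$truth, co$grid, co$config,
                                     "5mC", "fischer", "male"), "strain")
})
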