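test_that("planted truth honors DE fraction, balance and concordance flags", {
  cfg <- sim_config(n_genes = 100L, fraction_de = 0.3, seed = 5)
  gg <- sim_genome(cfg)
  tr <- plant_truth(gg$genes, cfg)
  de <- tr$de_log2fc != 0
  expect_equal(sum(de), 30)
  expect_equal(sum(tr$de_log2fc > 0), 15)
  expect_equal(sum(tr$de_log2fc < 0), 15)
  expect_true(all(tr$chip_effect[!de] == 1))
  expect_true(all(tr$meth_delta[!de] == 0))
  expect_true(all(abs(tr$meth_delta) <= 1))
  expect_true(all(tr$chip_effect > 0))
  # concordant flag matches the planted directions
  up <- tr$de_log2fc > 0
  expect_identical(tr$chip_concordant[up], unname(tr$chip_effect[up] > 1))
  expect_identical(tr$meth_concordant[up], unname(tr$meth_delta[up] < 0))

  none <- plant_truth(gg$genes, sim_config(n_genes = 100L, fraction_de = 0, seed = 5))
  expect_true(all(none$de_log2fc == 0))

  tr2 <- plant_truth(gg$genes, cfg)
  expect_identical(tr, tr2) # same seed, same truth
})

test_that("odd DE counts round up the upregulated half", {
  cfg <- sim_config(n_genes = 100L, fraction_de = 0.05, seed = 1)
  tr <- plant_truth(sim_genome(cfg)$genes, cfg)
  expect_equal(sum(tr$de_log2fc > 0), 3) # 5 DE genes: ties to up
  expect_equal(sum(tr$de_log2fc < 0), 2)
})

test_that("RNA counts recover the planted fold change at high depth", {
  cfg <- sim_config(n_genes = 50L, fraction_de = 0.04, lfc = 1,
                    rna_depth = 1e7, dispersion = 0, seed = 9)
  gg <- sim_genome(cfg)
  tr <- plant_truth(gg$genes, cfg)
  cm <- simulate_rnaseq(gg$genes, tr, cfg)
  lr <- log2(cm$counts[, "EDC_1"] / cm$counts[, "VEH_1"])
  de <- tr$de_log2fc != 0
  # null genes measure the depth-matching composition factor; DE genes sit
  # exactly the planted log2fc above it
  expect_equal(unname(lr[de] - median(lr[!de])), tr$de_log2fc[de],
               tolerance = 0.08)
  expect_lt(mean(abs(lr[!de] - median(lr[!de]))), 0.05)
  expect_true(all(cm$counts >= 0))
  # depth scaling: totals track configured depth within 5%
  expect_equal(unname(cm$lib_sizes), rep(1e7, 2), tolerance = 0.05)
})

test_that("ChIP windows carry the planted promoter signal ratio", {
  cfg <- sim_config(n_genes = 20L, fraction_de = 0.1,
                    fraction_concordant_chip = 1, chip_effect = 3,
                    chip_background = 50, peak_height = 40, seed = 13)
  gg <- sim_genome(cfg)
  tr <- plant_truth(gg$genes, cfg)
  wt <- simulate_chip_windows(gg$genome, gg$genes, tr, cfg)
  w <- wt$windows
  up_gene <- tr$gene_id[tr$chip_effect > 1][1]
  tss <- gg$genes$tss[gg$genes$gene_id == up_gene]
  chrom <- gg$genes$chrom[gg$genes$gene_id == up_gene]
  at_peak <- w$chrom == chrom & w$start <= tss & w$end > tss
  ratio <- sum(w$count_edc[at_peak]) / sum(w$count_veh[at_peak])
  expect_equal(ratio, 3, tolerance = 0.25) # Poisson noise at lambda = 2000
  # exchangeable background away from all promoters
  near_tss <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(gg$genes))) {
    near_tss <- near_tss | (w$chrom == gg$genes$chrom[i] &
                            w$end > gg$genes$tss[i] - 1500 &
                            w$start < gg$genes$tss[i] + 1500)
  }
  expect_equal(mean(w$count_edc[!near_tss]), 50, tolerance = 0.05)
  expect_equal(mean(w$count_veh[!near_tss]), 50, tolerance = 0.05)

  zero <- sim_config(n_genes = 20L, fraction_de = 0, chip_background = 0, seed = 13)
  wt0 <- simulate_chip_windows(gg$genome, gg$genes,
                               plant_truth(gg$genes, zero), zero)
  out_peak <- !near_tss
  expect_true(all(wt0$windows$count_veh[out_peak] == 0))
})

test_that("RRBS deltas center on the planted shift and clip at bounds", {
  cfg <- sim_config(n_genes = 40L, fraction_de = 0.5,
                    fraction_concordant_meth = 1, meth_delta = 0.25,
                    cpg_coverage = 500, seed = 21)
  gg <- sim_genome(cfg)
  tr <- plant_truth(gg$genes, cfg)
  sites <- simulate_rrbs(gg$genes, tr, cfg)
  sites$obs_delta <- sites$meth_edc / sites$total_edc -
                     sites$meth_veh / sites$total_veh
  m <- tapply(sites$obs_delta, sites$gene_id, mean)
  hypo_genes <- tr$gene_id[tr$meth_delta < 0]
  # clipping makes the realized delta slightly smaller than planted
  expect_lt(mean(m[hypo_genes]), -0.18)
  null_genes <- tr$gene_id[tr$meth_delta == 0]
  expect_equal(unname(mean(m[null_genes])), 0, tolerance = 0.02)
  expect_equal(nrow(sites), 40 * cfg$cpg_per_gene)
})

test_that("panel simulation validates deltas and is seed-stable", {
  panel <- data.frame(gene = "Esr1", chrom = "chr1", pos = seq(100, 750, 50))
  expect_error(simulate_panel(panel, rep(-2, 14), 100, 1), "\\[-1, 1\\]")
  expect_error(simulate_panel(panel, rep(0, 10), 100, 1), "panel size")
  a <- simulate_panel(panel, rep(-0.25, 14), 100, 7)
  b <- simulate_panel(panel, rep(-0.25, 14), 100, 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 14)
  null <- simulate_panel(panel, rep(0, 14), 2000, 7)
  expect_equal(mean(null$meth_edc / null$total_edc -
                    null$meth_veh / null$total_veh), 0, tolerance = 0.03)
})

test_that("identical configurations give bit-identical datasets", {
  cfg <- sim_config(n_genes = 30L, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$rna$counts, d2$rna$counts)
  expect_identical(d1$chip$windows, d2$chip$windows)
  expect_identical(d1$cpg, d2$cpg)
})
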