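test_that("G-test matches the textbook formula and chi-square limit", {
  gt <- gtest_2x2(10, 10, 1000, 1000)
  expect_equal(gt$G, 0)
  expect_equal(gt$p, 1)
  g30 <- gtest_2x2(30, 10, 1000, 1000)
  expect_equal(g30$G, oracle_gtest(30, 10, 1000, 1000), tolerance = 1e-12)
  expect_equal(g30$p, pchisq(g30$G, 1, lower.tail = FALSE))
  # doubling all cells doubles G exactly
  g60 <- gtest_2x2(60, 20, 2000, 2000)
  expect_equal(g60$G, 2 * g30$G, tolerance = 1e-9)
  # zero-total convention
  z <- gtest_2x2(0, 0, 100, 100)
  expect_equal(z$G, 0)
  expect_equal(z$p, 1)
  # random tables against the independent implementation
  set.seed(17)
  for (i in 1:200) {
    na <- sample(50:5000, 1); nb <- sample(50:5000, 1)
    a <- sample(0:min(40, na), 1); b <- sample(0:min(40, nb), 1)
    expect_equal(gtest_2x2(a, b, na, nb)$G, oracle_gtest(a, b, na, nb),
                 tolerance = 1e-9)
  }
  # large-count agreement with Pearson chi-square
  a <- 1200; b <- 1000; na <- nb <- 1e6
  G <- gtest_2x2(a, b, na, nb)$G
  chisq <- suppressWarnings(stats::chisq.test(
    rbind(c(a, na - a), c(b, nb - b)), correct = FALSE))$statistic
  expect_lt(abs(G - chisq) / chisq, 0.02)
})

test_that("window scan recovers a planted enriched window and merges runs", {
  g <- genome_spec("chr1", 1e6)
  wins <- make_windows(g, 1000)
  set.seed(4)
  wins$count_veh <- rpois(nrow(wins), 20)
  wins$count_edc <- rpois(nrow(wins), 20)
  # plant a 3x block spanning windows 40-42, small against the library
  wins$count_edc[40:42] <- rpois(3, 600)
  wins$count_veh[40:42] <- rpois(3, 200)
  tr <- window_track(wins, 1000, genome = g)
  regions <- scan_windows(tr)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$direction, "enriched")
  expect_equal(regions$start, 39000)
  expect_equal(regions$end, 42000)
  expect_equal(regions$n_windows, 3L)
  # monotone in the fold-change threshold
  expect_equal(nrow(scan_windows(tr, fc_cut = 1e6)), 0)
  # empty track
  empty <- window_track(wins[0, ], 1000, genome = g)
  expect_equal(nrow(scan_windows(empty)), 0)
})

test_that("null tracks stay near the nominal false-positive rate", {
  g <- genome_spec("chr1", 1e7)
  wins <- make_windows(g, 1000)
  set.seed(5)
  wins$count_veh <- rpois(nrow(wins), 20)
  wins$count_edc <- rpois(nrow(wins), 20)
  tr <- window_track(wins, 1000, genome = g)
  regions <- scan_windows(tr, fdr_cut = 0.01)
  n_sig_windows <- sum(regions$n_windows)
  expect_lte(n_sig_windows / nrow(wins), 0.02)
})

test_that("merging is idempotent and directions stay disjoint", {
  cfg <- sim_config(n_genes = 60L, fraction_de = 0.5, chip_background = 8,
                    seed = 77)
  gg <- sim_genome(cfg)
  tr <- plant_truth(gg$genes, cfg)
  wt <- simulate_chip_windows(gg$genome, gg$genes, tr, cfg)
  regions <- scan_windows(wt)
  expect_gt(nrow(regions), 0)
  for (dir in c("enriched", "reduced")) {
    d <- regions[regions$direction == dir, ]
    if (nrow(d) < 2) next
    d <- d[order(d$chrom, d$start), ]
    same <- d$chrom[-1] == d$chrom[-nrow(d)]
    expect_true(all(d$start[-1][same] > d$end[-nrow(d)][same])) # disjoint
  }
})

test_that("TSS annotation respects the 3 kb rule", {
  w <- tiny_world()
  genes <- w$genes
  tss <- genes$tss[1] # gene 1, + strand, tss = 5000
  regions <- data.frame(
    region_id = c("r1", "r2", "r3"),
    chrom = "chr1",
    start = c(tss - 1001 - 500, tss - 4000 - 500, tss - 200),
    end = c(tss - 1001, tss - 4000, tss + 300),
    direction = "enriched", stringsAsFactors = FALSE)
  ann <- annotate_tss(regions, genes, max_dist = 3000)
  hit <- ann[ann$gene_id == "g1", ]
  expect_setequal(hit$region_id, c("r1", "r3"))
  # r1 ends 1001 bp before the TSS: annotated at distance 1001 + 1 - 1
  expect_equal(hit$distance[hit$region_id == "r1"],
               distance_to_tss("chr1", tss - 1501, tss - 1001, "chr1", tss))
  expect_equal(hit$distance[hit$region_id == "r3"], 0)
  expect_false("r2" %in% ann$region_id)
})

test_that("gene mark status combines directions inside the 10 kb window", {
  w <- tiny_world(n_genes = 4, spacing = 30000)
  genes <- w$genes
  mk <- function(id, start, end, dir)
    data.frame(region_id = id, chrom = "chr1", start = start, end = end,
               direction = dir, stringsAsFactors = FALSE)
  g1s <- genes$start[1]
  regions <- rbind(
    mk("e1", g1s - 5000, g1s - 4000, "enriched"),
    mk("r1", g1s + 200, g1s + 400, "reduced"),
    mk("e2", genes$start[2] - 500, genes$start[2] + 100, "enriched"))
  st <- gene_mark_status(genes, regions, w$genome, flank = 10000)
  expect_equal(st$status[st$gene_id == "g1"], "both")
  expect_equal(st$status[st$gene_id == "g2"], "enriched")
  expect_equal(st$status[st$gene_id == "g3"], "none")
  far <- mk("x", 1, 100, "enriched")
  far$chrom <- "chrZ"
  # disjoint chromosome sets: GenomicRanges warns about seqlevels, which is
  # exactly the situation under test
  st2 <- suppressWarnings(gene_mark_status(genes, far, w$genome))
  expect_true(all(st2$status == "none"))
})

test_that("planted promoter effects are recovered with correct direction", {
  cfg <- sim_config(n_genes = 100L, fraction_de = 0.5,
                    fraction_concordant_chip = 1, chip_effect = 3,
                    chip_background = 5, seed = 19)
  gg <- sim_genome(cfg)
  tr <- plant_truth(gg$genes, cfg)
  wt <- simulate_chip_windows(gg$genome, gg$genes, tr, cfg)
  regions <- scan_windows(wt)
  st <- gene_mark_status(gg$genes, regions, gg$genome)
  m <- merge(tr, st)
  planted_up <- m$chip_effect > 1
  planted_dn <- m$chip_effect < 1
  sens <- (sum(m$status[planted_up] == "enriched") +
           sum(m$status[planted_dn] == "reduced")) /
          sum(planted_up | planted_dn)
  expect_gte(sens, 0.9)
  # no planted effect called in the wrong direction
  expect_equal(sum(m$status[planted_up] == "reduced") +
               sum(m$status[planted_dn] == "enriched"), 0)
})
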