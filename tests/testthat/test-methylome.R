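test_that("percent methylation applies the coverage and variant floors", {
  expect_equal(meth_pct(5, 10), 0.5)
  expect_equal(meth_pct(0, 500), 0)
  expect_true(is.na(meth_pct(0, 0)))
  # sub-0.1% frequencies are not called
  expect_equal(meth_pct(1, 2000), 0)
  expect_equal(meth_pct(3, 2000), 3 / 2000)
  sites <- data.frame(total_veh = c(5, 4, 10), total_edc = c(5, 10, 4))
  expect_identical(is_analyzable(sites), c(TRUE, FALSE, FALSE))
})

test_that("per-site differential matches Fisher enumeration and conventions", {
  s <- data.frame(chrom = "c", pos = 1:3,
                  meth_veh = c(5, 10, 10), total_veh = c(10, 10, 20),
                  meth_edc = c(5, 0, 2), total_edc = c(10, 10, 20))
  out <- site_differential(s)
  expect_equal(out$p[1], 1)
  expect_equal(out$delta[1], 0)
  # [[0,10],[10,0]]: the classic extreme table
  expect_equal(out$p[2], 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(out$delta[2], 0) # EDC lower => hypo direction is negative
  expect_equal(out$p[3], oracle_fisher(2, 18, 10, 10), tolerance = 1e-12)
  low <- data.frame(chrom = "c", pos = 1, meth_veh = 2, total_veh = 4,
                    meth_edc = 2, total_edc = 10)
  expect_true(is.na(site_differential(low)$p))
})

test_that("Fisher exact p equals full enumeration on random small tables", {
  f <- fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(f$odds_ratio, 1)
  expect_equal(f$p, 1)
  d <- fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))
  expect_equal(d$p, 2 / choose(10, 5), tolerance = 1e-12)
  set.seed(23)
  for (i in 1:300) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    got <- fisher_exact_2x2(tab)
    if (got$flagged) {
      expect_true(sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
                  sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0)
      next
    }
    expect_equal(got$p, oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
    # transposition symmetry
    expect_equal(fisher_exact_2x2(t(tab))$p, got$p, tolerance = 1e-12)
    # cross-check against the standard implementation
    expect_equal(got$p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("gene methylation status follows the any-site rule", {
  expect_equal(gene_meth_status(c(-0.40, -0.35, 0), 0.33)$status, "hypo")
  expect_equal(gene_meth_status(c(-0.40, 0.40), 0.33)$status, "mixed")
  expect_equal(gene_meth_status(c(-0.10, 0.10), 0.33)$status, "none")
  expect_equal(gene_meth_status(c(0.5, NA), 0.33)$status, "hyper")
  expect_equal(gene_meth_status(numeric(0), 0.33)$status, "none")
  # threshold sweep on one profile
  d <- c(-0.2, 0.12)
  expect_equal(gene_meth_status(d, 0.10)$status, "mixed")
  expect_equal(gene_meth_status(d, 0.33)$status, "none")
  expect_equal(gene_meth_status(d, 0.50)$status, "none")
})

test_that("paired Wilcoxon matches 2^n enumeration, ties included", {
  w <- wilcoxon_paired(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(w$W, 15)
  expect_equal(w$p, 2 / 32)
  expect_equal(wilcoxon_paired(1:4, 1:4), list(W = 0, p = 1))
  set.seed(31)
  for (i in 1:120) {
    n <- sample(3:10, 1)
    x <- sample(0:5, n, replace = TRUE) / 4 # many ties
    y <- sample(0:5, n, replace = TRUE) / 4
    got <- wilcoxon_paired(x, y)
    ora <- oracle_wilcoxon(x, y)
    expect_equal(got$W, ora$W)
    expect_equal(got$p, ora$p, tolerance = 1e-9)
    # sign-flip symmetry
    expect_equal(wilcoxon_paired(y, x)$p, got$p, tolerance = 1e-12)
  }
  # tie-free case agrees with the standard exact implementation
  set.seed(33)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_paired(x, y)$p,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("panel summaries count hypo sites against the full panel size", {
  panel <- data.frame(gene = "Pgr", chrom = "chr8",
                      pos = seq(100, by = 50, length.out = 19))
  # deterministic counts: 7 unambiguously hypo sites, 12 exactly null
  sites <- data.frame(
    gene = "Pgr", chrom = "chr8", pos = panel$pos,
    meth_veh = c(rep(250, 7), rep(250, 12)), total_veh = 500,
    meth_edc = c(rep(100, 7), rep(250, 12)), total_edc = 500,
    stringsAsFactors = FALSE)
  rpt <- summarize_panel(panel, sites)
  expect_equal(rpt$n_hypo, 7)
  expect_equal(rpt$panel_size, 19)
  expect_equal(rpt$pct_hypo, 36.8)
  expect_lt(rpt$wilcoxon_p, 0.05)
  # site order must not matter
  shuf <- sample(nrow(sites))
  expect_equal(summarize_panel(panel, sites[shuf, ])$pct_hypo, 36.8)
  # missing sites are reported, not fabricated
  rpt2 <- summarize_panel(panel, sites[-1, ])
  expect_equal(rpt2$missing, panel$pos[1])
  expect_equal(nrow(rpt2$sites), 18)
})
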