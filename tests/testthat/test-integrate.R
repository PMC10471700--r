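test_that("concordance categories follow the expected-mark rules", {
  expect_equal(classify_gene("up", "enriched", "hypo"),
               list(chip_category = "expected", meth_category = "expected"))
  expect_equal(classify_gene("down", "enriched", "hypo"),
               list(chip_category = "opposite", meth_category = "opposite"))
  expect_equal(classify_gene("up", "none", "mixed"),
               list(chip_category = "none", meth_category = "mixed"))
  expect_equal(classify_gene("down", "both", "hyper"),
               list(chip_category = "mixed", meth_category = "expected"))
  expect_error(classify_gene("ns", "none", "none"), "up")
  expect_error(classify_gene("up", "sideways", "none"), "chip")
})

test_that("summaries partition DE genes and recompute percentages exactly", {
  de <- data.frame(gene_id = paste0("g", 1:5),
                   direction = c("up", "up", "up", "up", "ns"))
  chip <- data.frame(gene_id = paste0("g", 1:5),
                     status = c("enriched", "reduced", "both", "none", "enriched"))
  meth <- data.frame(gene_id = paste0("g", 1:5),
                     status = c("hypo", "hyper", "mixed", "none", "hypo"))
  rec <- concordance_records(de, chip, meth)
  expect_equal(nrow(rec), 4) # ns gene excluded
  s <- summarize_concordance(rec, threshold = 0.33)
  expect_equal(s$up$n_genes, 4)
  expect_equal(s$up$chip$pct, rep(25, 4))
  expect_equal(s$up$meth$pct, rep(25, 4))
  expect_equal(sum(s$up$chip$count), 4) # categories partition the gene list
  expect_equal(sum(s$up$meth$pct), 100, tolerance = 0.05)
  expect_equal(s$up$overlap_both_marks, 3)
  # percentages recompute from counts
  expect_equal(s$up$chip$pct, round(100 * s$up$chip$count / s$up$n_genes, 2))
  expect_error(summarize_concordance(rec[0, ]), "no DE genes")
})

test_that("ERG summary counts dysregulated set members", {
  de <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    direction = c(rep("up", 60), rep("down", 27), rep("ns", 113)))
  erg <- sprintf("g%03d", 1:100)
  s <- erg_summary(de, erg)
  expect_equal(s$n_up, 60)
  expect_equal(s$n_down, 27)
  expect_equal(s$n_total, 87)
  expect_equal(erg_summary(de, "not_present")$n_total, 0)
  expect_error(erg_summary(de, character(0)), "empty")
})

test_that("hypergeometric ORA equals draw-by-draw enumeration", {
  r4 <- ora_hypergeom(paste0("g", 1:5), paste0("g", 1:4), paste0("g", 1:20))
  expect_equal(r4$k, 4)
  expect_equal(r4$p, 16 / 15504, tolerance = 1e-12)
  expect_equal(ora_hypergeom(paste0("g", 1:5), paste0("g", 6:9),
                             paste0("g", 1:20))$p, 1) # k = 0
  # enrichment ratio 1 when list frequency matches set frequency
  e <- ora_hypergeom(paste0("g", 1:5), paste0("g", c(1, 6:8)), paste0("g", 1:20))
  expect_equal(e$enrichment, (1 / 5) / (4 / 20))
  set.seed(41)
  for (i in 1:25) {
    N <- sample(6:12, 1)
    n <- sample(2:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    u <- paste0("u", 1:N)
    lst <- sample(u, n)
    st <- u[1:K] # oracle assumes the set is the first K labels
    got <- ora_hypergeom(lst, st, u)
    expect_equal(got$p, oracle_ora(N, n, K, got$k), tolerance = 1e-9)
  }
})

test_that("DE-by-mark Fisher association behaves under independence and linkage", {
  set.seed(51)
  ps <- replicate(40, {
    de <- runif(120) < 0.5
    mk <- runif(120) < 0.4
    integration_fisher(de, mk)$p
  })
  expect_gt(mean(ps < 0.05), 0)  # sanity: p-values vary
  expect_lt(mean(ps < 0.05), 0.15) # near-nominal under independence
  # perfect association reaches the enumeration minimum for the margins
  de <- rep(c(TRUE, FALSE), each = 10)
  p_perfect <- integration_fisher(de, de)$p
  expect_equal(p_perfect, 2 / choose(20, 10), tolerance = 1e-9)
  expect_error(integration_fisher(logical(0), logical(0)), "empty")
})

test_that("pipeline reruns are byte-identical and respect fraction_de = 0", {
  cfg <- default_config()
  cfg$synth$n_genes <- 80L
  cfg$synth$n_erg <- 12L
  cfg$chromstate$n_restarts <- 2L
  cfg$chromstate$max_iter <- 60L
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  unlink(c(d1, d2), recursive = TRUE)
  run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))

  cfg0 <- cfg
  cfg0$synth$fraction_de <- 0
  d0 <- file.path(tempdir(), "run_null")
  unlink(d0, recursive = TRUE)
  s0 <- run_pipeline(cfg0, d0)
  expect_equal(s0$n_de_up + s0$n_de_down, 0)
})

test_that("planted-concordant runs put expected above opposite for up genes", {
  cfg <- default_config()
  cfg$synth$n_genes <- 300L
  cfg$synth$n_erg <- 45L
  cfg$chromstate$n_restarts <- 2L
  cfg$chromstate$max_iter <- 60L
  out <- file.path(tempdir(), "run_conc")
  unlink(out, recursive = TRUE)
  s <- run_pipeline(cfg, out)
  up33 <- s$concordance$t33$up
  expect_gt(up33$chip_pct$expected, up33$chip_pct$opposite)
  expect_gt(up33$meth_pct$expected, up33$meth_pct$opposite)
})
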