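#!/usr/bin/env Rscript
# Stage 6 — tri-omics integration. Per-gene concordance categories
# (expected / opposite / mixed / none) for H3K4me3 and promoter
# methylation against the DE direction, percentage tables per threshold,
# the Fisher association between DE direction and mark presence, ERG
# over-representation among DE genes, and recovery scoring against the
# planted truth.

suppressPackageStartupMessages(library(fibroprog))
out <- "results/workflow"
cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")

genes <- read_tsv(file.path(out, "genes.tsv"))
genes$gene_sets[is.na(genes$gene_sets)] <- ""
de <- read_tsv(file.path(out, "de.tsv"))
mark <- read_tsv(file.path(out, "gene_mark_status.tsv"))
truth <- read_tsv(file.path(out, "truth.tsv"))

summary <- list(seed = cfg$seed)
for (t in cfg$methylome$thresholds) {
  tn <- sprintf("%d", round(100 * t))
  meth <- read_tsv(file.path(out, paste0("gene_meth_status_", tn, ".tsv")))
  records <- concordance_records(de, mark, meth)
  for (dir in c("up", "down"))
    write_tsv(records[records$de_direction == dir, ],
              file.path(out, sprintf("concordance_%s_%s.tsv", dir, tn)))
  s <- summarize_concordance(records, threshold = t)
  summary[[paste0("concordance_t", tn)]] <- lapply(s, function(dd) list(
    n_genes = dd$n_genes,
    chip_pct = as.list(setNames(dd$chip$pct, dd$chip$category)),
    meth_pct = as.list(setNames(dd$meth$pct, dd$meth$category)),
    overlap_both_marks = dd$overlap_both_marks))
  cat(sprintf("threshold %s%%: up-gene chip expected %.2f%%, meth expected %.2f%%\n",
              tn, s$up$chip$pct[1], s$up$meth$pct[1]))
}

de_dir <- de$direction[de$direction %in% c("up", "down")]
de_ids <- de$gene_id[de$direction %in% c("up", "down")]
fisher <- integration_fisher(
  de_dir == "up", mark$status[match(de_ids, mark$gene_id)] != "none")
cat(sprintf("DE direction x H3K4me3 mark: OR = %.2f, Fisher p = %.3g\n",
            fisher$odds_ratio, fisher$p))
summary$chip_de_fisher <- fisher[c("odds_ratio", "p")]

erg_ids <- genes_in_set(genes, c("ERG_early", "ERG_late"))
ora <- ora_hypergeom(de_ids, erg_ids, de$gene_id)
cat(sprintf("ERG over-representation among DE genes: k=%d/%d, p = %.3g\n",
            ora$k, ora$n, ora$p))
summary$erg_ora <- ora

m <- merge(truth, de)
planted <- m$de_log2fc != 0
summary$de_sensitivity <-
  mean(m$direction[planted] == ifelse(m$de_log2fc[planted] > 0, "up", "down"))
mm <- merge(truth, mark)
pl <- mm$chip_effect != 1
summary$chip_sensitivity <-
  mean(mm$status[pl] == ifelse(mm$chip_effect[pl] > 1, "enriched", "reduced"))
cat(sprintf("planted-truth recovery: DE sensitivity %.3f, ChIP sensitivity %.3f\n",
            summary$de_sensitivity, summary$chip_sensitivity))

write_summary_json(summary, file.path(out, "summary.json"))
cat("wrote", file.path(out, "summary.json"), "\n")
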