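#!/usr/bin/env Rscript
# Stage 2 — differential expression at the twofold / FDR 0.05 cutoff.
#
# Single pooled library per condition, so the per-gene test is the exact
# conditional binomial on each gene's (EDC, VEH) count pair given the
# library sizes; q-values are Benjamini-Hochberg.

suppressPackageStartupMessages(library(fibroprog))
out <- "results/workflow"
cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")

cm <- read_counts(file.path(out, "counts.tsv"))
cm <- filter_detected(cm, cfg$diffexpr$min_total)
de <- call_de(de_test(cm, cfg$diffexpr$dispersion),
              fc_cut = cfg$diffexpr$fc_cut, fdr_cut = cfg$diffexpr$fdr_cut)
write_tsv(de[c("gene_id", "log2fc", "p", "q", "direction")],
          file.path(out, "de.tsv"))

genes <- read_tsv(file.path(out, "genes.tsv"))
genes$gene_sets[is.na(genes$gene_sets)] <- ""
erg <- erg_summary(de, genes_in_set(genes, c("ERG_early", "ERG_late")))

cat(sprintf("genes detected: %d\n", nrow(cm$counts)))
cat(sprintf("DE genes: %d up, %d down\n",
            sum(de$direction == "up"), sum(de$direction == "down")))
cat(sprintf("dysregulated ERGs: %d (%d up / %d down)\n",
            erg$n_total, erg$n_up, erg$n_down))
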