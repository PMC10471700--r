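#!/usr/bin/env Rscript
# Stage 1 — simulate the tri-omics dataset.
#
# Generates the synthetic study: 2000 genes (299 tagged estrogen-responsive)
# on a two-chromosome genome, a pooled RNA library per condition at 1e7
# reads with 25% of genes differentially expressed at |log2FC| = 1.5,
# H3K4me3 window counts with threefold promoter perturbations (80%
# expression-concordant), and 14 promoter CpGs per gene at 30x with
# +/-0.40 planted methylation shifts (60% concordant). Everything below is
# recoverable ground truth for stages 2-6.

suppressPackageStartupMessages(library(fibroprog))
out <- "results/workflow"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")
write_config_echo(cfg, out)

sc <- do.call(sim_config, c(cfg$synth, cfg$genome, list(seed = cfg$seed)))
ds <- simulate_dataset(sc)

write_tsv(ds$genes, file.path(out, "genes.tsv"))
write_tsv(data.frame(chrom = ds$genome$chrom_names,
                     length = unname(ds$genome$chrom_lengths)),
          file.path(out, "genome.tsv"))
write_tsv(ds$truth, file.path(out, "truth.tsv"))
write_counts(ds$rna, file.path(out, "counts.tsv"))
write_bedgraph(ds$chip, "VEH", file.path(out, "chip_veh.bedgraph"))
write_bedgraph(ds$chip, "EDC", file.path(out, "chip_edc.bedgraph"))
write_tsv(ds$cpg[c("chrom", "pos", "meth_veh", "total_veh",
                   "meth_edc", "total_edc")],
          file.path(out, "cpg_counts.tsv"))

cat(sprintf("simulated %d genes on %d chromosomes (seed %d)\n",
            nrow(ds$genes), length(ds$genome$chrom_names), cfg$seed))
cat(sprintf("planted DE genes: %d (%d up / %d down)\n",
            sum(ds$truth$de_log2fc != 0), sum(ds$truth$de_log2fc > 0),
            sum(ds$truth$de_log2fc < 0)))
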