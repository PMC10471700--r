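#!/usr/bin/env Rscript
# Stage 3 — windowed differential H3K4me3 (G-test, 1.5x / q < 0.01),
# region merging, 3 kb TSS annotation, and per-gene mark status over the
# gene body +/- 10 kb.

suppressPackageStartupMessages(library(fibroprog))
out <- "results/workflow"
cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")

gn <- read_tsv(file.path(out, "genome.tsv"))
genome <- genome_spec(gn$chrom, gn$length)
genes <- read_tsv(file.path(out, "genes.tsv"))
track <- read_bedgraph_pair(file.path(out, "chip_veh.bedgraph"),
                            file.path(out, "chip_edc.bedgraph"), genome)

regions <- scan_windows(track, fc_cut = cfg$diffchip$fc_cut,
                        fdr_cut = cfg$diffchip$fdr_cut)
write_diff_regions(regions, file.path(out, "diff_regions.bed"))
write_tsv(regions, file.path(out, "diff_regions.tsv"))
ann <- annotate_tss(regions, genes, cfg$diffchip$tss_dist)
write_tsv(ann, file.path(out, "tss_annotation.tsv"))
mark <- gene_mark_status(genes, regions, genome, flank = cfg$diffchip$flank)
write_tsv(mark, file.path(out, "gene_mark_status.tsv"))

cat(sprintf("differential regions: %d (%d enriched / %d reduced)\n",
            nrow(regions), sum(regions$direction == "enriched"),
            sum(regions$direction == "reduced")))
cat(sprintf("genes with a region within 3 kb of the TSS: %d\n",
            length(unique(ann$gene_id))))
cat(sprintf("gene mark status: %s\n",
            paste(names(table(mark$status)), table(mark$status),
                  sep = "=", collapse = ", ")))
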