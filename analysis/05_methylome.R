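#!/usr/bin/env Rscript
# Stage 5 — differential CpG methylation. Genome-wide RRBS-style calls
# under the 5x/5x coverage rule with per-site Fisher tests, per-gene
# promoter status at the 10/33/50 percentage-point thresholds, and the
# eight targeted ERG panels (synthetic site catalog) at 500x with a
# planted -0.25 delta, summarized with paired Wilcoxon tests.

suppressPackageStartupMessages(library(fibroprog))
out <- "results/workflow"
cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")

genes <- read_tsv(file.path(out, "genes.tsv"))
cpg <- read_tsv(file.path(out, "cpg_counts.tsv"))
sites <- site_differential(cpg, min_cov = cfg$methylome$min_cov,
                           floor = cfg$methylome$pct_floor)
write_tsv(sites, file.path(out, "cpg_differential.tsv"))
cat(sprintf("CpG sites analyzable at %dx/%dx: %d of %d\n",
            cfg$methylome$min_cov, cfg$methylome$min_cov,
            sum(sites$analyzable), nrow(sites)))

mapped <- map_sites_to_promoters(sites, genes, flank = 1000)
for (t in cfg$methylome$thresholds) {
  st <- gene_meth_status_all(mapped, genes, t)
  write_tsv(st, file.path(out, sprintf("gene_meth_status_%d.tsv",
                                       round(100 * t))))
  cat(sprintf("threshold %.0f%%: %s\n", 100 * t,
              paste(names(table(st$status)), table(st$status),
                    sep = "=", collapse = ", ")))
}

panels <- read_panels(system.file("extdata", "erg_panels_synthetic.tsv",
                                  package = "fibroprog"))
for (g in unique(panels$gene)) {
  pd <- panels[panels$gene == g, ]
  ps <- simulate_panel(pd, rep(-0.25, nrow(pd)), coverage = 500,
                       seed = cfg$seed + match(g, unique(panels$gene)))
  rpt <- summarize_panel(pd, ps, site_p = cfg$methylome$site_p,
                         min_cov = cfg$methylome$min_cov)
  write_tsv(rpt$sites, file.path(out, "panels", paste0(g, ".tsv")))
  cat(sprintf("panel %-7s %2d sites: %2d hypo (%.1f%%), Wilcoxon p = %.3g\n",
              g, rpt$panel_size, rpt$n_hypo, rpt$pct_hypo, rpt$wilcoxon_p))
}
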