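#!/usr/bin/env Rscript
# Stage 4 — chromatin-state segmentation of the vehicle H3K4me3 track:
# Poisson binarization, a 4-state Bernoulli-emission HMM (Baum-Welch,
# seeded restarts), Viterbi decoding, and odds-ratio enrichment of the
# stage-3 differential regions per state.

suppressPackageStartupMessages(library(fibroprog))
out <- "results/workflow"
cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")

gn <- read_tsv(file.path(out, "genome.tsv"))
genome <- genome_spec(gn$chrom, gn$length)
track <- read_bedgraph_pair(file.path(out, "chip_veh.bedgraph"),
                            file.path(out, "chip_edc.bedgraph"), genome)

bt <- binarize(track$windows$count_veh,
               track$windows[c("chrom", "start", "end")],
               p_cut = cfg$chromstate$p_cut)
model <- fit_hmm(bt, n_states = cfg$chromstate$n_states, seed = cfg$seed,
                 n_restarts = cfg$chromstate$n_restarts,
                 tol = cfg$chromstate$tol, max_iter = cfg$chromstate$max_iter)
path <- decode(model, bt)
write_states_bed(path, bt, file.path(out, "states.bed"))
write_hmm_tsv(model, file.path(out, "hmm_model.tsv"))

regions <- read_tsv(file.path(out, "diff_regions.tsv"))
enr <- state_enrichment(path, bt, regions)
write_tsv(enr, file.path(out, "state_enrichment.tsv"))

cat(sprintf("binarization: lambda=%.2f, threshold=%d, %.2f%% of bins on\n",
            bt$lambda, bt$threshold, 100 * mean(bt$x)))
cat(sprintf("HMM emissions (by rank): %s\n",
            paste(sprintf("%.3f", model$e), collapse = ", ")))
print(enr[c("state", "label", "state_bp", "diff_bp", "odds_ratio")],
      row.names = FALSE)
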