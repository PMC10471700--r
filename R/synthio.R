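# Seeded tri-omics simulator with planted per-gene ground truth.
#
# The generator emulates the study design: one pooled library per condition
# (EDC vs VEH), TSS-proximal H3K4me3 signal, beta-binomial promoter CpG
# methylation, and configurable direction-concordance between the three
# layers. Each gene carries a TruthRecord so downstream calls can be scored
# against what was planted.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 2000 genes of which 299
#' are tagged estrogen-responsive, 25% differentially expressed at
#' |log2FC| = 1.5 with a pooled-library depth of 1e7 reads, promoter
#' H3K4me3 peaks perturbed threefold with 80% expression-concordance, and
#' promoter CpG methylation shifted by 0.40 with 60% concordance at 30x
#' bisulfite coverage over 14 CpGs per promoter.
#'
#' @param ... Overrides for any field of the `synth`, `genome` or `seed`
#'   entries of [default_config()] (flat names, e.g. `n_genes = 100`).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(...) {
  cfg <- default_config()
  flat <- c(cfg$synth, cfg$genome, list(seed = cfg$seed))
  over <- list(...)
  unknown <- setdiff(names(over), names(flat))
  if (length(unknown) > 0)
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  flat[names(over)] <- over
  with(flat, {
    stopifnot(fraction_de >= 0, fraction_de <= 1,
              fraction_concordant_chip >= 0, fraction_concordant_chip <= 1,
              fraction_concordant_meth >= 0, fraction_concordant_meth <= 1,
              rna_depth > 0, chip_background >= 0, cpg_coverage > 0,
              window_size > 0, replicates >= 1, abs(meth_delta) <= 1,
              chip_effect > 0)
  })
  structure(flat, class = "SimConfig")
}

#' Lay out a synthetic genome and its gene models
#'
#' Genes of fixed length are placed on `n_chrom` chromosomes separated by
#' `gene_spacing` bp, alternating strand; the first `n_erg` genes are tagged
#' `ERG_early` (first half) and `ERG_late` (second half).
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([genome_spec()]) and `genes` (gene models).
#' @export
sim_genome <- function(config) {
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chrom)
  pitch <- config$gene_length + config$gene_spacing
  chrom_names <- paste0("chr", seq_len(config$n_chrom))
  chrom_len <- per_chrom * pitch + config$gene_spacing
  genome <- genome_spec(chrom_names, rep(chrom_len, config$n_chrom))
  idx <- seq_len(n) - 1L
  chrom <- chrom_names[idx %/% per_chrom + 1L]
  slot <- idx %% per_chrom
  start <- config$gene_spacing + slot * pitch
  sets <- rep("", n)
  n_erg <- min(config$n_erg, n)
  if (n_erg > 0) {
    half <- ceiling(n_erg / 2)
    sets[seq_len(n_erg)] <- rep(c("ERG_early", "ERG_late"),
                                c(half, n_erg - half))
  }
  genes <- gene_models(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + config$gene_length,
    strand = rep_len(c("+", "-"), n),
    gene_sets = sets, genome = genome)
  list(genome = genome, genes = genes)
}

#' Plant per-gene ground truth
#'
#' Exactly `round(fraction_de * n_genes)` genes receive a nonzero
#' expression effect, half up and half down (ties to up). Among those DE
#' genes the H3K4me3 and methylation effects agree in direction with the
#' expression change ("expected mark": up with promoter H3K4me3 gain and
#' promoter hypo-methylation) with probabilities
#' `fraction_concordant_chip` / `fraction_concordant_meth`, and are opposite
#' otherwise. Null genes get null effects in all three layers.
#'
#' @param genes Gene models.
#' @param config [sim_config()].
#' @return Data frame `gene_id, de_log2fc, chip_effect, meth_delta,
#'   chip_concordant, meth_concordant`.
#' @export
plant_truth <- function(genes, config) {
  rng_for("plant_truth", config$seed)
  n <- nrow(genes)
  n_de <- round(config$fraction_de * n)
  if (config$fraction_de > 0 && n_de < 1)
    warning("fraction_de * n_genes < 1; planting zero DE genes", call. = FALSE)
  truth <- data.frame(
    gene_id = genes$gene_id,
    de_log2fc = 0, chip_effect = 1, meth_delta = 0,
    chip_concordant = NA, meth_concordant = NA,
    stringsAsFactors = FALSE)
  if (n_de >= 1) {
    de_idx <- sample.int(n, n_de)
    n_up <- ceiling(n_de / 2)
    sign_de <- rep(c(1, -1), c(n_up, n_de - n_up))
    truth$de_log2fc[de_idx] <- sign_de * config$lfc
    conc_chip <- runif(n_de) < config$fraction_concordant_chip
    conc_meth <- runif(n_de) < config$fraction_concordant_meth
    # expected mark: up goes with H3K4me3 gain (ratio > 1) and hypo (< 0)
    chip_dir <- ifelse(conc_chip, sign_de, -sign_de)
    meth_dir <- ifelse(conc_meth, -sign_de, sign_de)
    truth$chip_effect[de_idx] <- config$chip_effect^chip_dir
    truth$meth_delta[de_idx] <- meth_dir * abs(config$meth_delta)
    truth$chip_concordant[de_idx] <- conc_chip
    truth$meth_concordant[de_idx] <- conc_meth
  }
  truth
}

#' Simulate RNA-seq counts
#'
#' Gene base abundances are drawn log-normally and scaled so the VEH
#' library totals `rna_depth` in expectation; the EDC mean is the VEH mean
#' times `2^de_log2fc`. Counts are negative binomial with
#' `Var = mu + dispersion * mu^2` (Poisson when `dispersion = 0`), one
#' column per replicate per condition.
#'
#' @param genes Gene models.
#' @param truth Output of [plant_truth()].
#' @param config [sim_config()].
#' @return A [count_matrix()].
#' @export
simulate_rnaseq <- function(genes, truth, config) {
  stopifnot(identical(genes$gene_id, truth$gene_id))
  rng_for("rnaseq", config$seed)
  n <- nrow(genes)
  w <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  mu_veh <- config$rna_depth * w / sum(w)
  mu_edc <- mu_veh * 2^truth$de_log2fc
  # match the EDC library to the configured depth: relative abundance is
  # what a fixed-depth sequencer measures (composition shift stays in the
  # data, as it does in real pooled libraries)
  mu_edc <- mu_edc * config$rna_depth / sum(mu_edc)
  r <- config$replicates
  draw <- function(mu) {
    if (config$dispersion < 1e-12) rpois(n, mu)
    else rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }
  cols <- c(lapply(seq_len(r), function(i) draw(mu_veh)),
            lapply(seq_len(r), function(i) draw(mu_edc)))
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes$gene_id
  colnames(counts) <- c(paste0("VEH_", seq_len(r)), paste0("EDC_", seq_len(r)))
  count_matrix(counts, condition = rep(c("VEH", "EDC"), each = r))
}

#' Simulate H3K4me3 window counts for both conditions
#'
#' Chromosomes are tiled with `window_size` bins (last bin clipped).
#' Background bins draw Poisson(`chip_background`); bins overlapping a
#' gene's promoter (TSS +/- `promoter_flank`) draw Poisson with mean
#' `chip_background * peak_height` in VEH, scaled by the gene's planted
#' `chip_effect` in EDC, so the EDC/VEH mean ratio at a peak equals the
#' planted effect. Overlapping promoters sum their signals (with a
#' warning).
#'
#' @param genome [genome_spec()].
#' @param genes Gene models.
#' @param truth Output of [plant_truth()].
#' @param config [sim_config()].
#' @return A [window_track()] holding both condition counts.
#' @export
simulate_chip_windows <- function(genome, genes, truth, config) {
  stopifnot(identical(genes$gene_id, truth$gene_id))
  rng_for("chip", config$seed)
  wins <- make_windows(genome, config$window_size)
  lam_veh <- rep(config$chip_background, nrow(wins))
  lam_edc <- lam_veh
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - config$promoter_flank),
                     end = pmin(unname(genome$chrom_lengths[genes$chrom]),
                                genes$tss + config$promoter_flank + 1))
  ov <- GenomicRanges::findOverlaps(as_granges0(wins), as_granges0(prom))
  wi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  if (anyDuplicated(wi)) warning("overlapping gene promoters: signals summed", call. = FALSE)
  peak_veh <- config$chip_background * config$peak_height
  add_veh <- tapply(rep(peak_veh, length(gi)), wi, sum)
  add_edc <- tapply(peak_veh * truth$chip_effect[gi], wi, sum)
  at <- as.integer(names(add_veh))
  lam_veh[at] <- as.numeric(add_veh)
  lam_edc[at] <- as.numeric(add_edc)
  wins$count_veh <- rpois(nrow(wins), lam_veh)
  wins$count_edc <- rpois(nrow(wins), lam_edc)
  window_track(wins, window_size = config$window_size, genome = genome)
}

# beta-binomial site levels shared by the RRBS and panel simulators
sim_bisulfite_sites <- function(chrom, pos, delta, coverage, base_mean, base_conc) {
  n <- length(pos)
  lvl_veh <- rbeta(n, base_mean * base_conc, (1 - base_mean) * base_conc)
  lvl_edc <- pmin(1, pmax(0, lvl_veh + delta))
  tot_veh <- rpois(n, coverage)
  tot_edc <- rpois(n, coverage)
  data.frame(
    chrom = chrom, pos = pos,
    meth_veh = rbinom(n, tot_veh, lvl_veh), total_veh = tot_veh,
    meth_edc = rbinom(n, tot_edc, lvl_edc), total_edc = tot_edc,
    stringsAsFactors = FALSE)
}

#' Simulate RRBS-style promoter CpG counts
#'
#' Each gene's promoter (TSS +/- `promoter_flank`) carries `cpg_per_gene`
#' evenly spaced CpG sites. The VEH methylation level is Beta-distributed
#' around `meth_base_mean`; the EDC level is the VEH level plus the gene's
#' planted `meth_delta`, clipped to \[0, 1\]. Read totals are
#' Poisson(`cpg_coverage`) per condition and methylated counts binomial.
#'
#' @param genes Gene models.
#' @param truth Output of [plant_truth()].
#' @param config [sim_config()].
#' @return Data frame of CpG sites: `chrom, pos, meth_veh, total_veh,
#'   meth_edc, total_edc` plus a `gene_id` convenience column.
#' @export
simulate_rrbs <- function(genes, truth, config) {
  stopifnot(identical(genes$gene_id, truth$gene_id))
  rng_for("rrbs", config$seed)
  k <- config$cpg_per_gene
  offs <- round(seq(-config$promoter_flank, config$promoter_flank, length.out = k))
  pos <- rep(genes$tss, each = k) + rep(offs, nrow(genes))
  sites <- sim_bisulfite_sites(
    chrom = rep(genes$chrom, each = k), pos = pos,
    delta = rep(truth$meth_delta, each = k),
    coverage = config$cpg_coverage,
    base_mean = config$meth_base_mean, base_conc = config$meth_base_conc)
  sites$gene_id <- rep(genes$gene_id, each = k)
  sites
}

#' Simulate a targeted bisulfite panel
#'
#' Generates per-site counts at the exact panel positions under the same
#' beta-binomial model as [simulate_rrbs()], with a per-site planted
#' EDC - VEH delta.
#'
#' @param panel Panel definition: data frame `gene, chrom, pos`.
#' @param deltas Planted per-site deltas in \[-1, 1\], one per panel site.
#' @param coverage Mean read coverage (Poisson) per condition.
#' @param seed Integer seed.
#' @param base_mean,base_conc Beta parameters of the VEH level.
#' @return Data frame of panel sites with count columns as in
#'   [simulate_rrbs()] plus `gene`.
#' @export
simulate_panel <- function(panel, deltas, coverage, seed,
                           base_mean = 0.5, base_conc = 10) {
  if (length(deltas) != nrow(panel))
    stop("deltas must match panel size (", nrow(panel), ")", call. = FALSE)
  if (any(abs(deltas) > 1))
    stop("panel deltas must lie in [-1, 1]", call. = FALSE)
  rng_for("panel", seed)
  sites <- sim_bisulfite_sites(panel$chrom, panel$pos, deltas, coverage,
                               base_mean, base_conc)
  cbind(gene = panel$gene, sites, stringsAsFactors = FALSE)
}

#' Simulate a full tri-omics dataset
#'
#' Runs [sim_genome()], [plant_truth()] and the three layer simulators
#' under one configuration; identical configurations (including seed)
#' give bit-identical output.
#'
#' @param config [sim_config()].
#' @return List `genome, genes, truth, rna, chip, cpg`.
#' @export
simulate_dataset <- function(config) {
  gg <- sim_genome(config)
  truth <- plant_truth(gg$genes, config)
  list(genome = gg$genome, genes = gg$genes, truth = truth,
       rna = simulate_rnaseq(gg$genes, truth, config),
       chip = simulate_chip_windows(gg$genome, gg$genes, truth, config),
       cpg = simulate_rrbs(gg$genes, truth, config))
}
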