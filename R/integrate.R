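# Tri-omics direction-concordance classification, summary tables,
# gene-set statistics, and the end-to-end pipeline driver.
#
# Category rules ("expected mark"): an upregulated gene is expected to gain
# promoter H3K4me3 and lose promoter methylation; a downregulated gene the
# reverse. Discordant single-direction marks are "opposite", bidirectional
# marks "mixed", absent marks "none". Only genes with a DE direction
# (up/down) enter the tables.

CHIP_STATUSES <- c("enriched", "reduced", "both", "none")
METH_STATUSES <- c("hypo", "hyper", "mixed", "none")
CATEGORIES <- c("expected", "opposite", "mixed", "none")

#' Classify one gene's tri-omics concordance
#'
#' @param de_dir `"up"` or `"down"`.
#' @param chip_status One of `enriched, reduced, both, none`.
#' @param meth_status One of `hypo, hyper, mixed, none`.
#' @return List `chip_category, meth_category`, each one of
#'   `expected, opposite, mixed, none`.
#' @export
classify_gene <- function(de_dir, chip_status, meth_status) {
  if (!de_dir %in% c("up", "down"))
    stop("de_dir must be 'up' or 'down'", call. = FALSE)
  if (!chip_status %in% CHIP_STATUSES)
    stop("unknown chip status: ", chip_status, call. = FALSE)
  if (!meth_status %in% METH_STATUSES)
    stop("unknown methylation status: ", meth_status, call. = FALSE)
  chip_expected <- if (de_dir == "up") "enriched" else "reduced"
  meth_expected <- if (de_dir == "up") "hypo" else "hyper"
  cat_of <- function(status, expected, mixed_token) {
    if (status == "none") "none"
    else if (status == mixed_token) "mixed"
    else if (status == expected) "expected"
    else "opposite"
  }
  list(chip_category = cat_of(chip_status, chip_expected, "both"),
       meth_category = cat_of(meth_status, meth_expected, "mixed"))
}

#' Build per-gene concordance records
#'
#' Joins DE calls with H3K4me3 mark status and promoter methylation
#' status; genes with direction `ns` are excluded.
#'
#' @param de Data frame from [call_de()].
#' @param chip Data frame from [gene_mark_status()].
#' @param meth Data frame from [gene_meth_status_all()].
#' @return Data frame `gene_id, de_direction, chip_status, meth_status,
#'   chip_category, meth_category`.
#' @export
concordance_records <- function(de, chip, meth) {
  de <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  chip_status <- chip$status[match(de$gene_id, chip$gene_id)]
  meth_status <- meth$status[match(de$gene_id, meth$gene_id)]
  chip_status[is.na(chip_status)] <- "none"
  meth_status[is.na(meth_status)] <- "none"
  cats <- Map(classify_gene, de$direction, chip_status, meth_status)
  data.frame(
    gene_id = de$gene_id,
    de_direction = de$direction,
    chip_status = chip_status,
    meth_status = meth_status,
    chip_category = vapply(cats, `[[`, character(1), "chip_category"),
    meth_category = vapply(cats, `[[`, character(1), "meth_category"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance summary per DE direction
#'
#' Counts and percentages (two decimals) per category for the H3K4me3 and
#' methylation layers separately, plus the count of genes carrying both a
#' chip and a methylation mark.
#'
#' @param records Data frame from [concordance_records()].
#' @param threshold The methylation threshold the records were built at
#'   (carried through for reporting).
#' @return Named list of per-direction summaries, each with `n_genes`,
#'   `chip` and `meth` category tables and `overlap_both_marks`.
#' @export
summarize_concordance <- function(records, threshold = NA) {
  if (nrow(records) == 0) stop("no DE genes to summarize", call. = FALSE)
  out <- lapply(c(up = "up", down = "down"), function(dir) {
    r <- records[records$de_direction == dir, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    tab <- function(col) {
      counts <- vapply(CATEGORIES, function(cc) sum(r[[col]] == cc), numeric(1))
      data.frame(category = CATEGORIES, count = counts,
                 pct = round(100 * counts / nrow(r), 2),
                 stringsAsFactors = FALSE, row.names = NULL)
    }
    list(de_direction = dir, threshold = threshold, n_genes = nrow(r),
         chip = tab("chip_category"), meth = tab("meth_category"),
         overlap_both_marks = sum(r$chip_status != "none" & r$meth_status != "none"))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' ERG dysregulation counts
#'
#' @param de Data frame from [call_de()].
#' @param erg_set Character vector of estrogen-responsive gene ids.
#' @return List `n_up, n_down, n_total` over ERGs with a DE direction;
#'   set members absent from the DE table count as not detected.
#' @export
erg_summary <- function(de, erg_set) {
  if (length(erg_set) == 0) stop("empty ERG set", call. = FALSE)
  missing <- setdiff(erg_set, de$gene_id)
  if (length(missing) > 0)
    message(length(missing), " ERG(s) not in the DE table (not detected)")
  d <- de[de$gene_id %in% erg_set, , drop = FALSE]
  n_up <- sum(d$direction == "up")
  n_down <- sum(d$direction == "down")
  list(n_up = n_up, n_down = n_down, n_total = n_up + n_down)
}

#' Hypergeometric over-representation test
#'
#' With a universe of `N` genes containing a set of size `K`, the chance of
#' seeing `k` or more set members in a list of size `n` is the upper
#' hypergeometric tail `P(X >= k)`. Genes outside the universe are clipped
#' with a message.
#'
#' @param gene_list Character vector (the experimentally derived list).
#' @param gene_set Character vector (e.g. a pathway).
#' @param universe Character vector of all considered genes.
#' @return List `N, n, K, k, p, enrichment` (`enrichment =
#'   (k/n)/(K/N)`).
#' @export
ora_hypergeom <- function(gene_list, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  drop_l <- setdiff(gene_list, universe)
  drop_s <- setdiff(gene_set, universe)
  if (length(drop_l) + length(drop_s) > 0)
    message("clipping ", length(drop_l) + length(drop_s),
            " gene(s) outside the universe")
  gene_list <- intersect(unique(gene_list), universe)
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(universe)
  n <- length(gene_list)
  K <- length(gene_set)
  k <- length(intersect(gene_list, gene_set))
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  enr <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
  list(N = N, n = n, K = K, k = k, p = p, enrichment = enr)
}

#' Fisher association between DE direction and a mark
#'
#' Builds the 2x2 table of DE direction (up/down) by mark presence and
#' delegates to [fisher_exact_2x2()].
#'
#' @param de_flags Logical: TRUE = up, FALSE = down, per gene.
#' @param mark_flags Logical: mark present, same genes.
#' @return List `odds_ratio, p, flagged`.
#' @export
integration_fisher <- function(de_flags, mark_flags) {
  stopifnot(length(de_flags) == length(mark_flags))
  if (length(de_flags) == 0) stop("empty gene universe", call. = FALSE)
  tab <- rbind(c(sum(de_flags & mark_flags), sum(de_flags & !mark_flags)),
               c(sum(!de_flags & mark_flags), sum(!de_flags & !mark_flags)))
  fisher_exact_2x2(tab)
}

#' Run the full tri-omics pipeline on a synthetic dataset
#'
#' Simulates the dataset from the config, then runs differential
#' expression, windowed differential H3K4me3 with TSS annotation and gene
#' mark status, chromatin-state segmentation with odds-ratio enrichment,
#' genome-wide CpG differential methylation with per-gene status at every
#' configured threshold, and the concordance integration. All declared
#' outputs are written under `outdir`; reruns with the same config are
#' byte-identical.
#'
#' @param config Configuration list from [load_config()] /
#'   [default_config()].
#' @param outdir Output directory (created).
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config_echo(config, outdir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- stage("synthio", {
    sc <- do.call(sim_config, c(config$synth, config$genome, list(seed = config$seed)))
    ds <- simulate_dataset(sc)
    write_tsv(ds$truth, file.path(outdir, "truth.tsv"))
    write_counts(ds$rna, file.path(outdir, "counts.tsv"))
    write_bedgraph(ds$chip, "VEH", file.path(outdir, "chip_veh.bedgraph"))
    write_bedgraph(ds$chip, "EDC", file.path(outdir, "chip_edc.bedgraph"))
    write_tsv(ds$cpg[c("chrom", "pos", "meth_veh", "total_veh",
                       "meth_edc", "total_edc")],
              file.path(outdir, "cpg_counts.tsv"))
    ds
  })

  de <- stage("diffexpr", {
    cm <- filter_detected(sim$rna, config$diffexpr$min_total)
    res <- call_de(de_test(cm, config$diffexpr$dispersion),
                   fc_cut = config$diffexpr$fc_cut,
                   fdr_cut = config$diffexpr$fdr_cut)
    write_tsv(res[c("gene_id", "log2fc", "p", "q", "direction")],
              file.path(outdir, "de.tsv"))
    res
  })

  chip <- stage("diffchip", {
    regions <- scan_windows(sim$chip, fc_cut = config$diffchip$fc_cut,
                            fdr_cut = config$diffchip$fdr_cut)
    write_diff_regions(regions, file.path(outdir, "diff_regions.bed"))
    tss_map <- annotate_tss(regions, sim$genes, config$diffchip$tss_dist)
    write_tsv(tss_map, file.path(outdir, "tss_annotation.tsv"))
    mark <- gene_mark_status(sim$genes, regions, sim$genome,
                             flank = config$diffchip$flank)
    write_tsv(mark, file.path(outdir, "gene_mark_status.tsv"))
    list(regions = regions, mark = mark)
  })

  cs <- stage("chromstate", {
    bins <- sim$chip$windows[c("chrom", "start", "end")]
    bt <- binarize(sim$chip$windows$count_veh, bins, config$chromstate$p_cut)
    model <- fit_hmm(bt, n_states = config$chromstate$n_states,
                     seed = config$seed,
                     n_restarts = config$chromstate$n_restarts,
                     tol = config$chromstate$tol,
                     max_iter = config$chromstate$max_iter)
    path <- decode(model, bt)
    write_states_bed(path, bt, file.path(outdir, "states.bed"))
    write_hmm_tsv(model, file.path(outdir, "hmm_model.tsv"))
    enr <- state_enrichment(path, bt, chip$regions)
    write_tsv(enr, file.path(outdir, "state_enrichment.tsv"))
    list(model = model, path = path, enrichment = enr)
  })

  stage("panels", {
    panel_file <- system.file("extdata", "erg_panels_synthetic.tsv",
                              package = "fibroprog")
    panels <- read_panels(panel_file)
    for (g in unique(panels$gene)) {
      pd <- panels[panels$gene == g, , drop = FALSE]
      ps <- simulate_panel(pd, rep(-0.25, nrow(pd)), coverage = 500,
                           seed = config$seed + match(g, unique(panels$gene)))
      rpt <- summarize_panel(pd, ps, site_p = config$methylome$site_p,
                             min_cov = config$methylome$min_cov)
      out <- rpt$sites[c("chrom", "pos", "meth_veh", "total_veh", "meth_edc",
                         "total_edc", "pct_veh", "pct_edc", "delta", "p", "call")]
      write_tsv(out, file.path(outdir, "panels", paste0(g, ".tsv")))
    }
    invisible(NULL)
  })

  meth <- stage("methylome", {
    sites <- site_differential(sim$cpg, min_cov = config$methylome$min_cov,
                               floor = config$methylome$pct_floor)
    write_tsv(sites[c("chrom", "pos", "meth_veh", "total_veh", "meth_edc",
                      "total_edc", "pct_veh", "pct_edc", "delta", "p")],
              file.path(outdir, "cpg_differential.tsv"))
    status <- lapply(config$methylome$thresholds, function(t)
      gene_meth_status_all(sites, sim$genes, t))
    names(status) <- paste0("t", round(100 * config$methylome$thresholds))
    list(sites = sites, status = status)
  })

  summary <- stage("integrate", {
    erg <- erg_summary(de, genes_in_set(sim$genes, c("ERG_early", "ERG_late")))
    conc <- list()
    for (tn in names(meth$status)) {
      records <- concordance_records(de, chip$mark, meth$status[[tn]])
      for (dir in c("up", "down")) {
        r <- records[records$de_direction == dir, , drop = FALSE]
        write_tsv(r, file.path(outdir, sprintf("concordance_%s_%s.tsv",
                                               dir, sub("^t", "", tn))))
      }
      conc[[tn]] <- if (nrow(records) > 0)
        summarize_concordance(records, threshold = tn) else list()
    }
    de_dirs <- de$direction[de$direction %in% c("up", "down")]
    de_ids <- de$gene_id[de$direction %in% c("up", "down")]
    mark_present <- chip$mark$status[match(de_ids, chip$mark$gene_id)] != "none"
    fisher_chip <- if (length(de_ids) > 0)
      integration_fisher(de_dirs == "up", mark_present) else NULL
    s <- list(
      seed = config$seed,
      n_genes = nrow(sim$genes),
      n_genes_detected = sum(rowSums(sim$rna$counts) >= config$diffexpr$min_total),
      n_de_up = sum(de$direction == "up"),
      n_de_down = sum(de$direction == "down"),
      erg = erg,
      n_diff_regions = nrow(chip$regions),
      n_regions_enriched = sum(chip$regions$direction == "enriched"),
      n_regions_reduced = sum(chip$regions$direction == "reduced"),
      n_cpg_analyzable = sum(meth$sites$analyzable),
      chip_de_fisher = fisher_chip,
      concordance = lapply(conc, function(th) lapply(th, function(dd) list(
        n_genes = dd$n_genes,
        chip_pct = as.list(setNames(dd$chip$pct, dd$chip$category)),
        meth_pct = as.list(setNames(dd$meth$pct, dd$meth$category)),
        overlap_both_marks = dd$overlap_both_marks))))
    write_summary_json(s, file.path(outdir, "summary.json"))
    s
  })
  invisible(summary)
}
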