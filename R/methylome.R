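# Per-CpG methylation quantification, differential calls at the 10/33/50
# percentage-point thresholds, targeted-panel summaries, and the study's
# statistical tests (paired Wilcoxon signed-rank, Fisher's exact).
#
# A site is analyzable only with >= 5x coverage in both conditions; deltas
# are EDC - VEH, so hypo-methylation in EDC is negative.

#' Percent methylation at a site
#'
#' `meth / total`, with frequencies below the variant-calling floor
#' (default 0.1%) reported as 0 — sub-threshold variants are not called.
#'
#' @param meth,total Methylated and total read counts (vectorised).
#' @param floor Minimum reportable methylation fraction (default 0.001).
#' @return Fractions in \[0, 1\]; `NA` where `total` is 0 (site dropped).
#' @export
meth_pct <- function(meth, total, floor = 0.001) {
  stopifnot(all(meth <= total, na.rm = TRUE), all(meth >= 0, na.rm = TRUE))
  pct <- ifelse(total > 0, meth / total, NA_real_)
  pct[!is.na(pct) & pct > 0 & pct < floor] <- 0
  pct
}

#' Mark sites analyzable under the coverage rule
#'
#' @param sites CpG data frame with `total_veh`, `total_edc`.
#' @param min_cov Minimum coverage in both conditions (default 5).
#' @return Logical vector.
#' @export
is_analyzable <- function(sites, min_cov = 5) {
  sites$total_veh >= min_cov & sites$total_edc >= min_cov
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric test: the two-sided p sums the probabilities
#' of all tables (at fixed margins) no more likely than the observed one,
#' with a 1e-7 relative slack on the comparison. The odds ratio is the
#' sample `(a d)/(b c)` with zero cells replaced by 0.5 (Haldane).
#'
#' @param tab 2x2 matrix of non-negative integers
#'   `rbind(c(a, b), c(c, d))`.
#' @return List `odds_ratio, p, flagged` (`flagged` when a margin is zero,
#'   in which case `p = 1`).
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  h <- function(v) ifelse(v == 0, 0.5, v)
  or <- (h(a) * h(d)) / (h(b) * h(c))
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n)
    return(list(odds_ratio = or, p = 1, flagged = TRUE))
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p = p, flagged = FALSE)
}

# vectorised Fisher p over many sites (same enumeration as fisher_exact_2x2)
fisher_p_vec <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) {
    fisher_exact_2x2(rbind(c(a[i], b[i]), c(c[i], d[i])))$p
  }, numeric(1))
}

#' Per-site differential methylation
#'
#' Delta is `pct_edc - pct_veh` (EDC lower = negative = hypo direction);
#' p is the two-sided Fisher exact test on methylated/unmethylated counts
#' by condition. Only analyzable sites (>= `min_cov` in both conditions)
#' are tested.
#'
#' @param sites CpG data frame (`meth_veh, total_veh, meth_edc, total_edc`).
#' @param min_cov Coverage rule (default 5).
#' @param floor Variant-frequency floor passed to [meth_pct()].
#' @return `sites` with added `pct_veh, pct_edc, delta, p, analyzable`.
#' @export
site_differential <- function(sites, min_cov = 5, floor = 0.001) {
  sites$analyzable <- is_analyzable(sites, min_cov)
  sites$pct_veh <- meth_pct(sites$meth_veh, sites$total_veh, floor)
  sites$pct_edc <- meth_pct(sites$meth_edc, sites$total_edc, floor)
  sites$delta <- sites$pct_edc - sites$pct_veh
  sites$p <- NA_real_
  ok <- sites$analyzable
  if (any(ok)) {
    sites$p[ok] <- fisher_p_vec(
      sites$meth_edc[ok], sites$total_edc[ok] - sites$meth_edc[ok],
      sites$meth_veh[ok], sites$total_veh[ok] - sites$meth_veh[ok])
  }
  sites$delta[!ok] <- NA_real_
  sites
}

#' Methylation status of a gene's promoter at a threshold
#'
#' Any-site rule over the analyzable promoter CpGs: `hypo` when at least
#' one site drops by `threshold` or more and none rises as much; `hyper`
#' symmetric; `mixed` when both occur; `none` otherwise (including no
#' analyzable sites).
#'
#' @param deltas Per-site EDC - VEH deltas (NAs ignored).
#' @param threshold Absolute delta threshold, e.g. 0.33.
#' @return List `status` (`hypo`/`hyper`/`mixed`/`none`) and `n_sites`.
#' @export
gene_meth_status <- function(deltas, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  d <- deltas[!is.na(deltas)]
  lo <- any(d <= -threshold)
  hi <- any(d >= threshold)
  status <- if (lo && hi) "mixed" else if (lo) "hypo" else if (hi) "hyper" else "none"
  list(status = status, n_sites = length(d))
}

#' Methylation status for every gene at one threshold
#'
#' @param sites Output of [site_differential()] carrying a `gene_id` column
#'   (see [map_sites_to_promoters()] to attach one).
#' @param genes Gene models (genes without sites get status `none`).
#' @param threshold Absolute delta threshold.
#' @return Data frame `gene_id, threshold, status, n_sites`.
#' @export
gene_meth_status_all <- function(sites, genes, threshold) {
  by_gene <- split(sites$delta, factor(sites$gene_id, levels = genes$gene_id))
  st <- lapply(by_gene, gene_meth_status, threshold = threshold)
  data.frame(gene_id = genes$gene_id,
             threshold = threshold,
             status = vapply(st, `[[`, character(1), "status"),
             n_sites = vapply(st, `[[`, numeric(1), "n_sites"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attach promoter gene ids to CpG sites by position
#'
#' A site belongs to a gene when it falls within TSS +/- `flank`.
#' Sites outside every promoter are dropped.
#'
#' @param sites CpG data frame with `chrom, pos`.
#' @param genes Gene models.
#' @param flank Promoter half-width in bp (default 1000).
#' @return `sites` with a `gene_id` column.
#' @export
map_sites_to_promoters <- function(sites, genes, flank = 1000) {
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - flank),
                     end = genes$tss + flank + 1)
  pts <- data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1)
  ov <- GenomicRanges::findOverlaps(as_granges0(pts), as_granges0(prom))
  out <- sites[S4Vectors::queryHits(ov), , drop = FALSE]
  out$gene_id <- genes$gene_id[S4Vectors::subjectHits(ov)]
  rownames(out) <- NULL
  out
}

#' Read a targeted-panel definition TSV
#'
#' Columns `gene, chrom, pos`; positions must be strictly increasing
#' within each panel.
#'
#' @param path Panel TSV.
#' @return Data frame `gene, chrom, pos`.
#' @export
read_panels <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "chrom", "pos") %in% names(df)))
  bad <- vapply(split(df$pos, df$gene), function(p) any(diff(p) <= 0), logical(1))
  if (any(bad))
    stop("panel positions not strictly increasing: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  df
}

#' Summarize a targeted bisulfite panel
#'
#' Per-site percent methylation in both conditions, delta, and a
#' hypo/hyper call (Fisher `p < site_p` with a nonzero delta of the
#' corresponding sign); reports `n_hypo`, `n_hyper`, the percent of panel
#' sites hypo-methylated (one decimal, denominator = full panel size) and
#' a paired Wilcoxon signed-rank test across sites. Panel positions with
#' no site data are excluded and listed in `missing`.
#'
#' @param panel Panel definition for one gene (`gene, chrom, pos`).
#' @param sites CpG count data covering the panel positions.
#' @param site_p Per-site significance cutoff (default 0.05).
#' @param min_cov Coverage rule (default 5).
#' @return List `gene, sites` (per-site report), `n_hypo, n_hyper,
#'   panel_size, pct_hypo, wilcoxon_W, wilcoxon_p, missing`.
#' @export
summarize_panel <- function(panel, sites, site_p = 0.05, min_cov = 5) {
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(panel$chrom, panel$pos), key)
  missing <- panel$pos[is.na(idx)]
  hit <- sites[idx[!is.na(idx)], , drop = FALSE]
  report <- site_differential(hit, min_cov = min_cov)
  called <- !is.na(report$p) & report$p < site_p & report$delta != 0
  report$call <- ifelse(called & report$delta < 0, "hypo",
                        ifelse(called & report$delta > 0, "hyper", "ns"))
  n_hypo <- sum(report$call == "hypo")
  n_hyper <- sum(report$call == "hyper")
  wx <- if (nrow(report) > 0)
    wilcoxon_paired(report$pct_edc, report$pct_veh) else list(W = NA, p = NA)
  list(gene = panel$gene[1],
       sites = report,
       n_hypo = n_hypo, n_hyper = n_hyper,
       panel_size = nrow(panel),
       pct_hypo = round(100 * n_hypo / nrow(panel), 1),
       wilcoxon_W = wx$W, wilcoxon_p = wx$p,
       missing = missing)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences get midranks under
#' ties; `W` is the sum of positive-difference ranks. The two-sided p is
#' exact for n <= 25 — the null distribution of `W` is built by
#' generating-function convolution over the (doubled, hence integer)
#' midranks, which enumerates all 2^n sign patterns — and a tie-corrected
#' normal approximation with continuity correction beyond.
#'
#' @param x,y Paired numeric vectors (e.g. per-site EDC and VEH levels).
#' @return List `W, p`. All-zero differences give `W = 0, p = 1`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r)) # doubled midranks are integers
    # polynomial prod (1 + z^r2) / 2^n over W2 = 0..sum(r2)
    dist <- c(1, numeric(sum(r2)))
    for (rr in r2) {
      shifted <- c(numeric(rr), dist[seq_len(length(dist) - rr)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- round(2 * w)
    lo <- sum(dist[seq_len(w2 + 1)])            # P(W2 <= w2)
    hi <- sum(dist[(w2 + 1):length(dist)])      # P(W2 >= w2)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(W = w, p = p)
}
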