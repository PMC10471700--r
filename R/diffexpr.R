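# Differential expression on gene counts at the study cutoffs
# (twofold, FDR < 0.05), implemented in-repo.
#
# With a single pooled library per condition the test is the exact
# conditional binomial: given a gene's total t = a + b, the EDC count a is
# Binomial(t, N_EDC / (N_EDC + N_VEH)) under the null. With replicates a
# per-gene negative-binomial likelihood-ratio test at fixed dispersion is
# used instead.

#' Count matrix container
#'
#' @param counts Integer matrix, genes x samples, rownames = gene ids.
#' @param condition Character/factor per column, values `VEH` or `EDC`.
#' @return A `CountMatrix` list: `counts`, `condition`, `lib_sizes`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(ncol(counts) == length(condition))
  if (!all(condition %in% c("VEH", "EDC")))
    stop("condition labels must be 'VEH' or 'EDC'", call. = FALSE)
  if (!all(c("VEH", "EDC") %in% condition))
    stop("need at least one sample per condition", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames", call. = FALSE)
  structure(list(counts = counts, condition = condition,
                 lib_sizes = colSums(counts)),
            class = "CountMatrix")
}

#' Drop undetected genes
#'
#' Keeps genes whose summed count across all samples reaches `min_total`.
#'
#' @param cm A [count_matrix()].
#' @param min_total Minimum summed count (default 10).
#' @return Filtered `CountMatrix`. Library sizes are kept from the full
#'   matrix: depth is a property of the library, not of the retained genes.
#' @export
filter_detected <- function(cm, min_total = 10) {
  stopifnot(min_total >= 0)
  keep <- rowSums(cm$counts) >= min_total
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out
}

#' Per-gene differential test, EDC versus VEH
#'
#' Unreplicated design: exact conditional binomial per gene, two-sided p by
#' summing the probabilities of outcomes no more likely than the observed
#' one. Replicated design: negative-binomial likelihood-ratio test at the
#' given fixed dispersion (`Var = mu + dispersion * mu^2`), with log
#' library-size offsets. In both cases
#' `log2fc = log2((a + 0.5) / N_EDC) - log2((b + 0.5) / N_VEH)` on summed
#' counts and summed library sizes.
#'
#' @param cm A [count_matrix()] (filter first with [filter_detected()]).
#' @param dispersion Fixed NB dispersion for the replicated test.
#' @return Data frame `gene_id, log2fc, p`.
#' @export
de_test <- function(cm, dispersion = 0.01) {
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (any(cm$lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  edc <- cm$condition == "EDC"
  a <- rowSums(cm$counts[, edc, drop = FALSE])
  b <- rowSums(cm$counts[, !edc, drop = FALSE])
  n_edc <- sum(cm$lib_sizes[edc])
  n_veh <- sum(cm$lib_sizes[!edc])
  log2fc <- log2((a + 0.5) / n_edc) - log2((b + 0.5) / n_veh)
  replicated <- sum(edc) > 1 && sum(!edc) > 1
  if (!replicated) {
    p0 <- n_edc / (n_edc + n_veh)
    p <- vapply(seq_along(a), function(i) {
      t <- a[i] + b[i]
      if (t == 0) return(1)
      binom.test(a[i], t, p = p0)$p.value
    }, numeric(1))
  } else {
    p <- nb_lrt(cm$counts, edc, cm$lib_sizes, dispersion)
  }
  data.frame(gene_id = rownames(cm$counts), log2fc = unname(log2fc),
             p = pmin(1, unname(p)), stringsAsFactors = FALSE)
}

# NB likelihood-ratio p-values at fixed dispersion via glm with a
# negative.binomial family (theta = 1/dispersion); dispersion 0 falls back
# to Poisson.
nb_lrt <- function(counts, edc, lib_sizes, dispersion) {
  fam <- if (dispersion < 1e-12) stats::poisson()
         else MASS::negative.binomial(theta = 1 / dispersion)
  cond <- factor(ifelse(edc, "EDC", "VEH"), levels = c("VEH", "EDC"))
  off <- log(lib_sizes)
  apply(counts, 1, function(y) {
    fit1 <- try(glm(y ~ cond + offset(off), family = fam), silent = TRUE)
    fit0 <- try(glm(y ~ 1 + offset(off), family = fam), silent = TRUE)
    if (inherits(fit1, "try-error") || inherits(fit0, "try-error")) return(NA_real_)
    lr <- max(0, fit0$deviance - fit1$deviance)
    pchisq(lr, df = 1, lower.tail = FALSE)
  })
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return q-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Label genes by direction at the study cutoffs
#'
#' `up` requires `log2fc >= log2(fc_cut)` and `q < fdr_cut`; `down` is
#' symmetric; everything else is `ns`.
#'
#' @param results Data frame from [de_test()].
#' @param fc_cut Fold-change cutoff (default 2).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return `results` with added `q` and `direction` columns.
#' @export
call_de <- function(results, fc_cut = 2, fdr_cut = 0.05) {
  results$q <- bh_adjust(results$p)
  lcut <- log2(fc_cut)
  results$direction <- ifelse(
    results$log2fc >= lcut & results$q < fdr_cut, "up",
    ifelse(results$log2fc <= -lcut & results$q < fdr_cut, "down", "ns"))
  results$direction[is.na(results$direction)] <- "ns"
  results
}

#' Read a counts TSV (gene_id plus one column per sample)
#'
#' Condition is parsed from column names (`VEH_*` / `EDC_*`).
#'
#' @param path TSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  count_matrix(counts, condition = sub("_.*$", "", colnames(counts)))
}

#' Write a counts TSV
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  write_tsv(data.frame(gene_id = rownames(cm$counts), cm$counts,
                       check.names = FALSE), path)
}
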