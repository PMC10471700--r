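# diffReps-style sliding-window differential H3K4me3 enrichment.
#
# Per window a G-test on the 2x2 of (window reads, library remainder) by
# condition; BH across all testable windows; significance requires both an
# rpm fold change past 1.5x (0.5-read pseudocount) and q < 0.01; adjacent
# or overlapping significant windows of one direction merge into regions.

#' Window track container
#'
#' @param windows Data frame `chrom, start, end, count_veh, count_edc`
#'   (0-based half-open, tiling each chromosome in order).
#' @param window_size Window width in bp.
#' @param step Step between window starts (defaults to `window_size`,
#'   i.e. non-overlapping tiling).
#' @param genome [genome_spec()].
#' @return A `WindowTrack` list; per-condition totals are the column sums.
#' @export
window_track <- function(windows, window_size, step = window_size, genome) {
  stopifnot(all(c("chrom", "start", "end", "count_veh", "count_edc") %in% names(windows)))
  if (any(windows$count_veh < 0) || any(windows$count_edc < 0))
    stop("window counts must be non-negative", call. = FALSE)
  structure(list(windows = windows, window_size = window_size, step = step,
                 total_veh = sum(windows$count_veh),
                 total_edc = sum(windows$count_edc),
                 genome = genome),
            class = "WindowTrack")
}

#' Tile a genome with fixed-width windows
#'
#' @param genome [genome_spec()].
#' @param window_size Window width (bp).
#' @param step Step between starts (default `window_size`).
#' @return Data frame `chrom, start, end`; the last window of each
#'   chromosome is clipped to the chromosome end.
#' @export
make_windows <- function(genome, window_size, step = window_size) {
  out <- lapply(genome$chrom_names, function(ch) {
    len <- genome$chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' G-test of independence on a 2x2 count table
#'
#' Table is `[[a, Na - a], [b, Nb - b]]`; `G = 2 * sum(O * ln(O / E))` with
#' expecteds from the margins (zero cells contribute nothing), and p from
#' the chi-square distribution with 1 df. All arguments vectorise.
#'
#' @param a,b Window counts in the two conditions.
#' @param na,nb Condition totals.
#' @return List of vectors `G` and `p`. Windows with `a + b = 0` return
#'   `G = 0, p = 1` by convention.
#' @export
gtest_2x2 <- function(a, b, na, nb) {
  stopifnot(all(na > 0), all(nb > 0), all(a <= na), all(b <= nb))
  a <- as.numeric(a); b <- as.numeric(b)
  na <- as.numeric(na); nb <- as.numeric(nb)
  o <- cbind(a, na - a, b, nb - b)
  tot <- na + nb
  col1 <- a + b
  e <- cbind(na * col1 / tot, na * (tot - col1) / tot,
             nb * col1 / tot, nb * (tot - col1) / tot)
  terms <- o * log(o / e)
  terms[o == 0] <- 0
  g <- 2 * rowSums(terms)
  g <- pmax(0, g) # guard tiny negative rounding
  p <- pchisq(g, df = 1, lower.tail = FALSE)
  zero <- (a + b) == 0
  g[zero] <- 0
  p[zero] <- 1
  list(G = unname(g), p = unname(p))
}

#' Scan windows for differential enrichment and merge into regions
#'
#' Fold change is the EDC/VEH rpm ratio with a 0.5-read pseudocount;
#' G-test p-values are BH-adjusted across all windows with nonzero total.
#' A window is significant when `q < fdr_cut` and its fold change passes
#' `fc_cut` in either direction; touching significant windows of one
#' direction merge, keeping the extremal fold change, maximal G and
#' minimal p and q.
#'
#' @param track A [window_track()].
#' @param fc_cut Fold-change cutoff (default 1.5).
#' @param fdr_cut FDR cutoff (default 0.01).
#' @return Data frame of regions: `region_id, chrom, start, end, direction,
#'   fold_change, G, p, q, n_windows`, ordered by chromosome then start.
#' @export
scan_windows <- function(track, fc_cut = 1.5, fdr_cut = 0.01) {
  w <- track$windows
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = character(), fold_change = numeric(),
                      G = numeric(), p = numeric(), q = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (nrow(w) == 0) return(empty)
  testable <- (w$count_veh + w$count_edc) > 0
  w <- w[testable, , drop = FALSE]
  if (nrow(w) == 0) return(empty)
  na <- track$total_edc
  nb <- track$total_veh
  fc <- ((w$count_edc + 0.5) / na) / ((w$count_veh + 0.5) / nb)
  gt <- gtest_2x2(w$count_edc, w$count_veh, na, nb)
  q <- bh_adjust(gt$p)
  sig <- q < fdr_cut & (fc >= fc_cut | fc <= 1 / fc_cut)
  if (!any(sig)) return(empty)
  s <- data.frame(chrom = w$chrom[sig], start = w$start[sig], end = w$end[sig],
                  direction = ifelse(fc[sig] > 1, "enriched", "reduced"),
                  fold_change = fc[sig], G = gt$G[sig], p = gt$p[sig],
                  q = q[sig], stringsAsFactors = FALSE)
  merge_sig_windows(s)
}

# merge touching/overlapping significant windows of one direction
merge_sig_windows <- function(s) {
  s <- s[order(s$chrom, s$start, s$end), , drop = FALSE]
  out <- list()
  for (dir in c("enriched", "reduced")) {
    d <- s[s$direction == dir, , drop = FALSE]
    if (nrow(d) == 0) next
    grp <- integer(nrow(d))
    g <- 1L
    grp[1] <- g
    cur_end <- d$end[1]
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      touch <- d$chrom[i] == d$chrom[i - 1L] && d$start[i] <= cur_end
      if (!touch) {
        g <- g + 1L
        cur_end <- d$end[i]
      } else cur_end <- max(cur_end, d$end[i])
      grp[i] <- g
    }
    ext <- if (dir == "enriched") max else min
    m <- do.call(rbind, lapply(split(d, grp), function(x) data.frame(
      chrom = x$chrom[1], start = min(x$start), end = max(x$end),
      direction = dir, fold_change = ext(x$fold_change), G = max(x$G),
      p = min(x$p), q = min(x$q), n_windows = nrow(x),
      stringsAsFactors = FALSE)))
    out[[dir]] <- m
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  res <- cbind(region_id = paste0("dr", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Annotate differential regions to nearby TSSs
#'
#' A region annotates every gene whose TSS lies within `max_dist` bp of it
#' ([distance_to_tss()]); one region may annotate several genes.
#'
#' @param regions Region data frame from [scan_windows()].
#' @param genes Gene models.
#' @param max_dist Maximum TSS distance in bp (default 3000).
#' @return Data frame `gene_id, region_id, distance, direction`.
#' @export
annotate_tss <- function(regions, genes, max_dist = 3000) {
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    d <- distance_to_tss(regions$chrom, regions$start, regions$end,
                         genes$chrom[i], genes$tss[i])
    j <- which(d <= max_dist)
    if (length(j) == 0) return(NULL)
    data.frame(gene_id = genes$gene_id[i], region_id = regions$region_id[j],
               distance = d[j], direction = regions$direction[j],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(gene_id = character(), region_id = character(),
                       distance = numeric(), direction = character(),
                       stringsAsFactors = FALSE)
  hits
}

#' H3K4me3 mark status per gene
#'
#' Intersects each gene body plus a `flank` window (default 10 kb) with the
#' significant differential regions: `enriched` / `reduced` when only one
#' direction overlaps, `both` when regions of both directions fall in the
#' window, `none` otherwise.
#'
#' @param genes Gene models.
#' @param regions Region data frame from [scan_windows()].
#' @param genome [genome_spec()].
#' @param flank Flank in bp (default 10000).
#' @return Data frame `gene_id, status, region_ids`.
#' @export
gene_mark_status <- function(genes, regions, genome, flank = 10000) {
  win <- gene_window(genes, flank, genome)
  status <- rep("none", nrow(genes))
  region_ids <- rep("", nrow(genes))
  if (nrow(regions) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(win), as_granges0(regions))
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    for (i in unique(qi)) {
      dirs <- unique(regions$direction[si[qi == i]])
      status[i] <- if (length(dirs) == 2) "both" else dirs
      region_ids[i] <- paste(regions$region_id[si[qi == i]], collapse = ",")
    }
  }
  data.frame(gene_id = genes$gene_id, status = status,
             region_ids = region_ids, stringsAsFactors = FALSE)
}

#' Write differential regions as BED6+
#'
#' Name holds the direction, score `-10 log10(q)` capped at 1000, then
#' `fold_change, G, p, q` as extra columns.
#'
#' @param regions Region data frame from [scan_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_regions <- function(regions, path) {
  score <- pmin(1000, round(-10 * log10(pmax(regions$q, 1e-100)), 2))
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end, name = regions$direction,
                   score = score, strand = rep(".", nrow(regions)),
                   fold_change = signif(regions$fold_change, 6),
                   G = signif(regions$G, 6), p = signif(regions$p, 6),
                   q = signif(regions$q, 6), stringsAsFactors = FALSE)
  write_bed(df, path)
}

#' Read a fixed-bin bedGraph pair into a window track
#'
#' @param path_veh,path_edc bedGraph files with identical bins.
#' @param genome [genome_spec()].
#' @return A [window_track()].
#' @export
read_bedgraph_pair <- function(path_veh, path_edc, genome) {
  rd <- function(p) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1,
               end = BiocGenerics::end(gr),
               value = S4Vectors::mcols(gr)$score, stringsAsFactors = FALSE)
  }
  v <- rd(path_veh)
  e <- rd(path_edc)
  if (!identical(v[c("chrom", "start", "end")], e[c("chrom", "start", "end")]))
    stop("bedGraph bins differ between conditions", call. = FALSE)
  wins <- v[c("chrom", "start", "end")]
  wins$count_veh <- v$value
  wins$count_edc <- e$value
  window_track(wins, window_size = max(v$end - v$start), genome = genome)
}

#' Write one condition of a window track as bedGraph
#'
#' @param track A [window_track()].
#' @param condition `"VEH"` or `"EDC"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, condition, path) {
  col <- if (condition == "VEH") "count_veh" else "count_edc"
  df <- track$windows
  out <- data.frame(df$chrom, format_bp(df$start), format_bp(df$end), df[[col]])
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
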