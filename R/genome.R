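# Genomic coordinate model shared by all stages.
#
# Every coordinate inside the package is 0-based half-open (BED convention);
# GTF's 1-based inclusive coordinates are converted at the boundary. Strand
# affects only TSS placement, never counting.

#' Genome specification
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Positive integer lengths (bp), same order.
#' @return A `GenomeSpec` list with `chrom_names` and `chrom_lengths`
#'   (named by chromosome).
#' @export
genome_spec <- function(chrom_names, chrom_lengths) {
  stopifnot(length(chrom_names) == length(chrom_lengths))
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique", call. = FALSE)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = setNames(as.numeric(chrom_lengths), chrom_names)),
    class = "GenomeSpec")
}

#' Construct a table of gene models
#'
#' The TSS is `start` on the + strand and `end - 1` on the - strand
#' (0-based). `gene_sets` holds comma-separated set memberships (for
#' example `"ERG_early"`); empty string means none.
#'
#' @param gene_id Unique identifiers.
#' @param chrom,start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param gene_sets Comma-separated set names per gene (default none).
#' @param genome Optional [genome_spec()] used to validate coordinates.
#' @return Data frame with columns `gene_id, chrom, start, end, strand,
#'   tss, gene_sets`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        gene_sets = "", genome = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique", call. = FALSE)
  if (any(end <= start)) stop("gene end must exceed start", call. = FALSE)
  if (any(start < 0)) stop("gene start must be >= 0", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (!is.null(genome)) {
    if (!all(chrom %in% genome$chrom_names))
      stop("gene chromosome absent from genome", call. = FALSE)
    if (any(end > genome$chrom_lengths[chrom]))
      stop("gene end exceeds chromosome length", call. = FALSE)
  }
  data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = strand,
    tss = ifelse(strand == "+", as.numeric(start), as.numeric(end) - 1),
    gene_sets = rep_len(as.character(gene_sets), length(gene_id)),
    stringsAsFactors = FALSE)
}

#' Genes belonging to one or more gene sets
#'
#' @param genes Gene-model data frame.
#' @param sets Character vector of set names; a gene matches if it belongs
#'   to any of them.
#' @return Character vector of gene ids.
#' @export
genes_in_set <- function(genes, sets) {
  membership <- strsplit(genes$gene_sets, ",", fixed = TRUE)
  hit <- vapply(membership, function(m) any(m %in% sets), logical(1))
  genes$gene_id[hit]
}

#' Read gene annotations from BED or GTF
#'
#' BED (4 or 6 columns) is read as-is (already 0-based half-open); GTF is
#' restricted to `gene` features and converted from 1-based inclusive to
#' 0-based half-open. Format is chosen by file extension (`.bed` versus
#' `.gtf`/`.gff`). An empty file yields an empty table with a warning.
#'
#' @param path Annotation file.
#' @param genome Optional [genome_spec()] for coordinate validation.
#' @return Gene-model data frame as from [gene_models()].
#' @export
read_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (length(readLines(path, n = 1L)) == 0L) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(gene_models(character(), character(), numeric(), numeric(), character()))
  }
  gr <- tryCatch({
    if (ext == "bed") {
      rtracklayer::import(path, format = "BED")
    } else if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
      g <- rtracklayer::import(path, format = "GFF")
      g[S4Vectors::mcols(g)$type == "gene"]
    } else stop("unsupported annotation format: .", ext, call. = FALSE)
  }, error = function(e) {
    stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids) || anyNA(ids)) ids <- paste0("feature_", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  gene_models(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1, # back to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    genome = genome)
}

#' Write regions as BED
#'
#' Internal 0-based half-open coordinates are BED-native, so intervals
#' round-trip bit-exactly through [read_annotation()].
#'
#' @param df Data frame with `chrom, start, end` and optionally
#'   `name, score, strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  n <- nrow(df)
  name <- if ("name" %in% names(df)) df$name else rep(".", n)
  score <- if ("score" %in% names(df)) df$score else rep(0, n)
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", n)
  out <- data.frame(df$chrom, format_bp(df$start), format_bp(df$end),
                    name, score, strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "name", "score", "strand"))
  for (e in extra) out[[e]] <- df[[e]]
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Distance from a region to a gene's TSS
#'
#' Zero when the TSS lies inside the region; otherwise the distance from the
#' region edge nearest the TSS, `min(|start - tss|, |end - 1 - tss|)`.
#' Regions on a different chromosome are infinitely far away.
#'
#' @param chrom,start,end Region coordinates (vectorised, 0-based half-open).
#' @param tss_chrom,tss TSS position.
#' @return Numeric distances in bp (`Inf` across chromosomes).
#' @export
distance_to_tss <- function(chrom, start, end, tss_chrom, tss) {
  d <- pmin(abs(start - tss), abs(end - 1 - tss))
  d[tss >= start & tss < end] <- 0
  d[chrom != tss_chrom] <- Inf
  d
}

#' Gene body plus symmetric flank, clipped to the chromosome
#'
#' @param genes Gene-model data frame.
#' @param flank Flank size in bp (>= 0).
#' @param genome [genome_spec()] providing chromosome lengths.
#' @return Data frame `chrom, start, end, gene_id`.
#' @export
gene_window <- function(genes, flank, genome) {
  stopifnot(flank >= 0)
  data.frame(
    chrom = genes$chrom,
    start = pmax(0, genes$start - flank),
    end = pmin(unname(genome$chrom_lengths[genes$chrom]), genes$end + flank),
    gene_id = genes$gene_id,
    stringsAsFactors = FALSE)
}

# GRanges view of a 0-based half-open data frame (internal helper for
# overlap machinery; +1 start converts to Bioconductor's 1-based closed).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}
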