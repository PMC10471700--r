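# Shared configuration, seeding and file plumbing used by every stage.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every stage's defaults: the
#' study's cutoffs (twofold / FDR 0.05 for expression; 1.5x / q < 0.01 for
#' differential H3K4me3; 3 kb TSS annotation; 10 kb gene-window flank;
#' 5x bisulfite coverage in both conditions; 10/33/50 percentage-point
#' methylation thresholds) plus synthetic-generator and HMM settings.
#'
#' @return Nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(
      n_chrom = 2L,
      gene_length = 2000L,
      gene_spacing = 30000L
    ),
    synth = list(
      n_genes = 2000L,
      n_erg = 299L,
      fraction_de = 0.25,
      fraction_concordant_chip = 0.8,
      fraction_concordant_meth = 0.6,
      lfc = 1.5,
      chip_effect = 3,
      meth_delta = 0.4,
      rna_depth = 1e7,
      replicates = 1L,
      dispersion = 0.01,
      chip_background = 5,
      peak_height = 20,
      window_size = 1000L,
      promoter_flank = 1000L,
      cpg_per_gene = 14L,
      cpg_coverage = 30,
      meth_base_mean = 0.5,
      meth_base_conc = 10
    ),
    diffexpr = list(
      min_total = 10L,
      dispersion = 0.01,
      fc_cut = 2,
      fdr_cut = 0.05
    ),
    diffchip = list(
      fc_cut = 1.5,
      fdr_cut = 0.01,
      tss_dist = 3000L,
      flank = 10000L
    ),
    chromstate = list(
      n_states = 4L,
      p_cut = 1e-4,
      n_restarts = 5L,
      tol = 1e-6,
      max_iter = 500L
    ),
    methylome = list(
      min_cov = 5L,
      thresholds = c(0.10, 0.33, 0.50),
      site_p = 0.05,
      pct_floor = 0.001
    ),
    integrate = list()
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    d <- defaults[[k]]
    u <- user[[k]]
    kp <- sub("^\\.", "", paste0(path, ".", k))
    if (is.list(d)) {
      defaults[[k]] <- merge_config(d, u, kp)
    } else {
      if (!is.numeric(u) && is.numeric(d)) {
        stop("config key '", kp, "' must be numeric, got: ", deparse(u), call. = FALSE)
      }
      defaults[[k]] <- u
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys (naming the offending key path),
#' type-checks numeric fields and fills every missing value from
#' [default_config()]. An empty or absent file yields the defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
  }
  merge_config(default_config(), user)
}

#' Write the effective configuration next to the outputs
#'
#' @param config Configuration list.
#' @param outdir Output directory.
#' @return Path to the written YAML, invisibly.
#' @export
write_config_echo <- function(config, outdir) {
  p <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, p)
  invisible(p)
}

#' Derive an independent seed for a pipeline stage
#'
#' Deterministically maps `(seed, stage_name)` to a 31-bit substream seed and
#' installs it with `set.seed()`, so each stage draws from its own stream and
#' the whole pipeline is reproducible from the single master seed. The
#' derivation is a 31-bit multiplicative hash of the stage name folded into
#' the master seed; it is plain integer arithmetic, identical on every
#' platform.
#'
#' @param stage Character stage name.
#' @param seed Integer master seed.
#' @return The derived seed, invisibly (the RNG is already seeded).
#' @export
rng_for <- function(stage, seed) {
  stopifnot(is.character(stage), length(stage) == 1L,
            is.numeric(seed), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  s <- (as.double(seed) %% m * 48271 + h) %% m
  s <- as.integer(s)
  if (s <= 0L) s <- s + 1L
  set.seed(s)
  invisible(s)
}

# -- tab-separated IO: headers mandatory, '.' for missing, deterministic ----

#' Write a data frame as a TSV
#'
#' Tab-separated, mandatory header, `.` for missing values; byte-identical
#' across reruns for identical input.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a named list of headline counts as JSON
#'
#' Keys are stable across runs; numbers are written unrounded.
#'
#' @param x Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
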