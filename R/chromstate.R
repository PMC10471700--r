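# Single-mark chromatin-state segmentation: Poisson binarization of the
# H3K4me3 track, a Bernoulli-emission HMM fitted by Baum-Welch with seeded
# restarts, Viterbi decoding, and odds-ratio enrichment of differential
# regions per state computed from cumulative genome-wide state sizes.

#' Binarize a count track against the genome-wide background
#'
#' The background rate is the mean count per bin; a bin is called present
#' (1) when its count's Poisson upper tail `P(X >= c)` at that rate falls
#' below `p_cut`.
#'
#' @param counts Integer counts per bin (one condition).
#' @param bins Data frame `chrom, start, end` aligned with `counts`.
#' @param p_cut Poisson tail cutoff (default 1e-4).
#' @return A `BinaryTrack` list: `bins`, `x` (0/1 per bin), `threshold`
#'   (the smallest count called 1), `lambda`.
#' @export
binarize <- function(counts, bins, p_cut = 1e-4) {
  stopifnot(all(counts >= 0), nrow(bins) == length(counts))
  lambda <- mean(counts)
  if (lambda == 0) {
    warning("all-zero track: binarization yields all zeros", call. = FALSE)
    thr <- Inf
  } else {
    # smallest c with P(X >= c) < p_cut; tail(c) = ppois(c - 1, lower = FALSE)
    thr <- qpois(p_cut, lambda, lower.tail = FALSE) + 1
    while (ppois(thr - 1, lambda, lower.tail = FALSE) >= p_cut)
      thr <- thr + 1
    while (thr > 0 && ppois(thr - 2, lambda, lower.tail = FALSE) < p_cut)
      thr <- thr - 1
  }
  structure(list(bins = bins, x = as.integer(counts >= thr),
                 threshold = thr, lambda = lambda),
            class = "BinaryTrack")
}

#' Fit a Bernoulli-emission HMM by Baum-Welch
#'
#' Scaled forward-backward recursions (log-likelihood accumulated from the
#' scaling constants, so genome-length tracks cannot underflow); several
#' random restarts drawn from a single seeded stream; the best-likelihood
#' model is returned with states relabelled in decreasing emission order,
#' so state 1 is always the most signal-rich.
#'
#' @param binary A [binarize()] track.
#' @param n_states Number of states (default 4).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Random restarts (default 5).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap (default 500).
#' @return An `HMMModel` list: `n_states, pi, A, e, loglik, trace`.
#' @export
fit_hmm <- function(binary, n_states = 4, seed = 1, n_restarts = 5,
                    tol = 1e-6, max_iter = 500) {
  x <- binary$x
  if (n_states < 1) stop("n_states must be >= 1", call. = FALSE)
  if (n_states > length(x))
    stop("n_states exceeds the number of bins", call. = FALSE)
  rng_for("fit_hmm", seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    e0 <- runif(n_states, 0.05, 0.95)
    pi0 <- rgamma(n_states, 1)
    pi0 <- pi0 / sum(pi0)
    A0 <- matrix(rgamma(n_states^2, 1), n_states) + diag(5, n_states)
    A0 <- A0 / rowSums(A0)
    fit <- hmm_baum_welch_cpp(x, pi0, A0, e0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$e, decreasing = TRUE)
  structure(list(n_states = n_states,
                 pi = best$pi[ord],
                 A = best$A[ord, ord, drop = FALSE],
                 e = best$e[ord],
                 loglik = best$loglik,
                 trace = best$trace),
            class = "HMMModel")
}

#' Total log-likelihood of a binary track under a model
#'
#' @param model An [fit_hmm()] model.
#' @param binary A [binarize()] track.
#' @param method `"forward"` or `"backward"` recursion (they agree to
#'   numerical precision; both are exposed for verification).
#' @return Log-likelihood.
#' @export
hmm_loglik <- function(model, binary, method = c("forward", "backward")) {
  method <- match.arg(method)
  A <- matrix(as.numeric(model$A), model$n_states)
  if (method == "forward")
    hmm_forward_cpp(binary$x, model$pi, A, model$e)$loglik
  else
    hmm_loglik_backward_cpp(binary$x, model$pi, A, model$e)
}

#' Viterbi state path
#'
#' Maximum-probability state sequence; deterministic, with score ties
#' resolved toward the lowest state index.
#'
#' @param model An [fit_hmm()] model.
#' @param binary A [binarize()] track.
#' @return Integer state per bin (1-based, 1 = highest emission).
#' @export
decode <- function(model, binary) {
  A <- matrix(as.numeric(model$A), model$n_states)
  as.integer(hmm_viterbi_cpp(binary$x, model$pi, A, model$e))
}

#' Default state annotation labels by emission rank
#'
#' @param n_states Number of states.
#' @return Character labels, most to least signal-rich.
#' @export
state_labels <- function(n_states) {
  base <- c("active-high", "active", "weak", "quiescent")
  lab <- if (n_states <= 4) base[seq_len(n_states)]
         else c(base, paste0("quiescent", seq_len(n_states - 4) + 1))
  paste0("E", seq_len(n_states), "_", lab)
}

#' Odds-ratio enrichment of differential regions per chromatin state
#'
#' For each state the 2x2 table is (differential bp in/out of the state)
#' versus (non-differential bp in/out), using the cumulative genome-wide
#' size of each state; `OR = (a d) / (b c)` with zero cells replaced by
#' 0.5 bp (Haldane). With no differential bp at all, ORs are reported as 0
#' and flagged.
#'
#' @param path Integer state per bin from [decode()].
#' @param binary The decoded [binarize()] track (provides bin coordinates).
#' @param regions Differential regions from [scan_windows()].
#' @return Data frame `state, label, state_bp, diff_bp, odds_ratio, flagged`.
#' @export
state_enrichment <- function(path, binary, regions) {
  bins <- binary$bins
  widths <- bins$end - bins$start
  n_states <- max(path)
  state_bp <- vapply(seq_len(n_states),
                     function(s) sum(widths[path == s]), numeric(1))
  diff_in_bin <- numeric(nrow(bins))
  if (nrow(regions) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(bins), as_granges0(regions))
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    ovl <- pmin(bins$end[qi], regions$end[si]) - pmax(bins$start[qi], regions$start[si])
    for (k in seq_along(qi)) diff_in_bin[qi[k]] <- diff_in_bin[qi[k]] + ovl[k]
  }
  diff_in_bin <- pmin(diff_in_bin, widths)
  diff_bp <- vapply(seq_len(n_states),
                    function(s) sum(diff_in_bin[path == s]), numeric(1))
  tot_diff <- sum(diff_bp)
  tot_bp <- sum(widths)
  flagged <- tot_diff == 0
  or <- vapply(seq_len(n_states), function(s) {
    if (flagged) return(0)
    a <- diff_bp[s]
    b <- tot_diff - a
    c <- state_bp[s] - a
    d <- (tot_bp - tot_diff) - c
    h <- function(v) ifelse(v == 0, 0.5, v)
    (h(a) * h(d)) / (h(b) * h(c))
  }, numeric(1))
  data.frame(state = seq_len(n_states),
             label = state_labels(n_states)[seq_len(n_states)],
             state_bp = state_bp, diff_bp = diff_bp,
             odds_ratio = or, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Write a decoded state path as BED4
#'
#' Consecutive bins in one state merge into a single BED record named by
#' the state label.
#'
#' @param path Integer state per bin.
#' @param binary The decoded [binarize()] track.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_states_bed <- function(path, binary, file) {
  bins <- binary$bins
  labs <- state_labels(max(path))
  newseg <- c(TRUE, path[-1] != path[-length(path)] |
                    bins$chrom[-1] != bins$chrom[-nrow(bins)])
  seg <- cumsum(newseg)
  df <- do.call(rbind, lapply(split(seq_along(path), seg), function(i) {
    data.frame(chrom = bins$chrom[i[1]], start = bins$start[i[1]],
               end = bins$end[i[length(i)]], name = labs[path[i[1]]],
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(df$chrom, format_bp(df$start), format_bp(df$end), df$name)
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write HMM emissions and transitions as TSV
#'
#' @param model An [fit_hmm()] model.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_hmm_tsv <- function(model, file) {
  S <- model$n_states
  em <- data.frame(state = seq_len(S), label = state_labels(S),
                   emission = model$e, initial = model$pi)
  tr <- as.data.frame(matrix(as.numeric(model$A), S))
  names(tr) <- paste0("to_", seq_len(S))
  write_tsv(cbind(em, tr), file)
}
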