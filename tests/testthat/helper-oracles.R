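# Independent brute-force oracles used to verify the package's statistics.
# Each deliberately takes a different computational route from the
# implementation it checks.

# G statistic from the textbook definition, cell by cell
oracle_gtest <- function(a, b, na, nb) {
  obs <- c(a, na - a, b, nb - b)
  rows <- c(na, na, nb, nb)
  cols <- c(a + b, na + nb - a - b, a + b, na + nb - a - b)
  exp_ <- rows * cols / (na + nb)
  g <- 0
  for (i in 1:4) if (obs[i] > 0) g <- g + obs[i] * log(obs[i] / exp_[i])
  2 * g
}

# Fisher two-sided p by full enumeration of tables with fixed margins,
# probabilities via log-binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact paired Wilcoxon by explicit enumeration of all 2^n sign patterns
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  list(W = w_obs, p = min(1, 2 * min(lo, hi)))
}

# BH from the definition: q_i = min over thresholds t >= p_i of m*t/#{p <= t}
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi - 1e-12]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t + 1e-12), numeric(1))))
  }, numeric(1))
}

# ORA upper tail by enumeration of every size-n draw from the universe
oracle_ora <- function(N, n, K, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k) # first K elements are the set
}

# Poisson upper-tail threshold by direct summation
oracle_pois_threshold <- function(lambda, p_cut, cmax = 1000) {
  for (c in 0:cmax) {
    tail <- 1 - sum(exp(-lambda + (0:(c - 1)) * log(lambda) - lgamma(1:c)))
    if (c == 0) tail <- 1
    if (tail < p_cut) return(c)
  }
  Inf
}

# small deterministic genome + genes shared by several tests
tiny_world <- function(n_genes = 6, spacing = 5000, len = 1000) {
  pitch <- spacing + len
  g <- genome_spec("chr1", n_genes * pitch + spacing)
  genes <- gene_models(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = "chr1",
    start = spacing + (seq_len(n_genes) - 1) * pitch,
    end = spacing + (seq_len(n_genes) - 1) * pitch + len,
    strand = rep_len(c("+", "-"), n_genes),
    genome = g)
  list(genome = g, genes = genes)
}
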