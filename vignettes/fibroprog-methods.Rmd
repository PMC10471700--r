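---
title: "Methods: tri-omics reprogramming analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-omics reprogramming analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroprog)
```

## The design being modelled

The package analyses a two-condition developmental-reprogramming design:
myometrial stem cells sorted from animals exposed neonatally to an
endocrine-disrupting chemical (EDC) versus vehicle (VEH), profiled on
three layers — RNA-seq expression, H3K4me3 ChIP-seq (an activating
promoter mark), and bisulfite CpG methylation. Tissue from several animals
is pooled into a single library per condition per assay, so the default
statistics are exact conditional tests rather than dispersion-estimating
models; replicated designs are supported where noted.

All genomic coordinates inside the package are 0-based half-open (BED
convention); GTF input is converted at the boundary. Strand affects only
TSS placement — ChIP and bisulfite signals are counted unstranded.

## Differential expression

With one library per condition, a gene with counts $(a, b)$ and library
sizes $(N_E, N_V)$ is tested by the exact conditional binomial: under the
null, $a \mid a+b=t \sim \mathrm{Bin}(t,\; N_E/(N_E+N_V))$, with the
two-sided p-value summing the probabilities of all outcomes no more likely
than the observed one. With at least two replicates per condition, a
per-gene negative-binomial likelihood-ratio test at fixed dispersion
$\phi$ ($\mathrm{Var} = \mu + \phi\mu^2$, default $\phi = 0.01$, i.e.
BCV 0.1) with log library-size offsets is used instead. Fold changes are
pseudocounted, $\log_2\frac{(a+0.5)/N_E}{(b+0.5)/N_V}$, so zero counts
stay finite. A gene is called `up` when $\log_2\mathrm{FC} \ge 1$ and the
Benjamini–Hochberg q-value is below 0.05 (`down` symmetric). Genes are
considered detected when their summed count reaches 10 (configurable; the
source study reports a detected-gene count without stating its rule).

Deliberate non-goals, matching the unreplicated design: TMM
normalisation and empirical-Bayes dispersion shrinkage. One consequence
is visible in the synthetic runs: when planted up- and down-regulated
genes do not balance in expression, the fixed-depth libraries acquire a
composition shift that subtracts a few tenths of a log2 unit from
upregulated genes, which is the dominant cause of DE misses at
$|\log_2\mathrm{FC}| = 1.5$.

## Windowed differential H3K4me3

Each chromosome is tiled with 1 kb windows. Per window the counts
$(a, b)$ against the library remainders form a 2×2 table tested with the
G-test, $G = 2\sum O \ln(O/E)$ (zero cells contribute nothing; p from
$\chi^2_1$). Fold change is computed on reads-per-million with a 0.5-read
pseudocount; direction comes from the fold change, significance from the
G-test. BH adjustment runs across all windows with nonzero total — empty
windows would only dilute the FDR. A window is significant at fold change
$\ge 1.5\times$ in either direction **and** q < 0.01; touching significant
windows of one direction merge into regions keeping the extremal fold
change and minimal q. Regions annotate genes whose TSS lies within 3 kb
(distance measured from the nearest region edge — the package's choice;
peak-annotation tools commonly do the same and the source design does not
specify). A gene's mark status intersects its body ± 10 kb with the
merged regions: `enriched`, `reduced`, `both`, or `none`.

## Chromatin states

The single-mark segmentation follows the ChromHMM recipe restricted to
one mark: counts are binarized against the genome-wide mean rate
$\lambda$ (a bin is "on" when its Poisson upper tail falls below
$10^{-4}$), then a Bernoulli-emission HMM is fitted by Baum–Welch. The
recursions are the standard scaled forward–backward form, with the total
log-likelihood accumulated from the scaling constants — numerically
equivalent to log-space arithmetic and immune to underflow at genome
length. Five random restarts are drawn from one seeded stream and the
best-likelihood fit kept; states are relabelled by decreasing emission
probability so state 1 is always the most signal-rich, and annotation
labels (`active-high` … `quiescent`) follow that rank. Viterbi decoding
breaks score ties toward the lower state index for determinism.

Four states is the default: single-mark binary data cannot support
Roadmap-scale state counts, and in practice the fitted emissions collapse
to a signal/background dichotomy with duplicated states — harmless for
the enrichment analysis, which is computed per labelled state. Per-state
enrichment uses the cumulative genome-wide bp of each state versus the bp
of differential regions falling in it, as an odds ratio with zero cells
replaced by 0.5 (Haldane).

## Methylome

A CpG site is analyzable when both conditions reach 5× coverage. Percent
methylation is $m/t$ with one wrinkle inherited from the source
variant-calling workflow: frequencies below the 0.1% variant floor are
reported as 0 (sub-threshold variants are not called — the floor zeroes,
it does not raise). Per-site differential calls are two-sided Fisher
exact tests on methylated/unmethylated by condition, with
$\Delta = \mathrm{pct}_{EDC} - \mathrm{pct}_{VEH}$, so hypo-methylation
in EDC is negative.

Gene-level promoter status at a threshold $T \in \{0.10, 0.33, 0.50\}$
uses an any-site rule: `hypo` if at least one analyzable promoter site
has $\Delta \le -T$ and none has $\Delta \ge +T$, `hyper` symmetric,
`mixed` when both occur. The thresholds are interpreted as absolute
percentage-point differences (bisulfite deltas are conventionally
reported that way; a relative reading is the open alternative). The
any-site rule rather than a promoter mean is required for the `mixed`
category to be representable at all.

Targeted panels are summarized per site (percent methylation both
conditions, delta, hypo/hyper call at Fisher p < 0.05 with a nonzero
delta), with percent-of-panel-hypo computed against the full panel size
to one decimal, and a paired Wilcoxon signed-rank test across sites. The
Wilcoxon is exact for up to 25 informative pairs, including midranks
under ties: the null distribution of the rank sum is built by
generating-function convolution over the doubled midranks, which is
mathematically the enumeration of all $2^n$ sign assignments; beyond 25
pairs a tie-corrected normal approximation with continuity correction
takes over. The shipped panel catalog
(`erg_panels_synthetic.tsv`) is a synthetic stand-in: the published
panel sizes for Esr1 (14), Ar (17) and Pgr (19) and the published total
of 102 sites across eight estrogen-responsive-gene panels are respected,
but the five remaining sizes and every genomic position are invented.

## Integration

Only genes with a DE direction enter the concordance tables (the
categories partition "EDC-regulated genes"; `ns` genes are excluded).
The expected mark pairs upregulation with H3K4me3 gain and with promoter
hypo-methylation, and symmetrically for downregulation; discordant
single-direction marks are `opposite`, bidirectional `mixed`, absent
`none`. Summaries report per-category counts and percentages (two
decimals) per DE direction and threshold, plus the count of genes
carrying both marks. Gene-set over-representation uses the upper
hypergeometric tail $P(X \ge k)$; the DE-direction-by-mark association
is a Fisher exact test on the 2×2 of up/down by mark present/absent.

## The synthetic generator and what passing tests mean

`plant_truth()` draws exactly $\mathrm{round}(f_{DE} \cdot n)$ DE genes
(half up, half down, ties to up). Each DE gene's H3K4me3 effect agrees
with its expression direction with probability 0.8 and its methylation
effect with probability 0.6 (both configurable); null genes are null on
all layers. The layer simulators then emulate:

* RNA: log-normal base abundances scaled to a 1e7-read library;
  negative-binomial counts; the EDC library is renormalised to the
  configured depth, so composition bias behaves as it does in real
  fixed-depth sequencing.
* ChIP: Poisson background (5 reads per 1 kb window), promoter windows
  (TSS ± 1 kb) at 20× background in VEH and scaled by the planted ratio
  (default 3) in EDC, so the expected peak ratio equals the planted
  effect exactly; overlapping promoters sum.
* Methylation: 14 promoter CpGs per gene; VEH levels Beta around 0.5
  (concentration 10); EDC level clipped to $[0,1]$ after adding the
  planted delta (default magnitude 0.40 — the kind of shift the 33-point
  calling threshold presupposes); Poisson 30× coverage, binomial
  methylated counts.

Defaults were fixed once as the emulated study conditions. Two geometry
choices deserve note: genes sit on a 32 kb pitch (2 kb bodies, 30 kb
spacing) so that the ±10 kb mark window does not systematically swallow
neighbouring promoters, mimicking realistic mammalian gene density at
desk scale; and the promoter is TSS ± 1 kb throughout (the conventional
choice; the source design never defines it numerically).

What the generator does **not** emulate: read-level artifacts
(mappability, duplicates, bisulfite conversion errors), input/IgG
correction, biological replicate variance in the pooled default, genuine
CpG-island structure, and correlated noise between layers. Passing the
planted-recovery tests therefore demonstrates that the statistics and
bookkeeping are correct under the declared generative model — not that
the pipeline is robust to every artifact of real libraries.

## Numerical and reproducibility choices

* Every stochastic stage seeds its own substream via a 31-bit hash of
  `(master seed, stage name)`; identical configurations reproduce every
  output byte for byte.
* EM stops when the relative log-likelihood change falls below $10^{-6}$
  (cap 500 iterations); emissions are clamped to $[10^{-8}, 1-10^{-8}]$.
* Fisher two-sided p-values compare table probabilities with a $10^{-7}$
  relative slack, avoiding floating-point misclassification of
  equal-probability tables.
* Degenerate inputs have defined conventions: empty windows G = 0 / p = 1,
  zero-margin Fisher tables p = 1 (flagged), all-zero Wilcoxon
  differences W = 0 / p = 1, empty differential-region sets give flagged
  zero odds ratios.
* Problem sizes in the shipped tests (2000-gene default run, 50k-bin HMM
  recovery, 1000-instance oracle batteries) were chosen so the whole
  suite completes in a few minutes on one CPU while keeping sampling
  error well inside the asserted tolerances.

## Known limitations

The unreplicated exact tests treat sequencing noise as the only error
source, as the pooled design forces; their p-values are anticonservative
for biological inference (the study design's limitation, reproduced
faithfully). The HMM state count is not selected by any criterion.
diffReps' negative-binomial and hidden-window modes, TMM, GSEA-style
ranked enrichment, and causal-network z-scores are out of scope.
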