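---
title: "Estimating and removing ambient RNA contamination"
author: "soupclean authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and removing ambient RNA contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soupclean)
library(Matrix)
```

## The problem

Droplet-based single-cell RNA-seq partitions a cell suspension into
emulsion droplets, tags the mRNA captured in each droplet, and reports a
UMI count matrix over genes and droplet barcodes. The input suspension
always carries some cell-free mRNA — released by lysed or stressed cells
during dissociation — and every droplet captures a sample of it. A droplet
containing a cell therefore yields a mixture of that cell's transcripts
and this ambient "soup", and every downstream analysis that treats the
observed counts as purely endogenous inherits the confusion: negative
marker genes appear weakly expressed everywhere, cluster markers lose
specificity, and channel-specific soup composition acts as a batch effect.

## The model

Let $n_{g,c}$ be the observed UMI count for gene $g$ in cell $c$, with
cell total $N_c = \sum_g n_{g,c}$. We assume an additive decomposition

$$ n_{g,c} = m_{g,c} + o_{g,c}, $$

where $m_{g,c}$ are the cell's endogenous counts and $o_{g,c}$ the
contaminating counts. Two assumptions make the problem tractable:

1. **A channel-wide soup composition.** The relative abundance of genes in
   the ambient pool, $b_g$ with $\sum_g b_g = 1$, is the same for every
   droplet in a channel. The expected contamination is then
   $$ o_{g,c} = N_c \, \rho_c \, b_g, $$
   where $\rho_c \in [0,1]$ is the contamination fraction — the share of
   the cell's UMIs that came from the soup.
2. **A constant contamination fraction within a channel.** Capture
   efficiency varies across droplets by an order of magnitude, which
   swamps any systematic dependence of $\rho_c$ on cell size, so a single
   global $\rho$ is used for all cells of a channel.

The workflow has three steps: estimate $b_g$, estimate $\rho$, remove
$o_{g,c}$.

## Step 1: the soup profile

Droplets with at most `umi_threshold` total UMIs (default 10) are assumed
to contain no cell, and their counts are pooled:

$$ b_g = \frac{\sum_{d \in \text{empty}} n_{g,d}}
               {\sum_{d \in \text{empty}} N_d}. $$

This is the maximum-likelihood estimate of the soup composition under
multinomial sampling. The threshold is deliberately low: any cutoff below
roughly 100 UMIs gives a very similar profile, but a low cutoff minimises
the chance of pooling in droplets holding debris or dying cells. Both the
inclusive ($\le$) and strict ($<$) reading of the cutoff are exposed via
the `inclusive` flag; the difference is negligible because droplets at
exactly the threshold contribute a vanishing share of the pooled counts.

`soup_cell_correlation()` checks the plausibility of a profile: if the
soup arises from roughly uniform sampling of the cells in the channel, it
should correlate strongly with the aggregate cell profile. Genes above
the 99th quantile of aggregate expression are trimmed first (a handful of
ultra-abundant genes otherwise dominate the statistic) and both count
vectors are subsampled to equal depth — an exact multivariate
hypergeometric draw, seeded for reproducibility — so that sampling noise
is comparable on both sides.

## Step 2: the contamination fraction

For genes that a given cell does not express endogenously
($m_{g,c} = 0$), everything observed is soup, so for a gene set $G$ with
soup share $B = \sum_{g \in G} b_g > 0$:

$$ \rho_c = \frac{\sum_{g \in G} n_{g,c}}{N_c \, B}. $$

The global estimate pools counts over all usable cells,
$\hat\rho = \sum_c \sum_{g \in G} n_{g,c} \big/ \sum_c N_c B$, which is
the $N_c B$-weighted mean of the per-cell values; a median summary is
available for robustness.

### Which cells can be assumed non-expressing?

Given a candidate negative-marker set (haemoglobin genes in solid
tissue, immunoglobulin genes in PBMC-like data), `non_expressing_cells()`
tests each cell against the most conservative null: even if the cell were
*nothing but soup*, its expected gene-set count would be $N_c B$. Cells
whose observed count is significantly above this Poisson expectation
(upper tail, Benjamini–Hochberg at FDR 0.05) must express the set
endogenously. When clusters are supplied, any cluster containing such a
cell is excluded wholesale — the cluster is evidence that its cell type
expresses the gene, and low-count sister cells would otherwise bias
$\hat\rho$ upward. The null scale is exposed as `maximum_contamination`
(default 1) for users who want a stricter exclusion.

### Nominating genes: the bimodality heuristic

Good estimation genes are abundant in the soup but endogenously expressed
by only some cells. Across cells, the statistic
$r_{g,c} = \log_{10}\!\big((n_{g,c}/N_c)/b_g\big)$ then separates into a
low mode near $\log_{10}\rho$ (cells whose counts are pure soup) and a
high mode well above 0 (expressing cells). `rank_estimation_genes()`
takes the `top_n` genes by soup fraction (default 500 — in a typical
20–30k-gene channel this restricts to genuinely abundant genes) and ranks
them by the sample bimodality coefficient
$(\text{skewness}^2 + 1)/\text{kurtosis}$ of $r$, using the
pseudo-fraction $0.1/N_c$ for zero counts. Values above $5/9$ (the
uniform-distribution benchmark) suggest bimodality; any two-point mixture
scores 1. The coefficient is computed from population moments, making the
ranking deterministic and cheap. It is a screening aid, not a test: at
very low expression, count discreteness alone can inflate the score,
which is why the candidate pool is restricted by soup abundance first.

### Automated estimation

Without prior knowledge, cluster markers stand in for negative-marker
sets: a strong marker of cluster $k$ can be assumed silent in all other
clusters (after the same Poisson exclusion), so each marker yields an
independent $\hat\rho$. Markers are found by tf–idf specificity: tf is
the fraction of the cluster's cells detecting the gene, idf the log
inverse fraction of all cells detecting it, and pairs with
$\text{tf} \cdot \text{idf} \ge 1$ are kept. Detection here is
*soup-aware*: a cell counts as detecting a gene only when its expression
rate exceeds the gene's pure-soup rate ($n_{g,c} > N_c b_g$). With plain
nonzero detection, contamination itself trips the detector for precisely
the soup-rich genes that carry information about $\rho$, draining their
idf; the soup-aware rule is the detection analogue of $r_{g,c} > 0$.
Markers must additionally sit at or above the 90th percentile of nonzero
soup fractions — a marker absent from the soup says nothing about
contamination.

Poor markers produce scattered estimates with no preferred value, while
good markers concentrate at the truth, so the final estimate is the mode
of a weighted Gaussian kernel density over the per-marker estimates
(weights proportional to each marker's soup counts, Silverman bandwidth,
argmax on a 512-point grid over $[0,1]$). The per-marker table is
retained in the result for inspection, and a TSV export of it is written
by the command-line workflow.

## Step 3: correction

Naively, $\hat m_{g,c} = n_{g,c} - N_c \rho b_g$ (available as
`subtract_naive()`), but this leaves the deficit unallocated wherever the
expectation exceeds the observation. `correct_counts()` instead removes
exactly $T = \mathrm{round}(\rho N)$ counts per correction unit by
maximising the multinomial likelihood of the removed counts under the
soup composition,

$$ \max_{o} \; \sum_g \big( o_g \log b_g - \log o_g! \big)
   \quad \text{s.t.} \quad 0 \le o_g \le n_g, \;\; \textstyle\sum_g o_g = T, $$

with $o_g = 0$ forced for genes absent from the soup. The continuous
maximiser has a water-filling form: the KKT conditions give
$o_g = \psi^{-1}(\log b_g - \mu) - 1$ clamped to $[0, n_g]$, where $\psi$
is the digamma function and the level $\mu$ is found by bisection. To
Stirling accuracy this is proportional allocation $o_g \approx T b_g$,
i.e. exactly the naive rule — but it handles the caps correctly
(removals that would exceed an observation spill over to the remaining
soup genes) and it tracks the integer optimum closely: on exhaustive
enumeration over random small units it stays within one count per gene of
the brute-force integer maximiser, whereas plain proportional allocation
can be off by substantially more on small, skewed units. If a unit's
soup-supported counts fall short of $T$, everything removable is removed
and the unit is flagged infeasible rather than silently under-corrected.

### Cluster-level correction

Counts in single cells are sparse: one observed count of a soup-rich gene
could equally be contamination or faint endogenous expression. When
cluster assignments are given, removal is computed on counts aggregated
per cluster, where this ambiguity largely disappears, and the removed
counts of each gene are then distributed back to member cells in
proportion to each cell's observed counts of that gene. A literal
"proportional to cell size" redistribution can assign removals to cells
that never observed the gene (driving corrected counts negative); the
per-gene rule coincides with size-proportionality when expression is
homogeneous across the cluster, automatically takes more from the cells
that observed more, and can never remove counts a cell does not have.

### Output conventions

Corrected counts are fractional by default; conservation
($m + o = n$, element-wise) and bounds ($0 \le m \le n$) hold exactly.
`round_to_int = TRUE` applies seeded stochastic rounding that preserves
each unit's removed total: fractional removals are floored and the
leftover counts are assigned by weighted sampling on the fractional
parts. Removal targets use half-up rounding (`floor(x + 0.5)`) rather
than banker's rounding so that results are platform-stable. Fractional
matrices are written as `real` MatrixMarket files, integer matrices as
`integer` ones.

## The channel simulator

`simulate_channel()` generates ground-truth channels directly from the
model: per-cell totals are log-normal around each type's mean
(`umi_sdlog = 0.5`, reproducing the order-of-magnitude capture-efficiency
spread of real droplet data); endogenous counts are multinomial draws
from the type profile with $\mathrm{round}((1-\rho)N_c)$ trials; soup
counts fill the remainder from the soup composition; empty droplets are
pure soup with uniform totals on $[1, 10]$. The soup composition is the
UMI-weighted mean of the cell-type profiles — the uniform-sampling
picture supported by the soup/cell correlation diagnostic — with an
optional `soup_distortion` dial to break that assumption deliberately.
Generated profiles give each type a block of private marker genes
(default 10 genes holding 30% of the type's expression, with the other
types at exactly zero), so every channel carries known negative markers
and known cluster markers. `species_mix_fixture()` is the two-type
special case with fully disjoint gene blocks, in which every cross-block
count is contamination by construction — the in-silico analogue of a
human/mouse mixing experiment.

What the simulator does *not* emulate: doublets, ambient DNA, barcode
swapping/index hopping, UMI collisions, cell-cycle or other within-type
expression structure, and droplet-size-dependent contamination. Passing
tests on simulated channels therefore validate the estimators and the
correction under the model's own assumptions — constant $\rho$, constant
soup composition — plus multinomial noise; they do not certify behaviour
when those assumptions are violated in real tissue.

## Validation scale and numerical choices

The packaged tests exercise: equation-level exactness on hand-computed
toy inputs; exhaustive brute-force comparison of the removal allocator on
over a hundred random units of up to 6 genes and 30 counts; conservation,
identity-at-zero and monotonicity-in-$\rho$ on 50 random channels;
parameter recovery over 20 simulated channels of 500 cells at
$\rho \in \{0.02, 0.05, 0.1, 0.2\}$ (mean absolute error well under 0.01
for both estimators); the species-mix purge (cross-block expression
reduced more than tenfold at $\rho = 0.02$, own-block expression changed
by under 1% in the across-cell median); and byte-identical outputs under
fixed seeds. These sizes were chosen so the whole suite runs in well
under a minute while keeping Monte-Carlo error far below the tested
tolerances.

Numerical details worth knowing: the water-fill bisection uses 80
iterations on $\mu \in [-50, 50]$ and then rescales interior allocations
so unit totals are met exactly; the inverse digamma uses 8 Newton steps
from the standard initial guess; KDE bandwidth is Silverman's rule
computed on the unweighted estimates (degenerate bandwidths fall back to
the median); ties in stochastic rounding are broken by the seeded
sampler; `0/0` removal fractions are reported as 0.

## Limitations

- $\rho$ is global per channel. Cells with genuinely atypical
  contamination (e.g. droplets near clumps) are corrected at the channel
  rate; cluster-level redistribution mitigates but does not remove this.
- The empty-droplet profile is the soup definition; channels whose raw
  matrix was filtered upstream (no empty droplets retained) cannot be
  profiled.
- Negative-marker estimation is only as good as the biological assumption
  that the gene set is truly silent in the usable cells; the Poisson
  exclusion guards against gross violations, not subtle low-level
  expression.
- Corrected fractional counts are suitable for most downstream tools, but
  pipelines that require integers should opt into stochastic rounding and
  fix the seed.
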