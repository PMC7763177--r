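# soupclean

Ambient RNA ("soup") decontamination for droplet-based single-cell
RNA-seq count matrices.

Droplet assays capture not only each cell's transcripts but also the
cell-free mRNA floating in the input suspension. Every cell-containing
droplet therefore reports a mixture of endogenous and ambient counts,
which blurs marker specificity, paints negative markers (haemoglobin,
immunoglobulin, hormone genes) across cell types that never express
them, and acts as a channel-specific batch effect. `soupclean`
quantifies this contamination and removes it, producing a corrected
count matrix that drops into any downstream pipeline. It is aimed at
anyone processing 10x-style droplet data who has access to the *raw*
(unfiltered) count matrix.

## The model

For gene $g$ in cell $c$, observed counts decompose as

$$n_{g,c} = m_{g,c} + o_{g,c}, \qquad o_{g,c} = N_c\,\rho_c\,b_g ,$$

where $m$ is endogenous expression, $N_c$ the cell's total UMIs, $b_g$
the channel-wide soup composition and $\rho_c$ the contamination
fraction. The workflow:

1. **Soup profile** — $b_g$ is the pooled per-gene fraction over empty
   droplets (total UMIs ≤ 10):
   $b_g = \sum_d n_{g,d} / \sum_d N_d$.
2. **Contamination fraction** — for a gene set $G$ known to be silent in
   a cell ($m_{g,c}=0$ for $g\in G$),
   $\rho_c = \sum_{g\in G} n_{g,c} / (N_c \sum_{g\in G} b_g)$.
   Cells that demonstrably express $G$ (Poisson test against the
   everything-is-soup null, BH-corrected at FDR 0.05) are excluded along
   with their whole cluster. Lacking a known gene set, an automated mode
   derives one estimate per strong cluster marker and takes the mode of
   their weighted kernel density.
3. **Correction** — exactly $\rho N$ counts are removed per cell (or per
   cluster, redistributed to cells per gene in proportion to observed
   counts) by maximising the multinomial likelihood of the removed
   counts under $b$, subject to never removing more of a gene than was
   observed.

A seeded channel simulator with known ground truth
(`simulate_channel()`, `species_mix_fixture()`) backs the test suite —
no external data needed.

## Worked example

```r
library(soupclean)

# a simulated channel standing in for read_mtx_dir("raw/") etc.
sim  <- simulate_channel(
  n_genes    = 400,
  cell_types = list(cell_type_spec("B_cell", 125, 2000),
                    cell_type_spec("T_cell", 125, 2000),
                    cell_type_spec("NK",     125, 2000),
                    cell_type_spec("mono",   125, 2000)),
  rho = 0.1, n_empty = 2000, seed = 7)

soup <- estimate_soup(sim$raw, umi_threshold = 10)
soup
#> SoupProfile: 400 genes, 10949 soup UMIs pooled from 2000 droplets (threshold <=10 UMIs)

soup_cell_correlation(sim$filtered, soup, seed = 7)
#> [1] 0.956579

est <- auto_estimate_rho(sim$filtered, soup, sim$clusters)
est
#> ContaminationEstimate: rho = 0.1018 (method: automated, 500 cells, 30 markers)

res <- correct_counts(sim$filtered, soup, est, clusters = sim$clusters)
res
#> CorrectionResult: 400 genes x 500 cells; removed 104562 of 1027518 counts (10.18%)

write_mtx_dir(res, "corrected/")   # 10x-style directory for downstream tools
```

Reading the numbers: the soup profile was pooled from 10,949 UMIs across
2,000 empty droplets and correlates at 0.96 with the aggregate cell
profile, as expected if the soup samples the channel's cells roughly
uniformly. The automated estimator put the contamination fraction at
0.102 against a simulated truth of 0.10, and correction removed 10.18%
of all counts — the effective contamination — while conserving
`corrected + removed == observed` exactly.

The same workflow runs from the shell via the bundled launcher:

```sh
exec/soupclean simulate --out channel/ --seed 7
exec/soupclean profile  --raw channel/raw --filtered channel/filtered --out profile/
exec/soupclean correct  --raw channel/raw --filtered channel/filtered \
    --clusters channel/clusters.tsv --rho-mode auto --out corrected/
```

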