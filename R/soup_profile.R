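#' Estimate the ambient RNA (soup) expression profile from empty droplets
#'
#' Droplets whose total UMI count falls at or below `umi_threshold` are
#' assumed to contain no cell, only ambient mRNA. The soup profile is the
#' pooled per-gene fraction of all counts in those droplets:
#' `b_g = sum_d n_{g,d} / sum_d N_d`, the maximum-likelihood estimate of the
#' ambient composition under multinomial sampling.
#'
#' @param raw A [DropletMatrix] including empty droplets.
#' @param umi_threshold Empty-droplet UMI cutoff (default 10). Any cutoff
#'   below ~100 gives a faithful profile; low cutoffs minimise the chance of
#'   including droplets with cell debris.
#' @param inclusive If `TRUE` (default) droplets with exactly
#'   `umi_threshold` UMIs are included; if `FALSE` the cutoff is strict
#'   (`< umi_threshold`).
#' @return An object of class `SoupProfile`: list with `fractions` (named
#'   per-gene composition, sums to 1), `counts` (pooled per-gene soup
#'   counts), `umi_threshold`, `inclusive`, `total_soup_umis` and
#'   `n_droplets_used`.
#' @export
estimate_soup <- function(raw, umi_threshold = 10, inclusive = TRUE) {
  stopifnot(inherits(raw, "DropletMatrix"))
  tot <- Matrix::colSums(raw$counts)
  sel <- if (inclusive) tot <= umi_threshold else tot < umi_threshold
  if (!any(sel))
    stop("no empty droplets below threshold (", umi_threshold, ")")
  counts <- Matrix::rowSums(raw$counts[, sel, drop = FALSE])
  total <- sum(counts)
  if (total == 0)
    stop("all selected empty droplets have zero counts; cannot estimate soup")
  structure(list(
    fractions = stats::setNames(counts / total, raw$gene_ids),
    counts = stats::setNames(counts, raw$gene_ids),
    umi_threshold = umi_threshold,
    inclusive = inclusive,
    total_soup_umis = total,
    n_droplets_used = sum(sel)
  ), class = "SoupProfile")
}

#' @export
print.SoupProfile <- function(x, ...) {
  cat("SoupProfile: ", length(x$fractions), " genes, ",
      x$total_soup_umis, " soup UMIs pooled from ", x$n_droplets_used,
      " droplets (threshold ", if (x$inclusive) "<=" else "<",
      x$umi_threshold, " UMIs)\n", sep = "")
  invisible(x)
}

#' Correlation between the soup profile and the aggregate cell profile
#'
#' A diagnostic of how well the ambient profile resembles an average over
#' the cells in the channel (as expected if the soup arises from roughly
#' uniform sampling of cell contents). All cell counts are pooled into one
#' profile; genes above the given quantile of the aggregate expression are
#' trimmed (very highly expressed genes otherwise dominate the statistic);
#' the larger of the two count vectors is subsampled without replacement to
#' the smaller total so both have equal depth; the Pearson correlation of
#' the two count vectors is returned.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param trim_quantile Quantile of aggregate cell expression above which
#'   genes are removed (default 0.99).
#' @param seed Integer seed for the subsampling step.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
soup_cell_correlation <- function(cells, soup, trim_quantile = 0.99,
                                  seed = 1L) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  agg <- Matrix::rowSums(cells$counts)
  if (length(agg) != length(soup$fractions))
    stop("cells and soup cover different gene sets")
  keep <- agg <= stats::quantile(agg, trim_quantile)
  if (sum(keep) < 3) stop("fewer than 3 genes remain after trimming")
  a <- agg[keep]
  s <- soup$counts[keep]
  ta <- sum(a); ts <- sum(s)
  with_seed(seed, {
    if (ta > ts) a <- subsample_counts(a, ts)
    else if (ts > ta) s <- subsample_counts(s, ta)
  })
  stats::cor(a, s)
}

#' Per-cell expression of a gene set relative to its rate in the soup
#'
#' For each cell, the fraction of the cell's UMIs falling in `gene_set`
#' divided by the soup fraction of the same genes. A value near 1 means the
#' cell's gene-set expression is fully explained by ambient contamination
#' at contamination fraction 1; values far above 1 indicate endogenous
#' expression (e.g. haemoglobin genes in red blood cells). Useful for
#' spotting which cells genuinely express a candidate negative-marker set.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param gene_set Character vector of gene symbols or ids.
#' @return Named numeric vector, one ratio per cell (`NA` for cells with
#'   zero total counts).
#' @export
soup_fraction_per_cell <- function(cells, soup, gene_set) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  idx <- match_genes(cells, gene_set)
  if (!length(idx)) stop("gene set not present in matrix")
  B <- sum(soup$fractions[idx])
  if (B == 0) stop("gene set absent from soup")
  n_set <- Matrix::colSums(cells$counts[idx, , drop = FALSE])
  N <- Matrix::colSums(cells$counts)
  ratio <- ifelse(N > 0, (n_set / N) / B, NA_real_)
  stats::setNames(ratio, cells$barcodes)
}
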