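#' Construct a ContaminationEstimate
#'
#' Container for an estimated (or user-fixed) contamination fraction: the
#' channel-wide fraction of each cell's UMIs that originates from ambient
#' mRNA rather than the cell itself.
#'
#' @param rho_global Global contamination fraction in `[0, 1]`.
#' @param method One of `"manual_gene_set"`, `"automated"`, `"fixed"`.
#' @param cells Optional [DropletMatrix]; when given, `rho_per_cell` is
#'   populated with the global value for every cell (a constant
#'   contamination fraction within a channel is assumed).
#' @param per_marker_estimates Data frame of per-marker estimates
#'   (columns `gene`, `clusters_used`, `estimate`, `weight`); empty for
#'   `method = "fixed"`.
#' @param n_cells_used Number of cells that informed the estimate.
#' @return An object of class `ContaminationEstimate`.
#' @export
ContaminationEstimate <- function(rho_global,
                                  method = c("manual_gene_set", "automated",
                                             "fixed"),
                                  cells = NULL,
                                  per_marker_estimates = NULL,
                                  n_cells_used = 0L) {
  method <- match.arg(method)
  if (!is.numeric(rho_global) || length(rho_global) != 1 ||
      is.na(rho_global) || rho_global < 0 || rho_global > 1)
    stop("rho_global must be a single value in [0, 1]")
  if (is.null(per_marker_estimates))
    per_marker_estimates <- data.frame(gene = character(0),
                                       clusters_used = character(0),
                                       estimate = numeric(0),
                                       weight = numeric(0))
  if (method == "fixed" && nrow(per_marker_estimates))
    stop("a fixed estimate carries no per-marker table")
  rho_per_cell <- NULL
  if (!is.null(cells))
    rho_per_cell <- stats::setNames(rep(rho_global, ncol(cells$counts)),
                                    cells$barcodes)
  structure(list(rho_global = rho_global,
                 rho_per_cell = rho_per_cell,
                 method = method,
                 per_marker_estimates = per_marker_estimates,
                 n_cells_used = as.integer(n_cells_used)),
            class = "ContaminationEstimate")
}

#' @export
print.ContaminationEstimate <- function(x, ...) {
  cat("ContaminationEstimate: rho = ", signif(x$rho_global, 4),
      " (method: ", x$method,
      if (x$n_cells_used > 0) paste0(", ", x$n_cells_used, " cells") else "",
      if (nrow(x$per_marker_estimates))
        paste0(", ", nrow(x$per_marker_estimates), " markers") else "",
      ")\n", sep = "")
  invisible(x)
}

# Per-cell rho vector for a cell matrix, from an estimate or a bare number.
rho_vector <- function(rho, cells) {
  n <- ncol(cells$counts)
  if (inherits(rho, "ContaminationEstimate")) {
    if (!is.null(rho$rho_per_cell)) {
      v <- rho$rho_per_cell[cells$barcodes]
      if (anyNA(v)) v[is.na(v)] <- rho$rho_global
    } else v <- rep(rho$rho_global, n)
  } else if (is.numeric(rho) && length(rho) == 1L) {
    v <- rep(rho, n)
  } else if (is.numeric(rho) && length(rho) == n) {
    v <- as.numeric(rho)
  } else stop("rho must be a ContaminationEstimate, a scalar, ",
              "or one value per cell")
  if (any(v < 0 | v > 1)) stop("contamination fractions must lie in [0, 1]")
  stats::setNames(v, cells$barcodes)
}

#' Identify cells that cannot be assumed free of endogenous expression
#'
#' Tests, per cell, whether the observed count of a gene set exceeds what
#' ambient contamination alone could supply. Under the null that the cell is
#' at most `maximum_contamination` soup, the gene-set count is Poisson with
#' mean `maximum_contamination * N_c * B`, where `N_c` is the cell's total
#' UMIs and `B` the soup fraction of the gene set. Upper-tail p-values are
#' corrected by Benjamini-Hochberg at the given FDR; rejected cells
#' endogenously express the set. When clusters are supplied, any cluster
#' containing an expressing cell is excluded entirely — the remaining cells
#' are "usable" for contamination estimation under the assumption that their
#' endogenous expression of the gene set is zero.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param gene_set Character vector of gene symbols or ids.
#' @param clusters Optional named vector mapping barcode to cluster label
#'   (see [read_clusters()]). Without clusters the decision is per-cell.
#' @param fdr False-discovery rate for the Poisson test (default 0.05).
#' @param maximum_contamination Null contamination level; the default 1
#'   ("the cell is nothing but soup") is maximally conservative.
#' @return An object of class `NonExpressionMask`: list with named logical
#'   `usable` and `expressing`, numeric `p_values` (BH-adjusted in
#'   `q_values`), the `fdr` used, and the matched gene rows.
#' @export
non_expressing_cells <- function(cells, soup, gene_set, clusters = NULL,
                                 fdr = 0.05, maximum_contamination = 1.0) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  idx <- match_genes(cells, gene_set)
  if (!length(idx)) stop("gene set not present in matrix")
  B <- sum(soup$fractions[idx])
  if (B == 0) stop("gene set absent from soup")
  N <- Matrix::colSums(cells$counts)
  obs <- Matrix::colSums(cells$counts[idx, , drop = FALSE])
  lambda <- maximum_contamination * N * B
  p <- stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  expressing <- q <= fdr
  if (is.null(clusters)) {
    usable <- !expressing
  } else {
    cl <- clusters[cells$barcodes]
    if (anyNA(cl))
      stop("cells without cluster assignment: ",
           paste(utils::head(cells$barcodes[is.na(cl)], 5), collapse = ", "))
    bad_clusters <- unique(cl[expressing])
    usable <- !(cl %in% bad_clusters)
  }
  structure(list(
    usable = stats::setNames(usable, cells$barcodes),
    expressing = stats::setNames(expressing, cells$barcodes),
    p_values = stats::setNames(p, cells$barcodes),
    q_values = stats::setNames(q, cells$barcodes),
    fdr = fdr,
    gene_rows = idx
  ), class = "NonExpressionMask")
}

#' Estimate the contamination fraction from a negative-marker gene set
#'
#' Given genes assumed absent from the usable cells' endogenous expression
#' (so every observed count is soup), the per-cell contamination fraction is
#' `rho_c = sum_g n_{g,c} / (N_c * B)` with `B` the soup fraction of the
#' set. The global estimate pools counts across usable cells:
#' `sum_c sum_g n_{g,c} / sum_c (N_c * B)`, i.e. the `N_c * B`-weighted mean
#' of the per-cell values; a median across cells is available as a robust
#' alternative.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param gene_set Character vector of gene symbols or ids.
#' @param mask A `NonExpressionMask` from [non_expressing_cells()] marking
#'   the cells for which the no-endogenous-expression assumption holds.
#' @param summary Either `"pooled"` (default) or `"median"` of per-cell
#'   estimates.
#' @return A [ContaminationEstimate] with `method = "manual_gene_set"` and
#'   per-cell values populated for the usable cells (global value
#'   elsewhere).
#' @export
estimate_rho_gene_set <- function(cells, soup, gene_set, mask,
                                  summary = c("pooled", "median")) {
  summary <- match.arg(summary)
  stopifnot(inherits(mask, "NonExpressionMask"))
  idx <- match_genes(cells, gene_set)
  B <- sum(soup$fractions[idx])
  if (B == 0) stop("gene set absent from soup")
  usable <- mask$usable[cells$barcodes]
  if (!any(usable)) stop("no cells satisfy m=0 assumption")
  N <- Matrix::colSums(cells$counts)[usable]
  obs <- Matrix::colSums(cells$counts[idx, usable, drop = FALSE])
  ok <- N > 0
  rho_c <- obs[ok] / (N[ok] * B)
  if (any(rho_c > 1)) {
    warning(sum(rho_c > 1), " per-cell estimate(s) exceeded 1; clipped")
    rho_c <- pmin(rho_c, 1)
  }
  rho_global <- switch(summary,
    pooled = sum(obs[ok]) / sum(N[ok] * B),
    median = stats::median(rho_c))
  rho_global <- min(max(rho_global, 0), 1)
  est <- ContaminationEstimate(rho_global, method = "manual_gene_set",
                               cells = cells,
                               n_cells_used = sum(ok))
  est$rho_per_cell[names(rho_c)] <- rho_c
  est
}

# Sample bimodality coefficient (skewness^2 + 1) / kurtosis on population
# moments; 5/9 for the uniform distribution, 1 for any two-point mixture.
bimodality_coefficient <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2
  (skew^2 + 1) / kurt
}

#' Rank soup-rich genes by bimodality for contamination estimation
#'
#' Good genes for estimating contamination are abundant in the soup yet
#' expressed endogenously by only some cells: across cells, their
#' expression relative to the soup is then bimodal, with non-expressing
#' cells clustered near the contamination fraction and expressing cells far
#' above it. This heuristic takes the `top_n` genes by soup fraction,
#' computes per cell `r = log10((n_{g,c}/N_c) / b_g)` (zero counts replaced
#' by the pseudo-fraction `0.1/N_c`) and scores the bimodality of `r` by
#' the sample bimodality coefficient `(skewness^2 + 1)/kurtosis` (values
#' above 5/9, the uniform-distribution benchmark, suggest bimodality).
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param top_n Number of top soup genes to score (default 500).
#' @return Data frame (`gene`, `symbol`, `soup_fraction`,
#'   `bimodality_score`) sorted by descending score.
#' @export
rank_estimation_genes <- function(cells, soup, top_n = 500) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  if (top_n < 1) stop("top_n must be at least 1")
  b <- soup$fractions
  cand <- order(b, decreasing = TRUE)[seq_len(min(top_n, sum(b > 0)))]
  N <- Matrix::colSums(cells$counts)
  keep_cells <- N > 0
  N <- N[keep_cells]
  score <- vapply(cand, function(g) {
    n_g <- as.numeric(cells$counts[g, keep_cells])
    frac <- ifelse(n_g > 0, n_g / N, 0.1 / N)
    bimodality_coefficient(log10(frac / b[g]))
  }, numeric(1))
  out <- data.frame(gene = cells$gene_ids[cand],
                    symbol = cells$gene_symbols[cand],
                    soup_fraction = unname(b[cand]),
                    bimodality_score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$bimodality_score), , drop = FALSE]
}

# tf-idf marker detection: tf = in-cluster detection rate, idf =
# log(n_cells / n_cells expressing). Detection is soup-aware: a cell
# detects gene g only when its expression rate exceeds the full-soup rate
# (n_{g,c} > N_c * b_g); plain nonzero detection would let contamination
# itself trip the detector for exactly the soup-rich genes of interest.
# Returns data.frame(gene_row, cluster, score) for pairs with
# score >= min_score.
tfidf_markers <- function(cells, clusters, soup, min_score = 1.0) {
  cl <- factor(clusters[cells$barcodes])
  if (anyNA(cl)) stop("cells without cluster assignment")
  N <- Matrix::colSums(cells$counts)
  b <- unname(soup$fractions)
  det <- methods::as(cells$counts, "TsparseMatrix")
  det@x <- as.numeric(det@x > N[det@j + 1L] * b[det@i + 1L])
  det <- Matrix::drop0(methods::as(det, "CsparseMatrix"))
  n_cells <- ncol(det)
  n_expr <- Matrix::rowSums(det)
  idf <- log(n_cells / pmax(n_expr, 1))
  res <- list()
  for (k in levels(cl)) {
    in_k <- cl == k
    tf <- Matrix::rowSums(det[, in_k, drop = FALSE]) / sum(in_k)
    score <- tf * idf
    hit <- which(score >= min_score & n_expr > 0)
    if (length(hit))
      res[[k]] <- data.frame(gene_row = hit, cluster = k,
                             score = score[hit], stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(gene_row = integer(0), cluster = character(0),
                      score = numeric(0)))
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Automated contamination-fraction estimation from cluster markers
#'
#' When no negative-marker gene set is known a priori, strong cluster
#' markers stand in for one: a gene that marks cluster `k` can be assumed
#' endogenously silent (`m = 0`) in cells of all other clusters, after the
#' Poisson exclusion of [non_expressing_cells()] removes clusters with
#' evidence of genuine expression. Each marker thus yields an independent
#' estimate of the contamination fraction. Inaccurate estimates have no
#' preferred value while accurate ones concentrate at the truth, so the
#' most common value — the mode of a weighted kernel density over the
#' per-marker estimates (weights proportional to each marker's soup
#' counts; Gaussian kernel, Silverman bandwidth, argmax on a 512-point grid
#' over `[0, 1]`) — is returned as the global estimate.
#'
#' Markers are found by tf-idf specificity (tf = fraction of the cluster's
#' cells detecting the gene; idf = log inverse fraction of all cells
#' detecting it; a cell counts as detecting a gene only when its
#' expression rate exceeds the gene's rate in pure soup, so contamination
#' cannot masquerade as detection) and must also be detectable in the soup (soup fraction at
#' or above the `soup_quantile` quantile of nonzero soup fractions), since
#' a marker absent from the soup carries no information about
#' contamination.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param clusters Named vector mapping barcode to cluster label; at least
#'   2 clusters are required.
#' @param tfidf_min Minimum tf-idf score for a (gene, cluster) marker pair
#'   (default 1.0).
#' @param soup_quantile Quantile of nonzero soup fractions a marker must
#'   reach (default 0.90).
#' @param fdr FDR for the Poisson endogenous-expression exclusion
#'   (default 0.05).
#' @return A [ContaminationEstimate] with `method = "automated"` and the
#'   per-marker estimate table retained.
#' @export
auto_estimate_rho <- function(cells, soup, clusters, tfidf_min = 1.0,
                              soup_quantile = 0.90, fdr = 0.05) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  cl <- clusters[cells$barcodes]
  if (anyNA(cl)) stop("cells without cluster assignment")
  if (length(unique(cl)) < 2) stop("at least 2 clusters are required")
  markers <- tfidf_markers(cells, clusters, soup, min_score = tfidf_min)
  b <- soup$fractions
  soup_min <- stats::quantile(b[b > 0], soup_quantile)
  markers <- markers[b[markers$gene_row] >= soup_min, , drop = FALSE]
  if (!nrow(markers))
    stop("no marker passes the tf-idf and soup-abundance filters; ",
         "consider estimate_rho_gene_set() with a manual gene set")
  N <- Matrix::colSums(cells$counts)
  est_rows <- list()
  for (g in unique(markers$gene_row)) {
    marker_cl <- markers$cluster[markers$gene_row == g]
    gene_name <- cells$gene_ids[g]
    mask <- non_expressing_cells(cells, soup, gene_name,
                                 clusters = clusters, fdr = fdr)
    use <- mask$usable[cells$barcodes] & !(cl %in% marker_cl) & N > 0
    if (!any(use)) next
    obs <- as.numeric(cells$counts[g, use])
    denom <- sum(N[use]) * b[g]
    est_rows[[length(est_rows) + 1L]] <- data.frame(
      gene = gene_name,
      clusters_used = paste(sort(unique(cl[use])), collapse = ","),
      estimate = sum(obs) / denom,
      weight = unname(soup$counts[g]),
      n_cells = sum(use),
      stringsAsFactors = FALSE)
  }
  if (!length(est_rows))
    stop("no marker retains usable m=0 cells after Poisson exclusion; ",
         "consider estimate_rho_gene_set() with a manual gene set")
  tab <- do.call(rbind, c(est_rows, make.row.names = FALSE))
  if (all(tab$estimate == 0)) {
    warning("all per-marker estimates are 0; returning 0")
    rho <- 0
  } else {
    rho <- density_mode(tab$estimate, tab$weight)
  }
  est <- ContaminationEstimate(min(max(rho, 0), 1), method = "automated",
                               cells = cells,
                               per_marker_estimates = tab,
                               n_cells_used = ncol(cells$counts))
  est
}

# Mode of a weighted Gaussian KDE (Silverman bandwidth computed on the
# unweighted sample), argmax over a 512-point grid on [0, 1].
density_mode <- function(x, w) {
  if (length(x) == 1L) return(x)
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(stats::median(x))
  d <- suppressWarnings(
    stats::density(x, weights = w / sum(w), bw = bw, n = 512,
                   from = 0, to = 1))
  d$x[which.max(d$y)]
}
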