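#' Expected soup counts per gene and cell
#'
#' Under a channel-wide ambient profile, the expected number of
#' contaminating counts of gene `g` in cell `c` is `N_c * rho_c * b_g`:
#' the cell's soup UMIs spread over genes in soup proportions.
#'
#' @param cell_totals Numeric vector of per-cell total UMIs `N_c`.
#' @param rho Per-cell contamination fractions (scalar recycled).
#' @param soup A `SoupProfile`.
#' @return Dense genes x cells matrix of expected soup counts.
#' @export
expected_soup_counts <- function(cell_totals, rho, soup) {
  stopifnot(inherits(soup, "SoupProfile"))
  rho <- rep_len(rho, length(cell_totals))
  if (any(rho < 0)) stop("negative contamination fraction")
  outer(unname(soup$fractions), cell_totals * rho)
}

#' Naive soup subtraction
#'
#' Subtracts the expected soup counts from the observed counts:
#' `m = n - N_c * rho_c * b_g`, clipped at zero by default. Fast and
#' intuitive, but it can leave spurious residuals on genes whose observed
#' count is below expectation (the deficit is never reallocated); prefer
#' [correct_counts()], which removes exactly the targeted total per cell.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param rho A [ContaminationEstimate], scalar, or per-cell vector.
#' @param soup A `SoupProfile`.
#' @param clip Truncate negative corrected values at 0 (default `TRUE`).
#' @return Genes x cells matrix of corrected counts: sparse `dgCMatrix`
#'   when `clip = TRUE` (zero entries stay zero), dense otherwise.
#' @export
subtract_naive <- function(cells, rho, soup, clip = TRUE) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  rho_c <- rho_vector(rho, cells)
  N <- Matrix::colSums(cells$counts)
  b <- unname(soup$fractions)
  if (clip) {
    m <- methods::as(cells$counts, "TsparseMatrix")
    m@x <- pmax(m@x - N[m@j + 1L] * rho_c[m@j + 1L] * b[m@i + 1L], 0)
    out <- methods::as(m, "CsparseMatrix")
    dimnames(out) <- list(cells$gene_ids, cells$barcodes)
    return(Matrix::drop0(out))
  }
  out <- as.matrix(cells$counts) -
    expected_soup_counts(N, rho_c, soup)
  dimnames(out) <- list(cells$gene_ids, cells$barcodes)
  out
}

# Vectorised inverse digamma (Newton from the standard initial guess).
invpsi <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y + 0.5772156649))
  for (i in 1:8) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

# Capped "water-filling" removal of `target` counts from a unit with
# observed counts n and soup composition b: the continuous maximiser of the
# multinomial removal log-likelihood sum_g (o_g log b_g - lgamma(o_g + 1))
# subject to 0 <= o_g <= n_g (genes absent from the soup keep o_g = 0) and
# sum_g o_g = target. The KKT conditions give o_g = invpsi(log b_g - mu) - 1
# clamped to [0, n_g] for a common level mu, found by bisection; the water
# level rises until the target is met, with abundant-in-soup genes filling
# first and genes capping out at their observed counts. Within Stirling
# accuracy (about half a count per gene) this coincides with proportional
# allocation o_g = target * b_g / sum(b), i.e. plain model subtraction, and
# it stays within one count per gene of the exact integer optimum.
water_fill <- function(n, b, target) {
  o <- numeric(length(n))
  active <- b > 0 & n > 0
  removable <- sum(n[active])
  if (removable < target)
    return(list(removed = { o[active] <- n[active]; o },
                infeasible = TRUE))
  if (removable == target) {
    o[active] <- n[active]
    return(list(removed = o, infeasible = FALSE))
  }
  if (target <= 0) return(list(removed = o, infeasible = FALSE))
  lb <- log(b[active])
  nn <- n[active]
  alloc <- function(mu) pmin(pmax(invpsi(lb - mu) - 1, 0), nn)
  lo <- -50; hi <- 50   # mu bracket; alloc is decreasing in mu
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (sum(alloc(mid)) > target) lo <- mid else hi <- mid
  }
  oa <- alloc((lo + hi) / 2)
  # close the bisection residual exactly on the interior (uncapped) genes
  interior <- oa > 0 & oa < nn
  if (any(interior)) {
    rest <- sum(oa[!interior])
    oa[interior] <- oa[interior] * (target - rest) / sum(oa[interior])
  }
  o[active] <- oa
  list(removed = o, infeasible = FALSE)
}

#' Remove the soup contribution from each cell
#'
#' The main correction step. For each correction unit (a cluster when
#' cluster assignments are given, otherwise a single cell) the targeted
#' number of soup counts `T_u = round(rho * N_u)` is removed from the
#' unit's aggregated counts by capped water-filling over the soup profile:
#' the allocation maximising the multinomial likelihood of the removed
#' counts under the soup composition, subject to never removing more of a
#' gene than was observed (equal to proportional subtraction of
#' `target * b_g` up to Stirling accuracy when no cap binds). Working at cluster
#' level pools sparse per-cell counts so that contamination and genuine
#' low-level expression can be told apart. Cluster-level removals are then
#' distributed back to member cells per gene, in proportion to each cell's
#' observed counts of that gene — cells observing more of a contaminated
#' gene give up proportionally more, and no cell can lose counts it never
#' had.
#'
#' @param cells A [DropletMatrix] of cells.
#' @param soup A `SoupProfile`.
#' @param rho A [ContaminationEstimate], scalar, or per-cell vector in
#'   `[0, 1]`.
#' @param clusters Optional named barcode-to-cluster vector covering all
#'   cells.
#' @param round_to_int Return integer counts via seeded stochastic rounding
#'   that preserves each unit's removed total (default `FALSE`: fractional
#'   output).
#' @param seed Seed for the stochastic rounding (unused otherwise).
#' @return An object of class `CorrectionResult`: list with sparse
#'   `corrected` and `removed` matrices (`corrected + removed` equals the
#'   input exactly), `target_removed_per_cell`, per-unit `target_removed`,
#'   and `infeasible_cells` (cells of units whose soup-supported counts
#'   fell short of the target; there, everything removable was removed).
#' @export
correct_counts <- function(cells, soup, rho, clusters = NULL,
                           round_to_int = FALSE, seed = 1L) {
  stopifnot(inherits(cells, "DropletMatrix"), inherits(soup, "SoupProfile"))
  rho_c <- rho_vector(rho, cells)
  b <- unname(soup$fractions)
  if (length(b) != nrow(cells$counts))
    stop("soup profile and matrix cover different gene sets")
  N <- Matrix::colSums(cells$counts)
  if (is.null(clusters)) {
    unit_of <- seq_len(ncol(cells$counts))
    names(unit_of) <- cells$barcodes
  } else {
    unit_of <- clusters[cells$barcodes]
    if (anyNA(unit_of))
      stop("cells without cluster assignment: ",
           paste(utils::head(cells$barcodes[is.na(unit_of)], 5),
                 collapse = ", "))
  }
  units <- split(seq_len(ncol(cells$counts)), unit_of)
  trip <- methods::as(cells$counts, "TsparseMatrix")
  entries_by_col <- split(seq_along(trip@x), trip@j + 1L)

  rem_i <- integer(0); rem_j <- integer(0); rem_x <- numeric(0)
  infeasible_cells <- character(0)
  target_unit <- stats::setNames(numeric(length(units)), names(units))
  do_round <- isTRUE(round_to_int)

  body <- function() {
    for (u in seq_along(units)) {
      cols <- units[[u]]
      target <- round_half_up(sum(rho_c[cols] * N[cols]))
      target_unit[u] <<- target
      if (target <= 0) next
      eidx <- unlist(entries_by_col[as.character(cols)], use.names = FALSE)
      if (is.null(eidx) || !length(eidx)) next
      n_u <- numeric(nrow(cells$counts))
      agg <- tapply(trip@x[eidx], trip@i[eidx], sum)
      n_u[as.integer(names(agg)) + 1L] <- agg
      wf <- water_fill(n_u, b, target)
      if (wf$infeasible)
        infeasible_cells <<- c(infeasible_cells, cells$barcodes[cols])
      o_u <- wf$removed
      gi <- trip@i[eidx] + 1L
      scale <- ifelse(n_u[gi] > 0, o_u[gi] / n_u[gi], 0)
      o_e <- trip@x[eidx] * scale
      if (do_round) {
        tot <- if (wf$infeasible) sum(o_u) else target
        o_e <- stochastic_round_total(o_e, tot, trip@x[eidx])
      }
      keep <- o_e > 0
      rem_i <<- c(rem_i, trip@i[eidx][keep])
      rem_j <<- c(rem_j, trip@j[eidx][keep])
      rem_x <<- c(rem_x, o_e[keep])
    }
  }
  if (do_round) with_seed(seed, body()) else body()

  removed <- Matrix::sparseMatrix(i = rem_i + 1L, j = rem_j + 1L, x = rem_x,
                                  dims = dim(cells$counts),
                                  dimnames = list(cells$gene_ids,
                                                  cells$barcodes))
  corrected <- Matrix::drop0(cells$counts - removed)
  structure(list(
    corrected = corrected,
    removed = removed,
    gene_ids = cells$gene_ids,
    gene_symbols = cells$gene_symbols,
    barcodes = cells$barcodes,
    target_removed_per_cell = stats::setNames(rho_c * N, cells$barcodes),
    target_removed = target_unit,
    infeasible_cells = infeasible_cells
  ), class = "CorrectionResult")
}

# Round fractional removals o to integers preserving sum(o) == total:
# floor everything, then hand out the remaining counts by weighted
# sampling without replacement on the fractional parts. caps are the
# observed entry counts (never exceeded, since o <= cap and caps are
# integral).
stochastic_round_total <- function(o, total, caps) {
  fl <- floor(o)
  extra <- round_half_up(total - sum(fl))
  if (extra <= 0) return(fl)
  frac <- o - fl
  pool <- which(frac > 1e-12 & fl + 1 <= caps)
  if (length(pool) < extra) {
    pool <- which(fl + 1 <= caps)
    frac[frac <= 1e-12] <- 1e-12
  }
  pick <- if (length(pool) == 1L) pool else
    sample(pool, extra, prob = frac[pool])
  fl[pick] <- fl[pick] + 1
  fl
}

#' @export
print.CorrectionResult <- function(x, ...) {
  tot <- sum(x$corrected) + sum(x$removed)
  cat("CorrectionResult: ", nrow(x$corrected), " genes x ",
      ncol(x$corrected), " cells; removed ", round(sum(x$removed), 1),
      " of ", round(tot), " counts (",
      sprintf("%.2f%%", 100 * sum(x$removed) / max(tot, 1)), ")\n",
      sep = "")
  if (length(x$infeasible_cells))
    cat("  ", length(x$infeasible_cells),
        " cell(s) could not meet the removal target\n", sep = "")
  invisible(x)
}

#' Convert a CorrectionResult to a DropletMatrix
#'
#' Only possible for integer corrected counts (use
#' `round_to_int = TRUE` in [correct_counts()], or round yourself).
#'
#' @param x A `CorrectionResult`.
#' @return A [DropletMatrix] of the corrected counts.
#' @export
corrected_matrix <- function(x) {
  stopifnot(inherits(x, "CorrectionResult"))
  DropletMatrix(x$corrected, x$gene_ids, x$gene_symbols, x$barcodes)
}

#' Summaries of removed counts
#'
#' @param result A `CorrectionResult`.
#' @return List with `per_gene` (data frame: gene, symbol, total_before,
#'   total_removed, fraction_removed; 0/0 reported as 0), `per_cell`
#'   (named vector: fraction of each cell's counts removed) and `global`
#'   (total removed / total counts — the effective contamination removed).
#' @export
removal_summary <- function(result) {
  stopifnot(inherits(result, "CorrectionResult"))
  before_g <- Matrix::rowSums(result$corrected) +
    Matrix::rowSums(result$removed)
  rem_g <- Matrix::rowSums(result$removed)
  before_c <- Matrix::colSums(result$corrected) +
    Matrix::colSums(result$removed)
  rem_c <- Matrix::colSums(result$removed)
  list(
    per_gene = data.frame(
      gene = result$gene_ids,
      symbol = result$gene_symbols,
      total_before = unname(before_g),
      total_removed = unname(rem_g),
      fraction_removed = unname(ifelse(before_g > 0, rem_g / before_g, 0)),
      stringsAsFactors = FALSE),
    per_cell = stats::setNames(
      ifelse(before_c > 0, rem_c / before_c, 0), result$barcodes),
    global = sum(rem_c) / max(sum(before_c), 1)
  )
}
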