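#' Construct a DropletMatrix
#'
#' A `DropletMatrix` is the package's core container: a sparse genes x
#' droplets UMI count matrix together with gene identifiers, display symbols
#' and droplet barcodes. A "raw" matrix includes empty droplets; a "filtered"
#' matrix contains only droplets called as cells.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer UMI counts,
#'   genes in rows, droplets in columns.
#' @param gene_ids Character vector of unique gene identifiers (one per row).
#' @param gene_symbols Character vector of display symbols (may contain
#'   duplicates). Defaults to `gene_ids`.
#' @param barcodes Character vector of unique droplet barcodes (one per
#'   column).
#'
#' @return An object of class `DropletMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `gene_symbols` and `barcodes`.
#' @export
DropletMatrix <- function(counts, gene_ids, gene_symbols = gene_ids,
                          barcodes) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  gene_ids <- as.character(gene_ids)
  gene_symbols <- as.character(gene_symbols)
  barcodes <- as.character(barcodes)
  obj <- structure(
    list(counts = counts, gene_ids = gene_ids,
         gene_symbols = gene_symbols, barcodes = barcodes),
    class = "DropletMatrix"
  )
  validate_droplet_matrix(obj)
  rownames(obj$counts) <- gene_ids
  colnames(obj$counts) <- barcodes
  obj
}

validate_droplet_matrix <- function(x) {
  stopifnot(inherits(x, "DropletMatrix"))
  cnt <- x$counts
  if (length(x$gene_ids) != nrow(cnt))
    stop("gene_ids length (", length(x$gene_ids),
         ") does not match row count (", nrow(cnt), ")")
  if (length(x$gene_symbols) != nrow(cnt))
    stop("gene_symbols length does not match row count")
  if (length(x$barcodes) != ncol(cnt))
    stop("barcodes length (", length(x$barcodes),
         ") does not match column count (", ncol(cnt), ")")
  if (anyDuplicated(x$gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", "))
  if (anyDuplicated(x$barcodes))
    stop("duplicate barcodes: ",
         paste(unique(x$barcodes[duplicated(x$barcodes)]), collapse = ", "))
  v <- cnt@x
  if (length(v)) {
    if (any(v < 0)) stop("negative counts are not allowed")
    if (any(v != floor(v))) stop("non-integer counts are not allowed")
  }
  invisible(x)
}

#' @export
print.DropletMatrix <- function(x, ...) {
  cat("DropletMatrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " droplets, ", sum(x$counts), " total UMIs (",
      length(x$counts@x), " nonzero entries)\n", sep = "")
  invisible(x)
}

#' @export
dim.DropletMatrix <- function(x) dim(x$counts)

#' Subset a DropletMatrix by droplet barcode
#'
#' @param x A `DropletMatrix`.
#' @param barcodes Character vector of barcodes to keep (order preserved).
#' @return A `DropletMatrix` restricted to the requested droplets.
#' @export
subset_droplets <- function(x, barcodes) {
  idx <- match(barcodes, x$barcodes)
  if (anyNA(idx))
    stop("unknown barcodes: ",
         paste(utils::head(barcodes[is.na(idx)], 5), collapse = ", "))
  DropletMatrix(x$counts[, idx, drop = FALSE], x$gene_ids,
                x$gene_symbols, x$barcodes[idx])
}

#' Per-droplet total UMI counts
#'
#' @param x A `DropletMatrix`.
#' @return Named numeric vector of column sums (one per droplet).
#' @export
droplet_totals <- function(x) {
  tot <- Matrix::colSums(x$counts)
  names(tot) <- x$barcodes
  tot
}

#' Resolve gene symbols or ids to row indices
#'
#' Matching follows 10x conventions: a query matches on display symbol first
#' and falls back to gene id. An ambiguous symbol selects all matching rows
#' (with a message), since distinct Ensembl ids can share a symbol.
#'
#' @param x A `DropletMatrix`.
#' @param genes Character vector of symbols or ids.
#' @return Integer vector of row indices (deduplicated, in query order).
#' @export
match_genes <- function(x, genes) {
  idx <- integer(0)
  missing <- character(0)
  for (g in genes) {
    hit <- which(x$gene_symbols == g)
    if (!length(hit)) hit <- which(x$gene_ids == g)
    if (!length(hit)) {
      missing <- c(missing, g)
      next
    }
    if (length(hit) > 1L)
      message("gene symbol '", g, "' matches ", length(hit),
              " rows; using all")
    idx <- c(idx, hit)
  }
  if (length(missing))
    warning("genes not found in matrix: ", paste(missing, collapse = ", "))
  unique(idx)
}
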