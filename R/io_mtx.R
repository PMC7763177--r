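#' Read a 10x-style MatrixMarket count directory
#'
#' Expects the CellRanger triplet layout: `matrix.mtx[.gz]`,
#' `barcodes.tsv[.gz]` and `features.tsv[.gz]` (or the older
#' `genes.tsv[.gz]`). Both 2-column (id, symbol) and 3-column
#' (id, symbol, type) feature files are accepted.
#'
#' @param path Directory containing the three files.
#' @return A [DropletMatrix] with rows ordered as in the features file and
#'   columns as in the barcodes file.
#' @export
read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("malformed 10x directory: '", path,
                              "' does not exist")
  find1 <- function(names) {
    for (nm in names) {
      f <- file.path(path, nm)
      if (file.exists(f)) return(f)
    }
    NULL
  }
  mtx <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  bcs <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  fts <- find1(c("features.tsv", "features.tsv.gz",
                 "genes.tsv", "genes.tsv.gz"))
  if (is.null(mtx) || is.null(bcs) || is.null(fts))
    stop("malformed 10x directory: '", path, "' must contain matrix.mtx[.gz]",
         ", barcodes.tsv[.gz] and features.tsv[.gz] or genes.tsv[.gz]")

  m <- if (grepl("\\.gz$", mtx)) Matrix::readMM(gzfile(mtx)) else
    Matrix::readMM(mtx)
  if (length(m@x) && any(m@x != floor(m@x)))
    stop("non-integer values in ", mtx)

  read_tsv_plain <- function(f) {
    con <- if (grepl("\\.gz$", f)) gzfile(f) else file(f)
    on.exit(close(con), add = TRUE)
    readLines(con)
  }
  barcodes <- read_tsv_plain(bcs)
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in ", bcs, ": ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  feat_lines <- read_tsv_plain(fts)
  feat <- do.call(rbind, strsplit(feat_lines, "\t", fixed = TRUE))
  if (ncol(feat) < 1L) stop("malformed features file: ", fts)
  gene_ids <- feat[, 1]
  gene_symbols <- if (ncol(feat) >= 2L) feat[, 2] else feat[, 1]

  DropletMatrix(m, gene_ids, gene_symbols, barcodes)
}

# Minimal MatrixMarket coordinate writer. Matrix::writeMM cannot be used
# here: it picks a "symmetric" header for square matrices (10x readers
# expect "general") and offers no control over integer vs real fields.
write_mm_coordinate <- function(m, path, integer_field) {
  m <- methods::as(m, "TsparseMatrix")
  field <- if (integer_field) "integer" else "real"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    paste("%%MatrixMarket matrix coordinate", field, "general"),
    paste(nrow(m), ncol(m), length(m@x))
  ), con)
  if (length(m@x)) {
    val <- if (integer_field) format(as.integer(round(m@x)),
                                     scientific = FALSE, trim = TRUE)
           else format(m@x, digits = 15, scientific = FALSE, trim = TRUE)
    writeLines(paste(m@i + 1L, m@j + 1L, val), con)
  }
  invisible(path)
}

#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' Emits `matrix.mtx`, `barcodes.tsv` and a 3-column `features.tsv`
#' (id, symbol, "Gene Expression"). Corrected matrices may carry fractional
#' counts; these are written as a "real" MatrixMarket file unless all stored
#' values are whole numbers, in which case an "integer" file is written.
#'
#' @param m A [DropletMatrix], or a list with the same fields whose `counts`
#'   may be fractional (as produced by [correct_counts()]).
#' @param path Output directory (created if needed).
#' @param gzip Write `.gz`-compressed members (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_mtx_dir <- function(m, path, gzip = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  ext <- if (gzip) ".gz" else ""
  counts <- if (inherits(m, "CorrectionResult")) m$corrected else m$counts
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
  integer_field <- !length(vals) || all(vals == floor(vals))
  write_mm_coordinate(counts, file.path(path, paste0("matrix.mtx", ext)),
                      integer_field)
  wl <- function(lines, f) {
    con <- if (gzip) gzfile(f, "wb") else file(f, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con)
  }
  wl(m$barcodes, file.path(path, paste0("barcodes.tsv", ext)))
  wl(paste(m$gene_ids, m$gene_symbols, "Gene Expression", sep = "\t"),
     file.path(path, paste0("features.tsv", ext)))
  invisible(path)
}

#' Read cluster assignments for the cells of a matrix
#'
#' Reads a two-column TSV (barcode, cluster label), with or without a header
#' line, and restricts it to barcodes present in `cells`. Barcodes in the
#' file but absent from the matrix are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param cells A [DropletMatrix] of cell-containing droplets.
#' @param strict If `TRUE`, every cell barcode must be assigned a cluster;
#'   unassigned cells raise an error.
#' @return Named character vector mapping barcode to cluster label, ordered
#'   as the cells of the matrix (unassigned cells absent in lenient mode).
#' @export
read_clusters <- function(path, cells, strict = FALSE) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("cluster file must have two columns: ", path)
  # tolerate a header row: drop line 1 if its barcode is unknown and looks
  # like a column name
  if (nrow(tab) && !(tab[1, 1] %in% cells$barcodes) &&
      tolower(tab[1, 1]) %in% c("barcode", "cell", "cell_id"))
    tab <- tab[-1, , drop = FALSE]
  if (anyDuplicated(tab[, 1]))
    stop("duplicate barcodes in cluster file: ",
         paste(unique(tab[duplicated(tab[, 1]), 1]), collapse = ", "))
  if (any(!nzchar(tab[, 2]))) stop("empty cluster labels in ", path)
  known <- tab[, 1] %in% cells$barcodes
  if (any(!known))
    warning(sum(!known), " barcode(s) in cluster file absent from matrix ",
            "(e.g. ", tab[which(!known)[1], 1], "); dropped")
  map <- stats::setNames(tab[known, 2], tab[known, 1])
  missing <- setdiff(cells$barcodes, names(map))
  if (strict && length(missing))
    stop("cells without cluster assignment: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10) else "")
  map[intersect(cells$barcodes, names(map))]
}

#' Read a gene-set list
#'
#' One gene symbol (or id) per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of gene names.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
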