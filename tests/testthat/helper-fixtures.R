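# Small builders and independent oracles shared across the suite.

# Hand-built DropletMatrix from a dense integer matrix.
toy_matrix <- function(counts, gene_ids = NULL, barcodes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- paste0("d", seq_len(ncol(counts)))
  DropletMatrix(counts, gene_ids, gene_ids, barcodes)
}

# A SoupProfile with prescribed fractions, bypassing estimation (for unit
# tests that need exact soup compositions).
toy_soup <- function(fractions, total = 1000L) {
  fractions <- fractions / sum(fractions)
  structure(list(
    fractions = fractions,
    counts = fractions * total,
    umi_threshold = 10, inclusive = TRUE,
    total_soup_umis = total, n_droplets_used = 1L
  ), class = "SoupProfile")
}

# Default 4-type channel used by recovery tests.
default_types <- function(n_cells = 500, mean_umis = 2000) {
  per <- diff(c(floor((0:3) * n_cells / 4), n_cells))
  lapply(1:4, function(j)
    cell_type_spec(paste0("type", j), per[j], mean_umis))
}

# Independent oracle for the capped multinomial removal optimum: exhaustive
# enumeration of integer o with sum(o) = target, 0 <= o <= n (b_g = 0 forces
# o_g = 0), maximising sum(o * log(b)) - sum(lgamma(o + 1)).
brute_force_removal <- function(n, b, target) {
  k <- length(n)
  cap <- ifelse(b > 0, n, 0)
  best <- NULL
  best_ll <- -Inf
  rec <- function(i, remaining, acc) {
    if (i == k) {
      if (remaining > cap[k]) return()
      o <- c(acc, remaining)
      ll <- sum(ifelse(o > 0, o * log(b), 0)) - sum(lgamma(o + 1))
      if (ll > best_ll) {
        best_ll <<- ll
        best <<- o
      }
      return()
    }
    for (o_i in 0:min(cap[i], remaining)) rec(i + 1, remaining - o_i,
                                              c(acc, o_i))
  }
  rec(1, target, numeric(0))
  list(removed = best, loglik = best_ll)
}

# Per-cell fraction of counts on the opposite species block.
cross_block_fraction <- function(counts, block_of, type_of) {
  h <- Matrix::colSums(counts[block_of == "human", , drop = FALSE])
  m <- Matrix::colSums(counts[block_of == "mouse", , drop = FALSE])
  tot <- h + m
  ifelse(type_of == "human", m, h) / pmax(tot, 1e-12)
}
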