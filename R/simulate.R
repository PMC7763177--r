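#' Describe a cell type for the channel simulator
#'
#' @param name Cluster label.
#' @param n_cells Number of cells of this type.
#' @param mean_umis Mean total UMIs per cell (log-normal across cells).
#' @param profile Optional gene expression probability vector (length
#'   `n_genes`, sums to 1). When omitted, [simulate_channel()] draws one:
#'   a gamma-sampled background over the shared genes plus a block of
#'   private marker genes carrying `private_weight` of the type's
#'   expression (other types express those genes at exactly 0, giving
#'   ground-truth negative markers).
#' @return A list understood by [simulate_channel()].
#' @export
cell_type_spec <- function(name, n_cells, mean_umis, profile = NULL) {
  stopifnot(n_cells >= 1, mean_umis > 0)
  list(name = as.character(name), n_cells = as.integer(n_cells),
       mean_umis = mean_umis, profile = profile)
}

#' Simulate a droplet channel with known ground truth
#'
#' Generates an observed raw matrix (cells plus empty droplets), the
#' filtered cell subset, cluster labels and a `ChannelTruth` record, under
#' the additive ambient-contamination model: each cell's observed counts
#' are endogenous counts (multinomial draw from its cell-type profile,
#' `round((1-rho) * N_c)` trials) plus soup counts (multinomial draw from
#' the channel soup profile for the remainder). The soup composition is
#' the UMI-weighted mean of the cell-type profiles, reflecting ambient
#' mRNA arising from approximately uniform sampling of the cells in the
#' channel; `soup_distortion > 0` perturbs it to probe robustness to that
#' assumption. Empty droplets are pure soup draws with small uniform
#' totals. Per-cell totals `N_c` are log-normal around each type's mean
#' (sdlog 0.5 by default, matching the order-of-magnitude capture
#' efficiency spread of droplet assays).
#'
#' @param n_genes Number of genes.
#' @param cell_types List of [cell_type_spec()] entries.
#' @param rho True contamination fraction: scalar or one value per cell,
#'   in `[0, 1]`.
#' @param n_empty Number of empty droplets (default 2000).
#' @param empty_umi_range Integer pair: uniform range of empty-droplet
#'   totals (default `c(1, 10)`, below the default soup threshold).
#' @param seed Integer seed; fixes every byte of the output.
#' @param umi_sdlog Log-normal sdlog of per-cell totals (default 0.5).
#' @param n_private Private marker genes per type for generated profiles
#'   (default 10).
#' @param private_weight Expression share of the private block
#'   (default 0.3).
#' @param soup_distortion Dirichlet-style multiplicative noise on the soup
#'   composition (default 0: soup is exactly the weighted profile mean).
#' @return List with `raw` and `filtered` ([DropletMatrix]), `clusters`
#'   (named barcode-to-type vector) and `truth` (class `ChannelTruth`:
#'   `profiles`, `soup_fractions`, `rho_true`, `cell_types`,
#'   `endogenous_counts`, `soup_counts`; endogenous + soup equals the
#'   filtered counts exactly).
#' @export
simulate_channel <- function(n_genes, cell_types, rho, n_empty = 2000,
                             empty_umi_range = c(1, 10), seed = 1L,
                             umi_sdlog = 0.5, n_private = 10,
                             private_weight = 0.3, soup_distortion = 0) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  stopifnot(n_genes >= 2, length(cell_types) >= 1)
  n_cells_total <- sum(vapply(cell_types, `[[`, integer(1), "n_cells"))
  rho <- rep_len(rho, n_cells_total)

  with_seed(seed, {
    k <- length(cell_types)
    need_profiles <- vapply(cell_types, function(ct) is.null(ct$profile),
                            logical(1))
    if (any(need_profiles) && k * n_private >= n_genes)
      stop("n_genes too small for ", k, " x ", n_private, " private genes")
    profiles <- matrix(0, n_genes, k)
    shared <- if (any(need_profiles))
      setdiff(seq_len(n_genes), seq_len(k * n_private)) else seq_len(n_genes)
    for (j in seq_len(k)) {
      ct <- cell_types[[j]]
      if (!is.null(ct$profile)) {
        stopifnot(length(ct$profile) == n_genes,
                  abs(sum(ct$profile) - 1) < 1e-6)
        profiles[, j] <- ct$profile
      } else {
        bg <- stats::rgamma(length(shared), shape = 0.5)
        priv <- seq.int((j - 1L) * n_private + 1L, j * n_private)
        profiles[shared, j] <- bg / sum(bg) * (1 - private_weight)
        pw <- stats::rgamma(n_private, shape = 2)
        profiles[priv, j] <- pw / sum(pw) * private_weight
      }
    }
    type_names <- vapply(cell_types, `[[`, character(1), "name")
    colnames(profiles) <- type_names

    umi_weight <- vapply(cell_types, function(ct) ct$n_cells * ct$mean_umis,
                         numeric(1))
    soup <- as.vector(profiles %*% (umi_weight / sum(umi_weight)))
    if (soup_distortion > 0) {
      soup <- soup * stats::rgamma(n_genes, shape = 1 / soup_distortion,
                                   rate = 1 / soup_distortion)
      soup <- soup / sum(soup)
    }

    type_of <- rep(type_names,
                   vapply(cell_types, `[[`, integer(1), "n_cells"))
    mean_of <- rep(vapply(cell_types, `[[`, numeric(1), "mean_umis"),
                   vapply(cell_types, `[[`, integer(1), "n_cells"))
    N <- pmax(1L, round(stats::rlnorm(n_cells_total,
                                      log(mean_of) - umi_sdlog^2 / 2,
                                      umi_sdlog)))
    endo <- matrix(0L, n_genes, n_cells_total)
    soup_m <- matrix(0L, n_genes, n_cells_total)
    for (c_i in seq_len(n_cells_total)) {
      n_endo <- round_half_up((1 - rho[c_i]) * N[c_i])
      n_soup <- N[c_i] - n_endo
      p <- profiles[, type_of[c_i]]
      if (n_endo > 0) endo[, c_i] <- stats::rmultinom(1, n_endo, p)
      if (n_soup > 0) soup_m[, c_i] <- stats::rmultinom(1, n_soup, soup)
    }
    obs <- endo + soup_m

    empty_tot <- sample(seq.int(empty_umi_range[1], empty_umi_range[2]),
                        n_empty, replace = TRUE)
    empties <- vapply(empty_tot, function(t) stats::rmultinom(1, t, soup)[, 1],
                      integer(n_genes))

    gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
    cell_bc <- sprintf("CELL%05d", seq_len(n_cells_total))
    empty_bc <- sprintf("EMPTY%05d", seq_len(n_empty))

    filtered <- DropletMatrix(obs, gene_ids, gene_ids, cell_bc)
    raw <- DropletMatrix(cbind(obs, empties), gene_ids, gene_ids,
                         c(cell_bc, empty_bc))
    truth <- structure(list(
      profiles = profiles,
      soup_fractions = stats::setNames(soup, gene_ids),
      rho_true = stats::setNames(rho, cell_bc),
      cell_types = stats::setNames(type_of, cell_bc),
      endogenous_counts = `dimnames<-`(endo, list(gene_ids, cell_bc)),
      soup_counts = `dimnames<-`(soup_m, list(gene_ids, cell_bc)),
      private_genes = if (any(need_profiles))
        lapply(stats::setNames(seq_len(k), type_names), function(j)
          gene_ids[seq.int((j - 1L) * n_private + 1L, j * n_private)])
      else NULL
    ), class = "ChannelTruth")
    list(raw = raw, filtered = filtered,
         clusters = stats::setNames(type_of, cell_bc), truth = truth)
  })
}

#' Two-block ("species-mixing" style) fixture with disjoint transcriptomes
#'
#' Emulates a mixed-species experiment: two cell types whose expression
#' profiles occupy disjoint gene blocks, so that every cross-block count
#' observed in a cell is unambiguously ambient contamination. This gives
#' exact per-cell ground truth for validating contamination estimates and
#' correction, as in barnyard human/mouse mixtures.
#'
#' @param n_genes_per_block Genes per species block.
#' @param n_cells_per_block Cells per species.
#' @param rho True contamination fraction (default 0.02, a typical rate
#'   in clean channels).
#' @param seed Integer seed.
#' @param mean_umis Mean UMIs per cell (default 5000).
#' @param n_empty Number of empty droplets (default 2000).
#' @return As [simulate_channel()]; gene ids are prefixed `HUMA`/`MOUS`
#'   by block.
#' @export
species_mix_fixture <- function(n_genes_per_block, n_cells_per_block,
                                rho = 0.02, seed = 1L, mean_umis = 5000,
                                n_empty = 2000) {
  g <- n_genes_per_block
  prof <- with_seed(seed + 1L, {
    p1 <- stats::rgamma(g, shape = 0.7); p1 <- p1 / sum(p1)
    p2 <- stats::rgamma(g, shape = 0.7); p2 <- p2 / sum(p2)
    list(c(p1, numeric(g)), c(numeric(g), p2))
  })
  sim <- simulate_channel(
    n_genes = 2L * g,
    cell_types = list(
      cell_type_spec("human", n_cells_per_block, mean_umis, prof[[1]]),
      cell_type_spec("mouse", n_cells_per_block, mean_umis, prof[[2]])),
    rho = rho, n_empty = n_empty, seed = seed)
  ids <- c(sprintf("HUMA%05d", seq_len(g)), sprintf("MOUS%05d", seq_len(g)))
  relabel <- function(dm) DropletMatrix(dm$counts, ids, ids, dm$barcodes)
  sim$raw <- relabel(sim$raw)
  sim$filtered <- relabel(sim$filtered)
  rownames(sim$truth$endogenous_counts) <- ids
  rownames(sim$truth$soup_counts) <- ids
  names(sim$truth$soup_fractions) <- ids
  rownames(sim$truth$profiles) <- ids
  sim$block_of <- stats::setNames(rep(c("human", "mouse"), each = g), ids)
  sim
}

#' Write a simulated channel to disk as 10x directories plus truth sidecar
#'
#' @param sim Output of [simulate_channel()] or [species_mix_fixture()].
#' @param path Output directory; `raw/` and `filtered/` subdirectories,
#'   `clusters.tsv` and `truth.json` are created inside.
#' @param gzip Gzip the matrix files (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_channel <- function(sim, path, gzip = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_mtx_dir(sim$raw, file.path(path, "raw"), gzip = gzip)
  write_mtx_dir(sim$filtered, file.path(path, "filtered"), gzip = gzip)
  utils::write.table(
    data.frame(barcode = names(sim$clusters), cluster = sim$clusters),
    file.path(path, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(list(
    rho_true = unname(truth$rho_true),
    cell_types = unname(truth$cell_types),
    soup_fractions = unname(truth$soup_fractions),
    total_observed = sum(sim$filtered$counts),
    total_endogenous = sum(truth$endogenous_counts),
    total_soup = sum(truth$soup_counts)
  ), file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
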