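test_that("expected soup counts and naive subtraction follow the model", {
  soup <- toy_soup(c(0.02, 0.98))
  # N=100, rho=0.05, b=0.02 -> expected 0.1
  o <- expected_soup_counts(100, 0.05, soup)
  expect_equal(o[1, 1], 0.1)
  # column sums are N*rho since b sums to 1
  o2 <- expected_soup_counts(c(100, 200), c(0.05, 0.1), soup)
  expect_equal(colSums(o2), c(5, 20))
  expect_equal(expected_soup_counts(c(100, 50), 0, soup),
               matrix(0, 2, 2))
  expect_error(expected_soup_counts(100, -0.1, soup), "negative")

  # n=10, N=100, rho=0.05, b=0.02 -> m = 9.9
  cells <- toy_matrix(matrix(c(10, 90), 2, 1))
  m <- subtract_naive(cells, 0.05, soup)
  expect_equal(m[1, 1], 9.9)
  # clipping never leaves negatives and keeps zeros at zero
  cells2 <- toy_matrix(matrix(c(0, 100), 2, 1))
  m2 <- subtract_naive(cells2, 0.5, soup)
  expect_equal(m2[1, 1], 0)
  expect_true(all(m2 >= 0))
  m3 <- subtract_naive(cells2, 0.5, soup, clip = FALSE)
  expect_equal(m3[1, 1], -1)
})

test_that("water-filling reproduces the hand-executed fixed points", {
  # uncapped symmetric case: equals plain proportional subtraction
  wf <- soupclean:::water_fill(c(10, 10), c(0.5, 0.5), 10)
  expect_equal(wf$removed, c(5, 5))
  expect_false(wf$infeasible)

  # capped case n=(1,19), b=(.5,.5), T=10: cap gene 1 at 1, give 9 to gene 2
  wf2 <- soupclean:::water_fill(c(1, 19), c(0.5, 0.5), 10)
  expect_equal(wf2$removed, c(1, 9))

  # infeasible: soup-supported counts below target
  expect_equal(soupclean:::water_fill(c(2, 0, 3), c(0.5, 0.25, 0.25), 8),
               list(removed = c(2, 0, 3), infeasible = TRUE))

  # genes with b=0 are never touched
  wf4 <- soupclean:::water_fill(c(5, 5), c(1, 0), 3)
  expect_equal(wf4$removed, c(3, 0))
})

test_that("correct_counts matches naive subtraction when no cap binds", {
  soup <- toy_soup(c(0.5, 0.5))
  cells <- toy_matrix(matrix(c(10, 10), 2, 1))
  res <- correct_counts(cells, soup, 0.5)
  expect_equal(as.matrix(res$removed), as.matrix(matrix(c(5, 5), 2, 1)),
               ignore_attr = TRUE)
  expect_equal(as.matrix(res$corrected), matrix(c(5, 5), 2, 1),
               ignore_attr = TRUE)

  # a cell where no gene's expected soup exceeds its observation: agrees
  # with the naive rule to Stirling accuracy (under half a count per gene),
  # with the same total removed
  cells2 <- toy_matrix(matrix(c(40, 30, 30), 3, 1))
  soup2 <- toy_soup(c(0.2, 0.3, 0.5))
  res2 <- correct_counts(cells2, soup2, 0.2)
  naive <- as.matrix(cells2$counts) -
    expected_soup_counts(100, 0.2, soup2)
  expect_lt(max(abs(as.matrix(res2$corrected) - naive)), 0.5)
  expect_equal(sum(res2$removed), 20)
})

test_that("cluster correction redistributes by observed counts", {
  # two cells with identical totals; gene G1 is soup-only and observed in
  # cell 1 alone: its removals must land on cell 1
  cnt <- matrix(c(4, 16, 0, 20), 2, 2)
  cells <- toy_matrix(cnt, barcodes = c("c1", "c2"))
  soup <- toy_soup(c(0.5, 0.5))
  clusters <- c(c1 = "P", c2 = "P")
  res <- correct_counts(cells, soup, 0.1, clusters = clusters)
  expect_equal(res$removed[1, 2], 0)
  expect_gt(res$removed[1, 1], 0)
  # conservation at cluster level: unit removed total equals target
  expect_equal(sum(res$removed), unname(res$target_removed["P"]))
  # no cell loses counts it never had
  expect_true(all(as.matrix(res$corrected) >= 0))
})

test_that("conservation, identity and monotonicity hold on random channels", {
  for (s in 1:50) {
    set.seed(s)
    n_genes <- sample(3:10, 1)
    n_cells <- sample(2:8, 1)
    cnt <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
    cells <- toy_matrix(cnt)
    b <- rgamma(n_genes, 0.5)
    if (s %% 3 == 0) b[sample(n_genes, 1)] <- 0   # soup-absent genes
    if (sum(b) == 0) b[1] <- 1
    soup <- toy_soup(b)
    rho1 <- runif(1, 0, 0.3)
    clusters <- if (s %% 2 == 0)
      setNames(sample(c("P", "Q"), n_cells, TRUE), cells$barcodes)
    else NULL
    res1 <- correct_counts(cells, soup, rho1, clusters = clusters)
    # conservation: corrected + removed == original exactly
    expect_lt(max(abs((res1$corrected + res1$removed) - cells$counts)),
              1e-9)
    # bounds: 0 <= corrected <= original
    expect_true(all(as.matrix(res1$corrected) >= -1e-12))
    expect_true(all(as.matrix(res1$removed) >= -1e-12))
    expect_true(all(as.matrix(res1$corrected) <= cnt + 1e-12))
    # identity at rho = 0
    res0 <- correct_counts(cells, soup, 0, clusters = clusters)
    expect_equal(as.matrix(res0$corrected), as.matrix(cells$counts))
    # monotonicity in rho, per gene within each unit
    rho2 <- min(1, rho1 + runif(1, 0.05, 0.4))
    res2 <- correct_counts(cells, soup, rho2, clusters = clusters)
    unit <- if (is.null(clusters))
      setNames(cells$barcodes, cells$barcodes) else clusters
    for (u in unique(unit)) {
      cols <- names(unit)[unit == u]
      r1 <- Matrix::rowSums(res1$removed[, cols, drop = FALSE])
      r2 <- Matrix::rowSums(res2$removed[, cols, drop = FALSE])
      expect_true(all(r2 - r1 >= -1e-9))
    }
  }
})

test_that("capped removal attains the brute-force multinomial optimum", {
  # small random units: exhaustive enumeration of integer removals
  mismatches <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    k <- sample(2:5, 1)
    n <- rpois(k, 4)
    if (sum(n) == 0) n[1] <- 3
    b <- rgamma(k, 1)
    b <- b / sum(b)
    target <- sample.int(max(sum(n) - 1, 1), 1)
    wf <- soupclean:::water_fill(n, b, target)
    if (wf$infeasible) next
    bf <- brute_force_removal(n, b, target)
    expect_equal(sum(wf$removed), target, tolerance = 1e-9)
    if (any(abs(wf$removed - bf$removed) > 1)) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("infeasible cells are flagged and fully drained", {
  cells <- toy_matrix(matrix(c(2, 50), 2, 1))
  soup <- toy_soup(c(1, 0))   # soup supported on G1 only
  res <- correct_counts(cells, soup, 0.5)   # target 26 > removable 2
  expect_equal(res$infeasible_cells, "d1")
  expect_equal(as.vector(res$removed[, 1]), c(2, 0))
})

test_that("integer rounding preserves unit totals and is seeded", {
  sim <- simulate_channel(100, default_types(60, 500), rho = 0.15,
                          n_empty = 800, seed = 71)
  soup <- estimate_soup(sim$raw)
  res_a <- correct_counts(sim$filtered, soup, 0.15, clusters = sim$clusters,
                          round_to_int = TRUE, seed = 5)
  res_b <- correct_counts(sim$filtered, soup, 0.15, clusters = sim$clusters,
                          round_to_int = TRUE, seed = 5)
  expect_identical(as.matrix(res_a$removed), as.matrix(res_b$removed))
  expect_true(all(res_a$removed@x == floor(res_a$removed@x)))
  expect_true(all(as.matrix(res_a$corrected) >= 0))
  # per-unit removed totals equal the integer targets
  frac <- correct_counts(sim$filtered, soup, 0.15, clusters = sim$clusters)
  for (u in unique(sim$clusters)) {
    cols <- names(sim$clusters)[sim$clusters == u]
    expect_equal(sum(res_a$removed[, cols]), sum(frac$removed[, cols]),
                 tolerance = 1e-9)
  }
})

test_that("removal summaries report the expected fractions", {
  soup <- toy_soup(c(0.5, 0.5))
  cells <- toy_matrix(matrix(c(10, 10, 6, 14), 2, 2))
  res0 <- correct_counts(cells, soup, 0)
  s0 <- removal_summary(res0)
  expect_true(all(s0$per_gene$fraction_removed == 0))
  expect_equal(s0$global, 0)

  res <- correct_counts(cells, soup, 0.2)
  s <- removal_summary(res)
  # uncapped units: per-cell fraction equals rho up to target rounding
  expect_equal(unname(s$per_cell), c(4 / 20, 4 / 20))
  expect_equal(s$global, 0.2)
  expect_equal(s$per_gene$total_before, c(16, 24))
})

test_that("cross-type genes are purged while markers are barely touched", {
  sm <- species_mix_fixture(150, 80, rho = 0.02, seed = 13)
  soup <- estimate_soup(sm$raw)
  res <- correct_counts(sm$filtered, soup, 0.02, clusters = sm$clusters)
  summ <- removal_summary(res)
  blk <- sm$block_of[sm$filtered$gene_ids]
  # per-cell: cross-block genes lose essentially everything
  human_cells <- names(sm$clusters)[sm$clusters == "human"]
  cross_before <- sum(sm$filtered$counts[blk == "mouse", human_cells])
  cross_after <- sum(res$corrected[blk == "mouse", human_cells])
  expect_lt(cross_after, cross_before / 2)
  # marker genes lose only about rho * b_g worth of counts
  own_frac <- summ$per_gene$fraction_removed[blk == "human"]
  tot_h <- summ$per_gene$total_before[blk == "human"]
  expect_lt(median(own_frac[tot_h > 100]), 0.05)
})
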