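# Differential correlation: per-group Pearson matrices, delta-CC, selection

test_that("pathway gene subset is the sorted triple intersection", {
  mat <- toy_matrix(1:12, c("A", "B", "C", "D"), paste0("s", 1:3))
  expect_identical(
    pathway_gene_subset(c("A", "B", "C"), degs = c("B", "C", "D"), mat),
    c("B", "C")
  )
  expect_identical(
    pathway_gene_subset(c("X", "Y"), degs = c("B"), mat), character(0)
  )
  # the 17-gene Wnt DEG list, all measured and all DEGs
  wnt <- wnt_deg_genes()
  big <- toy_matrix(seq_len(3 * length(wnt)), sort(wnt), paste0("s", 1:3))
  expect_identical(pathway_gene_subset(wnt, wnt, big), sort(wnt))
  expect_length(pathway_gene_subset(wnt, wnt, big), 17)
})

test_that("correlation matrix matches the hand formula and its contracts", {
  fx <- pearson_fixture()
  groups_all <- paste0("s", 1:6)
  res <- correlation_matrix(fx$mat, rownames(fx$mat), groups_all)
  expect_equal(res$cc, fx$expected, tolerance = 1e-12)
  # same thing via the written-out formula, entry by entry
  for (i in 1:3) for (j in 1:3) {
    expect_equal(res$cc[i, j],
                 pearson_hand(fx$mat[i, ], fx$mat[j, ]), tolerance = 1e-12)
  }
  expect_true(isSymmetric(res$cc))
  expect_equal(unname(diag(res$cc)), rep(1, 3))
  expect_true(all(abs(res$cc) <= 1 + 1e-12))

  # perfect anticorrelation
  m2 <- toy_matrix(c(1, 2, 3, 4, 8, 6, 4, 2), c("u", "v"), paste0("s", 1:4))
  r2 <- correlation_matrix(m2, c("u", "v"), paste0("s", 1:4))
  expect_equal(r2$cc["u", "v"], -1)

  expect_error(correlation_matrix(fx$mat, rownames(fx$mat), c("s1", "s2")),
               ">= 3 samples")
})

test_that("zero-variance genes are masked, not dropped", {
  mat <- toy_matrix(c(1, 2, 3, 4,
                      5, 5, 5, 5,
                      4, 3, 2, 1), c("A", "flat", "C"), paste0("s", 1:4))
  res <- correlation_matrix(mat, rownames(mat), colnames(mat))
  expect_false(res$mask["A", "flat"])
  expect_true(res$mask["A", "C"])
  expect_true(is.na(res$cc["A", "flat"]))
  expect_false(res$mask["flat", "flat"])
  expect_identical(rownames(res$cc), c("A", "flat", "C"))
})

test_that("correlations are invariant under sample reordering", {
  sim <- small_sim(seed = 9)
  gs <- names(sim$groups)[sim$groups == "cancer"]
  genes <- sprintf("G%04d", 1:6)
  r1 <- correlation_matrix(sim$matrix, genes, gs)
  r2 <- correlation_matrix(sim$matrix, genes, rev(gs))
  expect_equal(r1$cc, r2$cc)
})

test_that("delta-CC matrix is the elementwise difference, bounded in [-2,2]", {
  cc <- diag(3); cc[lower.tri(cc)] <- cc[upper.tri(cc)] <- c(.5, -.2, .9)
  pair <- fake_pair(cc, cc, letters[1:3])
  expect_true(all(delta_cc_matrix(pair)$delta == 0))

  ctl <- matrix(c(1, 0.5, 0.5, 1), 2)
  can <- matrix(c(1, -0.2, -0.2, 1), 2)
  p2 <- fake_pair(ctl, can, c("a", "b"))
  expect_equal(delta_cc_matrix(p2)$delta["a", "b"], -0.7)

  set.seed(1)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    m1 <- stats::cor(matrix(rnorm(n * 10), ncol = n))
    m2 <- stats::cor(matrix(rnorm(n * 10), ncol = n))
    d <- delta_cc_matrix(fake_pair(m1, m2, paste0("g", seq_len(n))))$delta
    expect_true(all(abs(d) <= 2 + 1e-12))
  }

  bad <- fake_pair(diag(2), diag(2), c("a", "b"))
  bad$cc_cancer <- diag(3)
  expect_error(delta_cc_matrix(bad), "shape")
})

test_that("pair selection is boundary-inclusive at the cutoff", {
  ctl <- diag(3)
  can <- diag(3)
  can[1, 2] <- can[2, 1] <- 0.70   # delta exactly 0.70
  can[1, 3] <- can[3, 1] <- 0.69   # just under
  ctl[2, 3] <- ctl[3, 2] <- 0.75
  can[2, 3] <- can[3, 2] <- 0.75   # no shift
  pair <- fake_pair(ctl, can, c("a", "b", "c"))
  rec <- select_shifted_pairs(pair, cutoff = 0.70)
  expect_identical(nrow(rec), 1L)
  expect_identical(c(rec$gene_a, rec$gene_b), c("a", "b"))
  expect_equal(rec$delta_cc, 0.70)
  expect_identical(rec$pathways, "pw")
})

test_that("selection equals a brute-force scan over all pairs", {
  sim <- small_sim(seed = 21, n_control = 20, n_cancer = 60)
  genes <- sprintf("G%04d", 1:6)
  gs <- split(names(sim$groups), sim$groups)
  pair <- corr_matrix_pair(sim$matrix, sim$groups, genes, pathway = "pwA")
  got <- select_shifted_pairs(pair, cutoff = 0.70)

  # oracle: every one of the 15 pairs, correlations via the hand formula
  combos <- utils::combn(genes, 2)
  keep <- character(0)
  for (j in seq_len(ncol(combos))) {
    a <- combos[1, j]; b <- combos[2, j]
    d <- pearson_hand(sim$matrix[a, gs$cancer], sim$matrix[b, gs$cancer]) -
      pearson_hand(sim$matrix[a, gs$control], sim$matrix[b, gs$control])
    if (abs(d) >= 0.70) keep <- c(keep, paste(a, b))
  }
  expect_setequal(paste(got$gene_a, got$gene_b), keep)
  expect_gte(nrow(got), 1)  # the planted 0.9 -> -0.3 flip must show up
})

test_that("lowering the cutoff never removes a selected pair", {
  sim <- small_sim(seed = 33)
  pair <- corr_matrix_pair(sim$matrix, sim$groups, sprintf("G%04d", 1:8),
                           pathway = "pwA")
  hi <- select_shifted_pairs(pair, 0.9)
  lo <- select_shifted_pairs(pair, 0.4)
  expect_true(all(paste(hi$gene_a, hi$gene_b) %in%
                    paste(lo$gene_a, lo$gene_b)))
})

test_that("pathways with fewer than two eligible genes are skipped with a warning", {
  sim <- small_sim(seed = 2)
  sets <- list(good = sprintf("G%04d", 1:5), tiny = "G0001",
               absent = c("NOPE1", "NOPE2"))
  warns <- capture_warnings(
    res <- diffcorr_pathways(sim$matrix, sim$groups, sets,
                             degs = rownames(sim$matrix))
  )
  expect_length(warns, 2)
  expect_match(warns, "tiny", all = FALSE)
  expect_match(warns, "absent", all = FALSE)
  expect_named(res$matrices, "good")
})

test_that("selection is invariant to gene order within the pathway", {
  sim <- small_sim(seed = 13)
  genes <- sprintf("G%04d", 1:6)
  degs <- rownames(sim$matrix)
  r1 <- diffcorr_pathways(sim$matrix, sim$groups, list(p = genes), degs)
  r2 <- diffcorr_pathways(sim$matrix, sim$groups, list(p = rev(genes)),
                          degs)
  expect_equal(r1$records, r2$records)
})
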