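# Synthetic data: determinism, planted-effect recovery, validation

test_that("the same configuration and seed reproduce the dataset exactly", {
  s1 <- small_sim(seed = 99)
  s2 <- small_sim(seed = 99)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$groups, s2$groups)
  s3 <- small_sim(seed = 100)
  expect_false(identical(s1$matrix, s3$matrix))
})

test_that("values are valid FPKM-like abundances", {
  sim <- small_sim(seed = 3)
  expect_true(all(sim$matrix >= 0))
  expect_true(all(is.finite(sim$matrix)))
  expect_silent(validate_expression_matrix(sim$matrix))
  expect_identical(sum(sim$groups == "control"), 10L)
  expect_identical(sum(sim$groups == "cancer"), 30L)
})

test_that("planted correlations converge to target at n = 2000 per group", {
  cfg <- simulation_config(
    n_control = 2000, n_cancer = 2000, n_genes = 4,
    planted_pairs = data.frame(gene_a = "G0001", gene_b = "G0002",
                               rho_control = 0.8, rho_cancer = -0.2),
    seed = 17
  )
  sim <- simulate_dataset(cfg)
  gs <- split(names(sim$groups), sim$groups)
  r_ctl <- cor(sim$matrix["G0001", gs$control],
               sim$matrix["G0002", gs$control])
  r_can <- cor(sim$matrix["G0001", gs$cancer],
               sim$matrix["G0002", gs$cancer])
  # raw-space correlation is slightly attenuated by the lognormal
  # transform; +/-0.05 absorbs that plus sampling noise
  expect_lt(abs(r_ctl - 0.8), 0.05)
  expect_lt(abs(r_can - (-0.2)), 0.05)
  # an unplanted pair stays near zero
  r_null <- cor(sim$matrix["G0003", gs$control],
                sim$matrix["G0004", gs$control])
  expect_lt(abs(r_null), 0.1)
})

test_that("a planted 3-log2-unit shift is recovered and flagged as up", {
  cfg <- simulation_config(
    n_genes = 50,
    planted_degs = data.frame(gene = "G0007", delta = 3),
    seed = 23
  )
  sim <- simulate_dataset(cfg)
  tab <- deg_table(sim$matrix, sim$groups)
  hit <- tab[tab$gene_id == "G0007", ]
  expect_equal(hit$log2fc, 3, tolerance = 0.2)
  expect_identical(hit$direction, "up")
})

test_that("at low noise every planted fold change is recovered within 0.2", {
  deltas <- c(3, 4.5, -3, -6, 8, -8, 2.6, -2.6)
  pd <- data.frame(gene = sprintf("G%04d", seq_along(deltas)),
                   delta = deltas,
                   baseline = ifelse(deltas < 0, 3.5 - deltas, 5))
  cfg <- simulation_config(n_genes = 20, planted_degs = pd,
                           noise_sd = 0.1, seed = 31)
  sim <- simulate_dataset(cfg)
  lfc <- compute_log2fc(sim$matrix, sim$groups)
  expect_true(all(abs(lfc[pd$gene] - deltas) <= 0.2))
})

test_that("invalid planted structure is rejected with the offending block named", {
  expect_error(
    simulation_config(n_genes = 4, planted_pairs = data.frame(
      gene_a = "G0001", gene_b = "G0002",
      rho_control = 1.0, rho_cancer = 0)),
    "G0001-G0002"
  )
  expect_error(
    simulation_config(n_genes = 6, planted_pairs = data.frame(
      gene_a = c("G0001", "G0002"), gene_b = c("G0002", "G0003"),
      rho_control = c(0.5, 0.5), rho_cancer = c(0, 0))),
    "overlapping.*G0002"
  )
  expect_error(
    simulation_config(n_genes = 4, planted_degs = data.frame(
      gene = "G9999", delta = 3)),
    "G9999"
  )
  expect_error(simulation_config(n_control = 2), "n_control")
})

test_that("the cohort-scale fixture has the stated shape", {
  fx <- make_paper_shaped_fixture(seed = 4)
  expect_identical(sum(fx$groups == "control"), 41L)
  expect_identical(sum(fx$groups == "cancer"), 471L)
  expect_identical(nrow(fx$matrix), 2000L)
  expect_length(fx$pathways, 10)
  expect_identical(unname(lengths(fx$pathways)),
                   c(275L, 126L, 258L, 329L, 72L, 140L, 144L, 73L, 67L,
                     135L))
  truth <- fx$ground_truth
  expect_gte(sum(abs(truth$log2fc) >= 2.5), 40)
  expect_gte(sum(abs(truth$pairs$delta_rho) >= 0.7), 10)
  # planted pairs live inside pathways, among planted DEGs
  pw_members <- unlist(fx$pathways, use.names = FALSE)
  expect_true(all(c(truth$pairs$gene_a, truth$pairs$gene_b) %in%
                    pw_members))
})

test_that("a null cohort yields zero DEGs at the standard cutoffs", {
  # specificity over 20 seeds; scaled to 500 genes to keep the suite fast
  # (the DEG test is per-gene, so gene count only affects runtime)
  n_fail <- 0L
  for (seed in 1:20) {
    cfg <- simulation_config(n_genes = 500, seed = seed)
    sim <- simulate_dataset(cfg)
    tab <- deg_table(sim$matrix, sim$groups)
    if (any(tab$direction != "none")) n_fail <- n_fail + 1L
  }
  expect_lte(n_fail, 1L)  # >= 95% of seeds fully clean
})

test_that("write_dataset emits the standard files and round-trips", {
  sim <- small_sim(seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("expression.tsv", "samples.tsv", "sets.gmt",
           "ground_truth.tsv")))))
  back <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(back, sim$matrix, tolerance = 1e-12)
  groups <- read_sample_sheet(file.path(dir, "samples.tsv"), back)
  expect_identical(groups, sim$groups)
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_identical(lapply(sets, `[[`, "genes"), sim$pathways)
})
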