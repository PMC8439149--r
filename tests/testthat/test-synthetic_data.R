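small_cfg <- function(seed = 1, ...) {
  sim_config(n_lines = 8L, n_mice = 3L, read_depth = 5e4, n_pre = 2L,
             seed = seed, ...)
}

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_experiment(small_cfg(7))
  b <- simulate_experiment(small_cfg(7))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$true_log10_potential, b$truth$true_log10_potential)
  expect_identical(a$library$sequence, b$library$sequence)
  c <- simulate_experiment(small_cfg(8))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("simulated counts and compositions satisfy the accounting identities", {
  sim <- simulate_experiment(small_cfg(3))
  # every non-empty sample sequenced to the configured depth; a mouse organ
  # in which no line seeded yields an all-zero column
  comp <- sim$truth$compositions
  ok <- colSums(is.na(comp)) == 0
  tot <- colSums(sim$counts$counts)
  expect_true(all(tot[colnames(comp)[ok]] == 5e4))
  expect_true(all(tot[colnames(comp)[!ok]] == 0))
  expect_true(all(tot[setdiff(names(tot), colnames(comp))] == 5e4))  # pre
  # realized compositions lie on the simplex
  expect_equal(unname(colSums(comp[, ok, drop = FALSE])), rep(1, sum(ok)),
               tolerance = 1e-9)
  # cell-count table rows match the organ samples
  meta <- sim$counts$samples
  expect_equal(nrow(sim$cell_counts), sum(meta$organ != "pre_injection"))
  # realized cells are consistent with the truth array
  expect_equal(sim$cell_counts$total_cells[1],
               sum(sim$truth$cells[, meta$organ[1], 1]))
})

test_that("a single fully-penetrant line owns every organ composition", {
  cfg <- sim_config(n_lines = 1L, n_mice = 2L, read_depth = 1e4, n_pre = 1L,
                    true_log10_potential = matrix(0, 1, 5),
                    penetrance_prob = matrix(1, 1, 5), seed = 4)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$compositions == 1))
  expect_true(all(colSums(sim$counts$counts) == 1e4))
})

test_that("the overdispersion parameter exposes the multinomial limit", {
  set.seed(55)
  p <- c(0.5, 0.3, 0.15, 0.05)
  depth <- 1e6
  draws <- replicate(500, metpool:::rdirichlet_multinom(depth, p, Inf))
  v <- apply(draws, 1, var)
  expect_equal(v, depth * p * (1 - p), tolerance = 0.1)
  # finite concentration is overdispersed relative to multinomial
  draws2 <- replicate(500, metpool:::rdirichlet_multinom(depth, p, 50))
  expect_true(all(apply(draws2, 1, var) > v))
})

test_that("expected composition ranks follow true potential ranks", {
  # no-noise limit: deterministic outgrowth, full penetrance
  tp <- matrix(seq(-3, 1, length.out = 10), 10, 1)
  cfg <- sim_config(n_lines = 10L, organs = "brain", n_mice = 2L,
                    true_log10_potential = tp,
                    penetrance_prob = matrix(1, 10, 1),
                    growth_cv = 0, read_depth = 1e6,
                    overdispersion = Inf, n_pre = 1L, seed = 6)
  sim <- simulate_experiment(cfg)
  comp <- sim$truth$compositions[, 1]
  expect_equal(cor(comp, tp[, 1], method = "spearman"), 1)
})

test_that("emitted FASTQ round-trips through the counter exactly", {
  sim <- simulate_experiment(sim_config(n_lines = 5L, organs = "brain",
                                        n_mice = 1L, read_depth = 400,
                                        n_pre = 1L, seed = 12))
  dir <- tempfile()
  paths <- emit_fastq(sim$counts, dir = dir, seed = 3)
  expect_length(paths, ncol(sim$counts$counts))
  for (smp in colnames(sim$counts$counts)) {
    got <- count_barcodes(paths[[smp]], sim$library, sample_id = smp)
    expect_identical(got$counts[, smp], sim$counts$counts[, smp])
    expect_equal(unname(got$unassigned + got$ambiguous), 0L)
  }
  # record count equals fragment count
  n_rec <- length(readLines(paths[[1]])) / 4
  expect_equal(n_rec, sum(sim$counts$counts[, 1]))
  expect_error(emit_fastq(sim$counts, read_length = 10L), "read_length")
})

test_that("sequencing errors are absorbed by mismatch-tolerant matching", {
  sim <- simulate_experiment(sim_config(n_lines = 5L, organs = "brain",
                                        n_mice = 1L, read_depth = 500,
                                        n_pre = 1L, seed = 13))
  dir <- tempfile()
  paths <- emit_fastq(sim$counts, dir = dir, error_rate = 0.01, seed = 21)
  smp <- colnames(sim$counts$counts)[1]
  got <- count_barcodes(paths[[smp]], sim$library,
                        params = match_params(max_mismatches = 2L),
                        sample_id = smp)
  agree <- sum(pmin(got$counts[, smp], sim$counts$counts[, smp]))
  expect_gte(agree / sum(sim$counts$counts[, smp]), 0.99)
})

test_that("expression simulation reduces to the exact mixture without noise or DE", {
  sim <- simulate_experiment(small_cfg(2))
  ex <- simulate_expression(sim, n_genes = 100L, n_de = 0L, noise_sd = 0,
                            seed = 5)
  mix <- insilico_mixtures(ex$invitro, ex$truth$compositions)
  expect_equal(ex$invivo$values, mix$values, tolerance = 1e-9)
  # reproducible under the seed
  ex2 <- simulate_expression(sim, n_genes = 100L, n_de = 0L, noise_sd = 0,
                             seed = 5)
  expect_identical(ex$invitro$values, ex2$invitro$values)
  expect_error(simulate_expression(sim, n_genes = 10L, n_de = 11L), "n_de")
})
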