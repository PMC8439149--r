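test_that("in-silico mixtures are composition-weighted averages on the linear scale", {
  m <- matrix(c(10, 0, 5,
                20, 10, 5,
                30, 100, 5), nrow = 3, byrow = FALSE,
              dimnames = list(paste0("g", 1:3), c("l1", "l2", "l3")))
  iv <- expression_matrix(m, scale = "cpm")

  one <- insilico_mixture(iv, c(l2 = 1))
  expect_equal(unname(as.numeric(one)), unname(m[, "l2"]))

  half <- insilico_mixture(iv, c(l1 = 0.5, l2 = 0.5))
  expect_equal(unname(half["g1"]), 15)  # (10 + 20) / 2

  # three lines p = {0.3, 0.2, 0.5}, gene with g = {0, 10, 100} -> 52
  g2 <- matrix(c(0, 10, 100), 1, dimnames = list("gX", c("l1", "l2", "l3")))
  mix <- insilico_mixture(expression_matrix(g2, "cpm"),
                          c(l1 = 0.3, l2 = 0.2, l3 = 0.5))
  expect_equal(unname(mix["gX"]), 52)

  expect_error(insilico_mixture(iv, c(l1 = 0.5, ghost = 0.5)), "ghost")
  expect_error(insilico_mixture(iv, c(l1 = 0.6, l2 = 0.5)), "sum to 1")
  expect_error(insilico_mixture(expression_matrix(log2(m + 1), "log2"),
                                c(l1 = 1)), "linear")
})

test_that("mixing is linear in the composition", {
  set.seed(13)
  m <- matrix(rlnorm(40, 3, 1), 10,
              dimnames = list(paste0("g", 1:10), paste0("l", 1:4)))
  iv <- expression_matrix(m, scale = "cpm")
  p1 <- c(l1 = 0.7, l2 = 0.3, l3 = 0, l4 = 0)
  p2 <- c(l1 = 0, l2 = 0.1, l3 = 0.4, l4 = 0.5)
  for (alpha in c(0.25, 0.5, 0.9)) {
    blend <- alpha * p1 + (1 - alpha) * p2
    lhs <- as.numeric(insilico_mixture(iv, blend))
    rhs <- alpha * as.numeric(insilico_mixture(iv, p1)) +
      (1 - alpha) * as.numeric(insilico_mixture(iv, p2))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("bh_fdr matches the brute-force step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p rank
  }
})

test_that("identical paired matrices give zero fold-changes", {
  set.seed(5)
  m <- matrix(rnorm(50, 8, 2), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  a <- expression_matrix(m, "log2")
  suppressMessages(res <- paired_moderated_test(a, a))
  expect_equal(res$lfc, rep(0, 10))
  expect_true(all(is.na(res$p_value)))  # no variance information
})

test_that("the paired moderated test is calibrated under the null", {
  set.seed(404)
  n_genes <- 2000; n_pairs <- 5
  base <- matrix(rnorm(n_genes * n_pairs, 8, 2), n_genes,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 paste0("s", 1:n_pairs)))
  noise <- matrix(rnorm(n_genes * n_pairs, 0, 0.3), n_genes)
  res <- paired_moderated_test(expression_matrix(base + noise, "log2"),
                               expression_matrix(base, "log2"))
  expect_lte(mean(res$q_value < 0.05, na.rm = TRUE), 0.05)
  # p-values roughly uniform: no gross anti-conservatism
  expect_lte(mean(res$p_value < 0.05, na.rm = TRUE), 0.08)
})

test_that("spiked genes are recovered with accurate fold-change estimates", {
  set.seed(808)
  n_genes <- 2000; n_pairs <- 5; spike <- sprintf("g%04d", 1:100)
  base <- matrix(rnorm(n_genes * n_pairs, 8, 2), n_genes,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 paste0("s", 1:n_pairs)))
  invivo <- base + matrix(rnorm(n_genes * n_pairs, 0, 0.3), n_genes)
  invivo[spike, ] <- invivo[spike, ] + 2
  res <- paired_moderated_test(expression_matrix(invivo, "log2"),
                               expression_matrix(base, "log2"))
  hits <- res$gene[res$q_value < 0.05 & !is.na(res$q_value)]
  expect_gte(sum(spike %in% hits), 80)
  expect_lt(abs(median(res$lfc[res$gene %in% spike]) - 2), 0.3)
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(99)
  d <- matrix(rnorm(500 * 6, 0, 1), 500,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:6)))
  d[1:20, ] <- d[1:20, ] + 1.5
  zero <- matrix(0, 500, 6, dimnames = dimnames(d))
  res <- paired_moderated_test(expression_matrix(d, "log2"),
                               expression_matrix(zero, "log2"))
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, 6, 1)))
  expect_equal(res$t, unname(fit$t[, 1]), tolerance = 2e-3)
  expect_equal(res$p_value, unname(fit$p.value[, 1]), tolerance = 5e-3)
  expect_equal(unique(res$df), unname(fit$df.total[1]), tolerance = 0.05)
})

test_that("signature scores are mean z-scores and affine-invariant", {
  set.seed(15)
  m <- matrix(rnorm(60, 5, 1), 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  expr <- expression_matrix(m, "log2")
  sc <- signature_score(expr, rownames(m))
  expect_equal(unname(sc["s1"]), mean(apply(m, 1, scale)[1, ]), tolerance = 1e-9)

  # identical samples score identically
  m2 <- cbind(m, s11 = m[, "s1"])
  sc2 <- signature_score(expression_matrix(m2, "log2"), rownames(m))
  expect_equal(unname(sc2["s11"]), unname(sc2["s1"]))

  # gene-wise affine rescaling leaves scores unchanged
  resc <- m * rep(runif(6, 0.5, 3), 10) + rep(rnorm(6), 10)
  sc3 <- signature_score(expression_matrix(resc, "log2"), rownames(m))
  expect_equal(sc3, sc, tolerance = 1e-9)

  # a sample elevated by 2 SD on every set gene scores about 2
  base <- matrix(rnorm(5 * 20, 0, 1), 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  base[, "s1"] <- apply(base[, -1], 1, mean) + 2 * apply(base[, -1], 1, sd)
  sc4 <- signature_score(expression_matrix(base, "log2"), paste0("g", 1:5))
  expect_gt(unname(sc4["s1"]), 1.5)

  expect_error(signature_score(expr, c("nope1", "nope2")), "nope1")
})

test_that("GMT gene sets parse and drive signature scoring", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  set.seed(2)
  m <- matrix(rnorm(50), 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  sc <- signature_score(expression_matrix(m, "log2"), sets$setB)
  expect_length(sc, 10L)
  bad <- tempfile(fileext = ".gmt")
  writeLines("setA\tonly_desc", bad)
  expect_error(read_gmt(bad), "malformed")
})
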