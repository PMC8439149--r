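# Small fully-specified experiment used across the potential tests:
# 2 lines, 1 organ + pre-injection, counts chosen for hand computation.
toy_counts <- function(organ_counts, pre_counts, organs = "brain") {
  lib <- barcode_library(c("bcA", "bcB"), c(strrep("AC", 13), strrep("GT", 13)),
                         c("A", "B"))
  nm <- ncol(organ_counts)
  m <- cbind(organ_counts, pre_counts)
  rownames(m) <- lib$id
  colnames(m) <- c(paste0("m", seq_len(nm), "_", organs),
                   paste0("pre", seq_len(ncol(pre_counts))))
  meta <- sample_meta(colnames(m),
                      mouse_id = c(paste0("m", seq_len(nm)),
                                   rep(NA, ncol(pre_counts))),
                      organ = c(rep(organs, nm),
                                rep("pre_injection", ncol(pre_counts))))
  barcode_count_table(m, library = lib, samples = meta)
}

test_that("absolute potential is the mean of inferred cell numbers", {
  # one mouse: c = 1e5 cells, p_A = 0.2 -> M_A = 20000 cells
  counts <- toy_counts(matrix(c(200L, 800L), 2), matrix(c(500L, 500L), 2))
  cc <- cell_count_table("m1", "brain", 1e5)
  pt <- absolute_potential(counts, cc, B = 10, seed = 1)
  expect_equal(unname(pt$potential["A", "brain"]), 20000)
  expect_equal(pt$kind, "absolute")

  # two mice: (c=1e5, p=0.2) and (c=2e5, p=0.1) -> (20000+20000)/2
  counts2 <- toy_counts(matrix(c(200L, 800L, 100L, 900L), 2), matrix(c(500L, 500L), 2))
  cc2 <- cell_count_table(c("m1", "m2"), "brain", c(1e5, 2e5))
  pt2 <- absolute_potential(counts2, cc2, B = 10, seed = 1)
  expect_equal(unname(pt2$potential["A", "brain"]), 20000)

  # a line never observed has zero potential
  counts3 <- toy_counts(matrix(c(0L, 1000L), 2), matrix(c(500L, 500L), 2))
  pt3 <- absolute_potential(counts3, cc, B = 10, seed = 1)
  expect_equal(unname(pt3$potential["A", "brain"]), 0)

  # missing total cell count is an error naming the mouse and organ
  expect_error(absolute_potential(counts, cell_count_table("m9", "brain", 1), B = 5),
               "m1.*brain")
})

test_that("relative potential is the CPM ratio to the pre-injection mean", {
  # organ {A:800, B:200} vs pre {A:500, B:500}: rM = {1.6, 0.4}
  counts <- toy_counts(matrix(c(800L, 200L), 2), matrix(c(500L, 500L), 2))
  pt <- relative_potential(counts, B = 10, seed = 1)
  expect_equal(unname(pt$potential[, "brain"]), c(1.6, 0.4))
  expect_equal(pt$kind, "relative")

  # equal composition -> rM = 1 for every line
  eq <- toy_counts(matrix(c(300L, 300L), 2), matrix(c(9000L, 9000L), 2))
  expect_equal(unname(relative_potential(eq, B = 5)$potential[, 1]), c(1, 1))

  # zero organ counts, nonzero pre-injection -> rM = 0
  z <- toy_counts(matrix(c(0L, 600L), 2), matrix(c(500L, 500L), 2))
  expect_equal(unname(relative_potential(z, B = 5)$potential["A", 1]), 0)

  # absent pre-injection -> NA with warning, never infinite
  ab <- toy_counts(matrix(c(800L, 200L), 2), matrix(c(0L, 500L), 2))
  expect_warning(pa <- relative_potential(ab, B = 5), "undefined")
  expect_true(is.na(pa$potential["A", 1]))
  expect_false(any(is.infinite(pa$potential)))
})

test_that("relative potential is invariant to per-sample depth rescaling", {
  set.seed(11)
  organ <- matrix(rpois(10, 200L), 2)
  pre <- matrix(rpois(2, 400L), 2)
  a <- relative_potential(toy_counts(organ, pre), B = 5)
  b <- relative_potential(toy_counts(organ * 7L, pre * 3L), B = 5)
  expect_equal(a$potential, b$potential, tolerance = 1e-12)
})

test_that("penetrance applies the detection rule per mouse", {
  counts <- toy_counts(matrix(c(6L, 100L, 4L, 100L, 0L, 100L, 12L, 100L, 5L, 100L), 2),
                       matrix(c(500L, 500L), 2))
  pen <- penetrance(counts, min_reads = 5L)
  expect_equal(unname(pen["A", "brain"]), 0.6)   # {6,4,0,12,5} -> 3/5
  expect_equal(unname(pen["B", "brain"]), 1.0)
  pen0 <- penetrance(counts, min_reads = 1000L)
  expect_equal(unname(pen0["A", "brain"]), 0)
  expect_true(all(pen >= 0 & pen <= 1))
})

test_that("bootstrap intervals are percentile, seeded, and degenerate correctly", {
  expect_equal(unname(bootstrap_ci(rep(3.5, 8), B = 100, seed = 2)),
               c(3.5, 3.5))
  c1 <- bootstrap_ci(c(1, 5, 2, 8, 3, 7, 4, 6, 9, 2), B = 200, seed = 42)
  c2 <- bootstrap_ci(c(1, 5, 2, 8, 3, 7, 4, 6, 9, 2), B = 200, seed = 42)
  expect_identical(c1, c2)
  expect_lte(c1[1], c1[2])
  expect_error(bootstrap_ci(1:5, B = 0), "B")
  expect_error(bootstrap_ci(1:5, level = 1.2), "level")
})

test_that("bootstrap CIs bracket the estimate inside potential tables", {
  set.seed(21)
  organ <- matrix(rpois(12, 300L), 2)
  pre <- matrix(rpois(4, 300L), 2)
  pt <- relative_potential(toy_counts(organ, pre), B = 200, seed = 9)
  ok <- !is.na(pt$potential)
  expect_true(all(pt$ci_low[ok] <= pt$potential[ok] + 1e-9))
  expect_true(all(pt$ci_high[ok] >= pt$potential[ok] - 1e-9))
})

test_that("overall potential is the floored log10 mean across organs", {
  lines <- paste0("L", 1:2)
  organs <- paste0("o", 1:5)
  mk <- function(v) {
    new <- matrix(v, nrow = 1, dimnames = list("L1", organs))
    structure(list(potential = new, ci_low = new, ci_high = new,
                   penetrance = new * 0 + 1,
                   n_mice = stats::setNames(rep(5L, 5), organs),
                   kind = "relative"),
              class = "potential_table")
  }
  expect_equal(unname(overall_potential(mk(rep(1, 5)))), 0)
  expect_equal(unname(overall_potential(mk(rep(0, 5)), floor = 1e-4)), -4)
  expect_equal(unname(overall_potential(mk(c(1, 0.01, 1, 1, 1)))), -0.4)
  bad <- mk(rep(1, 5)); bad$kind <- "absolute"
  expect_error(overall_potential(bad), "relative")
})

test_that("petal export is long-format with one row per line-organ pair", {
  set.seed(31)
  organ <- matrix(rpois(8, 250L), 2)
  pre <- matrix(rpois(2, 250L), 2)
  counts <- toy_counts(organ, pre)
  pt <- relative_potential(counts, B = 20, seed = 4)
  path <- tempfile(fileext = ".csv")
  df <- export_petal(pt, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(pt$potential) * ncol(pt$potential))
  expect_equal(back$potential, df$potential, tolerance = 1e-9)
  expect_true(all(back$penetrance >= 0 & back$penetrance <= 1))
  expect_named(back, c("line", "organ", "potential", "ci_low", "ci_high",
                       "penetrance"))
})
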