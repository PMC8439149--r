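make_lib <- function() {
  # two fixed, dissimilar 26-nt barcodes
  barcode_library(c("A", "B"),
                  c("ACGTACGTACGTACGTACGTACGTAC",
                    "GGTTCCAAGGTTCCAAGGTTCCAAGG"),
                  c("lineA", "lineB"))
}

test_that("the coverage rule accepts >50% terminal overlap and rejects 50%", {
  lib <- make_lib()
  bcA <- lib$sequence[1]
  filler <- strrep("T", 40)

  # full containment anywhere in the read
  full <- paste0(strrep("T", 20), bcA, strrep("C", 29))
  expect_equal(match_read(full, lib)$barcode_id, "A")

  # 13/26 nt at the read 3' end: exactly 50%, not over -> none
  half <- paste0(filler, substr(bcA, 1, 13))
  expect_equal(match_read(half, lib)$status, "none")

  # 14/26 nt: strictly over 50% -> assigned (checked against the oracle)
  over <- paste0(filler, substr(bcA, 1, 14))
  expect_equal(match_read(over, lib)$barcode_id, "A")
  expect_equal(oracle_match_read(over, lib), "A")
  expect_equal(oracle_match_read(half, lib), "none")

  # suffix of the barcode at the read 5' end behaves symmetrically
  suf <- paste0(substr(bcA, 13, 26), filler)
  expect_equal(match_read(suf, lib)$barcode_id, "A")

  # two distinct barcodes in full -> ambiguous
  two <- paste0(bcA, strrep("T", 10), lib$sequence[2])
  expect_equal(match_read(two, lib)$status, "ambiguous")

  # reverse complement orientation found by default, off when disabled
  rc <- oracle_revcomp(full)
  expect_equal(match_read(rc, lib)$barcode_id, "A")
  expect_equal(match_read(rc, lib,
                          match_params(count_reverse_complement = FALSE))$status,
               "none")

  # N never matches; non-ACGTN is invalid
  nfull <- paste0(strrep("N", 49), substr(bcA, 1, 26))
  expect_equal(match_read(chartr("A", "N", full), lib)$status, "none")
  expect_equal(match_read(paste0("ACGU", bcA), lib)$status, "invalid")
})

test_that("Hamming mismatch tolerance is honoured inside the overlap", {
  lib <- make_lib()
  bcA <- lib$sequence[1]
  mutated <- paste0(strrep("T", 20), "T", substr(bcA, 2, 26), strrep("C", 28))
  expect_equal(match_read(mutated, lib)$status, "none")
  expect_equal(match_read(mutated, lib, match_params(max_mismatches = 1))$barcode_id,
               "A")
  expect_equal(oracle_match_read(mutated, lib, match_params(max_mismatches = 1)),
               "A")
})

test_that("matcher agrees exactly with the sliding-window oracle on random reads", {
  set.seed(101)
  for (L in c(8L, 12L, 26L)) {
    lib <- random_library(6, L)
    for (params in list(match_params(),
                        match_params(max_mismatches = 1L),
                        match_params(count_reverse_complement = FALSE))) {
      reads <- random_read_set(lib, 120, read_length = max(40L, 3L * L))
      got <- match_reads(reads, lib, params)
      got_status <- ifelse(got$status == "assigned", got$barcode_id, got$status)
      want <- vapply(reads, oracle_match_read, character(1),
                     library = lib, params = params, USE.NAMES = FALSE)
      expect_identical(got_status, want,
                       label = sprintf("L=%d mm=%d rc=%s", L,
                                       params$max_mismatches,
                                       params$count_reverse_complement))
    }
  }
})

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  if (length(seqs)) {
    writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                               strrep("I", nchar(seqs)))), path)
  } else {
    file.create(path)
  }
  path
}

test_that("count_barcodes tallies fragments conservatively", {
  set.seed(7)
  lib <- make_lib()
  rand <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
  embed <- function(bc) paste0(rand(20), bc, rand(29))
  reads <- c(replicate(50, embed(lib$sequence[1])),
             replicate(30, embed(lib$sequence[2])),
             replicate(20, strrep("T", 75)))
  tab <- count_barcodes(write_fastq(reads), lib, sample_id = "s1")
  expect_equal(unname(tab$counts[, 1]), c(50L, 30L))
  expect_equal(unname(tab$unassigned), 20L)
  expect_equal(sum(tab$counts) + sum(tab$unassigned) + sum(tab$ambiguous), 100L)

  # against the oracle, read by read
  want <- table(vapply(reads, oracle_match_read, character(1), library = lib,
                       USE.NAMES = FALSE))
  expect_equal(unname(tab$counts["A", 1]), unname(as.integer(want["A"])))

  empty <- count_barcodes(write_fastq(character(0)), lib)
  expect_equal(sum(empty$counts), 0L)
  expect_equal(unname(empty$unassigned), 0L)
})

test_that("paired-end fragments count once and disagreement is ambiguous", {
  lib <- make_lib()
  r1 <- c(paste0(strrep("T", 20), lib$sequence[1], strrep("C", 29)),
          strrep("T", 75),
          paste0(strrep("T", 20), lib$sequence[1], strrep("C", 29)))
  r2 <- c(strrep("G", 75),
          paste0(strrep("T", 20), lib$sequence[2], strrep("C", 29)),
          paste0(strrep("T", 20), lib$sequence[2], strrep("C", 29)))
  tab <- count_barcodes(write_fastq(r1), lib, fastq2 = write_fastq(r2))
  expect_equal(unname(tab$counts[, 1]), c(1L, 1L))   # fragments 1 and 2
  expect_equal(unname(tab$ambiguous), 1L)            # fragment 3 disagrees
  expect_equal(sum(tab$counts) + sum(tab$unassigned) + sum(tab$ambiguous), 3L)
})

test_that("truncated FASTQ records raise an error naming the record", {
  lib <- make_lib()
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(count_barcodes(path, lib), "record 2")
})

test_that("composition estimates live on the simplex", {
  m <- matrix(c(50L, 50L, 0L, 100L, 30L, 20L), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  comp <- estimate_composition(m)
  expect_equal(unname(comp$fractions[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(comp$fractions[, "s2"]), c(0, 1))
  expect_equal(unname(comp$fractions[, "s3"]), c(0.6, 0.4))
  expect_equal(unname(colSums(comp$fractions)), rep(1, 3), tolerance = 1e-12)

  z <- matrix(c(0L, 0L), 2, dimnames = list(c("A", "B"), "s1"))
  expect_warning(cz <- estimate_composition(z), "undefined")
  expect_true(all(is.na(cz$fractions)))
  expect_silent(estimate_composition(z, pseudocount = 1))
  expect_error(estimate_composition(m, pseudocount = -1), ">= 0")

  # monotonicity: adding reads for a barcode never decreases its fraction
  set.seed(3)
  for (i in 1:20) {
    v <- matrix(rpois(4, 50), 4, dimnames = list(paste0("b", 1:4), "s"))
    before <- estimate_composition(v)$fractions["b2", ]
    v["b2", ] <- v["b2", ] + sample(1:100, 1)
    after <- estimate_composition(v)$fractions["b2", ]
    expect_gte(after, before)
  }
})

test_that("depth normalization equalizes library size", {
  m <- matrix(c(800L, 200L, 80L, 20L), 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  n <- depth_normalize(m)
  expect_equal(unname(n[, "s1"]), c(8e5, 2e5))
  expect_equal(unname(n[, "s1"]), unname(n[, "s2"]))  # proportional samples
  expect_equal(depth_normalize(n), n)                 # already normalized
  zero <- matrix(c(1L, 0L), 1, dimnames = list("A", c("s1", "s2")))
  expect_error(depth_normalize(zero), "s2")
})
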