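# Independent brute-force oracles, deliberately written with plain string
# operations and full enumeration rather than the package's code paths.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av == "N" | av != bv)
}

# One barcode, one read, one orientation: enumerate every full placement
# and every flush terminal overlap, apply the strict >50% (min_frac) rule.
oracle_is_candidate <- function(read, bc, min_frac = 0.5, max_mm = 0L) {
  n <- nchar(read); L <- nchar(bc)
  if (n >= L) {
    for (o in 1:(n - L + 1)) {
      if (oracle_hamming(substr(read, o, o + L - 1), bc) <= max_mm) return(TRUE)
    }
  }
  for (k in seq_len(min(L - 1, n))) {
    if (k <= min_frac * L + 1e-9) next
    # barcode prefix at the read's 3' end
    if (oracle_hamming(substr(read, n - k + 1, n), substr(bc, 1, k)) <= max_mm)
      return(TRUE)
    # barcode suffix at the read's 5' end
    if (oracle_hamming(substr(read, 1, k), substr(bc, L - k + 1, L)) <= max_mm)
      return(TRUE)
  }
  FALSE
}

oracle_match_read <- function(read, library, params = match_params()) {
  if (nchar(read) == 0 || grepl("[^ACGTN]", read)) return("invalid")
  hits <- character(0)
  for (j in seq_len(nrow(library))) {
    bc <- library$sequence[j]
    hit <- oracle_is_candidate(read, bc, params$min_overlap_fraction,
                               params$max_mismatches)
    if (!hit && params$count_reverse_complement) {
      hit <- oracle_is_candidate(read, oracle_revcomp(bc),
                                 params$min_overlap_fraction,
                                 params$max_mismatches)
    }
    if (hit) hits <- c(hits, library$id[j])
  }
  if (length(hits) == 0) "none" else if (length(hits) > 1) "ambiguous" else hits
}

# Random reads exercising all match classes: full containment, terminal
# overlaps of every length, pure noise, and multi-barcode reads.
random_read_set <- function(library, n, read_length = 75L) {
  L <- nchar(library$sequence[1])
  bases <- c("A", "C", "G", "T")
  rand <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  vapply(seq_len(n), function(i) {
    kind <- sample(c("contain", "end5", "end3", "noise", "double", "rc"), 1)
    bc <- sample(library$sequence, 1)
    switch(kind,
      contain = {
        off <- sample.int(max(read_length - L, 0) + 1, 1) - 1
        paste0(rand(off), bc, rand(read_length - L - off))
      },
      end3 = {
        k <- sample.int(L, 1)
        paste0(rand(read_length - k), substr(bc, 1, k))
      },
      end5 = {
        k <- sample.int(L, 1)
        paste0(substr(bc, L - k + 1, L), rand(read_length - k))
      },
      noise = rand(read_length),
      double = {
        bc2 <- sample(library$sequence, 1)
        paste0(rand(5), bc, rand(max(read_length - 2 * L - 10, 0)), bc2, rand(5))
      },
      rc = {
        off <- sample.int(max(read_length - L, 0) + 1, 1) - 1
        paste0(rand(off), oracle_revcomp(bc), rand(read_length - L - off))
      })
  }, character(1))
}

random_library <- function(n_barcodes, L, prefix = "bc") {
  repeat {
    seqs <- vapply(seq_len(n_barcodes), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(seqs)) break
  }
  barcode_library(paste0(prefix, seq_len(n_barcodes)), seqs,
                  cell_line = paste0("line_", prefix, seq_len(n_barcodes)))
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- 1
  for (r in n:1) {
    running <- min(running, p[o[r]] * n / r)
    q[o[r]] <- running
  }
  pmin(q, 1)
}

# Brute-force one/two-sided Fisher p by hypergeometric tail enumeration
# over all tables with the observed margins.
oracle_fisher <- function(a, b, c2, d, alternative = "two.sided") {
  m <- a + b; n <- c2 + d; k <- a + c2
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  obs <- probs[xs == a]
  switch(alternative,
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]),
         two.sided = sum(probs[probs <= obs * (1 + 1e-7)]))
}
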