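#' Read-to-barcode matching parameters
#'
#' A barcode is accepted for a read when the read covers it sufficiently:
#' either the full barcode occurs within the read, or a terminal fragment
#' of the barcode — a prefix at the read's 3' end or a suffix at the 5'
#' end — covers strictly more than `min_overlap_fraction` of the barcode
#' length. With the defaults (fraction 0.5, 26-nt barcodes) this is the
#' "over 50% coverage from either end" rule: at least 14 of 26 nt.
#'
#' @param min_overlap_fraction fraction of the barcode that a terminal
#'   overlap must strictly exceed; in (0, 1].
#' @param max_mismatches Hamming mismatches tolerated inside the overlap
#'   (no indels). Default 0: exact matching.
#' @param count_reverse_complement also match the reverse complement of
#'   each barcode (read orientation is not guaranteed by library prep).
#' @return a list of class `match_params`.
#' @export
match_params <- function(min_overlap_fraction = 0.5, max_mismatches = 0L,
                         count_reverse_complement = TRUE) {
  if (!is.numeric(min_overlap_fraction) || min_overlap_fraction <= 0 ||
      min_overlap_fraction > 1) {
    stop("min_overlap_fraction must be in (0, 1]")
  }
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  p <- list(min_overlap_fraction = min_overlap_fraction,
            max_mismatches = as.integer(max_mismatches),
            count_reverse_complement = isTRUE(count_reverse_complement))
  class(p) <- "match_params"
  p
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign reads to barcodes
#'
#' `match_reads()` assigns each read to the unique candidate barcode under
#' the coverage rule of [match_params()]; reads with zero candidates are
#' `none`, reads with more than one are `ambiguous` (excluded from counts),
#' and reads containing characters outside A/C/G/T/N are `invalid`. `N`
#' bases never match. `match_read()` is the single-read convenience form.
#'
#' @param reads character vector of read sequences.
#' @param library a [barcode_library()].
#' @param params a [match_params()].
#' @return `match_reads()`: a data.frame with columns `barcode_id`
#'   (`NA` unless assigned) and `status` in
#'   `{"assigned","none","ambiguous","invalid"}`. `match_read()`: a
#'   one-row slice of the same.
#' @export
match_reads <- function(reads, library, params = match_params()) {
  stopifnot(inherits(library, "barcode_library"))
  reads <- toupper(as.character(reads))
  rc <- if (params$count_reverse_complement) reverse_complement(library$sequence)
        else character(length(library$sequence))
  code <- cpp_match_reads(reads, library$sequence, rc,
                          params$min_overlap_fraction, params$max_mismatches,
                          params$count_reverse_complement)
  status <- rep("none", length(code))
  status[code > 0] <- "assigned"
  status[code == -1] <- "ambiguous"
  status[code == -2] <- "invalid"
  data.frame(barcode_id = ifelse(code > 0, library$id[pmax(code, 1L)], NA_character_),
             status = status, stringsAsFactors = FALSE)
}

#' @rdname match_reads
#' @param read a single read sequence.
#' @export
match_read <- function(read, library, params = match_params()) {
  stopifnot(length(read) == 1L)
  match_reads(read, library, params)
}

# Minimal FASTQ reader: returns character vector of sequences. A truncated
# trailing record or malformed separators raise an error naming the record
# index. Sequences may contain any characters; validation happens at match
# time so non-ACGTN reads can be tallied rather than aborting the run.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L, " in ", path)
  }
  idx <- seq(1L, length(lines), by = 4L)
  bad_at <- !startsWith(lines[idx], "@")
  bad_plus <- !startsWith(lines[idx + 2L], "+")
  if (any(bad_at | bad_plus)) {
    stop("malformed FASTQ record ", which(bad_at | bad_plus)[1L], " in ", path)
  }
  lines[idx + 1L]
}

#' Count barcodes in FASTQ reads
#'
#' Streams single- or paired-end FASTQ, assigns each fragment to a barcode
#' with [match_reads()], and returns a one-column count table. A paired
#' fragment counts once: it is assigned if either mate is assigned (and
#' they agree), ambiguous if the mates disagree or either mate is
#' ambiguous. Conservation holds by construction:
#' `sum(counts) + unassigned + ambiguous == number of fragments` (invalid
#' reads are folded into the unassigned tally and also reported
#' separately).
#'
#' @param fastq path to the (optionally gzipped) FASTQ file.
#' @param library a [barcode_library()].
#' @param params a [match_params()].
#' @param sample_id sample identifier for the output column.
#' @param fastq2 optional mate FASTQ for paired-end data.
#' @param samples optional one-row [sample_meta()] for the sample.
#' @return a [barcode_count_table()] with one column; attribute
#'   `diagnostics` holds the tallies (assigned, unassigned, ambiguous,
#'   invalid, fragments).
#' @export
count_barcodes <- function(fastq, library, params = match_params(),
                           sample_id = "sample1", fastq2 = NULL,
                           samples = NULL) {
  r1 <- read_fastq_sequences(fastq)
  m1 <- match_reads(r1, library, params)
  if (!is.null(fastq2)) {
    r2 <- read_fastq_sequences(fastq2)
    if (length(r2) != length(r1)) {
      stop("mate FASTQ files differ in record count (", length(r1), " vs ",
           length(r2), ")")
    }
    m2 <- match_reads(r2, library, params)
    bc <- ifelse(m1$status == "assigned", m1$barcode_id, m2$barcode_id)
    disagree <- m1$status == "assigned" & m2$status == "assigned" &
      m1$barcode_id != m2$barcode_id
    status <- ifelse(m1$status == "assigned" | m2$status == "assigned",
                     "assigned", "none")
    status[m1$status == "ambiguous" | m2$status == "ambiguous" | disagree] <- "ambiguous"
    status[status == "none" & (m1$status == "invalid" & m2$status == "invalid")] <- "invalid"
    frag <- data.frame(barcode_id = ifelse(status == "assigned", bc, NA_character_),
                       status = status, stringsAsFactors = FALSE)
  } else {
    frag <- m1
  }
  counts <- matrix(0L, nrow = nrow(library), ncol = 1L,
                   dimnames = list(library$id, sample_id))
  assigned <- frag$barcode_id[frag$status == "assigned"]
  if (length(assigned)) {
    tab <- table(factor(assigned, levels = library$id))
    counts[, 1L] <- as.integer(tab)
  }
  n_amb <- sum(frag$status == "ambiguous")
  n_inv <- sum(frag$status == "invalid")
  n_un <- sum(frag$status == "none") + n_inv
  out <- barcode_count_table(counts, library = library, samples = samples,
                             unassigned = n_un, ambiguous = n_amb)
  attr(out, "diagnostics") <- c(fragments = nrow(frag),
                                assigned = length(assigned),
                                unassigned = n_un, ambiguous = n_amb,
                                invalid = n_inv)
  out
}

#' Estimate cell composition from barcode counts
#'
#' Barcode fractions per sample: `p_j = (count_j + pseudocount) /`
#' `sum_k (count_k + pseudocount)`. With `pseudocount = 0` an all-zero
#' sample has no defined composition; its column is `NA` and flagged.
#'
#' @param counts a [barcode_count_table()] or integer matrix.
#' @param pseudocount non-negative pseudocount added to every barcode.
#' @return list of class `composition_estimate` with `fractions`
#'   (barcodes x samples), `assigned_total` per sample and logical
#'   `undefined` per sample.
#' @export
estimate_composition <- function(counts, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  m <- if (inherits(counts, "barcode_count_table")) counts$counts else as.matrix(counts)
  if (ncol(m) < 1L) stop("at least one sample required")
  tot <- colSums(m)
  aug <- m + pseudocount
  denom <- colSums(aug)
  frac <- sweep(aug, 2L, denom, "/")
  undefined <- denom == 0
  frac[, undefined] <- NA_real_
  if (any(undefined)) {
    warning("composition undefined for all-zero sample(s): ",
            paste(colnames(m)[undefined], collapse = ", "))
  }
  out <- list(fractions = frac, assigned_total = tot, undefined = undefined)
  class(out) <- "composition_estimate"
  out
}

#' Depth-normalize a count matrix
#'
#' Scales each sample (column) to a common total, counts-per-million by
#' default.
#'
#' @param counts a [barcode_count_table()] or numeric matrix.
#' @param scale target column sum (default 1e6).
#' @return numeric matrix of normalized counts.
#' @export
depth_normalize <- function(counts, scale = 1e6) {
  m <- if (inherits(counts, "barcode_count_table")) counts$counts else as.matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("zero-total sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  }
  sweep(m, 2L, tot / scale, "/")
}
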