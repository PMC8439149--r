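#' Construct a barcode library
#'
#' A barcode library is the registry of clonal DNA barcode sequences and
#' their cell-line / pool assignments. All sequences must have identical
#' length, contain only A/C/G/T, and be pairwise distinct.
#'
#' @param id character vector of unique barcode identifiers.
#' @param sequence character vector of barcode sequences (default length 26 nt
#'   in the assay this package models; any common length is accepted).
#' @param cell_line character vector naming the cell line carrying each barcode.
#' @param pool_id optional character vector of pool memberships.
#' @return An object of class `barcode_library`: a data.frame with columns
#'   `id`, `sequence`, `cell_line`, `pool_id` and attribute `barcode_length`.
#' @export
barcode_library <- function(id, sequence, cell_line, pool_id = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  cell_line <- as.character(cell_line)
  pool_id <- rep_len(as.character(pool_id), length(id))
  stopifnot(length(sequence) == length(id), length(cell_line) == length(id))
  if (length(id) == 0L) stop("barcode library is empty")
  if (anyDuplicated(id)) {
    stop("duplicate barcode ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    stop("non-ACGT characters in barcode sequence(s): ",
         paste(id[bad], collapse = ", "))
  }
  lens <- nchar(sequence)
  if (length(unique(lens)) != 1L) {
    stop("heterogeneous barcode lengths (", paste(sort(unique(lens)), collapse = ", "),
         " nt); offending ids: ",
         paste(id[lens != lens[1L]], collapse = ", "))
  }
  dup <- duplicated(sequence) | duplicated(sequence, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate barcode sequences shared by ids: ",
         paste(id[dup], collapse = ", "))
  }
  lib <- data.frame(id = id, sequence = sequence, cell_line = cell_line,
                    pool_id = pool_id, stringsAsFactors = FALSE)
  attr(lib, "barcode_length") <- lens[1L]
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

#' Barcode length of a library
#' @param library a `barcode_library`.
#' @return integer barcode length in nucleotides.
#' @export
barcode_length <- function(library) attr(library, "barcode_length")

#' Read a barcode library from FASTA or CSV
#'
#' FASTA headers are whitespace-separated `id cell_line [pool_id]`.
#' CSV files carry columns `id`, `sequence`, `cell_line` and optionally
#' `pool_id`. Validation (ACGT alphabet, uniform length, unique ids and
#' sequences) is enforced on read.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"fasta"`, `"csv"`. `"auto"` decides by
#'   file extension.
#' @return a [barcode_library()].
#' @export
read_barcode_library <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    fields <- strsplit(trimws(names(seqs)), "[[:space:]|]+")
    id <- vapply(fields, `[`, "", 1L)
    cell_line <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else f[1L], "")
    pool_id <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")
    barcode_library(id, as.character(seqs), cell_line, pool_id)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "sequence", "cell_line")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("library CSV missing column(s): ", paste(miss, collapse = ", "))
    pool <- if ("pool_id" %in% names(tab)) tab$pool_id else NA_character_
    barcode_library(tab$id, tab$sequence, tab$cell_line, pool)
  }
}

#' Construct a sample metadata table
#'
#' One row per sequenced sample. `organ` is an open vocabulary; the five
#' canonical target organs are brain, lung, liver, kidney and bone, and
#' `"pre_injection"` is reserved for the pre-injected pool samples, which
#' enter the relative-potential denominator.
#'
#' @param sample_id unique sample identifiers.
#' @param mouse_id mouse of origin (`NA` for pre-injection replicates).
#' @param organ organ of origin or `"pre_injection"`.
#' @param cohort cohort label.
#' @param replicate_index integer replicate index.
#' @return a data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, mouse_id = NA_character_, organ,
                        cohort = "cohort1", replicate_index = 1L) {
  n <- length(sample_id)
  sm <- data.frame(sample_id = as.character(sample_id),
                   mouse_id = rep_len(as.character(mouse_id), n),
                   organ = rep_len(as.character(organ), n),
                   cohort = rep_len(as.character(cohort), n),
                   replicate_index = rep_len(as.integer(replicate_index), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(sm$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sm$sample_id[duplicated(sm$sample_id)]), collapse = ", "))
  }
  class(sm) <- c("sample_meta", "data.frame")
  sm
}

#' Read sample metadata from CSV
#' @param path CSV with columns sample_id, mouse_id, organ, cohort, replicate_index.
#' @return a [sample_meta()] data.frame.
#' @export
read_sample_meta <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("metadata CSV missing 'sample_id'")
  sample_meta(tab$sample_id,
              mouse_id = if ("mouse_id" %in% names(tab)) tab$mouse_id else NA,
              organ = if ("organ" %in% names(tab)) tab$organ else "other",
              cohort = if ("cohort" %in% names(tab)) tab$cohort else "cohort1",
              replicate_index = if ("replicate_index" %in% names(tab)) tab$replicate_index else 1L)
}

#' Construct a barcode count table
#'
#' The central count container: a non-negative integer matrix of reads per
#' barcode (rows) per sample (columns), the library it was counted against,
#' per-sample metadata, and per-sample tallies of unassigned and ambiguous
#' fragments.
#'
#' @param counts integer matrix, barcodes x samples; rownames are barcode ids,
#'   colnames sample ids.
#' @param library the [barcode_library()] counted against, or `NULL`.
#' @param samples a [sample_meta()] table matching the columns, or `NULL`.
#' @param unassigned,ambiguous per-sample integer tallies (recycled).
#' @return an object of class `barcode_count_table`.
#' @export
barcode_count_table <- function(counts, library = NULL, samples = NULL,
                                unassigned = 0L, ambiguous = 0L) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0L)) stop("negative counts are not allowed")
  if (is.null(rownames(counts))) stop("counts must carry barcode-id rownames")
  if (is.null(colnames(counts))) stop("counts must carry sample-id colnames")
  if (!is.null(library)) {
    unknown <- setdiff(rownames(counts), library$id)
    if (length(unknown)) {
      stop("barcode id(s) absent from library: ", paste(unknown, collapse = ", "))
    }
    # reorder/expand to full library so downstream shapes are stable
    full <- matrix(0L, nrow = nrow(library), ncol = ncol(counts),
                   dimnames = list(library$id, colnames(counts)))
    full[rownames(counts), ] <- counts
    counts <- full
  }
  if (!is.null(samples)) {
    if (!setequal(samples$sample_id, colnames(counts)) ||
        nrow(samples) != ncol(counts)) {
      stop("sample metadata does not match count columns")
    }
    samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  ns <- ncol(counts)
  obj <- list(counts = counts, library = library, samples = samples,
              unassigned = stats::setNames(rep_len(as.integer(unassigned), ns), colnames(counts)),
              ambiguous = stats::setNames(rep_len(as.integer(ambiguous), ns), colnames(counts)))
  class(obj) <- "barcode_count_table"
  obj
}

#' @export
print.barcode_count_table <- function(x, ...) {
  cat("barcode_count_table:", nrow(x$counts), "barcodes x", ncol(x$counts), "samples\n")
  cat("  total assigned:", sum(x$counts),
      "| unassigned:", sum(x$unassigned),
      "| ambiguous:", sum(x$ambiguous), "\n")
  invisible(x)
}

#' @export
dim.barcode_count_table <- function(x) dim(x$counts)

#' Write / read a barcode count table as TSV
#'
#' Tab-separated, first column `barcode_id`, remaining columns one per
#' sample. `write_count_table()` then [read_count_table()] reproduces the
#' count matrix bit-exactly.
#'
#' @param x a `barcode_count_table` (or bare integer matrix with dimnames).
#' @param path output TSV path.
#' @return `write_count_table()` returns `path` invisibly.
#' @export
write_count_table <- function(x, path) {
  m <- if (inherits(x, "barcode_count_table")) x$counts else as.matrix(x)
  df <- data.frame(barcode_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param library optional [barcode_library()]; ids are validated against it.
#' @param samples optional [sample_meta()].
#' @return `read_count_table()` returns a `barcode_count_table`.
#' @export
read_count_table <- function(path, library = NULL, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty count table: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (ncol(m) && !is.numeric(m)) stop("non-numeric entries in count table: ", path)
  if (any(is.na(m))) stop("missing values in count table: ", path)
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  rownames(m) <- as.character(df[[1L]])
  barcode_count_table(m, library = library, samples = samples)
}

#' Read total sorted cancer cell counts
#'
#' Per (mouse, organ) totals of cancer cells isolated by sorting; the
#' `c_i` term of the absolute metastatic potential.
#'
#' @param path CSV with columns `mouse_id`, `organ`, `total_cells`.
#' @return data.frame of class `cell_count_table`.
#' @export
read_cell_counts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "organ", "total_cells")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cell-count CSV missing column(s): ", paste(miss, collapse = ", "))
  cell_count_table(tab$mouse_id, tab$organ, tab$total_cells)
}

#' @rdname read_cell_counts
#' @param mouse_id,organ,total_cells vectors defining the table directly.
#' @export
cell_count_table <- function(mouse_id, organ, total_cells) {
  total_cells <- as.numeric(total_cells)
  if (any(is.na(total_cells)) || any(total_cells < 0)) {
    stop("total_cells must be non-negative numbers")
  }
  tab <- data.frame(mouse_id = as.character(mouse_id),
                    organ = as.character(organ),
                    total_cells = total_cells, stringsAsFactors = FALSE)
  class(tab) <- c("cell_count_table", "data.frame")
  tab
}

#' Construct an expression matrix
#'
#' Genes x samples abundance matrix with an explicit scale. Negative values
#' are rejected on the `counts` and `cpm` scales (abundances) but allowed on
#' `log2`.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param scale one of `"counts"`, `"cpm"`, `"log2"`.
#' @param samples optional [sample_meta()].
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("counts", "cpm", "log2"),
                              samples = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene-id rownames")
  if (is.null(colnames(values))) stop("expression matrix needs sample-id colnames")
  if (scale %in% c("counts", "cpm") && any(values < 0, na.rm = TRUE)) {
    stop("negative values not allowed on scale '", scale, "'")
  }
  obj <- list(values = values, gene_ids = rownames(values),
              samples = samples, scale = scale)
  class(obj) <- "expression_matrix"
  obj
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples, scale =", x$scale, "\n")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV, first column gene ids, header row sample ids.
#' @param scale scale of the stored values (see [expression_matrix()]).
#' @param allow_missing if `FALSE` (default) any NA/NaN entry is an error.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, scale = c("counts", "cpm", "log2"),
                                   allow_missing = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!allow_missing && any(!is.finite(m))) {
    stop("missing/non-finite entries in ", path, " (set allow_missing = TRUE to accept)")
  }
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV
#' @param x an `expression_matrix` or plain matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
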