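#' Percentile bootstrap confidence interval
#'
#' Resamples the input values (one value per mouse — the mouse is the
#' biological replicate) with replacement `B` times, recomputes the
#' statistic, and returns the percentile interval. Deterministic given
#' `seed`.
#'
#' @param values numeric vector of per-mouse values.
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level in (0, 1), default 0.95.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param statistic function of a numeric vector, default [mean()].
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, B = 1000L, level = 0.95, seed = NULL,
                         statistic = mean) {
  if (B < 1) stop("B must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) return(c(low = NA_real_, high = NA_real_))
  stats <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    apply(idx, 2L, function(i) statistic(values[i]))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1L], high = q[2L])
}

#' Penetrance: fraction of mice in which each line is detected
#'
#' A line is detected in a mouse/organ sample when its raw count passes the
#' detection rule: at least `min_reads` reads (default 5), or at least
#' `min_fraction` of the sample's assigned reads if given.
#'
#' @param counts a [barcode_count_table()] whose samples carry `mouse_id`
#'   and `organ` metadata.
#' @param min_reads integer detection floor on raw reads.
#' @param min_fraction optional fractional detection threshold; overrides
#'   `min_reads` when supplied.
#' @param by_line aggregate barcodes to cell lines (default TRUE when a
#'   library is attached).
#' @return numeric matrix, lines x organs, of detection fractions in [0, 1].
#' @export
penetrance <- function(counts, min_reads = 5L, min_fraction = NULL,
                       by_line = !is.null(counts$library)) {
  stopifnot(inherits(counts, "barcode_count_table"), !is.null(counts$samples))
  m <- line_counts(counts, by_line)
  meta <- counts$samples
  keep <- meta$organ != "pre_injection"
  m <- m[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  organs <- unique(meta$organ)
  out <- matrix(NA_real_, nrow = nrow(m), ncol = length(organs),
                dimnames = list(rownames(m), organs))
  for (org in organs) {
    cols <- which(meta$organ == org)
    sub <- m[, cols, drop = FALSE]
    det <- if (is.null(min_fraction)) {
      sub >= min_reads
    } else {
      tot <- colSums(sub)
      sweep(sub, 2L, pmax(tot, 1), "/") >= min_fraction & sub > 0
    }
    out[, org] <- rowMeans(det)
  }
  out
}

# Collapse barcode rows to cell-line rows (sum). One barcode per line in
# the standard design, so this is usually the identity up to renaming.
line_counts <- function(counts, by_line = TRUE) {
  m <- counts$counts
  if (!by_line || is.null(counts$library)) return(m)
  lines <- counts$library$cell_line[match(rownames(m), counts$library$id)]
  rowsum(m, group = lines, reorder = FALSE)
}

new_potential_table <- function(potential, ci_low, ci_high, penetrance,
                                n_mice, kind) {
  obj <- list(potential = potential, ci_low = ci_low, ci_high = ci_high,
              penetrance = penetrance, n_mice = n_mice, kind = kind)
  class(obj) <- "potential_table"
  obj
}

#' @export
print.potential_table <- function(x, ...) {
  cat("potential_table (", x$kind, "): ", nrow(x$potential), " lines x ",
      ncol(x$potential), " organs\n", sep = "")
  invisible(x)
}

#' Absolute metastatic potential
#'
#' For each cell line j and organ i, the mean over mice of the inferred
#' cancer cell number: `M_ij = (1/n) * sum_k c_ik * p_jk`, where `c_ik` is
#' the total number of cancer cells sorted from organ i of mouse k and
#' `p_jk` the barcode fraction of line j in that sample. Units: cells.
#' Percentile-bootstrap confidence intervals resample mice.
#'
#' @param counts a [barcode_count_table()] with `mouse_id`/`organ` metadata
#'   (pre-injection samples ignored).
#' @param cell_counts a [cell_count_table()] of sorted totals per
#'   (mouse, organ).
#' @param B,level,seed bootstrap settings, see [bootstrap_ci()].
#' @param min_reads detection floor for the penetrance matrix.
#' @return a `potential_table` with `kind = "absolute"`.
#' @export
absolute_potential <- function(counts, cell_counts, B = 1000L, level = 0.95,
                               seed = NULL, min_reads = 5L) {
  stopifnot(inherits(counts, "barcode_count_table"), !is.null(counts$samples))
  m <- line_counts(counts)
  meta <- counts$samples
  keep <- meta$organ != "pre_injection"
  m <- m[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  key <- paste(meta$mouse_id, meta$organ, sep = "\r")
  ckey <- paste(cell_counts$mouse_id, cell_counts$organ, sep = "\r")
  miss <- !(key %in% ckey)
  if (any(miss)) {
    stop("missing total cell count for (mouse, organ): ",
         paste(unique(paste0("(", meta$mouse_id[miss], ", ", meta$organ[miss], ")")),
               collapse = ", "))
  }
  ci <- cell_counts$total_cells[match(key, ckey)]
  comp <- estimate_composition(m)
  # inferred cells per line per sample: c_i * p_j (0 when composition undefined
  # because the whole sample is empty: zero cells sorted implies zero of each line)
  inferred <- sweep(comp$fractions, 2L, ci, "*")
  inferred[, comp$undefined] <- 0
  organs <- unique(meta$organ)
  lines <- rownames(m)
  M <- lo <- hi <- matrix(NA_real_, length(lines), length(organs),
                          dimnames = list(lines, organs))
  n_mice <- stats::setNames(integer(length(organs)), organs)
  for (org in organs) {
    cols <- which(meta$organ == org)
    n_mice[org] <- length(cols)
    sub <- inferred[, cols, drop = FALSE]
    M[, org] <- rowMeans(sub)
    for (j in seq_along(lines)) {
      s <- if (!is.null(seed)) derive_seed(seed, paste0("abs:", lines[j], ":", org)) else NULL
      ciq <- bootstrap_ci(sub[j, ], B = B, level = level, seed = s)
      lo[j, org] <- ciq[1L]; hi[j, org] <- ciq[2L]
    }
  }
  pen <- penetrance(counts, min_reads = min_reads)
  new_potential_table(M, lo, hi, pen[lines, organs, drop = FALSE], n_mice, "absolute")
}

#' Relative metastatic potential
#'
#' For each line j and organ i, the ratio of its mean depth-normalized
#' organ read count across mice to its mean depth-normalized count across
#' pre-injection replicates:
#' `rM_ij = mean_k(cpm_ijk) / mean_m(cpm_j,pre,m)`. Dimensionless; 1 means
#' the line is as abundant in the organ as it was in the injected pool.
#' Lines absent from every pre-injection replicate have no defined ratio
#' and are returned as `NA` with a warning, never as infinity. Confidence
#' intervals bootstrap the organ mice; the pre-injection denominator is
#' held at its across-replicate mean.
#'
#' @inheritParams absolute_potential
#' @param pre_organ metadata organ value marking pre-injection samples.
#' @return a `potential_table` with `kind = "relative"`.
#' @export
relative_potential <- function(counts, B = 1000L, level = 0.95, seed = NULL,
                               min_reads = 5L, pre_organ = "pre_injection") {
  stopifnot(inherits(counts, "barcode_count_table"), !is.null(counts$samples))
  meta <- counts$samples
  is_pre <- meta$organ == pre_organ
  if (!any(is_pre)) stop("no pre-injection samples (organ == '", pre_organ, "')")
  m <- line_counts(counts)
  tot <- colSums(m)
  if (any(tot[is_pre] == 0)) {
    stop("zero-total pre-injection sample(s): ",
         paste(colnames(m)[is_pre & tot == 0], collapse = ", "))
  }
  if (any(tot == 0)) {
    # an organ sample with no assigned reads contributes zero abundance
    # for every line; it stays in the mouse average rather than erroring
    warning("organ sample(s) with zero assigned reads: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
  }
  cpm <- m
  nz <- tot > 0
  cpm[, nz] <- depth_normalize(m[, nz, drop = FALSE])
  pre_mean <- rowMeans(cpm[, is_pre, drop = FALSE])
  undef <- pre_mean == 0
  if (any(undef)) {
    warning("line(s) with zero pre-injection counts; rM undefined: ",
            paste(rownames(m)[undef], collapse = ", "))
  }
  org_meta <- meta[!is_pre, , drop = FALSE]
  org_cpm <- cpm[, !is_pre, drop = FALSE]
  organs <- unique(org_meta$organ)
  lines <- rownames(m)
  rM <- lo <- hi <- matrix(NA_real_, length(lines), length(organs),
                           dimnames = list(lines, organs))
  n_mice <- stats::setNames(integer(length(organs)), organs)
  for (org in organs) {
    cols <- which(org_meta$organ == org)
    n_mice[org] <- length(cols)
    sub <- org_cpm[, cols, drop = FALSE]
    num <- rowMeans(sub)
    rM[, org] <- ifelse(undef, NA_real_, num / pre_mean)
    for (j in seq_along(lines)) {
      if (undef[j]) next
      s <- if (!is.null(seed)) derive_seed(seed, paste0("rel:", lines[j], ":", org)) else NULL
      ciq <- bootstrap_ci(sub[j, ] / pre_mean[j], B = B, level = level, seed = s)
      lo[j, org] <- ciq[1L]; hi[j, org] <- ciq[2L]
    }
  }
  pen <- penetrance(counts, min_reads = min_reads)
  new_potential_table(rM, lo, hi, pen[lines, organs, drop = FALSE], n_mice, "relative")
}

#' Overall metastatic potential
#'
#' Collapses a relative potential table to one scalar per line: the mean
#' across organs of `log10(max(rM, floor))`. The floor (default 1e-4)
#' bounds the penalty for organs where a line was never detected; 0 means
#' pool-level abundance in every organ, -4 means undetected everywhere.
#'
#' @param table a `potential_table` with `kind == "relative"`.
#' @param floor lower bound applied to rM before the log.
#' @param agg aggregation over organs, default [mean()].
#' @return named numeric vector, one value per line (NA where every organ
#'   is undefined).
#' @export
overall_potential <- function(table, floor = 1e-4, agg = mean) {
  stopifnot(inherits(table, "potential_table"))
  if (table$kind != "relative") stop("overall potential is defined for relative tables")
  if (ncol(table$potential) == 0L) stop("empty organ set")
  lp <- log10(pmax(table$potential, floor))
  apply(lp, 1L, function(x) if (all(is.na(x))) NA_real_ else agg(x[!is.na(x)]))
}

#' Export petal-plot quantities
#'
#' Long-format CSV of the quantities a petal plot draws: per (line, organ)
#' the potential (petal length), its confidence bounds, and penetrance
#' (petal width).
#'
#' @param table a `potential_table`.
#' @param path optional CSV path; when `NULL` the data.frame is returned
#'   without writing.
#' @return the long data.frame, invisibly when written.
#' @export
export_petal <- function(table, path = NULL) {
  stopifnot(inherits(table, "potential_table"))
  lines <- rownames(table$potential)
  organs <- colnames(table$potential)
  df <- data.frame(
    line = rep(lines, times = length(organs)),
    organ = rep(organs, each = length(lines)),
    potential = as.vector(table$potential),
    ci_low = as.vector(table$ci_low),
    ci_high = as.vector(table$ci_high),
    penetrance = as.vector(table$penetrance),
    stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
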