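#' In-silico mixture expression profile
#'
#' The composition-matched control for an in vivo metastasis sample: the
#' weighted average of the baseline (in vitro) profiles of the lines
#' present in the sample, `g_hat_i = sum_j g_ij * p_j`, computed on the
#' linear (non-log) scale because read-derived proportions mix linearly in
#' abundance.
#'
#' @param invitro an [expression_matrix()] on a linear scale (`counts` or
#'   `cpm`), one column per cell line.
#' @param composition named numeric vector of line fractions summing to 1
#'   (within 1e-6), or a [estimate_composition()] column.
#' @return numeric vector over genes (class `mixture_profile`, with the
#'   composition attached as attribute `composition_used`).
#' @export
insilico_mixture <- function(invitro, composition) {
  stopifnot(inherits(invitro, "expression_matrix"))
  if (invitro$scale == "log2") {
    stop("mixing must be performed on the linear scale, not log2")
  }
  p <- composition[composition > 0]
  if (is.null(names(p))) stop("composition must be named by cell line")
  if (abs(sum(composition, na.rm = TRUE) - 1) > 1e-6) {
    stop("composition does not sum to 1 (got ", format(sum(composition)), ")")
  }
  miss <- setdiff(names(p), colnames(invitro$values))
  if (length(miss)) {
    stop("line(s) in composition missing from in vitro matrix: ",
         paste(miss, collapse = ", "))
  }
  g <- as.vector(invitro$values[, names(p), drop = FALSE] %*% p)
  names(g) <- rownames(invitro$values)
  structure(g, class = "mixture_profile", composition_used = composition)
}

#' Build the in-silico mixture matrix for a set of in vivo samples
#'
#' @param invitro linear-scale [expression_matrix()], columns = cell lines.
#' @param compositions matrix of fractions (lines x samples), e.g.
#'   `estimate_composition(...)$fractions` with rows named by cell line.
#' @return an [expression_matrix()] (same scale as `invitro`) with one
#'   column per in vivo sample.
#' @export
insilico_mixtures <- function(invitro, compositions) {
  cols <- lapply(seq_len(ncol(compositions)), function(s) {
    p <- compositions[, s]
    names(p) <- rownames(compositions)
    as.numeric(insilico_mixture(invitro, p))
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(invitro$values), colnames(compositions))
  expression_matrix(m, scale = invitro$scale)
}

#' Log2 counts-per-million
#'
#' Library-size normalization to counts-per-million followed by a log2
#' transform with a pseudocount; the standard pre-test transform here.
#'
#' @param x an [expression_matrix()] on the `counts` scale or a matrix.
#' @param pseudocount added before the log (default 0.5).
#' @return an [expression_matrix()] on the `log2` scale.
#' @export
log2_cpm <- function(x, pseudocount = 0.5) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  cpm <- sweep(m, 2L, colSums(m) / 1e6, "/")
  expression_matrix(log2(cpm + pseudocount), scale = "log2")
}

#' Composition-corrected paired differential expression
#'
#' Each in vivo sample is paired with its in-silico mixture counterpart,
#' and per-gene paired differences `d = log2(invivo) - log2(insilico)` are
#' tested with a moderated one-sample t-statistic: gene-wise variances are
#' squeezed toward an empirical-Bayes prior ([squeeze_var()]), the
#' statistic is `mean(d) / (s_tilde / sqrt(n))` on `n - 1 + d0` degrees of
#' freedom, and p-values are Benjamini-Hochberg adjusted. Genes whose
#' differences are identical across all pairs carry no variance
#' information and are excluded with a message.
#'
#' @param invivo,insilico [expression_matrix()] objects on the `log2`
#'   scale with matching, paired columns.
#' @param organ_labels optional per-sample organ labels; when given the
#'   test runs separately per organ and results are stacked.
#' @return data.frame with columns `gene`, `organ`, `lfc`, `t`, `df`,
#'   `p_value`, `q_value`.
#' @export
paired_moderated_test <- function(invivo, insilico, organ_labels = NULL) {
  stopifnot(inherits(invivo, "expression_matrix"),
            inherits(insilico, "expression_matrix"))
  if (invivo$scale != "log2" || insilico$scale != "log2") {
    stop("both matrices must be log2-transformed (see log2_cpm)")
  }
  A <- invivo$values; B <- insilico$values
  if (!identical(dim(A), dim(B))) stop("paired matrices differ in shape")
  if (!identical(rownames(A), rownames(B))) stop("gene ids differ between matrices")
  if (is.null(organ_labels)) organ_labels <- rep("all", ncol(A))
  out <- lapply(unique(organ_labels), function(org) {
    cols <- which(organ_labels == org)
    if (length(cols) < 2L) stop("organ '", org, "' has fewer than 2 pairs")
    d <- A[, cols, drop = FALSE] - B[, cols, drop = FALSE]
    n <- ncol(d)
    mu <- rowMeans(d)
    s2 <- apply(d, 1L, stats::var)
    keep <- s2 > 0
    if (!all(keep)) {
      message(sum(!keep), " constant gene(s) excluded from inference in organ '",
              org, "'")
    }
    sq <- squeeze_var(s2[keep], df = n - 1)
    tt <- p <- rep(NA_real_, nrow(d))
    tt[keep] <- mu[keep] / sqrt(sq$var_post / n)
    # total df cannot exceed the information in all genes combined
    dfree <- min(n - 1 + sq$df_prior, (n - 1) * sum(keep))
    p[keep] <- 2 * stats::pt(-abs(tt[keep]), df = dfree)
    data.frame(gene = rownames(d), organ = org, lfc = mu,
               t = tt, df = dfree, p_value = p, q_value = bh_fdr(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  sets
}

#' Mean-z signature score
#'
#' Per-sample score of a gene set: each gene is standardized across
#' samples (z-score), and the score is the mean z over set genes present
#' in the matrix. Transparent replacement for projection-style single-
#' sample enrichment: scores are comparable across samples, invariant to
#' gene-wise affine rescaling.
#'
#' @param expr an [expression_matrix()] on the `log2` scale.
#' @param gene_set character vector of gene ids.
#' @return named numeric vector, one score per sample.
#' @export
signature_score <- function(expr, gene_set) {
  stopifnot(inherits(expr, "expression_matrix"))
  hit <- intersect(gene_set, rownames(expr$values))
  if (length(hit) == 0L) {
    stop("no gene of the set is present in the matrix; missing: ",
         paste(utils::head(setdiff(gene_set, rownames(expr$values)), 10L),
               collapse = ", "))
  }
  m <- expr$values[hit, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  use <- sdv > 0
  if (!any(use)) stop("every set gene is constant across samples")
  z <- sweep(sweep(m[use, , drop = FALSE], 1L, mu[use], "-"), 1L, sdv[use], "/")
  colMeans(z)
}
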