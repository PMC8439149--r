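#' Construct / read a CRISPR guide library
#'
#' Guides targeting genes plus non-targeting controls. Controls are marked
#' either with `is_control = TRUE` or with gene equal to `"control"`.
#'
#' @param guide_id unique guide identifiers.
#' @param gene target gene per guide (controls may use `"control"`).
#' @param sequence optional ~20-nt protospacer sequences.
#' @param is_control logical; defaults to `gene == "control"`.
#' @return data.frame of class `guide_library`.
#' @export
guide_library <- function(guide_id, gene, sequence = NA_character_,
                          is_control = NULL) {
  guide_id <- as.character(guide_id); gene <- as.character(gene)
  if (anyDuplicated(guide_id)) {
    stop("duplicate guide_id: ",
         paste(unique(guide_id[duplicated(guide_id)]), collapse = ", "))
  }
  if (is.null(is_control)) is_control <- tolower(gene) == "control"
  gl <- data.frame(guide_id = guide_id, gene = gene,
                   sequence = rep_len(as.character(sequence), length(guide_id)),
                   is_control = rep_len(as.logical(is_control), length(guide_id)),
                   stringsAsFactors = FALSE)
  class(gl) <- c("guide_library", "data.frame")
  gl
}

#' @rdname guide_library
#' @param path CSV with columns guide_id, gene, and optionally sequence,
#'   is_control.
#' @export
read_guide_library <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("guide_id", "gene"), names(tab))
  if (length(miss)) stop("guide CSV missing column(s): ", paste(miss, collapse = ", "))
  guide_library(tab$guide_id, tab$gene,
                sequence = if ("sequence" %in% names(tab)) tab$sequence else NA,
                is_control = if ("is_control" %in% names(tab)) tab$is_control else NULL)
}

#' Upper-quartile depth normalization
#'
#' Scales each sample so that the 75th percentile of its nonzero guide
#' counts equals the geometric mean of the per-sample 75th percentiles.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param counts numeric matrix, guides x samples.
#' @return normalized numeric matrix of the same shape.
#' @export
upper_quartile_normalize <- function(counts) {
  m <- as.matrix(counts)
  q75 <- apply(m, 2L, function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0L) stop("all-zero sample in guide count matrix")
    stats::quantile(nz, 0.75, names = FALSE, type = 7)
  })
  target <- exp(mean(log(q75)))
  sweep(m, 2L, q75 / target, "/")
}

#' Guide depletion / enrichment scoring for a mini-pool screen
#'
#' Counts are upper-quartile normalized and log2-transformed with a 0.5
#' pseudocount. Each guide's log2 fold-change is its mean across tissue
#' samples minus its mean across reference samples. Gene-level inference
#' contrasts each gene's guide LFCs against the control-guide LFC
#' distribution with a two-sample moderated t (pooled variances squeezed
#' across genes, [squeeze_var()]), which anchors the null to the screen's
#' global outgrowth behaviour; p-values are Benjamini-Hochberg adjusted
#' across genes. The reported gene LFC is the mean of its guides' LFCs.
#'
#' @param counts guide count matrix (guides x samples), raw or already
#'   normalized (`normalize = FALSE`).
#' @param library a [guide_library()] covering the rows.
#' @param reference,tissue column names (or logical/integer indices) of
#'   the reference (e.g. pre-injection pool) and tissue samples.
#' @param normalize apply [upper_quartile_normalize()] first.
#' @return list of class `screen_result` with `genes` (gene, n_guides,
#'   lfc, delta_vs_control, t, p_value, q_value) and `guides` (guide_id,
#'   gene, is_control, lfc).
#' @export
guide_depletion <- function(counts, library, reference, tissue,
                            normalize = TRUE) {
  m <- as.matrix(counts)
  stopifnot(inherits(library, "guide_library"))
  unknown <- setdiff(rownames(m), library$guide_id)
  if (length(unknown)) stop("guide(s) absent from library: ",
                            paste(unknown, collapse = ", "))
  ref_idx <- if (is.character(reference)) match(reference, colnames(m)) else reference
  tis_idx <- if (is.character(tissue)) match(tissue, colnames(m)) else tissue
  if (any(is.na(ref_idx)) || any(is.na(tis_idx))) stop("unknown sample name in design")
  if (length(tis_idx) < 2L) stop("need >= 2 tissue replicates")
  if (normalize) m <- upper_quartile_normalize(m)
  lg <- log2(m + 0.5)
  lfc <- rowMeans(lg[, tis_idx, drop = FALSE]) -
         rowMeans(lg[, ref_idx, drop = FALSE])
  lib <- library[match(rownames(m), library$guide_id), ]
  ctrl_lfc <- lfc[lib$is_control]
  if (length(ctrl_lfc) < 2L) stop("need >= 2 control guides")
  genes <- unique(lib$gene[!lib$is_control])
  n0 <- length(ctrl_lfc); m0 <- mean(ctrl_lfc); v0 <- stats::var(ctrl_lfc)
  rows <- lapply(genes, function(g) {
    gl <- lfc[!lib$is_control & lib$gene == g]
    ng <- length(gl)
    if (ng == 0L) return(NULL)
    vg <- if (ng > 1L) stats::var(gl) else NA_real_
    s2 <- (ifelse(ng > 1, (ng - 1) * vg, 0) + (n0 - 1) * v0) / (ng + n0 - 2)
    data.frame(gene = g, n_guides = ng, lfc = mean(gl),
               delta_vs_control = mean(gl) - m0, s2 = s2, df = ng + n0 - 2,
               stringsAsFactors = FALSE)
  })
  dropped <- genes[vapply(rows, is.null, TRUE)]
  if (length(dropped)) message("gene(s) with 0 guides excluded: ",
                               paste(dropped, collapse = ", "))
  gt <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  sq <- squeeze_var(gt$s2, df = gt$df)
  gt$t <- gt$delta_vs_control / sqrt(sq$var_post * (1 / gt$n_guides + 1 / n0))
  gt$p_value <- 2 * stats::pt(-abs(gt$t), df = gt$df + sq$df_prior)
  gt$q_value <- bh_fdr(gt$p_value)
  gt$s2 <- NULL; gt$df <- NULL
  guides <- data.frame(guide_id = rownames(m), gene = lib$gene,
                       is_control = lib$is_control, lfc = lfc,
                       stringsAsFactors = FALSE, row.names = NULL)
  out <- list(genes = gt, guides = guides)
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", nrow(x$genes), "genes,", nrow(x$guides), "guides (",
      sum(x$guides$is_control), "controls)\n")
  invisible(x)
}
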