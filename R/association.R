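#' Binarize relative copy-number values into loss/gain tracks
#'
#' Each gene yields two binary feature tracks: `loss` where the relative
#' copy-number value is <= -1 and `gain` where it is >= +1. Missing values
#' propagate.
#'
#' @param cn numeric matrix of relative copy-number values, genes x lines.
#' @return binary matrix (2 * genes) x lines with rownames
#'   `<gene>_loss` / `<gene>_gain`, attribute
#'   `feature_type = "copy_number_binary"`.
#' @export
binarize_copy_number <- function(cn) {
  cn <- as.matrix(cn)
  if (is.null(rownames(cn))) stop("copy-number matrix needs gene rownames")
  loss <- (cn <= -1) * 1
  gain <- (cn >= 1) * 1
  rownames(loss) <- paste0(rownames(cn), "_loss")
  rownames(gain) <- paste0(rownames(cn), "_gain")
  out <- rbind(loss, gain)
  attr(out, "feature_type") <- "copy_number_binary"
  out
}

#' Form high/low potential classes from overall potential
#'
#' Two-threshold gating: lines above `high_cutoff` are `high`, below
#' `low_cutoff` are `low`, in between (or NA) `excluded`.
#'
#' @param overall named numeric vector from [overall_potential()].
#' @param high_cutoff,low_cutoff thresholds on the overall (log10) scale.
#' @return named factor with levels high/low/excluded.
#' @export
potential_classes <- function(overall, high_cutoff, low_cutoff) {
  if (low_cutoff > high_cutoff) stop("low_cutoff must be <= high_cutoff")
  cls <- rep("excluded", length(overall))
  cls[!is.na(overall) & overall > high_cutoff] <- "high"
  cls[!is.na(overall) & overall < low_cutoff] <- "low"
  factor(stats::setNames(cls, names(overall)),
         levels = c("high", "low", "excluded"))
}

#' Two-class feature association
#'
#' Tests each genomic feature for association with the high-vs-low
#' potential classes. Continuous features use a two-sample moderated t:
#' per-feature pooled variances are squeezed toward an empirical-Bayes
#' prior shared across features ([squeeze_var()]). Binary features use
#' Fisher's exact test on the 2x2 presence table, with the difference in
#' class proportions as effect size. Positive effects are enriched in the
#' high class. Missing values are dropped pairwise per feature; features
#' constant across the used lines are excluded.
#'
#' @param features numeric matrix, features x lines (binary features coded
#'   0/1); see [binarize_copy_number()].
#' @param labels factor/character per line with values high/low/excluded,
#'   named or ordered as the columns of `features`.
#' @param type `"auto"` (binary iff all values in {0,1,NA}), `"binary"`,
#'   or `"continuous"`.
#' @param alternative alternative hypothesis for the Fisher test.
#' @return data.frame with `feature`, `effect`, `statistic`, `p_value`,
#'   `q_value`, ordered as the input features (excluded ones dropped).
#' @export
two_class_compare <- function(features, labels,
                              type = c("auto", "binary", "continuous"),
                              alternative = c("two.sided", "greater", "less")) {
  type <- match.arg(type)
  alternative <- match.arg(alternative)
  features <- as.matrix(features)
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("feature", seq_len(nrow(features)))
  }
  if (!is.null(names(labels)) && !is.null(colnames(features))) {
    labels <- labels[colnames(features)]
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(features)) stop("labels do not match feature columns")
  use <- labels %in% c("high", "low")
  x <- features[, use, drop = FALSE]
  grp <- labels[use]
  if (sum(grp == "high") < 2L || sum(grp == "low") < 2L) {
    stop("need >= 2 lines per class (high: ", sum(grp == "high"),
         ", low: ", sum(grp == "low"), ")")
  }
  if (type == "auto") {
    vals <- x[is.finite(x)]
    type <- if (all(vals %in% c(0, 1))) "binary" else "continuous"
  }
  hi <- grp == "high"
  if (type == "binary") {
    res <- apply(x, 1L, function(v) {
      ok <- is.finite(v)
      if (sum(ok & hi) < 1L || sum(ok & !hi) < 1L) return(c(NA, NA, NA))
      a <- sum(v[ok & hi] == 1); b <- sum(ok & hi) - a
      c2 <- sum(v[ok & !hi] == 1); d <- sum(ok & !hi) - c2
      if ((a + c2) == 0 || (a + c2) == sum(ok)) return(c(NA, NA, NA))  # constant
      p <- stats::fisher.test(matrix(c(a, b, c2, d), 2L, byrow = TRUE),
                              alternative = alternative)$p.value
      c(a / (a + b) - c2 / (c2 + d), NA, p)
    })
    eff <- res[1L, ]; tstat <- res[2L, ]; p <- res[3L, ]
    keep <- !is.na(p)
  } else {
    n1 <- rowSums(!is.na(x[, hi, drop = FALSE])) ; n2 <- rowSums(!is.na(x[, !hi, drop = FALSE]))
    m1 <- rowMeans(x[, hi, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(x[, !hi, drop = FALSE], na.rm = TRUE)
    v1 <- apply(x[, hi, drop = FALSE], 1L, stats::var, na.rm = TRUE)
    v2 <- apply(x[, !hi, drop = FALSE], 1L, stats::var, na.rm = TRUE)
    dfree <- n1 + n2 - 2
    s2 <- ((n1 - 1) * ifelse(is.na(v1), 0, v1) +
           (n2 - 1) * ifelse(is.na(v2), 0, v2)) / dfree
    keep <- n1 >= 2 & n2 >= 2 & s2 > 0
    sq <- squeeze_var(s2[keep], df = dfree[keep])
    eff <- m1 - m2
    tstat <- rep(NA_real_, nrow(x))
    tstat[keep] <- eff[keep] / sqrt(sq$var_post * (1 / n1[keep] + 1 / n2[keep]))
    p <- rep(NA_real_, nrow(x))
    p[keep] <- 2 * stats::pt(-abs(tstat[keep]), df = dfree[keep] + sq$df_prior)
  }
  out <- data.frame(feature = rownames(x), effect = eff, statistic = tstat,
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[keep, , drop = FALSE]
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Rank top associated features
#'
#' Orders features by signed effect size (descending), breaking ties by
#' smaller q-value and then feature name; deterministic.
#'
#' @param result a [two_class_compare()] data.frame.
#' @param k number of features to return (default all).
#' @return the reordered data.frame, truncated to `k` rows.
#' @export
rank_top_correlates <- function(result, k = nrow(result)) {
  ord <- order(-result$effect, result$q_value, result$feature)
  utils::head(result[ord, , drop = FALSE], k)
}
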