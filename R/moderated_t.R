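# Empirical-Bayes variance moderation.
#
# Gene-wise sample variances s2 with d residual df are modelled as scaled
# F draws around a prior variance s0^2 with d0 prior df. The prior is
# estimated by moment matching on z = log(s2): for a scaled chi-square,
# E[log s2] and Var[log s2] are digamma/trigamma expressions in (d, d0),
# so d0 solves trigamma(d0/2) = Var[e] - trigamma(d/2) with
# e = z - digamma(d/2) + log(d/2), and s0^2 follows from the mean of e.
# The posterior ("squeezed") variance is the df-weighted blend
# (d0*s0^2 + d*s2) / (d0 + d), and moderated t-statistics gain d0 df.

trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Squeeze gene-wise variances toward an empirical-Bayes prior
#'
#' Estimates the prior degrees of freedom and prior variance by moment
#' matching of the log sample variances, and returns the posterior
#' variances used by the moderated t-statistic.
#'
#' @param s2 numeric vector of gene-wise sample variances (zeros and NAs
#'   are ignored for prior estimation).
#' @param df residual degrees of freedom of each variance (scalar or
#'   vector).
#' @return list with `df_prior`, `var_prior`, `var_post`.
#' @export
squeeze_var <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) {
    # too few informative genes to estimate a prior: no moderation
    return(list(df_prior = 0, var_prior = NA_real_, var_post = s2))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ev <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.na(ev) || ev <= 0) {
    df_prior <- Inf
    var_prior <- exp(mean(e))
  } else {
    df_prior <- 2 * trigamma_inverse(ev)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.infinite(df_prior)) {
    rep(var_prior, length(s2))
  } else {
    (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  var_post[!is.finite(s2)] <- NA_real_
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NAs passed through).
#' @return q-values on [0, 1], same length and order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
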