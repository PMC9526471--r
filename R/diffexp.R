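#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with a
#' positive geometric mean, of the ratio of the sample's count to that
#' geometric mean; the factors are rescaled to have geometric mean 1.
#'
#' @param x an [mtc_counts] or a count matrix.
#' @return Named numeric vector of positive size factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)
size_factors <- function(x) {
  counts <- if (inherits(x, "mtc_counts")) x$counts else x
  abort_if(!is.matrix(counts), "`x` must be a matrix or mtc_counts")
  zero <- colSums(counts) == 0
  abort_if(any(zero),
           paste0("sample(s) with all-zero counts: ",
                  paste(colnames(counts)[zero], collapse = ", ")))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  abort_if(!any(use), "no gene has a positive geometric mean")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnts) {
    exp(median(log(cnts[cnts > 0]) - log_geo[use][cnts > 0]))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with cumulative-minimum
#' enforcement, capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  abort_if(any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1),
           "p-values must lie in [0, 1]")
  n <- length(pvalues)
  if (n <= 1) return(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * pvalues[o]))[ro]
}

#' Two-group negative-binomial Wald test for one cohort context
#'
#' Tests MTC vs non-MTC differential expression within one context (training
#' `FNAB` samples or `tissue` samples) under a negative-binomial model with
#' per-gene moment dispersion. For each gene, class means of size-factor
#' normalized counts give the log2 fold change; its delta-method standard
#' error uses the NB variance `mu/s + alpha * mu^2`, and the two-sided Wald
#' p-value is the normal tail of `log2fc / se`. Genes with zero counts in
#' both classes get `p = 1` and `log2fc = 0`; when exactly one class mean is
#' zero, a pseudocount of 0.5 is added to both class means.
#'
#' @param x an [mtc_counts] containing the context's samples (training-split
#'   FNAB samples are used for the FNAB context).
#' @param context `"FNAB"` or `"tissue"`.
#' @return Tibble with columns `gene_id`, `context`, `base_mean`, `log2fc`,
#'   `se`, `wald_p`, `adj_p` (BH-adjusted within the context).
#' @export
nb_wald_test <- function(x, context = c("FNAB", "tissue")) {
  stopifnot(inherits(x, "mtc_counts"))
  context <- match.arg(context)
  sub <- if (context == "FNAB") {
    filter_samples(x, .data$cohort == "FNAB", .data$split == "train")
  } else {
    filter_samples(x, .data$cohort == "tissue")
  }
  lab <- sub$meta$label
  abort_if(!all(c("MTC", "non-MTC") %in% lab),
           paste0("both classes must be present in the ", context, " context"))
  idx1 <- lab == "MTC"; idx2 <- lab == "non-MTC"
  abort_if(sum(idx1) < 2 || sum(idx2) < 2,
           "each class needs >= 2 samples for the variance to be identifiable")
  sf <- size_factors(sub)
  q <- sweep(sub$counts, 2, sf, "/")
  q1 <- q[, idx1, drop = FALSE]; q2 <- q[, idx2, drop = FALSE]
  n1 <- ncol(q1); n2 <- ncol(q2)
  mu1 <- rowMeans(q1); mu2 <- rowMeans(q2)
  v1 <- row_vars(q1); v2 <- row_vars(q2)
  inv_s1 <- mean(1 / sf[idx1]); inv_s2 <- mean(1 / sf[idx2])

  # moment estimate of dispersion: Var(K/s) = mu/s + alpha * mu^2
  mom <- function(v, mu, inv_s) ifelse(mu > 0, (v - mu * inv_s) / mu^2, NA_real_)
  a1 <- mom(v1, mu1, inv_s1); a2 <- mom(v2, mu2, inv_s2)
  w1 <- ifelse(is.na(a1), 0, n1 - 1); w2 <- ifelse(is.na(a2), 0, n2 - 1)
  alpha <- (ifelse(is.na(a1), 0, a1) * w1 + ifelse(is.na(a2), 0, a2) * w2) /
    pmax(w1 + w2, 1)
  alpha <- pmax(alpha, 1e-8)

  both_zero <- mu1 == 0 & mu2 == 0
  some_zero <- (mu1 == 0 | mu2 == 0) & !both_zero
  m1 <- ifelse(some_zero, mu1 + 0.5, mu1)
  m2 <- ifelse(some_zero, mu2 + 0.5, mu2)
  log2fc <- ifelse(both_zero, 0, log2(m1 / m2))
  var_mean <- function(m, n, inv_s) (m * inv_s + alpha * m^2) / n
  se <- sqrt(var_mean(m1, n1, inv_s1) / m1^2 +
               var_mean(m2, n2, inv_s2) / m2^2) / log(2)
  se[both_zero] <- NA_real_
  z <- ifelse(both_zero, 0, log2fc / se)
  wald_p <- ifelse(both_zero, 1, 2 * pnorm(-abs(z)))
  tibble::tibble(
    gene_id = rownames(sub$counts),
    context = context,
    base_mean = rowMeans(q),
    log2fc = log2fc,
    se = se,
    wald_p = wald_p,
    adj_p = bh_adjust(wald_p)
  )
}

#' Differential-expression table across both cohort contexts
#'
#' Runs [nb_wald_test()] in the FNAB and tissue contexts and binds the
#' results, giving the dual-context table the feature-selection rules
#' consume.
#'
#' @param x an [mtc_counts] with training FNAB and tissue samples.
#' @return Tibble of class `mtc_de` (one row per gene per context).
#' @export
de_table <- function(x) {
  out <- dplyr::bind_rows(nb_wald_test(x, "FNAB"), nb_wald_test(x, "tissue"))
  class(out) <- c("mtc_de", class(out))
  out
}

#' Genes differentially expressed in both cohort contexts
#'
#' Selects genes whose BH-adjusted p-value is below `p_cut` in both the FNAB
#' and tissue contexts, and — when `fc_cut` is given — whose log2 fold change
#' exceeds `fc_cut` in both contexts. The fold-change rule is one-sided:
#' genes overexpressed in MTC, matching a positive-signal cassette.
#'
#' @param de a dual-context DE table from [de_table()].
#' @param p_cut adjusted-p threshold.
#' @param fc_cut optional log2-fold-change floor (one-sided, MTC over
#'   non-MTC); `NULL` disables the fold-change rule.
#' @return Character vector of gene ids ordered by FNAB adjusted p.
#' @export
dual_context_de <- function(de, p_cut, fc_cut = NULL) {
  abort_if(!all(c("FNAB", "tissue") %in% unique(de$context)),
           "DE table must contain both the FNAB and tissue contexts")
  wide <- tidyr::pivot_wider(
    dplyr::select(de, "gene_id", "context", "log2fc", "adj_p"),
    names_from = "context", values_from = c("log2fc", "adj_p")
  )
  keep <- wide$adj_p_FNAB < p_cut & wide$adj_p_tissue < p_cut
  if (!is.null(fc_cut)) {
    keep <- keep & wide$log2fc_FNAB > fc_cut & wide$log2fc_tissue > fc_cut
  }
  wide <- wide[keep, , drop = FALSE]
  wide$gene_id[order(wide$adj_p_FNAB, -abs(wide$log2fc_FNAB), wide$gene_id)]
}
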