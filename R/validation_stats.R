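# Blinded-validation statistics: confusion counts, exact binomial
# confidence intervals, and the one-sample proportion power analysis.

#' Confusion counts against a locked reference standard
#'
#' @param calls character vector of `positive` / `negative` calls (or an
#'   `mtc_scores` tibble).
#' @param reference character vector of reference labels (`MTC` /
#'   `non-MTC`), one per sample.
#' @return One-row tibble: `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @export
#' @examples
#' confusion(rep("positive", 3), rep("MTC", 3))
confusion <- function(calls, reference) {
  if (is.data.frame(calls)) calls <- calls$call
  abort_if(length(calls) == 0, "empty cohort")
  abort_if(length(calls) != length(reference),
           "each sample needs exactly one reference label")
  abort_if(any(is.na(reference)), "sample without reference label")
  pos <- reference == "MTC"
  tp <- sum(calls[pos] == "positive"); fn <- sum(pos) - tp
  tn <- sum(calls[!pos] == "negative"); fp <- sum(!pos) - tn
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = if (any(pos)) tp / (tp + fn) else NA_real_,
                 specificity = if (any(!pos)) tn / (tn + fp) else NA_real_)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from the beta-quantile construction, with the
#' one-sided closed forms at the edges: `lower = 0` when `x = 0` and
#' `upper = 1` when `x = n` (where the lower bound is
#' `(alpha/2)^(1/n)`).
#'
#' @param successes,trials counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(21, 21)   # lower bound 0.839
#' clopper_pearson(190, 190) # lower bound 0.981
clopper_pearson <- function(successes, trials, level = 0.95) {
  abort_if(!is.numeric(successes) || !is.numeric(trials) ||
             successes != round(successes) || trials != round(trials) ||
             trials < 1 || successes < 0 || successes > trials,
           "need integer counts with 0 <= successes <= trials, trials >= 1")
  abort_if(level <= 0 || level >= 1, "level must be in (0, 1)")
  a <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Power of the one-sample proportion test (arcsine approximation)
#'
#' Uses the arcsine-transformation effect size
#' `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p0))` and the normal approximation:
#' one-sided power is `Phi(h sqrt(n) - z_{1-alpha})`; the two-sided analog
#' uses `alpha/2` and both tails.
#'
#' @param p0 null proportion in (0, 1).
#' @param p1 alternative proportion in (0, 1].
#' @param n sample size.
#' @param alpha significance level (default 0.05).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' proportion_power(0.9, 1.0, 21) # > 0.90
proportion_power <- function(p0, p1, n, alpha = 0.05,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  abort_if(p0 <= 0 || p0 >= 1, "p0 must be in (0, 1)")
  abort_if(p1 <= 0 || p1 > 1, "p1 must be in (0, 1]")
  abort_if(n < 1, "n must be >= 1")
  abort_if(alternative == "greater" && p1 < p0,
           "p1 < p0 contradicts alternative = 'greater'")
  h <- 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p0))
  if (alternative == "greater") {
    pnorm(h * sqrt(n) - qnorm(1 - alpha))
  } else {
    pnorm(abs(h) * sqrt(n) - qnorm(1 - alpha / 2)) +
      pnorm(-abs(h) * sqrt(n) - qnorm(1 - alpha / 2))
  }
}

#' Blinded validation of a locked classifier
#'
#' Applies the locked classifier once to the validation cohort, tabulates
#' the confusion counts against the locked reference labels, and reports
#' sensitivity and specificity with two-sided 95% exact binomial intervals
#' plus the one-sample proportion power statement.
#'
#' @param object a locked `mtc_classifier` (unlocked models are refused: the
#'   lock must precede any contact with validation data).
#' @param x validation [mtc_counts] with reference labels.
#' @param level confidence level (default 0.95).
#' @param power_p0 null sensitivity for the power statement (default 0.90).
#' @param alpha significance level of the power statement (default 0.05).
#' @return Object of class `mtc_validation`.
#' @export
validate_classifier <- function(object, x, level = 0.95, power_p0 = 0.9,
                                alpha = 0.05) {
  stopifnot(inherits(object, "mtc_classifier"))
  abort_if(!isTRUE(object$locked),
           "classifier must be locked before validation")
  scores <- predict(object, x)
  cm <- confusion(scores$call, x$meta$label)
  ci_sens <- clopper_pearson(cm$tp, cm$tp + cm$fn, level)
  ci_spec <- clopper_pearson(cm$tn, cm$tn + cm$fp, level)
  pw <- if (cm$sensitivity >= power_p0) {
    proportion_power(power_p0, max(cm$sensitivity, power_p0 + 1e-12),
                     cm$tp + cm$fn, alpha, "greater")
  } else NA_real_
  structure(list(
    confusion = cm, scores = scores,
    ci_sens = ci_sens, ci_spec = ci_spec, level = level,
    power_statement = list(p0 = power_p0, p1 = cm$sensitivity,
                           n = cm$tp + cm$fn, alpha = alpha,
                           sided = "greater", power = pw)
  ), class = "mtc_validation")
}

#' @export
print.mtc_validation <- function(x, ...) {
  cm <- x$confusion
  fmt <- function(p) sprintf("%.1f", 100 * p)
  cat(sprintf("%s%% sensitivity (%d/%d; CI = %s-%s%%)\n",
              fmt(cm$sensitivity), cm$tp, cm$tp + cm$fn,
              fmt(x$ci_sens[["lower"]]), fmt(x$ci_sens[["upper"]])))
  cat(sprintf("%s%% specificity (%d/%d; CI = %s-%s%%)\n",
              fmt(cm$specificity), cm$tn, cm$tn + cm$fp,
              fmt(x$ci_spec[["lower"]]), fmt(x$ci_spec[["upper"]])))
  ps <- x$power_statement
  if (!is.na(ps$power)) {
    cat(sprintf(
      "power to reject sensitivity <= %.0f%% at alpha = %.2f (n = %d): %.1f%%\n",
      100 * ps$p0, ps$alpha, ps$n, 100 * ps$power))
  }
  invisible(x)
}

#' @export
tidy.mtc_validation <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity"),
    estimate = c(x$confusion$sensitivity, x$confusion$specificity),
    successes = c(x$confusion$tp, x$confusion$tn),
    trials = c(x$confusion$tp + x$confusion$fn,
               x$confusion$tn + x$confusion$fp),
    conf.low = c(x$ci_sens[["lower"]], x$ci_spec[["lower"]]),
    conf.high = c(x$ci_sens[["upper"]], x$ci_spec[["upper"]])
  )
}

#' @export
glance.mtc_validation <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 power = x$power_statement$power)
}
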