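# Classifier families: linear SVM and elastic-net logistic regression on
# standardized log2-CPM features, emitting a continuous "logit score" and a
# binary MTC call at a fixed threshold.

#' Expression features for classification
#'
#' Computes `log2(CPM + 1)` per gene (CPM from the sample's total count over
#' all genes, so features are invariant to library size), restricted to the
#' classifier's gene list, then centers and scales each gene. When
#' `normalization` is `NULL` the center/scale parameters are estimated from
#' the supplied (training) samples and attached as
#' `attr(features, "normalization")`; otherwise the stored training
#' parameters are applied unchanged, as required for validation samples.
#'
#' @param x an [mtc_counts].
#' @param genes gene ids to use as features.
#' @param normalization optional list with `center` and `scale` vectors from
#'   a previous call.
#' @return Samples-by-genes feature matrix with a `normalization` attribute.
#' @export
featurize <- function(x, genes, normalization = NULL) {
  stopifnot(inherits(x, "mtc_counts"))
  missing <- setdiff(genes, rownames(x$counts))
  abort_if(length(missing) > 0,
           paste0("genes missing from the count matrix: ",
                  paste(head(missing, 5), collapse = ", ")))
  cpm <- sweep(x$counts, 2, colSums(x$counts), "/") * 1e6
  feat <- t(log2(cpm[genes, , drop = FALSE] + 1))
  if (is.null(normalization)) {
    ctr <- colMeans(feat)
    scl <- apply(feat, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    normalization <- list(center = ctr, scale = scl)
  } else {
    abort_if(!all(genes %in% names(normalization$center)),
             "normalization parameters do not cover the gene list")
    normalization <- list(center = normalization$center[genes],
                          scale = normalization$scale[genes])
  }
  feat <- sweep(sweep(feat, 2, normalization$center, "-"),
                2, normalization$scale, "/")
  attr(feat, "normalization") <- normalization
  feat
}

# canonical JSON of the frozen fields, used for the lock hash
classifier_payload <- function(object) {
  jsonlite::toJSON(list(
    family = object$family,
    feature_set_id = object$feature_set_id,
    genes = object$genes,
    center = unname(object$normalization$center),
    scale = unname(object$normalization$scale),
    weights = unname(object$weights),
    intercept = object$intercept,
    threshold = object$threshold
  ), auto_unbox = TRUE, digits = NA)
}

classifier_hash <- function(object) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(classifier_payload(object)), tf)
  unname(tools::md5sum(tf))
}

#' Train an MTC classifier on a gene list
#'
#' Fits either a linear-kernel soft-margin SVM (class-weighted inversely to
#' class frequency) or an elastic-net logistic regression (mixing `alpha`,
#' penalty strength chosen by internal 3-fold cross-validation unless
#' `lambda` is fixed) on standardized log2-CPM features. The continuous
#' output is the model's "logit score": the signed decision value for the
#' SVM, the log-odds for the elastic net; scores above `threshold` (default
#' 0) are called positive. Both families are reduced to an explicit linear
#' score `w'f + b`, so prediction, serialization and the lock guard share
#' one code path.
#'
#' @param x an [mtc_counts] of training samples with a `label` column
#'   (`MTC` / `non-MTC`).
#' @param genes feature gene ids.
#' @param family `"svm"` or `"enet"`.
#' @param feature_set_id optional id of the candidate set the genes came
#'   from (bookkeeping).
#' @param cost SVM soft-margin cost (default 1).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param lambda optional fixed elastic-net penalty; `NULL` selects it by
#'   internal cross-validation.
#' @param threshold decision cutoff on the score (default 0).
#' @param seed seed for the internal lambda cross-validation folds.
#' @return An object of class `mtc_classifier`.
#' @export
train_mtc_classifier <- function(x, genes, family = c("svm", "enet"),
                                 feature_set_id = NA_integer_, cost = 1,
                                 alpha = 0.5, lambda = NULL, threshold = 0,
                                 seed = 1) {
  stopifnot(inherits(x, "mtc_counts"))
  family <- match.arg(family)
  y <- x$meta$label
  abort_if(length(unique(y)) < 2, "training data must contain both classes")
  feat <- featurize(x, genes)
  norm <- attr(feat, "normalization")
  yf <- factor(y, levels = c("non-MTC", "MTC"))
  if (family == "svm") {
    cw <- length(y) / (2 * table(yf))
    fit <- e1071::svm(feat, yf, kernel = "linear", cost = cost,
                      scale = FALSE, class.weights = cw)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # orient the score so MTC samples score high
    dec <- drop(feat %*% w + b)
    if (mean(dec[yf == "MTC"]) < mean(dec[yf == "non-MTC"])) {
      w <- -w; b <- -b
    }
    hyper <- list(cost = cost)
  } else {
    ybin <- as.integer(yf == "MTC")
    if (is.null(lambda) && min(table(ybin)) >= 3) {
      # class-stratified internal folds so every lambda fit sees both classes
      foldid <- with_seed(seed, {
        f <- integer(length(ybin))
        for (cl in 0:1) {
          idx <- which(ybin == cl)
          f[idx] <- sample(rep_len(1:3, length(idx)))
        }
        f
      })
      cvfit <- glmnet::cv.glmnet(feat, ybin, family = "binomial",
                                 alpha = alpha, foldid = foldid,
                                 nlambda = 30, standardize = FALSE)
      lambda <- cvfit$lambda.min
      fit <- cvfit$glmnet.fit
    } else {
      # too few minority samples for internal CV: light fixed penalty
      if (is.null(lambda)) lambda <- 0.01
      fit <- glmnet::glmnet(feat, ybin, family = "binomial", alpha = alpha,
                            standardize = FALSE)
    }
    cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda))
    b <- cf[1]
    w <- cf[-1]
    hyper <- list(alpha = alpha, lambda = lambda)
  }
  structure(list(
    family = family,
    feature_set_id = as.integer(feature_set_id),
    genes = genes,
    normalization = norm,
    weights = setNames(as.numeric(w), genes),
    intercept = as.numeric(b),
    threshold = threshold,
    hyper = hyper,
    locked = FALSE,
    hash = NA_character_
  ), class = "mtc_classifier")
}

#' Freeze a trained classifier
#'
#' Locks the gene list, normalization, weights and threshold and records a
#' hash of the frozen fields. Any later mutation makes prediction fail, so
#' the model applied to the blinded validation cohort is provably the model
#' that was locked.
#'
#' @param object an `mtc_classifier`.
#' @return The classifier with `locked = TRUE` and its integrity hash.
#' @export
lock_classifier <- function(object) {
  stopifnot(inherits(object, "mtc_classifier"))
  object$locked <- TRUE
  object$hash <- classifier_hash(object)
  object
}

#' Score samples with a trained classifier
#'
#' Applies the stored training normalization and linear weights; no
#' refitting occurs. For a locked classifier the integrity hash is verified
#' first and prediction refuses to run on a mutated model.
#'
#' @param object an `mtc_classifier`.
#' @param x an [mtc_counts] to score.
#' @param ... unused.
#' @return Tibble with `sample_id`, `score`, `call`
#'   (`positive` / `negative`).
#' @export
predict.mtc_classifier <- function(object, x, ...) {
  stopifnot(inherits(x, "mtc_counts"))
  if (isTRUE(object$locked)) {
    abort_if(!identical(classifier_hash(object), object$hash),
             "locked classifier has been modified; refusing to predict")
  }
  feat <- featurize(x, object$genes, normalization = object$normalization)
  score <- drop(feat %*% object$weights + object$intercept)
  out <- tibble::tibble(
    sample_id = x$meta$sample_id,
    score = as.numeric(score),
    call = ifelse(score > object$threshold, "positive", "negative")
  )
  class(out) <- c("mtc_scores", class(out))
  out
}

#' @export
print.mtc_classifier <- function(x, ...) {
  cat(sprintf("<mtc_classifier> family=%s, %d genes, feature set %s, %s\n",
              x$family, length(x$genes),
              ifelse(is.na(x$feature_set_id), "?", x$feature_set_id),
              if (isTRUE(x$locked)) "LOCKED" else "unlocked"))
  invisible(x)
}

#' @export
tidy.mtc_classifier <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$genes),
                 estimate = c(x$intercept, unname(x$weights)))
}

#' @export
glance.mtc_classifier <- function(x, ...) {
  tibble::tibble(family = x$family, feature_set_id = x$feature_set_id,
                 n_genes = length(x$genes),
                 n_nonzero = sum(x$weights != 0),
                 threshold = x$threshold, locked = isTRUE(x$locked))
}
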