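# The 16-setting model competition: 8 candidate feature sets x 2 classifier
# families under repeated stratified cross-validation, followed by the
# four-criterion choice of the single model to lock.

# stratified fold assignment: within each label, samples are permuted and
# dealt round-robin into k folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    abort_if(length(idx) < k,
             paste0("class ", lv, " has fewer samples than folds"))
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

sens_spec <- function(calls, labels) {
  pos <- labels == "MTC"
  c(sens = mean(calls[pos] == "positive"),
    spec = mean(calls[!pos] == "negative"))
}

#' Repeated stratified cross-validation over classifier settings
#'
#' Runs k-fold cross-validation, repeated `repeats` times with fresh
#' stratified fold assignments, for every combination of candidate feature
#' set and classifier family. Feature normalization (and, for the elastic
#' net, the penalty strength) is refit inside each training fold, so no
#' information leaks from the held-out fold. Folds are shared across
#' settings within a repeat so settings are compared on identical splits.
#'
#' @param x an [mtc_counts]; only training-split FNAB samples are used.
#' @param sets long-form feature sets from [build_feature_sets()].
#' @param families classifier families to compete (default both).
#' @param k folds (default 5).
#' @param repeats repeats (default 10).
#' @param seed seed controlling all fold assignments.
#' @param ... passed to [train_mtc_classifier()].
#' @return Tibble of class `mtc_cv` with one row per setting, repeat and
#'   fold: `set_id`, `family`, `rep`, `fold`, `sens`, `spec`.
#' @export
repeated_cv <- function(x, sets, families = c("svm", "enet"), k = 5,
                        repeats = 10, seed = 1, ...) {
  train <- filter_samples(x, .data$cohort == "FNAB", .data$split == "train")
  labels <- train$meta$label
  settings <- tidyr::expand_grid(set_id = unique(sets$set_id),
                                 family = families)
  res <- with_seed(derive_seed(seed, 11L), {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fold <- stratified_folds(labels, k)
      purrr::map_dfr(seq_len(k), function(f) {
        tr <- filter_samples(train, fold != f)
        te <- filter_samples(train, fold == f)
        purrr::map_dfr(seq_len(nrow(settings)), function(i) {
          genes <- feature_set_genes(sets, settings$set_id[i])
          fit <- train_mtc_classifier(tr, genes,
                                      family = settings$family[i],
                                      feature_set_id = settings$set_id[i],
                                      seed = derive_seed(seed, 100L * r + f),
                                      ...)
          ss <- sens_spec(predict(fit, te)$call, te$meta$label)
          tibble::tibble(set_id = settings$set_id[i],
                         family = settings$family[i],
                         rep = r, fold = f,
                         sens = ss[["sens"]], spec = ss[["spec"]])
        })
      })
    })
  })
  class(res) <- c("mtc_cv", class(res))
  res
}

#' Per-setting cross-validation summary
#'
#' @param cv fold-level results from [repeated_cv()].
#' @return Tibble with mean and sd of sensitivity and specificity per
#'   setting.
#' @export
summarize_cv <- function(cv) {
  dplyr::summarise(
    dplyr::group_by(cv, .data$set_id, .data$family),
    mean_sens = mean(.data$sens), sd_sens = sd(.data$sens),
    mean_spec = mean(.data$spec), sd_spec = sd(.data$spec),
    n_folds = dplyr::n(), .groups = "drop"
  )
}

#' Reference cassette score
#'
#' Stand-in for the legacy microarray cassette score: the mean standardized
#' log2-CPM of the 5 cassette genes per sample.
#'
#' @param x an [mtc_counts] (typically training FNAB samples).
#' @param cassette_genes ids of the 5 cassette genes.
#' @return Named numeric vector of per-sample reference scores.
#' @export
reference_cassette_score <- function(x, cassette_genes) {
  feat <- featurize(x, cassette_genes)
  setNames(rowMeans(feat), x$meta$sample_id)
}

#' Four selection criteria for one trained classifier
#'
#' Computes the locked-model selection criteria: (1) margin — the distance
#' between the minimum MTC and maximum non-MTC training scores; (2)
#' control_sd — the pooled within-replicate-group standard deviation of
#' scores on repeatedly sequenced control samples; (3) ref_corr — the
#' Pearson correlation between training scores and the reference cassette
#' score; (4) n_genes — the model size.
#'
#' @param object a trained `mtc_classifier`.
#' @param train training [mtc_counts] (FNAB training samples).
#' @param controls replicate control [mtc_counts]; groups need >= 2
#'   replicates. `NULL` skips the control criterion with a warning.
#' @param reference_scores per-sample reference cassette scores for the
#'   training samples.
#' @return One-row tibble: `set_id`, `family`, `margin`, `control_sd`,
#'   `ref_corr`, `n_genes`.
#' @export
compute_criteria <- function(object, train, controls, reference_scores) {
  sc <- predict(object, train)
  lab <- train$meta$label
  margin <- min(sc$score[lab == "MTC"]) - max(sc$score[lab == "non-MTC"])
  control_sd <- NA_real_
  if (is.null(controls) || ncol(controls$counts) == 0) {
    warning("no control samples; control-variability criterion skipped")
  } else {
    csc <- predict(object, controls)
    grp <- controls$meta$replicate_group
    abort_if(any(table(grp) < 2), "control groups need >= 2 replicates")
    dev <- stats::ave(csc$score, grp, FUN = function(s) s - mean(s))
    control_sd <- sqrt(sum(dev^2) / (length(dev) - length(unique(grp))))
  }
  ref_corr <- cor(sc$score, unname(reference_scores[sc$sample_id]))
  tibble::tibble(set_id = object$feature_set_id, family = object$family,
                 margin = margin, control_sd = control_sd,
                 ref_corr = ref_corr, n_genes = length(object$genes))
}

#' Select the final model by rank-sum over the four criteria
#'
#' Each criterion is converted to a rank across candidates (margin and
#' reference correlation descending, control variability and gene count
#' ascending; ties share the minimum rank) and the candidate with the
#' smallest rank sum wins. Rank-sum ties are broken by fewest genes, then by
#' set id. Criteria with missing values (e.g. no controls) are dropped from
#' the rank sum.
#'
#' @param criteria tibble of per-candidate criteria from
#'   [compute_criteria()].
#' @return The winning row, with the full rank table attached as
#'   `attr(x, "rank_table")`.
#' @export
select_final <- function(criteria) {
  abort_if(is.null(criteria) || nrow(criteria) == 0, "no candidate settings")
  rk <- function(v, desc) rank(if (desc) -v else v, ties.method = "min")
  tab <- dplyr::mutate(
    criteria,
    r_margin = rk(.data$margin, TRUE),
    r_control = if (all(is.na(criteria$control_sd))) 0 else
      rk(.data$control_sd, FALSE),
    r_corr = rk(.data$ref_corr, TRUE),
    r_genes = rk(.data$n_genes, FALSE)
  )
  tab$rank_sum <- tab$r_margin + tab$r_control + tab$r_corr + tab$r_genes
  ord <- order(tab$rank_sum, tab$n_genes, tab$set_id)
  winner <- criteria[ord[1], , drop = FALSE]
  attr(winner, "rank_table") <- tab[ord, ]
  winner
}
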