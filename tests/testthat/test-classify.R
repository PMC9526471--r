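clf_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- simulate_cohorts(small_cfg(seed = 31))
      train <- filter_samples(x, cohort == "FNAB", split == "train")
      truth <- sim_truth_of(x)
      genes <- truth$gene_ids[truth$signature_idx]
      cache <<- list(x = x, train = train, truth = truth, genes = genes,
                     svm = train_mtc_classifier(train, genes, "svm"),
                     enet = train_mtc_classifier(train, genes, "enet"))
    }
    cache
  }
})

test_that("training features are standardized and library-size invariant", {
  f <- clf_fixture()
  feat <- featurize(f$train, f$genes)
  expect_equal(unname(colMeans(feat)), rep(0, length(f$genes)),
               tolerance = 1e-12)
  expect_equal(unname(apply(feat, 2, sd)), rep(1, length(f$genes)),
               tolerance = 1e-12)
  # doubling a sample's library size leaves its features unchanged
  dbl <- f$train
  dbl$counts[, 1] <- dbl$counts[, 1] * 2
  norm <- attr(feat, "normalization")
  expect_equal(featurize(dbl, f$genes, norm)[1, ], feat[1, ],
               tolerance = 1e-12)
  expect_error(featurize(f$train, c(f$genes, "nope")), "missing")
})

test_that("a linearly separable toy problem is fit without training error", {
  cnt <- rbind(gA = c(200, 220, 10, 12),
               gB = c(10, 12, 200, 220),
               gC = c(50, 50, 50, 50),
               gD = c(40, 42, 44, 40))
  colnames(cnt) <- paste0("s", 1:4)
  x <- mtc_counts(cnt, tibble::tibble(sample_id = colnames(cnt),
                                      label = c("MTC", "MTC",
                                                "non-MTC", "non-MTC")))
  fit <- train_mtc_classifier(x, c("gA", "gB"), "svm")
  pred <- predict(fit, x)
  expect_identical(pred$call, c("positive", "positive",
                                "negative", "negative"))
  expect_true(min(pred$score[1:2]) > max(pred$score[3:4]))
})

test_that("elastic net with infinite penalty is intercept-only", {
  f <- clf_fixture()
  fit <- train_mtc_classifier(f$train, f$genes, "enet", lambda = 1e6)
  expect_equal(unname(fit$weights), rep(0, length(f$genes)))
})

test_that("training performance is perfect on simulated cohorts", {
  f <- clf_fixture()
  for (fit in list(f$svm, f$enet)) {
    pred <- predict(fit, f$train)
    expect_identical(pred$call,
                     ifelse(f$train$meta$label == "MTC",
                            "positive", "negative"))
  }
})

test_that("prediction is deterministic and refuses single-class training", {
  f <- clf_fixture()
  expect_identical(predict(f$svm, f$train), predict(f$svm, f$train))
  mtc_only <- filter_samples(f$train, label == "MTC")
  expect_error(train_mtc_classifier(mtc_only, f$genes, "svm"), "both classes")
})

test_that("a locked classifier round-trips through JSON to 1e-9", {
  f <- clf_fixture()
  locked <- lock_classifier(f$svm)
  path <- tempfile(fileext = ".json")
  write_model(locked, path)
  back <- read_model(path)
  expect_true(back$locked)
  s1 <- predict(locked, f$x)$score
  s2 <- predict(back, f$x)$score
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("mutating a locked classifier disables prediction", {
  f <- clf_fixture()
  locked <- lock_classifier(f$svm)
  tampered <- locked
  tampered$weights[1] <- tampered$weights[1] + 1
  expect_error(predict(tampered, f$train), "modified")
  tampered2 <- locked
  tampered2$threshold <- 5
  expect_error(predict(tampered2, f$train), "modified")
})

test_that("scores decrease monotonically under benign dilution", {
  f <- clf_fixture()
  truth <- f$truth
  mtc_prof <- truth$mu * 2^truth$signature_log2fc
  benign_prof <- truth$mu
  fractions <- c(0, 0.25, 0.5, 0.75, 1)
  scores <- vapply(fractions, function(fr) {
    prof <- dilute_sample(mtc_prof, benign_prof, fr)
    d <- simulate_from_profile(prof, truth$dispersion, n = 1,
                               gene_ids = truth$gene_ids, expected = TRUE,
                               meta_extra = list(dilution_fraction = fr))
    predict(f$svm, d)$score
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_gt(scores[1], 0)
  expect_lt(scores[5], 0)
})

test_that("tidy and glance expose coefficients and model shape", {
  f <- clf_fixture()
  td <- tidy(f$svm)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), length(f$genes) + 1)
  gl <- glance(f$enet)
  expect_identical(gl$family, "enet")
  expect_lte(gl$n_nonzero, gl$n_genes)
})
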