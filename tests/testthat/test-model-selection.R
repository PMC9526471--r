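ms_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- simulate_cohorts(small_cfg(seed = 51))
      de <- de_table(x)
      panel <- cassette_panel(x)
      sets <- build_feature_sets(de, x, panel$gene_id)
      cache <<- list(x = x, de = de, panel = panel, sets = sets)
    }
    cache
  }
})

test_that("repeated CV is deterministic given a seed and leakage-free", {
  f <- ms_fixture()
  cv1 <- repeated_cv(f$x, f$sets[f$sets$set_id %in% 1:2, ],
                     families = "svm", k = 3, repeats = 2, seed = 5)
  cv2 <- repeated_cv(f$x, f$sets[f$sets$set_id %in% 1:2, ],
                     families = "svm", k = 3, repeats = 2, seed = 5)
  expect_identical(as.data.frame(cv1), as.data.frame(cv2))
  expect_equal(nrow(cv1), 2 * 2 * 3) # settings x repeats x folds

  # permuting validation-cohort labels cannot change training-fold results
  shuffled <- f$x
  vidx <- shuffled$meta$split == "valid"
  shuffled$meta$label[vidx] <- sample(shuffled$meta$label[vidx])
  cv3 <- repeated_cv(shuffled, f$sets[f$sets$set_id %in% 1:2, ],
                     families = "svm", k = 3, repeats = 2, seed = 5)
  expect_identical(as.data.frame(cv1), as.data.frame(cv3))
})

test_that("cross-validated accuracy collapses when labels are permuted", {
  f <- ms_fixture()
  perm <- f$x
  tidx <- perm$meta$split == "train" & perm$meta$cohort == "FNAB"
  set.seed(99)
  perm$meta$label[tidx] <- sample(perm$meta$label[tidx])
  cv <- repeated_cv(perm, f$sets[f$sets$set_id == 2, ],
                    families = "svm", k = 3, repeats = 2, seed = 7)
  sm <- summarize_cv(cv)
  expect_lt(sm$mean_sens, 0.9)
})

test_that("CV on the intact simulation reaches perfect accuracy", {
  f <- ms_fixture()
  cv <- repeated_cv(f$x, f$sets, k = 3, repeats = 2, seed = 3)
  sm <- summarize_cv(cv)
  expect_equal(nrow(sm), 16)
  expect_true(all(sm$mean_sens == 1))
  expect_true(all(sm$mean_spec == 1))
})

test_that("selection criteria compute margin, control sd and correlation", {
  f <- ms_fixture()
  train <- filter_samples(f$x, cohort == "FNAB", split == "train")
  controls <- simulate_controls(small_cfg(seed = 51))
  ref <- reference_cassette_score(train,
                                  f$panel$gene_id[f$panel$role == "cassette"])
  fit <- train_mtc_classifier(train, feature_set_genes(f$sets, 2), "svm",
                              feature_set_id = 2)
  cr <- compute_criteria(fit, train, controls, ref)
  sc <- predict(fit, train)
  lab <- train$meta$label
  expect_equal(cr$margin,
               min(sc$score[lab == "MTC"]) - max(sc$score[lab != "MTC"]))
  expect_gte(cr$control_sd, 0)
  expect_true(abs(cr$ref_corr) <= 1)
  expect_equal(cr$n_genes, length(fit$genes))

  # replicate groups with identical counts give zero score variability
  cnt <- controls$counts[, rep(1, 4)]
  colnames(cnt) <- paste0("c", 1:4)
  dup <- mtc_counts(cnt, tibble::tibble(
    sample_id = colnames(cnt),
    replicate_group = rep(c("a", "b"), each = 2)))
  cr0 <- compute_criteria(fit, train, dup, ref)
  expect_equal(cr0$control_sd, 0)

  expect_warning(compute_criteria(fit, train, NULL, ref), "control")
})

test_that("a cassette-only model tracks the reference score more closely", {
  f <- ms_fixture()
  train <- filter_samples(f$x, cohort == "FNAB", split == "train")
  truth <- sim_truth_of(f$x)
  cassette5 <- f$panel$gene_id[f$panel$role == "cassette"]
  ref <- reference_cassette_score(train, cassette5)
  null_genes <- setdiff(truth$gene_ids,
                        truth$gene_ids[c(truth$signature_idx,
                                         truth$nuisance_idx)])[1:10]
  fit_cas <- train_mtc_classifier(train, cassette5, "svm")
  fit_null <- train_mtc_classifier(train, null_genes, "svm")
  r_cas <- cor(predict(fit_cas, train)$score, unname(ref))
  r_null <- cor(predict(fit_null, train)$score, unname(ref))
  expect_gt(r_cas, r_null)
})

test_that("rank-sum selection honors dominance and tie-breaks", {
  single <- tibble::tibble(set_id = 2L, family = "svm", margin = 1,
                           control_sd = 0.1, ref_corr = 0.9, n_genes = 50L)
  expect_identical(select_final(single)$set_id, 2L)

  # A dominates B on every criterion
  two <- tibble::tibble(set_id = c(1L, 2L), family = "svm",
                        margin = c(2, 1), control_sd = c(0.1, 0.2),
                        ref_corr = c(0.95, 0.9), n_genes = c(40L, 80L))
  expect_identical(select_final(two)$set_id, 1L)

  # hand-built rank-sum tie: set 5 and set 6 tie, fewer genes wins
  tie <- tibble::tibble(
    set_id = c(5L, 6L, 7L), family = "svm",
    margin = c(3, 2, 1),        # ranks 1, 2, 3
    control_sd = c(0.3, 0.2, 0.1), # ranks 3, 2, 1
    ref_corr = c(0.9, 0.8, 0.7),   # ranks 1, 2, 3
    n_genes = c(60L, 40L, 50L)     # ranks 3, 1, 2
  ) # rank sums: 8, 7, 9 -> set 6 wins outright; now force a tie
  tie$n_genes <- c(40L, 41L, 90L) # ranks 1, 2, 3 -> sums 6, 7, 10
  tie$control_sd <- c(0.3, 0.1, 0.2) # ranks 3, 1, 2 -> sums 6, 6, 10
  sel <- select_final(tie)
  expect_identical(sel$set_id, 5L) # tie on rank sum, 40 < 41 genes
  expect_error(select_final(tie[0, ]), "no candidate")
})

test_that("selection never returns a strictly dominated candidate", {
  set.seed(17)
  for (i in 1:20) {
    tab <- tibble::tibble(
      set_id = 1:5, family = "svm",
      margin = runif(5), control_sd = runif(5),
      ref_corr = runif(5), n_genes = sample(34:150, 5)
    )
    win <- select_final(tab)
    dominated <- vapply(seq_len(5), function(i) {
      any(tab$margin > tab$margin[i] & tab$control_sd < tab$control_sd[i] &
            tab$ref_corr > tab$ref_corr[i] & tab$n_genes < tab$n_genes[i])
    }, logical(1))
    expect_false(dominated[tab$set_id == win$set_id])
  }
})
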