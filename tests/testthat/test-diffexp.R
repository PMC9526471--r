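test_that("size factors satisfy symmetry, scaling and the brute-force oracle", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  set.seed(5)
  r <- matrix(rpois(51 * 6, 40) + 1, nrow = 51,
              dimnames = list(paste0("g", 1:51), paste0("s", 1:6)))
  expect_equal(unname(size_factors(r)), unname(size_factor_oracle(r)),
               tolerance = 1e-12)
})

test_that("size factors match the reference median-of-ratios implementation", {
  set.seed(8)
  r <- matrix(rnbinom(51 * 8, mu = 30, size = 5) + 1, nrow = 51,
              dimnames = list(paste0("g", 1:51), paste0("s", 1:8)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(r)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(size_factors(r)), unname(ref), tolerance = 1e-10)
})

test_that("all-zero samples are rejected by name", {
  m <- cbind(a = c(1, 2), bad = c(0, 0))
  rownames(m) <- c("g1", "g2")
  expect_error(size_factors(m), "bad")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force oracle and stats::p.adjust", {
  set.seed(1)
  for (i in 1:8) {
    p <- runif(6)
    for (perm in list(seq_along(p), sample(6), order(p), rev(order(p)))) {
      v <- p[perm]
      expect_equal(bh_adjust(v), bh_oracle(v), tolerance = 1e-12)
      expect_equal(bh_adjust(v), stats::p.adjust(v, "BH"), tolerance = 1e-12)
    }
  }
})

test_that("NB Wald test recovers planted signal and stays null-calibrated", {
  x <- simulate_cohorts(small_cfg(seed = 21))
  truth <- sim_truth_of(x)
  de <- nb_wald_test(x, "FNAB")
  sig <- de$gene_id %in% truth$gene_ids[truth$signature_idx]
  expect_gt(mean(de$adj_p[sig] < 1e-6), 0.9)
  expect_gt(mean(de$log2fc[sig] > 6), 0.9)
  # null genes: no systematic fold change
  null_idx <- !sig & !de$gene_id %in% truth$gene_ids[truth$nuisance_idx]
  expect_lt(median(abs(de$log2fc[null_idx])), 0.5)
})

test_that("NB Wald errors on unidentifiable designs", {
  x <- simulate_cohorts(small_cfg(seed = 2))
  one_mtc <- filter_samples(x, cohort == "FNAB", split == "train")
  keep <- c(which(one_mtc$meta$label == "MTC")[1],
            which(one_mtc$meta$label == "non-MTC"))
  y <- mtc_counts(one_mtc$counts[, keep], one_mtc$meta[keep, ])
  expect_error(nb_wald_test(y, "FNAB"), "2 samples")
})

poisson_se_oracle <- function(cnt, n1) {
  # independent closed-form two-group Poisson delta-method standard error
  sf <- size_factor_oracle(cnt)
  q <- sweep(cnt, 2, sf, "/")
  m1 <- rowMeans(q[, 1:n1, drop = FALSE])
  m2 <- rowMeans(q[, -(1:n1), drop = FALSE])
  n2 <- ncol(cnt) - n1
  sqrt(mean(1 / sf[1:n1]) / (n1 * m1) +
         mean(1 / sf[-(1:n1)]) / (n2 * m2)) / log(2)
}

test_that("the dispersion-to-zero limit equals the Poisson delta-method se", {
  # underdispersed counts force the moment dispersion to its floor, so the
  # NB standard error must collapse to the Poisson closed form exactly
  set.seed(44)
  n1 <- 20; n2 <- 30
  base <- matrix(rep(c(80, 20), c(n1, n2)), nrow = 51, ncol = n1 + n2,
                 byrow = TRUE) * matrix(seq(0.5, 1.5, length.out = 51),
                                        nrow = 51, ncol = n1 + n2)
  jitter <- matrix(sample(c(-1, 0, 1), 51 * (n1 + n2), replace = TRUE),
                   nrow = 51)
  cnt <- round(base) + jitter
  rownames(cnt) <- paste0("g", 1:51)
  colnames(cnt) <- paste0("s", seq_len(n1 + n2))
  meta <- tibble::tibble(sample_id = colnames(cnt), cohort = "FNAB",
                         split = "train",
                         label = rep(c("MTC", "non-MTC"), c(n1, n2)))
  de <- nb_wald_test(mtc_counts(cnt, meta), "FNAB")
  expect_true(all(abs(de$se / poisson_se_oracle(cnt, n1) - 1) < 1e-4))
})

test_that("Poisson data give standard errors near the delta-method form", {
  set.seed(33)
  n1 <- 300; n2 <- 300
  cnt <- cbind(matrix(rpois(30 * n1, 80), nrow = 30),
               matrix(rpois(30 * n2, 20), nrow = 30))
  rownames(cnt) <- paste0("g", 1:30)
  colnames(cnt) <- paste0("s", seq_len(n1 + n2))
  meta <- tibble::tibble(sample_id = colnames(cnt), cohort = "FNAB",
                         split = "train",
                         label = rep(c("MTC", "non-MTC"), c(n1, n2)))
  de <- nb_wald_test(mtc_counts(cnt, meta), "FNAB")
  dev <- abs(de$se / poisson_se_oracle(cnt, n1) - 1)
  # the moment dispersion fluctuates around zero, so typical agreement is
  # within 5% while individual genes can drift further
  expect_lt(median(dev), 0.05)
  expect_lt(max(dev), 0.15)
})

test_that("false discoveries are controlled under the null generator", {
  fractions <- vapply(1:10, function(i) {
    cfg <- sim_config(n_genes = 250, n_signature = 0, n_cassette = 0,
                      n_nuisance = 0,
                      cohort_sizes = list(train_fnab = c(mtc = 40, non_mtc = 80),
                                          tissue = c(mtc = 10, non_mtc = 10),
                                          valid_fnab = c(mtc = 3, non_mtc = 3)),
                      seed = 500 + i)
    de <- nb_wald_test(simulate_cohorts(cfg), "FNAB")
    mean(de$adj_p < 0.05)
  }, numeric(1))
  expect_lte(mean(fractions), 0.05)
})

test_that("raw p-values are calibrated under the null generator", {
  fractions <- vapply(1:5, function(i) {
    cfg <- sim_config(n_genes = 300, n_signature = 0, n_cassette = 0,
                      n_nuisance = 0,
                      cohort_sizes = list(train_fnab = c(mtc = 60, non_mtc = 120),
                                          tissue = c(mtc = 10, non_mtc = 10),
                                          valid_fnab = c(mtc = 3, non_mtc = 3)),
                      seed = 900 + i)
    de <- nb_wald_test(simulate_cohorts(cfg), "FNAB")
    mean(de$wald_p < 0.05)
  }, numeric(1))
  expect_gte(mean(fractions), 0.03)
  expect_lte(mean(fractions), 0.07)
})

test_that("dual-context selection intersects both cohorts", {
  de <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    context = rep(c("FNAB", "tissue"), each = 3),
    base_mean = 10,
    log2fc = c(8, 7, 0.1, 7, 0.2, 0.3),
    se = 1,
    wald_p = c(1e-10, 1e-9, 0.5, 1e-9, 0.6, 0.7),
    adj_p = c(3e-10, 3e-9, 0.6, 3e-9, 0.7, 0.8)
  )
  expect_setequal(dual_context_de(de, 1, NULL), c("g1", "g2", "g3"))
  # g2 is significant in FNAB only: excluded
  expect_identical(dual_context_de(de, 1e-6, NULL), "g1")
  expect_identical(dual_context_de(de, 1e-6, 6), "g1")
  # fold-change filtered set is nested in the p-only set
  expect_true(all(dual_context_de(de, 0.9, 6) %in% dual_context_de(de, 0.9)))
  expect_error(dual_context_de(de[de$context == "FNAB", ], 1), "both")
})

test_that("DE on the default simulation recovers the signature dual-context", {
  res <- full_pipeline()
  truth <- sim_truth_of(res$data)
  sig_genes <- truth$gene_ids[truth$signature_idx]
  hits <- dual_context_de(res$de, 1e-6, 6)
  expect_gte(mean(sig_genes %in% hits), 0.95)
  # at most a spurious gene or two sneaks past the dual strict threshold
  expect_lte(length(setdiff(hits, sig_genes)), 2)
})
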