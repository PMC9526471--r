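#' Simulation configuration for the synthetic study cohorts
#'
#' Defines the generating model for synthetic FNAB and surgical-tissue count
#' cohorts that mirror the classifier development design: a training FNAB
#' cohort of 21 MTC and 462 non-MTC samples, 97 surgical-tissue samples
#' (21 MTC, 76 non-MTC), and a blinded validation FNAB cohort of 21 MTC and
#' 190 non-MTC samples. A planted MTC signature of `n_signature` genes is
#' overexpressed multiplicatively in MTC samples of every cohort with
#' per-gene log2 fold changes drawn uniformly from `signature_log2fc_range`.
#' The first `n_cassette` signature genes form the mandatory cassette
#' (5 flagged `"cassette"`, the rest `"literature"`). Non-MTC heterogeneity
#' is modelled by a small nuisance signature separating benign from non-MTC
#' malignant samples, so specificity is tested against a mixed non-MTC class.
#'
#' Counts are negative binomial: gene `g` in sample `j` has mean
#' `s_j * mu_g * 2^lfc(g, class)` with library-size factor `s_j` drawn
#' log-normally and per-gene dispersion `alpha_g` drawn from a gamma
#' distribution once and shared across cohorts.
#'
#' @param n_genes number of genes (default 5000).
#' @param n_signature number of planted MTC-signature genes (default 120).
#' @param signature_log2fc_range interval for signature log2 fold changes
#'   (default `c(6, 10)`).
#' @param n_cassette number of mandatory genes embedded in the signature
#'   (default 34: 5 cassette + 29 literature).
#' @param cohort_sizes named list of `c(mtc, non_mtc)` pairs for
#'   `train_fnab`, `tissue`, `valid_fnab`.
#' @param libsize_lognormal_params `c(meanlog, sdlog)` of library-size
#'   factors.
#' @param dispersion_gamma_params `c(shape, scale)` of per-gene NB
#'   dispersions.
#' @param basemean_lognormal_params `c(meanlog, sdlog)` of per-gene baseline
#'   expected counts.
#' @param n_control_groups,n_control_replicates replicate control design
#'   (default 6 groups of 3).
#' @param n_nuisance,nuisance_log2fc_max size and amplitude of the non-MTC
#'   nuisance signature (default 50 genes, |log2FC| <= 1.5).
#' @param seed integer root seed; identical configurations give identical
#'   matrices.
#' @param scale optional factor in (0, 1] shrinking all cohort sizes
#'   (ceiling, minimum 3 per class) for quick experiments; the defaults are
#'   the study conditions.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 300, seed = 11, scale = 0.05)
#' cfg$cohort_sizes$train_fnab
sim_config <- function(n_genes = 5000,
                       n_signature = 120,
                       signature_log2fc_range = c(6, 10),
                       n_cassette = 34,
                       cohort_sizes = list(
                         train_fnab = c(mtc = 21, non_mtc = 462),
                         tissue     = c(mtc = 21, non_mtc = 76),
                         valid_fnab = c(mtc = 21, non_mtc = 190)
                       ),
                       libsize_lognormal_params = c(meanlog = 0, sdlog = 0.25),
                       dispersion_gamma_params = c(shape = 2, scale = 0.05),
                       basemean_lognormal_params = c(meanlog = 3, sdlog = 1.2),
                       n_control_groups = 6,
                       n_control_replicates = 3,
                       n_nuisance = 50,
                       nuisance_log2fc_max = 1.5,
                       seed = 1,
                       scale = 1) {
  abort_if(n_genes < 1, "n_genes must be positive")
  abort_if(n_signature < 0 || n_signature > n_genes,
           "signature count must lie in [0, n_genes]")
  abort_if(n_cassette > max(n_signature, 0) && n_signature > 0,
           "cassette genes must be a subset of the signature")
  abort_if(length(signature_log2fc_range) != 2 ||
             signature_log2fc_range[1] > signature_log2fc_range[2],
           "signature_log2fc_range must be an ordered interval")
  abort_if(dispersion_gamma_params[1] <= 0 || dispersion_gamma_params[2] <= 0,
           "dispersion gamma parameters must be positive")
  abort_if(scale <= 0 || scale > 1, "scale must be in (0, 1]")
  if (scale < 1) {
    cohort_sizes <- lapply(cohort_sizes, function(s) {
      pmax(ceiling(s * scale), 3)
    })
    n_nuisance <- min(n_nuisance, max(n_genes - n_signature, 0))
  }
  for (cs in cohort_sizes) {
    abort_if(any(cs < 1), "all cohort sizes must be >= 1")
  }
  abort_if(n_signature + n_nuisance > n_genes,
           "signature + nuisance genes exceed n_genes")
  structure(list(
    n_genes = as.integer(n_genes),
    n_signature = as.integer(n_signature),
    signature_log2fc_range = as.numeric(signature_log2fc_range),
    n_cassette = as.integer(min(n_cassette, n_signature)),
    cohort_sizes = lapply(cohort_sizes, function(s) {
      s <- as.integer(s); names(s) <- c("mtc", "non_mtc"); s
    }),
    libsize_lognormal_params = libsize_lognormal_params,
    dispersion_gamma_params = dispersion_gamma_params,
    basemean_lognormal_params = basemean_lognormal_params,
    n_control_groups = as.integer(n_control_groups),
    n_control_replicates = as.integer(n_control_replicates),
    n_nuisance = as.integer(n_nuisance),
    nuisance_log2fc_max = as.numeric(nuisance_log2fc_max),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# draw the gene-level generating parameters shared by all cohorts
sim_truth <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(n))
    mu <- rlnorm(n, config$basemean_lognormal_params[1],
                 config$basemean_lognormal_params[2])
    alpha <- stats::rgamma(n, shape = config$dispersion_gamma_params[1],
                           scale = config$dispersion_gamma_params[2])
    alpha <- pmax(alpha, 1e-6)
    sig_idx <- if (config$n_signature > 0) {
      sort(sample.int(n, config$n_signature))
    } else integer(0)
    lfc <- numeric(n)
    if (length(sig_idx)) {
      lfc[sig_idx] <- runif(length(sig_idx),
                            config$signature_log2fc_range[1],
                            config$signature_log2fc_range[2])
    }
    pool <- setdiff(seq_len(n), sig_idx)
    nuis_idx <- if (config$n_nuisance > 0 && length(pool)) {
      sort(sample(pool, min(config$n_nuisance, length(pool))))
    } else integer(0)
    nuis_lfc <- numeric(n)
    if (length(nuis_idx)) {
      nuis_lfc[nuis_idx] <- runif(length(nuis_idx),
                                  -config$nuisance_log2fc_max,
                                  config$nuisance_log2fc_max)
    }
    cassette_role <- rep(NA_character_, n)
    if (config$n_cassette > 0 && length(sig_idx)) {
      cas <- sig_idx[seq_len(config$n_cassette)]
      cassette_role[cas] <- c(rep("cassette", min(5, length(cas))),
                              rep("literature", max(0, length(cas) - 5)))
    }
    list(gene_ids = gene_ids, mu = mu, dispersion = alpha,
         signature_idx = sig_idx, signature_log2fc = lfc,
         nuisance_idx = nuis_idx, nuisance_log2fc = nuis_lfc,
         cassette_role = cassette_role)
  })
}

# expected-expression vector for one sample class
class_profile <- function(truth, class = c("MTC", "benign", "malignant")) {
  class <- match.arg(class)
  switch(class,
         MTC = truth$mu * 2^truth$signature_log2fc,
         benign = truth$mu,
         malignant = truth$mu * 2^truth$nuisance_log2fc)
}

# NB draws for a block of samples sharing one expected profile
draw_counts <- function(profile, libsizes, dispersion) {
  n <- length(libsizes)
  mat <- vapply(seq_len(n), function(j) {
    rnbinom(length(profile), mu = libsizes[j] * profile,
            size = 1 / dispersion)
  }, numeric(length(profile)))
  matrix(mat, nrow = length(profile))
}

bethesda_for <- function(label, split, n) {
  if (label == "MTC" && split == "train") {
    # 5/6/6/4 across III/IV/V/VI, the training-cohort cytology mix
    rep(rep(c("III", "IV", "V", "VI"), times = c(5, 6, 6, 4)), length.out = n)
  } else if (label == "MTC" && split == "valid") {
    rep(rep(c("III", "IV", "V"), times = c(8, 6, 7)), length.out = n)
  } else {
    rep(c("III", "IV"), length.out = n)
  }
}

#' Simulate the training, tissue and validation cohorts
#'
#' Draws negative-binomial counts for all three study cohorts under one
#' shared set of gene-level parameters, planting the MTC signature in the
#' MTC samples of both the FNAB and tissue contexts. The generating truth
#' (signature genes and their drawn fold changes, dispersions, baseline
#' means, cassette roles) is attached as `attr(x, "truth")` so that
#' parameter-recovery checks and the mandatory-gene list need no bookkeeping.
#'
#' @param config a [sim_config()].
#' @return An [mtc_counts] with metadata columns `cohort` (`FNAB`/`tissue`),
#'   `split` (`train`/`valid`), `label`, `bethesda`.
#' @export
#' @examples
#' x <- simulate_cohorts(sim_config(n_genes = 200, seed = 3, scale = 0.05))
#' dplyr::count(x$meta, cohort, split, label)
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  blocks <- list(
    list(tag = "trn", cohort = "FNAB", split = "train",
         sizes = config$cohort_sizes$train_fnab),
    list(tag = "tis", cohort = "tissue", split = "train",
         sizes = config$cohort_sizes$tissue),
    list(tag = "val", cohort = "FNAB", split = "valid",
         sizes = config$cohort_sizes$valid_fnab)
  )
  with_seed(derive_seed(config$seed, 2L), {
    mats <- list(); metas <- list()
    for (b in blocks) {
      n_mtc <- b$sizes[["mtc"]]; n_non <- b$sizes[["non_mtc"]]
      n_tot <- n_mtc + n_non
      libs <- rlnorm(n_tot, config$libsize_lognormal_params[1],
                     config$libsize_lognormal_params[2])
      # non-MTC samples alternate benign / non-MTC-malignant histologies
      non_classes <- rep(c("benign", "malignant"), length.out = n_non)
      prof_m <- class_profile(truth, "MTC")
      cnt_m <- draw_counts(prof_m, libs[seq_len(n_mtc)], truth$dispersion)
      cnt_n <- matrix(0, nrow = config$n_genes, ncol = n_non)
      for (cl in unique(non_classes)) {
        idx <- which(non_classes == cl)
        cnt_n[, idx] <- draw_counts(class_profile(truth, cl),
                                    libs[n_mtc + idx], truth$dispersion)
      }
      cnt <- cbind(cnt_m, cnt_n)
      ids <- sprintf("%s_%s%03d", b$tag,
                     rep(c("mtc", "non"), c(n_mtc, n_non)),
                     c(seq_len(n_mtc), seq_len(n_non)))
      colnames(cnt) <- ids
      rownames(cnt) <- truth$gene_ids
      mats[[b$tag]] <- cnt
      metas[[b$tag]] <- tibble::tibble(
        sample_id = ids,
        cohort = b$cohort,
        split = b$split,
        label = rep(c("MTC", "non-MTC"), c(n_mtc, n_non)),
        bethesda = if (b$cohort == "tissue") rep(NA_character_, n_tot) else
          c(bethesda_for("MTC", b$split, n_mtc),
            bethesda_for("non-MTC", b$split, n_non)),
        replicate_group = NA_character_,
        dilution_fraction = NA_real_
      )
    }
    out <- mtc_counts(do.call(cbind, mats), dplyr::bind_rows(metas))
    attr(out, "truth") <- truth
    attr(out, "config") <- config
    out
  })
}

#' Simulate replicate control samples
#'
#' Control samples are sequenced repeatedly in small replicate groups; all
#' replicates of a group share one expected-expression vector and differ only
#' by library size and NB sampling noise. Odd-numbered groups carry a benign
#' profile and even-numbered groups an MTC profile (each with mild
#' group-specific expression jitter), so control scores span the score range
#' of the classifier whose run-to-run variability they measure.
#'
#' @param config a [sim_config()].
#' @return An [mtc_counts] with `replicate_group` set; the per-group expected
#'   profiles are attached as `attr(x, "expected_profiles")`.
#' @export
simulate_controls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  abort_if(config$n_control_groups < 1, "need at least one control group")
  truth <- sim_truth(config)
  with_seed(derive_seed(config$seed, 3L), {
    mats <- list(); metas <- list(); profiles <- list()
    for (g in seq_len(config$n_control_groups)) {
      base <- if (g %% 2L == 0L) class_profile(truth, "MTC") else
        class_profile(truth, "benign")
      prof <- base * exp(rnorm(config$n_genes, 0, 0.3))
      nrep <- config$n_control_replicates
      libs <- rlnorm(nrep, config$libsize_lognormal_params[1],
                     config$libsize_lognormal_params[2])
      cnt <- draw_counts(prof, libs, truth$dispersion)
      ids <- sprintf("ctl_g%02d_r%d", g, seq_len(nrep))
      colnames(cnt) <- ids
      rownames(cnt) <- truth$gene_ids
      mats[[g]] <- cnt
      profiles[[sprintf("ctrl%02d", g)]] <- prof
      metas[[g]] <- tibble::tibble(
        sample_id = ids, cohort = "FNAB", split = "control",
        label = if (g %% 2L == 0L) "MTC" else "non-MTC",
        bethesda = NA_character_,
        replicate_group = sprintf("ctrl%02d", g),
        dilution_fraction = NA_real_
      )
    }
    out <- mtc_counts(do.call(cbind, mats), dplyr::bind_rows(metas))
    attr(out, "expected_profiles") <- profiles
    attr(out, "truth") <- truth
    out
  })
}

#' Mix an MTC expression profile with benign RNA
#'
#' Models in-silico dilution of tumour RNA: the expected expression of a
#' mixture is the convex combination `(1 - f) * mtc + f * benign`, applied
#' before count sampling.
#'
#' @param mtc_profile,benign_profile expected-expression vectors of equal
#'   length.
#' @param fraction_benign proportion of benign RNA in `[0, 1]`.
#' @return The mixed expected-expression vector.
#' @export
#' @examples
#' dilute_sample(c(100, 8), c(4, 8), 0.75)
dilute_sample <- function(mtc_profile, benign_profile, fraction_benign) {
  abort_if(length(mtc_profile) != length(benign_profile),
           "profiles must have the same length")
  abort_if(!is.numeric(fraction_benign) || length(fraction_benign) != 1 ||
             is.na(fraction_benign) ||
             fraction_benign < 0 || fraction_benign > 1,
           "fraction_benign must be a single value in [0, 1]")
  (1 - fraction_benign) * mtc_profile + fraction_benign * benign_profile
}

#' Draw count samples from a fixed expected-expression profile
#'
#' Used to materialise diluted or otherwise constructed samples as counts.
#' With `expected = TRUE` the deterministic rounded expectation is returned
#' instead of NB draws, which is useful for noise-free property checks.
#'
#' @param profile expected-expression vector (named by gene id or matching
#'   `gene_ids`).
#' @param dispersion per-gene NB dispersion vector (recycled if scalar).
#' @param n number of samples to draw.
#' @param libsizes library-size factors (recycled to `n`).
#' @param gene_ids gene identifiers (defaults to `names(profile)`).
#' @param seed optional seed for the draws.
#' @param expected if `TRUE`, return `round(libsize * profile)` instead of
#'   random draws.
#' @param meta_extra named list of metadata columns to set (e.g.
#'   `dilution_fraction`).
#' @return An [mtc_counts] with `n` samples.
#' @export
simulate_from_profile <- function(profile, dispersion, n = 1, libsizes = 1,
                                  gene_ids = names(profile), seed = NULL,
                                  expected = FALSE, meta_extra = list()) {
  abort_if(is.null(gene_ids), "gene ids are required")
  libsizes <- rep_len(libsizes, n)
  dispersion <- rep_len(dispersion, length(profile))
  draw <- function() {
    if (expected) {
      vapply(seq_len(n), function(j) round(libsizes[j] * profile),
             numeric(length(profile)))
    } else {
      draw_counts(profile, libsizes, dispersion)
    }
  }
  cnt <- if (is.null(seed)) draw() else with_seed(seed, draw())
  cnt <- matrix(cnt, nrow = length(profile))
  rownames(cnt) <- gene_ids
  colnames(cnt) <- sprintf("prof_s%03d", seq_len(n))
  meta <- tibble::tibble(sample_id = colnames(cnt))
  for (nm in names(meta_extra)) meta[[nm]] <- meta_extra[[nm]]
  mtc_counts(cnt, meta)
}

#' Generating truth of a simulated container
#'
#' @param x an [mtc_counts] produced by [simulate_cohorts()] or
#'   [simulate_controls()].
#' @return The truth list (gene ids, baseline means, dispersions, signature
#'   indices and log2 fold changes, cassette roles).
#' @export
sim_truth_of <- function(x) {
  truth <- attr(x, "truth")
  abort_if(is.null(truth), "object carries no generating truth")
  truth
}

#' Mandatory cassette gene panel of a simulated container
#'
#' @param x a simulated [mtc_counts].
#' @return Tibble with `gene_id` and `role` (`cassette` or `literature`).
#' @export
cassette_panel <- function(x) {
  truth <- sim_truth_of(x)
  idx <- which(!is.na(truth$cassette_role))
  tibble::tibble(gene_id = truth$gene_ids[idx],
                 role = truth$cassette_role[idx])
}
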