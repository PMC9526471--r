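# End-to-end driver: simulate -> DE -> feature sets -> CV competition ->
# four-criterion selection -> lock -> blinded validation -> report.

#' Run the full classifier development and validation pipeline
#'
#' Executes the study design end to end on synthetic cohorts: dual-context
#' differential expression on the training FNAB and tissue samples, the
#' eight candidate feature sets, the 16-setting repeated cross-validated
#' competition, the four-criterion selection of a single model, locking, and
#' one blinded application to the validation cohort. The validation split is
#' touched only in the final stage, after the model hash is frozen.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param k,repeats cross-validation design (default 5-fold, 10 repeats).
#' @param families classifier families in the competition.
#' @param outdir optional directory for the artifact tree (DE table, feature
#'   sets, CV report, criteria, locked model JSON, validation report,
#'   manifest with file hashes in execution order).
#' @return List of class `mtc_pipeline`: `config`, `data`, `controls`, `de`,
#'   `sets`, `cv`, `cv_summary`, `criteria`, `selected`, `classifier`
#'   (locked), `validation`.
#' @export
#' @examples
#' \donttest{
#' res <- run_mtc_pipeline(sim_config(n_genes = 400, seed = 5, scale = 0.05),
#'                         repeats = 2)
#' res$validation
#' }
run_mtc_pipeline <- function(config = sim_config(), k = 5, repeats = 10,
                             families = c("svm", "enet"), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- list()
  note <- function(stage, path = NA_character_) {
    manifest[[length(manifest) + 1]] <<- list(
      stage = stage,
      artifact = path,
      md5 = if (is.na(path)) NA_character_ else unname(tools::md5sum(path))
    )
  }
  emit <- function(obj, name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    writer(obj, path)
    note(sub("\\..*$", "", name), path)
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(obj, path) write.table(as.data.frame(obj), path,
                                               sep = "\t", quote = FALSE,
                                               row.names = FALSE)

  sim <- simulate_cohorts(config)
  controls <- simulate_controls(config)
  note("simulate")
  train_fnab <- filter_samples(sim, .data$cohort == "FNAB",
                               .data$split == "train")
  valid_fnab <- filter_samples(sim, .data$cohort == "FNAB",
                               .data$split == "valid")

  de <- de_table(filter_samples(sim, .data$split == "train"))
  emit(de, "de_table.tsv", write_tsv)

  panel <- cassette_panel(sim)
  sets <- build_feature_sets(de, sim, panel$gene_id)
  emit(sets, "feature_sets.tsv", write_tsv)

  cv <- repeated_cv(sim, sets, families = families, k = k, repeats = repeats,
                    seed = config$seed)
  cv_summary <- summarize_cv(cv)
  emit(cv_summary, "cv_report.tsv", write_tsv)

  perfect <- dplyr::filter(cv_summary, .data$mean_sens == 1,
                           .data$mean_spec == 1)
  if (nrow(perfect) == 0) {
    message("no setting reached perfect CV accuracy; ",
            "all settings enter the criteria stage")
    perfect <- cv_summary
  }

  ref <- reference_cassette_score(train_fnab,
                                  panel$gene_id[panel$role == "cassette"])
  fits <- purrr::map(seq_len(nrow(perfect)), function(i) {
    train_mtc_classifier(train_fnab,
                         feature_set_genes(sets, perfect$set_id[i]),
                         family = perfect$family[i],
                         feature_set_id = perfect$set_id[i],
                         seed = derive_seed(config$seed, 31L + i))
  })
  criteria <- purrr::map_dfr(fits, function(fit) {
    cr <- compute_criteria(fit, train_fnab, controls, ref)
    ss <- sens_spec(predict(fit, train_fnab)$call, train_fnab$meta$label)
    dplyr::mutate(cr, train_sens = ss[["sens"]], train_spec = ss[["spec"]])
  })
  emit(criteria, "criteria.tsv", write_tsv)

  selected <- select_final(criteria)
  final <- fits[[which(criteria$set_id == selected$set_id &
                         criteria$family == selected$family)[1]]]
  final <- lock_classifier(final)
  emit(final, "locked_model.json", function(o, p) write_model(o, p))
  if (!is.null(outdir)) {
    sel_out <- list(selected = as.list(selected),
                    rank_table = as.data.frame(attr(selected, "rank_table")))
    jsonlite::write_json(sel_out, file.path(outdir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
    note("select", file.path(outdir, "selection.json"))
  }

  # blinded stage: the validation split is first touched here, after the lock
  validation <- validate_classifier(final, valid_fnab)
  if (!is.null(outdir)) {
    jsonlite::write_json(list(confusion = as.list(validation$confusion),
                              ci_sens = as.list(validation$ci_sens),
                              ci_spec = as.list(validation$ci_spec),
                              power = validation$power_statement),
                         file.path(outdir, "validation_report.json"),
                         auto_unbox = TRUE, digits = NA)
    note("validate", file.path(outdir, "validation_report.json"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  structure(list(config = config, data = sim, controls = controls, de = de,
                 sets = sets, cv = cv, cv_summary = cv_summary,
                 criteria = criteria, selected = selected,
                 classifier = final, validation = validation,
                 manifest = manifest),
            class = "mtc_pipeline")
}

#' @export
print.mtc_pipeline <- function(x, ...) {
  cat("<mtc_pipeline>\n")
  cat(sprintf("  selected: feature set %d, %s (%d genes)\n",
              x$selected$set_id, x$selected$family, x$selected$n_genes))
  print(x$validation)
  invisible(x)
}
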