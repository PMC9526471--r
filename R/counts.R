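#' Construct a count-matrix container
#'
#' Bundles a genes-by-samples integer count matrix with a per-sample metadata
#' tibble. The metadata carries the study design: which cohort a sample
#' belongs to (`FNAB` or `tissue`), whether it is a training or validation
#' sample, its reference label (`MTC` or `non-MTC`), its Bethesda cytology
#' category, and optional replicate-group and dilution annotations.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Counts must be
#'   non-negative integers.
#' @param meta data frame with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(counts)`; columns `cohort`,
#'   `split`, `label`, `bethesda`, `replicate_group`, `dilution_fraction`
#'   are filled with `NA` when absent.
#'
#' @return An object of class `mtc_counts`: a list with elements `counts`
#'   (matrix) and `meta` (tibble).
#' @export
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' x <- mtc_counts(m, data.frame(sample_id = paste0("s", 1:4),
#'                               label = c("MTC", "MTC", "non-MTC", "non-MTC")))
#' x
mtc_counts <- function(counts, meta) {
  abort_if(!is.matrix(counts), "`counts` must be a matrix")
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "`counts` must have gene rownames and sample colnames")
  abort_if(any(counts < 0) || any(counts != round(counts)),
           "`counts` must contain non-negative integers")
  storage.mode(counts) <- "double" # keeps large counts safe; values stay integral
  meta <- tibble::as_tibble(meta)
  abort_if(!"sample_id" %in% names(meta), "`meta` must have a `sample_id` column")
  abort_if(!identical(as.character(meta$sample_id), colnames(counts)),
           "`meta$sample_id` must match `colnames(counts)` in order")
  for (col in c("cohort", "split", "label", "bethesda", "replicate_group")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  if (!"dilution_fraction" %in% names(meta)) meta$dilution_fraction <- NA_real_
  dup <- anyDuplicated(meta$sample_id)
  abort_if(dup > 0, paste0("duplicated sample id: ", meta$sample_id[dup]))
  structure(list(counts = counts, meta = meta), class = "mtc_counts")
}

#' @export
print.mtc_counts <- function(x, ...) {
  cat(sprintf("<mtc_counts> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$meta$cohort, x$meta$label, useNA = "ifany")
  print(tab)
  invisible(x)
}

#' @export
dim.mtc_counts <- function(x) dim(x$counts)

#' Subset samples of a count container by metadata predicates
#'
#' Filters the metadata with dplyr semantics and subsets the count matrix to
#' the matching samples, keeping matrix and metadata aligned.
#'
#' @param x an [mtc_counts] object.
#' @param ... predicates passed to [dplyr::filter()] on the metadata.
#' @return An `mtc_counts` with the selected samples.
#' @export
#' @examples
#' x <- simulate_cohorts(sim_config(n_genes = 50, seed = 1, scale = 0.05))
#' filter_samples(x, cohort == "FNAB", split == "train")
filter_samples <- function(x, ...) {
  stopifnot(inherits(x, "mtc_counts"))
  meta <- dplyr::filter(x$meta, ...)
  abort_if(nrow(meta) == 0, "no samples match the filter")
  out <- x
  out$counts <- x$counts[, meta$sample_id, drop = FALSE]
  out$meta <- meta
  out
}

#' Combine two count containers column-wise
#'
#' @param x,y [mtc_counts] objects sharing the same gene set.
#' @return An `mtc_counts` holding both sample sets.
#' @export
bind_samples <- function(x, y) {
  stopifnot(inherits(x, "mtc_counts"), inherits(y, "mtc_counts"))
  abort_if(!identical(rownames(x$counts), rownames(y$counts)),
           "gene sets differ between the two containers")
  mtc_counts(cbind(x$counts, y$counts), dplyr::bind_rows(x$meta, y$meta))
}
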