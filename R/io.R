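# Reading and writing the pipeline's on-disk formats: counts as TSV or
# MatrixMarket, metadata as TSV, models and reports as JSON.

# metadata columns keep fixed types even when entirely missing
read_meta_tsv <- function(path) {
  abort_if(!file.exists(path), paste0("missing metadata file: ", path))
  meta <- tibble::as_tibble(read.delim(path, sep = "\t",
                                       stringsAsFactors = FALSE,
                                       colClasses = "character"))
  if ("dilution_fraction" %in% names(meta)) {
    meta$dilution_fraction <- as.numeric(meta$dilution_fraction)
  }
  for (cn in setdiff(names(meta), "dilution_fraction")) {
    meta[[cn]][meta[[cn]] == "NA"] <- NA_character_
  }
  meta
}

#' Write a count container to TSV
#'
#' Writes `<prefix>_counts.tsv` (gene_id column plus one column per sample)
#' and `<prefix>_meta.tsv` with the fixed metadata columns.
#'
#' @param x an [mtc_counts].
#' @param prefix file path prefix.
#' @return The two file paths, invisibly.
#' @export
write_counts <- function(x, prefix) {
  stopifnot(inherits(x, "mtc_counts"))
  cf <- paste0(prefix, "_counts.tsv")
  mf <- paste0(prefix, "_meta.tsv")
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(x$meta), mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts = cf, meta = mf))
}

#' Read a count container from TSV
#'
#' @param prefix the prefix used by [write_counts()].
#' @return An [mtc_counts].
#' @export
read_counts <- function(prefix) {
  cf <- paste0(prefix, "_counts.tsv")
  mf <- paste0(prefix, "_meta.tsv")
  abort_if(!file.exists(cf), paste0("missing counts file: ", cf))
  df <- read.delim(cf, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  abort_if(names(df)[1] != "gene_id", "first column must be gene_id")
  bad <- which(!stats::complete.cases(df))
  abort_if(length(bad) > 0,
           paste0("malformed counts row(s) at line ", bad[1] + 1))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  mtc_counts(m, read_meta_tsv(mf))
}

#' Write counts in MatrixMarket format
#'
#' Writes `<prefix>.mtx` with companion `<prefix>_genes.txt` and
#' `<prefix>_samples.txt` id files plus the metadata TSV.
#'
#' @inheritParams write_counts
#' @export
write_counts_mtx <- function(x, prefix) {
  stopifnot(inherits(x, "mtc_counts"))
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(x$counts), paste0(prefix, "_genes.txt"))
  writeLines(colnames(x$counts), paste0(prefix, "_samples.txt"))
  write.table(as.data.frame(x$meta), paste0(prefix, "_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read counts from MatrixMarket format
#'
#' @inheritParams read_counts
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, "_genes.txt"))
  colnames(m) <- readLines(paste0(prefix, "_samples.txt"))
  mtc_counts(m, read_meta_tsv(paste0(prefix, "_meta.tsv")))
}

#' Serialize a classifier to JSON
#'
#' Numeric fields are written at full precision so reloading reproduces
#' scores to well below 1e-9.
#'
#' @param object an `mtc_classifier`.
#' @param path output path.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "mtc_classifier"))
  payload <- list(
    family = object$family,
    feature_set_id = object$feature_set_id,
    genes = object$genes,
    normalization = list(center = unname(object$normalization$center),
                         scale = unname(object$normalization$scale)),
    weights = unname(object$weights),
    intercept = object$intercept,
    threshold = object$threshold,
    hyper = object$hyper,
    locked = isTRUE(object$locked),
    hash = object$hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier from JSON
#'
#' @param path path written by [write_model()].
#' @return An `mtc_classifier`.
#' @export
read_model <- function(path) {
  abort_if(!file.exists(path), paste0("missing model file: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- structure(list(
    family = p$family,
    feature_set_id = as.integer(p$feature_set_id),
    genes = p$genes,
    normalization = list(center = setNames(p$normalization$center, p$genes),
                         scale = setNames(p$normalization$scale, p$genes)),
    weights = setNames(p$weights, p$genes),
    intercept = p$intercept,
    threshold = p$threshold,
    hyper = as.list(p$hyper),
    locked = isTRUE(p$locked),
    hash = if (is.null(p$hash)) NA_character_ else p$hash
  ), class = "mtc_classifier")
  if (obj$locked) {
    abort_if(!identical(classifier_hash(obj), obj$hash),
             "locked model file is corrupt: hash mismatch")
  }
  obj
}
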