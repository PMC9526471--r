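# Clinical derivations for the validation cohort: TNM parsing, AJCC
# 8th-edition MTC staging under stated missing-data assumptions, and the
# cohort summary table.

TNM_T <- c("T1a", "T1b", "T1", "T2", "T3a", "T3b", "T3", "T4a", "T4b", "TX")
TNM_N <- c("N1a", "N1b", "N1", "N0", "NX")
TNM_M <- c("M0", "M1", "MX")

#' Parse TNM strings
#'
#' Case-insensitive tokenization of strings like `"T1bNXMX"` into T/N/M
#' components. The literal `"NA"` (or an `NA` value) yields a missing
#' record.
#'
#' @param text character vector of TNM strings.
#' @return Tibble with columns `tnm`, `t`, `n`, `m` (all `NA` for missing
#'   records).
#' @export
#' @examples
#' parse_tnm(c("T1bNXMX", "T2N1MX", "NA"))
parse_tnm <- function(text) {
  alt <- function(x) paste(x, collapse = "|")
  pat <- sprintf("^(%s)(%s)(%s)$", alt(TNM_T), alt(TNM_N), alt(TNM_M))
  canon <- function(tok, table) table[match(toupper(tok), toupper(table))]
  out <- purrr::map_dfr(as.character(text), function(s) {
    if (is.na(s) || toupper(s) == "NA") {
      return(tibble::tibble(tnm = NA_character_, t = NA_character_,
                            n = NA_character_, m = NA_character_))
    }
    m <- regmatches(s, regexec(pat, s, ignore.case = TRUE))[[1]]
    abort_if(length(m) == 0,
             paste0("unrecognized TNM string: '", s, "'"))
    t <- canon(m[2], TNM_T); n <- canon(m[3], TNM_N); mm <- canon(m[4], TNM_M)
    tibble::tibble(tnm = paste0(t, n, mm), t = t, n = n, m = mm)
  })
  out
}

#' AJCC 8th-edition stage for medullary thyroid carcinoma
#'
#' Applies the missing-data substitutions NX -> N0, MX -> M0 and unspecified
#' N1 -> N1a, then maps: M1 -> IVC; T4b -> IVB; T4a -> IVA; N1b -> IVA;
#' N1a with T1-T3 -> III; N0 with T1 -> I; N0 with T2/T3 -> II. Records
#' whose stage cannot be determined (e.g. TX N0 M0) are `NA`.
#'
#' @param tnm a tibble from [parse_tnm()] or a character vector of TNM
#'   strings.
#' @return Character vector of stages (`I`, `II`, `III`, `IVA`, `IVB`,
#'   `IVC`, or `NA`).
#' @export
#' @examples
#' ajcc8_mtc_stage(c("T1bNXMX", "T2N1bMX", "T1aN1MX"))
ajcc8_mtc_stage <- function(tnm) {
  if (is.character(tnm)) tnm <- parse_tnm(tnm)
  purrr::pmap_chr(tnm[, c("t", "n", "m")], function(t, n, m) {
    if (is.na(t)) return(NA_character_)
    if (n == "NX") n <- "N0"
    if (m == "MX") m <- "M0"
    if (n == "N1") n <- "N1a"
    t_group <- sub("[ab]$", "", t) # T1a/T1b -> T1 etc.
    if (m == "M1") return("IVC")
    if (t == "T4b") return("IVB")
    if (t == "T4a") return("IVA")
    if (n == "N1b") return("IVA")
    if (n == "N1a") {
      return(if (t_group %in% c("T1", "T2", "T3")) "III" else NA_character_)
    }
    # n == "N0"
    if (t_group == "T1") return("I")
    if (t_group %in% c("T2", "T3")) return("II")
    NA_character_ # TX N0 M0: undeterminable
  })
}

#' Read a clinical table
#'
#' Reads the tab-separated clinical table with columns `sample`, `age`,
#' `sex`, `location`, `size_cm`, `bethesda`, `calcitonin_ng_l`, `tnm`.
#' The packaged validation-cohort table (21 MTC nodules) is returned when
#' `path` is omitted.
#'
#' @param path TSV path; default is the packaged validation MTC table.
#' @return Tibble of clinical records with a derived `stage` column.
#' @export
#' @examples
#' cl <- read_clinical()
#' dplyr::count(cl, stage)
read_clinical <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "validation_mtc_clinical.tsv",
                        package = "mtcseq")
  }
  abort_if(!file.exists(path), paste0("clinical table not found: ", path))
  df <- tibble::as_tibble(read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE,
                                     na.strings = "NA"))
  need <- c("sample", "age", "sex", "location", "size_cm", "bethesda",
            "calcitonin_ng_l", "tnm")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0,
           paste0("clinical table lacks columns: ", paste(miss, collapse = ", ")))
  abort_if(any(df$age < 18, na.rm = TRUE),
           "ages below 18 violate the study inclusion criteria")
  abort_if(any(df$calcitonin_ng_l <= 0, na.rm = TRUE),
           "calcitonin must be positive when present")
  df$stage <- ajcc8_mtc_stage(as.character(df$tnm))
  df
}

#' Summary statistics of a clinical cohort
#'
#' Computes, per numeric column, the median, mean and range over non-missing
#' values; per categorical column, integer percentages (rounded half-up)
#' over non-missing values; and the AJCC stage distribution over evaluable
#' (non-missing TNM) records. Missing values are excluded column-wise
#' throughout.
#'
#' @param records tibble from [read_clinical()].
#' @return List of class `mtc_cohort_summary` with elements `numeric`
#'   (tibble: column, n, median, mean, min, max), `categorical` (tibble:
#'   column, level, n, percent) and `stage` (tibble: stage, n, percent).
#' @export
summarize_cohort <- function(records) {
  abort_if(nrow(records) == 0, "empty cohort")
  num_cols <- c("age", "size_cm", "calcitonin_ng_l")
  num <- purrr::map_dfr(intersect(num_cols, names(records)), function(cn) {
    v <- records[[cn]][!is.na(records[[cn]])]
    tibble::tibble(column = cn, n = length(v), median = median(v),
                   mean = mean(v), min = min(v), max = max(v))
  })
  cat_cols <- c("sex", "location", "bethesda")
  cats <- purrr::map_dfr(intersect(cat_cols, names(records)), function(cn) {
    v <- records[[cn]][!is.na(records[[cn]])]
    tb <- table(v)
    tibble::tibble(column = cn, level = names(tb), n = as.integer(tb),
                   percent = pct_round(as.integer(tb) / length(v)))
  })
  stage <- NULL
  if ("stage" %in% names(records)) {
    v <- records$stage[!is.na(records$stage)]
    tb <- table(factor(v, levels = c("I", "II", "III", "IVA", "IVB", "IVC")))
    tb <- tb[tb > 0]
    stage <- tibble::tibble(stage = names(tb), n = as.integer(tb),
                            percent = pct_round(as.integer(tb) / length(v)))
  }
  structure(list(numeric = num, categorical = cats, stage = stage),
            class = "mtc_cohort_summary")
}

#' @export
print.mtc_cohort_summary <- function(x, ...) {
  cat("Numeric columns (median [range], non-missing):\n")
  for (i in seq_len(nrow(x$numeric))) {
    r <- x$numeric[i, ]
    cat(sprintf("  %-16s %g (%g-%g), mean %.2f, n=%d\n", r$column,
                r$median, r$min, r$max, r$mean, r$n))
  }
  cat("Categorical columns (percent of non-missing):\n")
  for (cn in unique(x$categorical$column)) {
    sub <- x$categorical[x$categorical$column == cn, ]
    cat(sprintf("  %-16s %s\n", cn,
                paste(sprintf("%s %d%%", sub$level, sub$percent),
                      collapse = ", ")))
  }
  if (!is.null(x$stage)) {
    cat(sprintf("  %-16s %s\n", "stage",
                paste(sprintf("%s %d%%", x$stage$stage, x$stage$percent),
                      collapse = ", ")))
  }
  invisible(x)
}
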