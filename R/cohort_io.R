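#' @useDynLib crtpredict, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pt rnorm runif predict coef var aggregate
#' @importFrom utils read.delim
"_PACKAGE"

DWORAK_CLASSES <- c("MI", "MO", "NT", "TO")
MULTICLASS_LABELS <- c("MI", "MO", "TO")

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2-scale (RMA-style)
#' intensities with unique gene symbols as row names and unique sample IDs as
#' column names. All downstream functions accept and return this form.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene symbols (row names).
#' @param sample_ids character vector of unique sample IDs (column names).
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || length(gene_ids) == 0L)
    abort_parse("expression matrix must have at least one gene")
  if (anyDuplicated(gene_ids))
    abort_duplicate_gene(sprintf(
      "duplicate gene symbol(s): %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (anyDuplicated(sample_ids))
    abort_parse("duplicate sample IDs in expression matrix")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    abort_parse("dimnames do not match matrix shape")
  if (!is.numeric(values) || any(!is.finite(values)))
    abort_parse("expression values must all be finite numbers")
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expected dialect: tab-delimited UTF-8, header row of sample IDs with first
#' column header `gene`, one row per gene symbol.
#'
#' @param path file path.
#' @param fmt format; only `"tsv"` is supported.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path, fmt = "tsv") {
  fmt <- match.arg(fmt, "tsv")
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = NULL)
  if (ncol(raw) < 2L) abort_parse("expression TSV needs a gene column plus >= 1 sample")
  genes <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | cells == "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort_parse(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                        genes[bad[1L, 1L]], colnames(raw)[-1L][bad[1L, 2L]]))
  expression_matrix(num, gene_ids = genes, sample_ids = colnames(raw)[-1L])
}

#' Write an expression matrix as TSV
#'
#' Values are serialized with `%.17g` so that a write-then-read round trip is
#' bit-exact for doubles.
#'
#' @param expr expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  expr <- expression_matrix(expr)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

# Accepted spellings for each Dworak regression grade. Grade 0 (no regression)
# is defined by the Dworak scale but absent from the modeled cohort and is
# rejected on input.
.grade_synonyms <- list(
  MI = c("MI", "1", "G1", "GRADE1", "GRADE 1"),
  MO = c("MO", "2", "G2", "GRADE2", "GRADE 2"),
  NT = c("NT", "3", "G3", "GRADE3", "GRADE 3"),
  TO = c("TO", "4", "G4", "GRADE4", "GRADE 4")
)

normalize_grade <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  for (g in names(.grade_synonyms)) out[key %in% .grade_synonyms[[g]]] <- g
  if (anyNA(out))
    abort_label(sprintf("unrecognized Dworak grade(s): %s",
                        paste(unique(key[is.na(out)]), collapse = ", ")))
  out
}

#' Construct validated per-sample Dworak grade labels
#'
#' Labels are represented as a factor with levels `MI < MO < NT < TO`, named by
#' sample ID. Numeric Dworak grades (`"1"`/`"G1"` etc.) are normalized; grade 0
#' is rejected.
#'
#' @param sample_ids character vector of unique sample IDs.
#' @param grade per-sample grade, any accepted spelling.
#' @return named factor of grades.
#' @export
dworak_labels <- function(sample_ids, grade) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(grade))
    abort_label("sample_ids and grade lengths differ")
  if (anyDuplicated(sample_ids))
    abort_label(sprintf("duplicate sample ID(s): %s",
                        paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  g <- factor(normalize_grade(grade), levels = DWORAK_CLASSES)
  names(g) <- sample_ids
  g
}

#' Read a sample-label table (sample_id, grade) from TSV
#'
#' @param path two-column tab-delimited file with a header row.
#' @return named factor of Dworak grades (see [dworak_labels()]).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_label(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort_label("label TSV needs columns (sample_id, grade)")
  dworak_labels(raw[[1L]], raw[[2L]])
}

#' Write a label table as TSV
#' @param labels named factor from [dworak_labels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("sample_id\tgrade",
               paste(names(labels), as.character(labels), sep = "\t")), con)
  invisible(path)
}

#' Bind an expression matrix and a label table into a cohort
#'
#' Samples are aligned by ID, not position; a sample present in only one of
#' the two inputs is an error.
#'
#' @param expr expression matrix.
#' @param labels named grade factor.
#' @return a `crt_cohort`: list with elements `expression` and `labels`
#'   (labels reordered to expression column order).
#' @export
bind_cohort <- function(expr, labels) {
  expr <- expression_matrix(expr)
  es <- colnames(expr)
  ls <- names(labels)
  if (length(intersect(es, ls)) == 0L)
    abort_alignment("expression and labels share no samples")
  only_e <- setdiff(es, ls)
  only_l <- setdiff(ls, es)
  if (length(only_e) || length(only_l))
    abort_alignment(sprintf(
      "sample sets differ (expression-only: %s; labels-only: %s)",
      paste(only_e, collapse = ",") , paste(only_l, collapse = ",")))
  structure(list(expression = expr, labels = labels[es]), class = "crt_cohort")
}

#' @export
print.crt_cohort <- function(x, ...) {
  cat(sprintf("<crt_cohort> %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  print(table(x$labels))
  invisible(x)
}

n_samples <- function(cohort) ncol(cohort$expression)

subset_cohort <- function(cohort, samples) {
  structure(list(expression = cohort$expression[, samples, drop = FALSE],
                 labels = cohort$labels[samples]),
            class = "crt_cohort")
}
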