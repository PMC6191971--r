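#' CSV dialect description
#'
#' Describes how an expression CSV is delimited.  The default dialect uses
#' `,` as field separator and `.` as decimal mark; the opt-in European
#' dialect uses `;` and `,` (some locales render FPKM values with decimal
#' commas).
#'
#' @param sep Field separator, `","` or `";"`.
#' @param dec Decimal mark, `"."` or `","`.
#' @return An object of class `csv_dialect`.
#' @export
csv_dialect <- function(sep = ",", dec = ".") {
  if (!sep %in% c(",", ";")) stop("sep must be ',' or ';'", call. = FALSE)
  if (!dec %in% c(".", ",")) stop("dec must be '.' or ','", call. = FALSE)
  if (sep == dec) stop("sep and dec must differ", call. = FALSE)
  structure(list(sep = sep, dec = dec), class = "csv_dialect")
}

#' Construct an expression matrix
#'
#' A labeled case-control expression matrix: samples in rows, genes in
#' columns, one class label per sample.  Values are FPKM-like non-negative
#' reals.  Class labels are matched case-insensitively throughout the
#' package but preserved verbatim.
#'
#' @param values Numeric matrix, samples x genes.
#' @param sample_ids Character vector of unique sample identifiers (rows).
#' @param gene_ids Character vector of unique gene identifiers (columns).
#' @param labels Character vector of class labels, one per sample.
#' @param id_column,class_column Stored header names for the first and last
#'   CSV columns; not interpreted.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, sample_ids, gene_ids, labels,
                              id_column = "Aliquot", class_column = "Class") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- structure(
    list(values = values,
         sample_ids = as.character(sample_ids),
         gene_ids = as.character(gene_ids),
         labels = as.character(labels),
         id_column = id_column,
         class_column = class_column),
    class = "expr_matrix")
  rep <- validate_matrix(m, for_learning = FALSE)
  if (!rep$ok) {
    stop("invalid expression matrix: ",
         paste(vapply(rep$problems, `[[`, "", "message"), collapse = "; "),
         call. = FALSE)
  }
  m
}

#' @export
print.expr_matrix <- function(x, ...) {
  cs <- class_summary(x)
  cat(sprintf("Expression matrix: %d samples x %d genes\n",
              length(x$sample_ids), length(x$gene_ids)))
  for (i in seq_len(nrow(cs))) {
    cat(sprintf("  %s: %d (%.2f%%)\n", cs$label[i], cs$count[i], cs$percentage[i]))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# canonical lower-cased label used for all class comparisons
label_key <- function(labels) tolower(labels)

#' Read an expression matrix from CSV
#'
#' Layout: header row, then one row per sample; first column = sample id,
#' last column = class label, middle columns = per-gene expression values.
#' The class column is identified by position, never by header name.
#' Missing or non-numeric expression cells are errors: missing data are not
#' supported.
#'
#' @param source Path to a CSV file, or a connection.
#' @param dialect A [csv_dialect()].
#' @return An [expression_matrix()].
#' @export
load_matrix <- function(source, dialect = csv_dialect()) {
  if (is.character(source) && !file.exists(source)) {
    stop("cannot read '", source, "': no such file", call. = FALSE)
  }
  nf <- utils::count.fields(source, sep = dialect$sep, quote = "\"",
                            blank.lines.skip = TRUE)
  if (length(nf) < 2) stop("need a header row and at least one data row", call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop(sprintf("row %d has %d fields, header has %d", bad[1], nf[bad[1]], nf[1]),
         call. = FALSE)
  }
  if (nf[1] < 3) stop("need at least one gene column between id and class columns",
                      call. = FALSE)
  df <- utils::read.table(source, sep = dialect$sep, dec = dialect$dec,
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  p <- ncol(df)
  gene_ids <- colnames(df)[2:(p - 1)]
  sample_ids <- df[[1]]
  labels <- df[[p]]
  raw <- as.matrix(df[, 2:(p - 1), drop = FALSE])
  if (dialect$dec == ",") raw[] <- gsub(",", ".", raw, fixed = TRUE)
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad_cell <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad_cell) > 0) {
    i <- bad_cell[1, 1]; j <- bad_cell[1, 2]
    cell <- raw[i, j]
    what <- if (is.na(cell) || !nzchar(trimws(cell))) "missing value" else
      sprintf("non-numeric value '%s'", cell)
    stop(sprintf("%s at sample '%s', gene '%s' (data row %d)",
                 what, sample_ids[i], gene_ids[j], i), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[anyDuplicated(gene_ids)], call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[anyDuplicated(sample_ids)], call. = FALSE)
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at sample '%s', gene '%s'",
                 sample_ids[neg[1, 1]], gene_ids[neg[1, 2]]), call. = FALSE)
  }
  expression_matrix(vals, sample_ids, gene_ids, labels,
                    id_column = colnames(df)[1], class_column = colnames(df)[p])
}

#' Validate an expression matrix
#'
#' Checks every structural invariant and reports all violations with their
#' locus instead of raising.  With `for_learning = TRUE` (default) a matrix
#' whose samples all carry one class label is flagged `single_class`,
#' mirroring the exclusion of tumor-only cohorts from supervised analysis.
#'
#' @param m An `expr_matrix` (or a structurally similar list).
#' @param for_learning Require >= 2 distinct class labels.
#' @return A list with `ok` (logical) and `problems`, a list of
#'   `list(locus, code, message)` records.
#' @export
validate_matrix <- function(m, for_learning = TRUE) {
  problems <- list()
  add <- function(locus, code, message) {
    problems[[length(problems) + 1L]] <<- list(locus = locus, code = code,
                                               message = message)
  }
  n <- length(m$sample_ids); g <- length(m$gene_ids)
  if (!is.matrix(m$values)) {
    add("values", "not_matrix", "values is not a matrix")
  } else {
    if (nrow(m$values) != n)
      add("values", "shape", sprintf("%d rows but %d sample ids", nrow(m$values), n))
    if (ncol(m$values) != g)
      add("values", "shape", sprintf("%d columns but %d gene ids", ncol(m$values), g))
    bad <- which(!is.finite(m$values), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      add(sprintf("(%d,%d)", bad[1, 1], bad[1, 2]), "non_finite",
          "non-finite expression value")
    }
    neg <- which(m$values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      add(sprintf("(%d,%d)", neg[1, 1], neg[1, 2]), "negative",
          sprintf("negative value at sample '%s', gene '%s'",
                  m$sample_ids[neg[1, 1]], m$gene_ids[neg[1, 2]]))
    }
  }
  if (length(m$labels) != n)
    add("labels", "shape", sprintf("%d labels but %d samples", length(m$labels), n))
  if (g < 1) add("gene_ids", "no_genes", "at least one gene column is required")
  d <- anyDuplicated(m$gene_ids)
  if (d) add(m$gene_ids[d], "duplicate_gene", paste0("duplicate gene id '", m$gene_ids[d], "'"))
  d <- anyDuplicated(m$sample_ids)
  if (d) add(m$sample_ids[d], "duplicate_sample",
             paste0("duplicate sample id '", m$sample_ids[d], "'"))
  if (for_learning && length(unique(label_key(m$labels))) < 2) {
    add("labels", "single_class",
        sprintf("only one class present ('%s'); supervised analysis impossible",
                m$labels[1]))
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Per-class sample counts and percentages
#'
#' One row per distinct class label (case-insensitive match, verbatim label
#' of first occurrence shown), with the count and the percentage of total
#' samples rounded to two decimals -- the numbers behind the class pie
#' chart of a results page.
#'
#' @param m An `expr_matrix`.
#' @return A data.frame with columns `label`, `count`, `percentage`,
#'   ordered by decreasing count (ties: label order of first appearance).
#' @export
class_summary <- function(m) {
  key <- label_key(m$labels)
  first <- !duplicated(key)
  shown <- stats::setNames(m$labels[first], key[first])
  tab <- table(factor(key, levels = key[first]))
  cnt <- as.integer(tab)
  ord <- order(-cnt, seq_along(cnt))
  data.frame(label = unname(shown[names(tab)])[ord],
             count = cnt[ord],
             percentage = round(100 * cnt[ord] / length(key), 2),
             stringsAsFactors = FALSE)
}

#' Write an expression matrix to CSV
#'
#' Inverse of [load_matrix()]: numbers are written with full precision
#' (`format(..., digits = 17)` trimmed) so that a write/load round trip
#' reproduces the matrix exactly.
#'
#' @param m An `expr_matrix`.
#' @param dest Path or connection.
#' @param dialect A [csv_dialect()].
#' @export
write_matrix <- function(m, dest, dialect = csv_dialect()) {
  rep <- validate_matrix(m, for_learning = FALSE)
  if (!rep$ok) stop("refusing to write an invalid matrix: ",
                    rep$problems[[1]]$message, call. = FALSE)
  num <- format(m$values, digits = 17, trim = TRUE, scientific = FALSE,
                drop0trailing = TRUE)
  if (dialect$dec == ",") num[] <- gsub(".", ",", num, fixed = TRUE)
  df <- data.frame(m$sample_ids, num, m$labels, stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- c(m$id_column, m$gene_ids, m$class_column)
  utils::write.table(df, dest, sep = dialect$sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(NULL)
}

# subset helpers used by the learner and engine --------------------------

# drop the named gene columns; errors if that would leave no genes
drop_genes <- function(m, genes) {
  keep <- !(m$gene_ids %in% genes)
  if (!any(keep)) stop("eliminating all gene columns", call. = FALSE)
  structure(list(values = m$values[, keep, drop = FALSE],
                 sample_ids = m$sample_ids,
                 gene_ids = m$gene_ids[keep],
                 labels = m$labels,
                 id_column = m$id_column,
                 class_column = m$class_column),
            class = "expr_matrix")
}

# row subset (samples)
subset_samples <- function(m, idx) {
  structure(list(values = m$values[idx, , drop = FALSE],
                 sample_ids = m$sample_ids[idx],
                 gene_ids = m$gene_ids,
                 labels = m$labels[idx],
                 id_column = m$id_column,
                 class_column = m$class_column),
            class = "expr_matrix")
}
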