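#' Create an empty knowledge base
#'
#' A relational store of runs, models, conjunctions and literals with
#' referential integrity (run -> model -> conjunction -> literal).  The
#' backing engine is a set of in-memory data frames persisted as a single
#' JSON document ([export_kb()] / [import_kb()]); the contract is the
#' schema, not the engine.  Rejected models are stored for auditability but
#' are invisible to every query.
#'
#' @return An object of class `camur_kb` (an environment holding the four
#'   tables).
#' @export
kb_create <- function() {
  kb <- new.env(parent = emptyenv())
  kb$runs <- data.frame(run_id = character(), mode = character(),
                        max_iterations = integer(), min_f_measure = double(),
                        seed = integer(), stop_reason = character(),
                        positive_class = character(), default_class = character(),
                        n_samples = integer(), n_genes = integer(),
                        class_summary = character(),
                        fingerprint = character(), stringsAsFactors = FALSE)
  kb$models <- data.frame(model_id = integer(), run_id = character(),
                          iteration = integer(), rule_text = character(),
                          positive_class = character(), default_class = character(),
                          precision = double(), recall = double(),
                          f_measure = double(), accuracy = double(),
                          accepted = logical(), stringsAsFactors = FALSE)
  kb$conjunctions <- data.frame(conjunction_id = integer(), model_id = integer(),
                                ordinal = integer(), text = character(),
                                correct = integer(), incorrect = integer(),
                                stringsAsFactors = FALSE)
  kb$literals <- data.frame(literal_id = integer(), conjunction_id = integer(),
                            gene = character(), op = character(),
                            threshold = double(), stringsAsFactors = FALSE)
  class(kb) <- "camur_kb"
  kb
}

reset_rownames <- function(df) { rownames(df) <- NULL; df }

#' @export
print.camur_kb <- function(x, ...) {
  cat(sprintf("Knowledge base: %d run(s), %d model(s) (%d accepted), %d conjunction(s), %d literal(s)\n",
              nrow(x$runs), nrow(x$models), sum(x$models$accepted),
              nrow(x$conjunctions), nrow(x$literals)))
  invisible(x)
}

# cheap deterministic content fingerprint of a matrix (polynomial rolling
# hash over a canonical text rendering, mod a Mersenne prime kept in double
# precision); identifies the dataset a run was trained on
matrix_fingerprint <- function(m) {
  txt <- paste(c(m$sample_ids, m$gene_ids, m$labels,
                 format(m$values, digits = 12, trim = TRUE)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Add a run to the knowledge base
#'
#' Stores every iteration record of the run; accepted models become visible
#' to the five queries, rejected ones are flagged and ignored.  Each
#' conjunction is stored with its correct/incorrect cover counts on the
#' supplied training matrix (covered samples of the model's positive class
#' versus the rest).
#'
#' @param kb A `camur_kb`.
#' @param run A `camur_run` from [run_camur()].
#' @param training_matrix The `expr_matrix` the run was executed on.
#' @param run_id Optional explicit run identifier; auto-numbered otherwise.
#'   Re-using an existing id is an error.
#' @return The run id, invisibly.
#' @export
add_run <- function(kb, run, training_matrix, run_id = NULL) {
  if (is.null(run_id)) run_id <- sprintf("run_%03d", nrow(kb$runs) + 1L)
  if (run_id %in% kb$runs$run_id)
    stop("run id '", run_id, "' already present", call. = FALSE)
  cfg <- run$config
  kb$runs <- rbind(kb$runs, data.frame(
    run_id = run_id, mode = cfg$mode, max_iterations = cfg$max_iterations,
    min_f_measure = cfg$min_f_measure, seed = cfg$seed,
    stop_reason = run$stop_reason, positive_class = run$positive_class,
    default_class = run$default_class,
    n_samples = length(training_matrix$sample_ids),
    n_genes = length(training_matrix$gene_ids),
    class_summary = as.character(jsonlite::toJSON(class_summary(training_matrix),
                                                  dataframe = "columns",
                                                  digits = NA)),
    fingerprint = matrix_fingerprint(training_matrix),
    stringsAsFactors = FALSE))
  pos <- label_key(training_matrix$labels) == tolower(run$positive_class)
  for (rec in run$records) {
    model_id <- nrow(kb$models) + 1L
    kb$models <- rbind(kb$models, data.frame(
      model_id = model_id, run_id = run_id, iteration = rec$iteration,
      rule_text = rec$rule_text,
      positive_class = rec$model$positive_class,
      default_class = rec$model$default_class,
      # 15 significant digits survive the JSON export/import round trip
      precision = signif(rec$metrics$precision, 15),
      recall = signif(rec$metrics$recall, 15),
      f_measure = signif(rec$metrics$f_measure, 15),
      accuracy = signif(rec$metrics$accuracy, 15),
      accepted = rec$accepted, stringsAsFactors = FALSE))
    for (ord in seq_along(rec$model$conjunctions)) {
      cj <- rec$model$conjunctions[[ord]]
      cov <- conj_cover(cj, training_matrix$values, training_matrix$gene_ids)
      conj_id <- nrow(kb$conjunctions) + 1L
      kb$conjunctions <- rbind(kb$conjunctions, data.frame(
        conjunction_id = conj_id, model_id = model_id, ordinal = ord,
        text = conjunction_text(cj),
        correct = sum(cov & pos), incorrect = sum(cov & !pos),
        stringsAsFactors = FALSE))
      for (lit in cj) {
        kb$literals <- rbind(kb$literals, data.frame(
          literal_id = nrow(kb$literals) + 1L, conjunction_id = conj_id,
          gene = lit$gene, op = lit$op, threshold = lit$threshold,
          stringsAsFactors = FALSE))
      }
    }
  }
  invisible(run_id)
}

# accepted model ids, optionally restricted to given run ids
visible_models <- function(kb, runs = NULL) {
  md <- kb$models[kb$models$accepted, , drop = FALSE]
  if (!is.null(runs)) md <- md[md$run_id %in% runs, , drop = FALSE]
  md
}

# model_id -> sorted distinct genes, via the literal table
model_gene_sets <- function(kb, model_ids) {
  cj <- kb$conjunctions[kb$conjunctions$model_id %in% model_ids, , drop = FALSE]
  li <- kb$literals[kb$literals$conjunction_id %in% cj$conjunction_id, , drop = FALSE]
  li$model_id <- cj$model_id[match(li$conjunction_id, cj$conjunction_id)]
  lapply(stats::setNames(model_ids, model_ids), function(id)
    sort(unique(li$gene[li$model_id == id])))
}

#' Features List query
#'
#' Distinct genes over all accepted models with their occurrence counts; a
#' gene counts once per model regardless of how many literals mention it.
#'
#' @param kb A `camur_kb`.
#' @param runs Optional character vector of run ids to restrict to.
#' @return data.frame(gene, occurrences) sorted by occurrences descending,
#'   ties lexicographically by gene.
#' @export
query_features_list <- function(kb, runs = NULL) {
  md <- visible_models(kb, runs)
  sets <- model_gene_sets(kb, md$model_id)
  genes <- unlist(sets, use.names = FALSE)
  if (length(genes) == 0)
    return(data.frame(gene = character(), occurrences = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(genes)
  out <- data.frame(gene = names(tab), occurrences = as.integer(tab),
                    stringsAsFactors = FALSE)
  reset_rownames(out[order(-out$occurrences, out$gene), , drop = FALSE])
}

#' Literals and conjunctions list query
#'
#' One row per stored conjunction of an accepted model with its correct and
#' incorrect training cover counts and their percentages over the covered
#' total, plus `n_models`, the number of accepted models containing a
#' textually identical conjunction.
#'
#' @inheritParams query_features_list
#' @return data.frame(conjunction, model_id, correct, incorrect,
#'   pct_correct, pct_incorrect, n_models) ordered by correct count
#'   descending, then conjunction text, then model id.
#' @export
query_conjunctions <- function(kb, runs = NULL) {
  md <- visible_models(kb, runs)
  cj <- kb$conjunctions[kb$conjunctions$model_id %in% md$model_id, , drop = FALSE]
  if (nrow(cj) == 0)
    return(data.frame(conjunction = character(), model_id = integer(),
                      correct = integer(), incorrect = integer(),
                      pct_correct = double(), pct_incorrect = double(),
                      n_models = integer(), stringsAsFactors = FALSE))
  covered <- cj$correct + cj$incorrect
  agg <- tapply(cj$model_id, cj$text, function(x) length(unique(x)))
  out <- data.frame(conjunction = cj$text, model_id = cj$model_id,
                    correct = cj$correct, incorrect = cj$incorrect,
                    pct_correct = round(100 * cj$correct / pmax(covered, 1L), 2),
                    pct_incorrect = round(100 * cj$incorrect / pmax(covered, 1L), 2),
                    n_models = as.integer(agg[cj$text]),
                    stringsAsFactors = FALSE)
  reset_rownames(out[order(-out$correct, out$conjunction, out$model_id), , drop = FALSE])
}

#' Rules list query
#'
#' One row per accepted model with its stored rule text and metrics.
#'
#' @inheritParams query_features_list
#' @return data.frame(rule, precision, accuracy, f_measure) sorted by
#'   f_measure descending, ties lexicographically by rule text.
#' @export
query_rules <- function(kb, runs = NULL) {
  md <- visible_models(kb, runs)
  out <- data.frame(rule = md$rule_text, precision = md$precision,
                    accuracy = md$accuracy, f_measure = md$f_measure,
                    stringsAsFactors = FALSE)
  reset_rownames(out[order(-out$f_measure, out$rule), , drop = FALSE])
}

#' Literals statistics query
#'
#' Threshold statistics of the stored literals of accepted models grouped
#' by (gene, operator).
#'
#' @inheritParams query_features_list
#' @return data.frame(gene, op, n_literals, min_threshold, mean_threshold,
#'   max_threshold) ordered by gene then operator (`<` before `>=`).
#' @export
query_literal_stats <- function(kb, runs = NULL) {
  md <- visible_models(kb, runs)
  cj <- kb$conjunctions[kb$conjunctions$model_id %in% md$model_id, , drop = FALSE]
  li <- kb$literals[kb$literals$conjunction_id %in% cj$conjunction_id, , drop = FALSE]
  if (nrow(li) == 0)
    return(data.frame(gene = character(), op = character(),
                      n_literals = integer(), min_threshold = double(),
                      mean_threshold = double(), max_threshold = double(),
                      stringsAsFactors = FALSE))
  key <- paste(li$gene, li$op, sep = "\x1f")
  sp <- split(li$threshold, key)
  parts <- strsplit(names(sp), "\x1f", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[[`, "", 1),
                    op = vapply(parts, `[[`, "", 2),
                    n_literals = vapply(sp, length, 0L),
                    min_threshold = vapply(sp, min, 0),
                    mean_threshold = vapply(sp, mean, 0),
                    max_threshold = vapply(sp, max, 0),
                    stringsAsFactors = FALSE)
  reset_rownames(out[order(out$gene, out$op), , drop = FALSE])
}

#' Feature pairs query
#'
#' Unordered pairs of distinct genes co-present in the same accepted model
#' (the full disjunction), with the number of models containing both.
#'
#' @inheritParams query_features_list
#' @return data.frame(gene1, gene2, co_occurrences) with
#'   `gene1 < gene2` lexicographically, sorted by count descending, ties by
#'   gene1 then gene2.
#' @export
query_feature_pairs <- function(kb, runs = NULL) {
  md <- visible_models(kb, runs)
  sets <- model_gene_sets(kb, md$model_id)
  pairs <- unlist(lapply(sets, function(g) {
    if (length(g) < 2) return(character())
    cmb <- utils::combn(g, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\x1f")
  }), use.names = FALSE)
  if (length(pairs) == 0)
    return(data.frame(gene1 = character(), gene2 = character(),
                      co_occurrences = integer(), stringsAsFactors = FALSE))
  tab <- table(pairs)
  parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
  out <- data.frame(gene1 = vapply(parts, `[[`, "", 1),
                    gene2 = vapply(parts, `[[`, "", 2),
                    co_occurrences = as.integer(tab),
                    stringsAsFactors = FALSE)
  reset_rownames(out[order(-out$co_occurrences, out$gene1, out$gene2), , drop = FALSE])
}

#' Run a named knowledge-base query
#'
#' @param kb A `camur_kb`.
#' @param query One of `"features"`, `"conjunctions"`, `"rules"`,
#'   `"literal-stats"`, `"pairs"`.
#' @param runs Optional run-id filter.
#' @return The query's data.frame.
#' @export
kb_query <- function(kb, query, runs = NULL) {
  switch(query,
         "features" = query_features_list(kb, runs),
         "conjunctions" = query_conjunctions(kb, runs),
         "rules" = query_rules(kb, runs),
         "literal-stats" = ,
         "literal_stats" = query_literal_stats(kb, runs),
         "pairs" = query_feature_pairs(kb, runs),
         stop("unknown query '", query, "'", call. = FALSE))
}

kb_query_names <- c("features", "conjunctions", "rules", "literal-stats", "pairs")

#' Export a knowledge base
#'
#' `format = "json"` writes the four relational tables as one document;
#' [import_kb()] on that file reproduces a knowledge base with identical
#' query results (a fixed point).  `format = "csv"` writes the five query
#' outputs plus the run table to a directory, one file per query.
#'
#' @param kb A `camur_kb`.
#' @param format `"json"` or `"csv"`.
#' @param dest JSON file path, or directory for CSV.
#' @export
export_kb <- function(kb, format = c("json", "csv"), dest) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(schema = "camur-kb/1", runs = kb$runs, models = kb$models,
                conjunctions = kb$conjunctions, literals = kb$literals)
    writeLines(jsonlite::toJSON(doc, dataframe = "columns", auto_unbox = TRUE,
                                digits = NA, pretty = TRUE), dest)
  } else {
    if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
    utils::write.csv(kb$runs, file.path(dest, "runs.csv"), row.names = FALSE)
    for (q in kb_query_names) {
      utils::write.csv(kb_query(kb, q),
                       file.path(dest, paste0("query_", gsub("-", "_", q), ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(NULL)
}

#' Import a JSON knowledge-base export
#'
#' @param path Path written by [export_kb()] with `format = "json"`.
#' @return A `camur_kb`.
#' @export
import_kb <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  kb <- kb_create()
  as_df <- function(tpl, cols) {
    if (length(cols) == 0 || length(cols[[1]]) == 0) return(tpl)
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    for (nm in names(tpl)) {
      if (is.integer(tpl[[nm]])) df[[nm]] <- as.integer(df[[nm]])
      if (is.double(tpl[[nm]])) df[[nm]] <- as.double(df[[nm]])
      if (is.logical(tpl[[nm]])) df[[nm]] <- as.logical(df[[nm]])
    }
    df[names(tpl)]
  }
  kb$runs <- as_df(kb$runs, doc$runs)
  kb$models <- as_df(kb$models, doc$models)
  kb$conjunctions <- as_df(kb$conjunctions, doc$conjunctions)
  kb$literals <- as_df(kb$literals, doc$literals)
  kb
}
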