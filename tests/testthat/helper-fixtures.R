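# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; no binary fixtures.

# small labeled matrix built directly from a value matrix
toy_matrix <- function(values, labels, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%d", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(values)))
  expression_matrix(values, sample_ids, gene_ids, labels)
}

# 1-gene separable data: positives < 5, negatives > 7
separable_1g <- function(n_per = 10, seed = 42) {
  set.seed(seed)
  vals <- c(runif(n_per, 0, 5), runif(n_per, 7, 12))
  toy_matrix(cbind(vals), rep(c("Tumoral", "Normal"), each = n_per))
}

# 2-gene matrix where each gene alone separates the classes
redundant_2g <- function(n_per = 10, seed = 7) {
  set.seed(seed)
  a <- c(runif(n_per, 0, 5), runif(n_per, 7, 12))
  b <- c(runif(n_per, 20, 30), runif(n_per, 40, 55))
  toy_matrix(cbind(a, b), rep(c("Tumoral", "Normal"), each = n_per),
             gene_ids = c("GA", "GB"))
}

# ORACLE: exhaustive best single-literal model on training data.
# Independent of the learner: enumerates every midpoint of every gene with
# both operators and counts the confusion directly.
best_single_literal_f <- function(m, positive_class) {
  pos <- tolower(m$labels) == tolower(positive_class)
  f_of <- function(cover) {
    tp <- sum(cover & pos); fp <- sum(cover & !pos); fn <- sum(!cover & pos)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }
  best <- 0
  for (j in seq_len(ncol(m$values))) {
    v <- m$values[, j]
    sv <- sort(unique(v))
    if (length(sv) < 2) next
    mids <- (sv[-1] + sv[-length(sv)]) / 2
    for (t in mids) {
      best <- max(best, f_of(v < t), f_of(v >= t))
    }
  }
  best
}

# ORACLE: recompute feature occurrences / pairs from stored rule texts by
# regex-scanning gene tokens, independently of the package's parser.
genes_from_text <- function(text) {
  body <- sub(" => [^=]+$", "", text)
  toks <- regmatches(body, gregexpr("\\(([^()<> ]+) (<|>=)", body))[[1]]
  sort(unique(sub("^\\(([^()<> ]+) .*$", "\\1", toks)))
}

oracle_feature_counts <- function(rule_texts) {
  genes <- unlist(lapply(rule_texts, genes_from_text))
  if (length(genes) == 0) return(integer())
  tab <- table(genes)
  stats::setNames(as.integer(tab), names(tab))
}

oracle_pair_counts <- function(rule_texts) {
  counts <- list()
  for (text in rule_texts) {
    g <- genes_from_text(text)
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    for (k in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, k], cmb[2, k], sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  r <- unlist(counts)
  if (is.null(r)) r <- stats::setNames(integer(), character())
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fabricate a camur_run holding hand-written models (for KB tests that do
# not need learning); metrics are supplied or default to a perfect model
fake_run <- function(models, accepted = rep(TRUE, length(models)),
                     metrics = NULL, mode = "loose", seed = 1L) {
  records <- lapply(seq_along(models), function(i) {
    mm <- metrics[[i]] %||% list(tp = 1L, fp = 0L, fn = 0L, tn = 1L,
                                 precision = 1, recall = 1, f_measure = 1,
                                 accuracy = 1)
    list(iteration = i, eliminated = character(), model = models[[i]],
         rule_text = format_rule(models[[i]]), metrics = mm,
         train_metrics = mm, accepted = accepted[i],
         model_genes = model_genes(models[[i]]))
  })
  acc <- records[accepted]
  structure(list(config = engine_config(mode, seed = seed),
                 positive_class = models[[1]]$positive_class,
                 default_class = models[[1]]$default_class,
                 records = records, stop_reason = "combinations_exhausted",
                 totals = list(iterations = length(records),
                               accepted_models = length(acc),
                               distinct_genes = length(unique(unlist(lapply(acc, `[[`, "model_genes")))))),
            class = "camur_run")
}

# quick literal/conjunction/model builders
lit <- function(gene, op, t) list(gene = gene, op = op, threshold = t)
mk_model <- function(conjs, positive = "Tumoral", default = "Normal") {
  rule_model(positive, default, conjs)
}

# cache expensive engine runs across test files within one session
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

redundant6_data <- function() {
  cached_run("redundant6_data",
             generate_dataset(camur:::fixture_spec("redundant6")))
}

redundant6_loose <- function() {
  cached_run("redundant6_loose",
             run_camur(redundant6_data()$matrix, engine_config("loose", seed = 7)))
}

redundant6_strict <- function() {
  cached_run("redundant6_strict",
             run_camur(redundant6_data()$matrix, engine_config("strict", seed = 7)))
}
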