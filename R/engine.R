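#' Engine configuration
#'
#' Defaults reproduce the reference run configuration: loose execution
#' mode, at most 100 iterations, minimum F-measure 0.8.
#'
#' @param mode `"loose"` (breadth-first walk over combinations of extracted
#'   features; worst-case exponential, extracts more knowledge) or
#'   `"strict"` (each round eliminates the cumulative set of all features
#'   seen so far; linear).
#' @param max_iterations Maximum number of learner invocations.
#' @param min_f_measure Gate: models with cross-validated F-measure below
#'   this are rejected and contribute no genes.
#' @param learner A [learner_params()]; its seed is overridden by `seed`.
#' @param seed Master seed for the run.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(mode = c("loose", "strict"), max_iterations = 100L,
                          min_f_measure = 0.8, learner = learner_params(),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(max_iterations >= 1, min_f_measure >= 0, min_f_measure <= 1)
  structure(list(mode = mode, max_iterations = as.integer(max_iterations),
                 min_f_measure = min_f_measure, learner = learner,
                 seed = as.integer(seed)),
            class = "engine_config")
}

comb_key <- function(genes) paste(sort(genes), collapse = "\x1f")

#' Fresh elimination-lattice state
#'
#' Holds the FIFO queue of pending feature combinations, the set of
#' combinations ever seen, the cumulative feature set S of all accepted
#' models, and whether the queue has ever grown.  Mutable (an environment),
#' consumed by [next_elimination()] and [stopping_check()].
#'
#' @return An environment of class-free elimination state.
#' @export
new_elim_state <- function() {
  e <- new.env(parent = emptyenv())
  e$pending <- list()        # FIFO queue of gene-id character vectors
  e$seen <- character()      # keys of combinations ever enqueued/processed
  e$cumulative <- character()  # S: genes of all accepted models
  e$grew <- FALSE            # queue ever extended past the initial empty set
  e
}

# enqueue unseen combination
enqueue_comb <- function(state, genes) {
  k <- comb_key(genes)
  if (k %in% state$seen) return(invisible(FALSE))
  state$seen <- c(state$seen, k)
  state$pending[[length(state$pending) + 1L]] <- sort(genes)
  state$grew <- TRUE
  invisible(TRUE)
}

# fold the outcome of one iteration into the elimination state: accepted
# models extend the cumulative feature set and the pending queue
update_elimination <- function(state, mode, last) {
  if (is.null(last) || !isTRUE(last$accepted)) return(invisible(state))
  feats <- last$model_genes
  state$cumulative <- sort(union(state$cumulative, feats))
  if (mode == "strict") {
    state$pending <- list()
    k <- comb_key(state$cumulative)
    if (!k %in% state$seen) {
      state$seen <- c(state$seen, k)
      state$pending <- list(state$cumulative)
      state$grew <- TRUE
    }
  } else {
    for (f in setdiff(feats, last$eliminated)) {
      enqueue_comb(state, union(last$eliminated, f))
    }
  }
  invisible(state)
}

pop_comb <- function(state) {
  if (length(state$pending) == 0) return(NULL)
  nxt <- state$pending[[1]]
  state$pending <- state$pending[-1]
  nxt
}

#' Next elimination combination
#'
#' Folds the outcome of the last iteration into the elimination state and
#' pops the next pending feature combination.  In strict mode every
#' accepted model collapses the queue to the single cumulative feature set
#' S.  In loose mode an accepted model with feature set F learned under
#' eliminated combination C enqueues C with each f in F \\ C appended (a
#' breadth-first FIFO walk of the combination lattice, skipping
#' combinations already seen).  Returns `NULL` when the queue is exhausted.
#'
#' @param state Elimination state environment from `new_elim_state()`.
#' @param mode `"loose"` or `"strict"`.
#' @param last The last iteration record (or `NULL` to pop only).
#' @return A character vector of gene ids, or `NULL` (exhausted).
#' @export
next_elimination <- function(state, mode, last = NULL) {
  update_elimination(state, mode, last)
  pop_comb(state)
}

#' Stopping criterion check
#'
#' Applied in the fixed order: (i) `max_iterations` reached;
#' (iii) `combinations_exhausted` -- the pending queue is empty after the
#' walk extended it at least once (every combination derivable from the
#' accepted models has been eliminated); (ii) `f_below_threshold` -- the
#' queue is empty and never grew because no model passed the gate.
#' Returns `"continue"` otherwise.
#'
#' @param state Elimination state.
#' @param records List of iteration records so far (non-empty).
#' @param cfg An [engine_config()].
#' @return One of `"max_iterations"`, `"combinations_exhausted"`,
#'   `"f_below_threshold"`, `"continue"`.
#' @export
stopping_check <- function(state, records, cfg) {
  if (length(records) >= cfg$max_iterations) return("max_iterations")
  if (length(state$pending) == 0) {
    if (state$grew) return("combinations_exhausted")
    return("f_below_threshold")
  }
  "continue"
}

#' Run the iterative multiple-model extraction loop
#'
#' Iteration 1 learns on the full matrix.  Each accepted model (cross-
#' validated F-measure at or above the gate) contributes its genes to the
#' cumulative feature set and spawns new elimination combinations per the
#' execution mode; each subsequent iteration removes one pending
#' combination's columns, learns, gates, and records.  Terminates on the
#' first satisfied stopping criterion.  Deterministic given `cfg$seed`.
#'
#' @param m A valid two-class `expr_matrix`.
#' @param cfg An [engine_config()].
#' @return A `camur_run` object: `config`, `positive_class`,
#'   `default_class`, `records` (one per iteration: `iteration`,
#'   `eliminated`, `model`, `rule_text`, `metrics`, `train_metrics`,
#'   `accepted`, `model_genes`), `stop_reason`, and `totals`
#'   (`iterations`, `accepted_models`, `distinct_genes`).
#' @export
run_camur <- function(m, cfg = engine_config()) {
  rep <- validate_matrix(m)
  if (!rep$ok) stop("invalid matrix: ", rep$problems[[1]]$message, call. = FALSE)
  positive <- resolve_positive_class(m$labels, cfg$learner$positive_class)
  default <- default_class_for(m$labels, positive)
  state <- new_elim_state()
  records <- list()
  eliminated <- character()  # iteration 1: nothing eliminated
  with_seed(cfg$seed, {
    iter_seeds <- sample.int(.Machine$integer.max - 1L, cfg$max_iterations)
  })
  stop_reason <- NULL
  repeat {
    it <- length(records) + 1L
    sub <- if (length(eliminated) == 0) m else drop_genes(m, eliminated)
    lp <- cfg$learner
    lp$seed <- iter_seeds[it]
    lp$positive_class <- positive
    # shrink the CV fold count if a class is smaller than the default k
    lp$k_folds <- max(2L, min(lp$k_folds,
                              min(table(label_key(sub$labels)))))
    model <- learn_model(sub, lp)
    train_metrics <- evaluate_model(model, sub)
    metrics <- if (length(model$conjunctions) == 0)
      metrics_from_counts(0L, 0L, sum(label_key(sub$labels) == tolower(positive)),
                          sum(label_key(sub$labels) != tolower(positive)))
    else cross_validate(sub, lp)
    accepted <- length(model$conjunctions) > 0 &&
      metrics$f_measure >= cfg$min_f_measure
    rec <- list(iteration = it, eliminated = eliminated, model = model,
                rule_text = format_rule(model), metrics = metrics,
                train_metrics = train_metrics, accepted = accepted,
                model_genes = model_genes(model))
    records[[it]] <- rec
    update_elimination(state, cfg$mode, rec)
    reason <- stopping_check(state, records, cfg)
    if (reason != "continue") { stop_reason <- reason; break }
    nxt <- pop_comb(state)
    # a combination spanning every gene cannot be eliminated; skip it
    while (!is.null(nxt) && all(m$gene_ids %in% nxt)) nxt <- pop_comb(state)
    if (is.null(nxt)) { stop_reason <- stopping_check(state, records, cfg); break }
    eliminated <- nxt
  }
  accepted_recs <- Filter(function(r) r$accepted, records)
  structure(list(
    config = cfg,
    positive_class = positive,
    default_class = default,
    records = records,
    stop_reason = stop_reason,
    totals = list(
      iterations = length(records),
      accepted_models = length(accepted_recs),
      distinct_genes = length(unique(unlist(lapply(accepted_recs,
                                                   `[[`, "model_genes")))))),
    class = "camur_run")
}

#' @export
print.camur_run <- function(x, ...) {
  cat(sprintf("CAMUR run (%s mode): %d iteration(s), %d accepted model(s), %d distinct gene(s)\n",
              x$config$mode, x$totals$iterations, x$totals$accepted_models,
              x$totals$distinct_genes))
  cat("  stop reason:", x$stop_reason, "\n")
  invisible(x)
}

#' Distinct genes across a run's accepted models
#' @param run A `camur_run`.
#' @return Sorted character vector.
#' @export
run_genes <- function(run) {
  sort(unique(unlist(lapply(Filter(function(r) r$accepted, run$records),
                            `[[`, "model_genes"))))
}

#' Serialize a run manifest to JSON
#'
#' The manifest carries the configuration snapshot, seed, stop reason and
#' one record per iteration (eliminated combination, rule text, metrics,
#' accepted flag) -- enough to replay or audit the run.  Byte-identical for
#' identical data, configuration and seed.
#'
#' @param run A `camur_run`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_manifest <- function(run, path = NULL) {
  cfg <- run$config
  doc <- list(
    config = list(mode = cfg$mode, max_iterations = cfg$max_iterations,
                  min_f_measure = cfg$min_f_measure, seed = cfg$seed,
                  positive_class = run$positive_class,
                  default_class = run$default_class,
                  validation = sprintf("stratified %d-fold cross-validation",
                                       cfg$learner$k_folds),
                  strict_elimination = "cumulative union",
                  learner = list(split_frac = cfg$learner$split_frac,
                                 mdl_slack = cfg$learner$mdl_slack,
                                 opt_passes = cfg$learner$opt_passes,
                                 k_folds = cfg$learner$k_folds)),
    stop_reason = run$stop_reason,
    totals = run$totals,
    iterations = lapply(run$records, function(r) {
      list(iteration = r$iteration,
           eliminated = as.list(r$eliminated),
           rule = r$rule_text,
           accepted = r$accepted,
           metrics = r$metrics[c("tp", "fp", "fn", "tn", "precision",
                                 "recall", "f_measure", "accuracy")])
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}
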