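#' Learner parameters
#'
#' Canonical published RIPPER settings are the defaults: stratified 2/3-1/3
#' grow/prune split, FOIL information gain for growing, worth metric
#' (p - n)/(p + n) for pruning, 64-bit description-length slack, two
#' optimization passes.  `positive_class = "auto"` resolves to the minority
#' class (ties broken lexicographically).
#'
#' @param positive_class Class label to learn rules for, or `"auto"`.
#' @param split_frac Fraction of samples in the grow set, in (0,1).
#' @param mdl_slack Description-length slack in bits before rule addition
#'   stops.
#' @param opt_passes Number of ruleset optimization passes.
#' @param k_folds Fold count for [cross_validate()].
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return A list of class `learner_params`.
#' @export
learner_params <- function(positive_class = "auto", split_frac = 2 / 3,
                           mdl_slack = 64, opt_passes = 2, k_folds = 10,
                           seed = 1L) {
  stopifnot(split_frac > 0, split_frac < 1, k_folds >= 2, mdl_slack >= 0)
  structure(list(positive_class = positive_class, split_frac = split_frac,
                 mdl_slack = mdl_slack, opt_passes = opt_passes,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "learner_params")
}

# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# format a threshold to the 6-significant-digit external representation
fmt_num <- function(x) {
  format(x, digits = 6, trim = TRUE, drop0trailing = TRUE, scientific = FALSE)
}

new_literal <- function(gene, op, threshold) {
  list(gene = gene, op = op, threshold = signif(threshold, 6))
}

literal_text <- function(lit) {
  sprintf("(%s %s %s)", lit$gene, lit$op, fmt_num(lit$threshold))
}

conjunction_text <- function(conj) {
  parts <- vapply(conj, literal_text, "")
  if (length(parts) == 1) parts else paste0("(", paste(parts, collapse = " AND "), ")")
}

#' Construct a rule model
#'
#' A model is a disjunction of conjunctions of threshold literals: a sample
#' is assigned `positive_class` iff at least one conjunction covers it,
#' otherwise `default_class`.
#'
#' @param positive_class,default_class Distinct class labels.
#' @param conjunctions List of conjunctions; each conjunction is a list of
#'   literals `list(gene, op, threshold)` with `op` one of `"<"`, `">="`
#'   (`"<"` strict, `">="` closed).
#' @return An object of class `rule_model`.
#' @export
rule_model <- function(positive_class, default_class, conjunctions = list()) {
  if (identical(tolower(positive_class), tolower(default_class)))
    stop("positive and default class must differ", call. = FALSE)
  structure(list(positive_class = positive_class, default_class = default_class,
                 conjunctions = conjunctions),
            class = "rule_model")
}

#' Genes referenced by a model
#' @param model A `rule_model`.
#' @return Sorted character vector of distinct gene ids.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$conjunctions, function(cj)
    vapply(cj, `[[`, "", "gene")))))
}

#' Render a model in the canonical rule-text grammar
#'
#' `(<gene> < <t>) OR ((<gene> >= <t>) AND (<gene> < <t>)) => <class>`,
#' thresholds printed to 6 significant digits.  [parse_rule()] accepts the
#' same grammar, and thresholds are stored already rounded to 6 significant
#' digits so text and structure round-trip exactly.  A model with no
#' conjunctions renders as `() => <class>`.
#'
#' @param model A `rule_model`.
#' @return A single string.
#' @export
format_rule <- function(model) {
  body <- if (length(model$conjunctions) == 0) "()" else
    paste(vapply(model$conjunctions, conjunction_text, ""), collapse = " OR ")
  paste0(body, " => ", model$positive_class)
}

#' @export
print.rule_model <- function(x, ...) {
  cat(format_rule(x), "\n")
  cat(sprintf("  [default: %s; %d conjunction(s), %d gene(s)]\n",
              x$default_class, length(x$conjunctions), length(model_genes(x))))
  invisible(x)
}

# split "A OR B OR C" at paren depth 0
split_top_or <- function(body) {
  depth <- 0L; start <- 1L; out <- character()
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L && i + 3L <= length(chars) &&
        identical(paste(chars[i + 1:3], collapse = ""), "OR ") && ch == " ") {
      out <- c(out, substr(body, start, i - 1L))
      i <- i + 4L; start <- i
      next
    }
    i <- i + 1L
  }
  c(out, substr(body, start, nchar(body)))
}

#' Parse canonical rule text
#'
#' @param text Rule text produced by [format_rule()].
#' @param default_class Default class of the resulting model (rule text only
#'   carries the positive class).
#' @return A `rule_model`.
#' @export
parse_rule <- function(text, default_class = "OTHER") {
  pos <- regmatches(text, regexpr(" => [^=]+$", text))
  if (length(pos) == 0) stop("malformed rule text: missing '=> class'", call. = FALSE)
  positive <- sub("^ => ", "", pos)
  body <- sub(" => [^=]+$", "", text)
  if (identical(body, "()")) return(rule_model(positive, default_class))
  lit_rx <- "\\(([^()<> ]+) (<|>=) ([-+0-9.eE]+)\\)"
  conjs <- lapply(split_top_or(body), function(chunk) {
    mm <- gregexpr(lit_rx, chunk)[[1]]
    if (mm[1] == -1) stop("malformed conjunction: ", chunk, call. = FALSE)
    lits <- regmatches(chunk, gregexpr(lit_rx, chunk))[[1]]
    lapply(lits, function(s) {
      g <- sub(lit_rx, "\\1", s); op <- sub(lit_rx, "\\2", s)
      t <- as.numeric(sub(lit_rx, "\\3", s))
      list(gene = g, op = op, threshold = t)
    })
  })
  rule_model(positive, default_class, conjs)
}

# coverage ---------------------------------------------------------------

# logical coverage of one conjunction over a values matrix with named cols
conj_cover <- function(conj, values, gene_ids) {
  cov <- rep(TRUE, nrow(values))
  for (lit in conj) {
    j <- match(lit$gene, gene_ids)
    if (is.na(j)) stop("gene '", lit$gene, "' absent from matrix", call. = FALSE)
    v <- values[, j]
    cov <- cov & if (lit$op == "<") v < lit$threshold else v >= lit$threshold
  }
  cov
}

model_cover <- function(model, values, gene_ids) {
  cov <- rep(FALSE, nrow(values))
  for (cj in model$conjunctions) cov <- cov | conj_cover(cj, values, gene_ids)
  cov
}

#' Predict class labels
#'
#' @param object A `rule_model`.
#' @param newdata An `expr_matrix`, or a numeric matrix with gene ids as
#'   column names, or a named numeric vector (one sample).  Every gene
#'   named in the model must be present.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.rule_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) {
    values <- newdata$values; gene_ids <- newdata$gene_ids
  } else if (is.matrix(newdata)) {
    values <- newdata; gene_ids <- colnames(newdata)
  } else {
    values <- matrix(as.numeric(newdata), nrow = 1); gene_ids <- names(newdata)
  }
  miss <- setdiff(model_genes(object), gene_ids)
  if (length(miss) > 0)
    stop("sample lacks value for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ifelse(model_cover(object, values, gene_ids),
         object$positive_class, object$default_class)
}

# thresholds and gain ----------------------------------------------------

#' Candidate split thresholds for one gene
#'
#' Midpoints between consecutive distinct sorted values whose flanking
#' label sets differ (a value's label set is the set of class indicators
#' observed at that exact value).  Only such class-boundary midpoints can
#' change a threshold literal's confusion counts.
#'
#' @param values Numeric vector of finite expression values.
#' @param labels Logical vector (`TRUE` = positive class), same length.
#' @return Ascending numeric vector of candidate thresholds; empty when all
#'   values are equal.
#' @export
candidate_thresholds <- function(values, labels) {
  if (length(values) != length(labels)) stop("length mismatch", call. = FALSE)
  threshold_counts(values, labels)$threshold
}

# candidates plus the (p, n) counts strictly below each threshold
threshold_counts <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]; y <- labels[ord]
  uv <- unique(v)
  if (length(uv) < 2)
    return(data.frame(threshold = numeric(), p_lt = integer(), n_lt = integer()))
  grp <- match(v, uv)
  has_pos <- vapply(split(y, grp), any, TRUE)
  has_neg <- vapply(split(!y, grp), any, TRUE)
  differ <- has_pos[-length(uv)] != has_pos[-1] | has_neg[-length(uv)] != has_neg[-1]
  # values strictly below the boundary after distinct value k
  n_below <- cumsum(tabulate(grp, nbins = length(uv)))
  cum_p <- cumsum(y)
  k <- which(differ)
  data.frame(threshold = (uv[k] + uv[k + 1]) / 2,
             p_lt = cum_p[n_below[k]],
             n_lt = n_below[k] - cum_p[n_below[k]])
}

#' FOIL information gain
#'
#' Gain of refining a rule that covers `p0` positives and `n0` negatives
#' into one covering `p1` positives and `n1` negatives:
#' `p1 * (log2(p1/(p1+n1)) - log2(p0/(p0+n0)))`.  `p1 = 0` yields `-Inf`
#' (the refinement is rejected).
#'
#' @param p0,n0 Positive/negative cover counts before the refinement.
#' @param p1,n1 Cover counts after.
#' @return Numeric gain in bits (vectorized over `p1`, `n1`).
#' @export
foil_gain <- function(p0, n0, p1, n1) {
  g <- p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0)))
  g[p1 == 0] <- -Inf
  g
}

# best literal over all genes on the covered subset; NULL if none usable.
# Tie order: lower gene column index, then '<' over '>=', then smaller
# threshold (strict > comparisons keep the earliest candidate).
best_literal <- function(values, pos, covered, gene_ids) {
  p0 <- sum(pos & covered); n0 <- sum(!pos & covered)
  best <- NULL; best_gain <- -Inf
  for (j in seq_along(gene_ids)) {
    tc <- threshold_counts(values[covered, j], pos[covered])
    if (nrow(tc) == 0) next
    g_lt <- foil_gain(p0, n0, tc$p_lt, tc$n_lt)
    g_ge <- foil_gain(p0, n0, p0 - tc$p_lt, n0 - tc$n_lt)
    gains <- c(g_lt, g_ge)
    ops <- rep(c("<", ">="), each = nrow(tc))
    ths <- c(tc$threshold, tc$threshold)
    i <- which.max(gains)
    if (length(i) == 1 && gains[i] > best_gain) {
      best_gain <- gains[i]
      best <- list(literal = new_literal(gene_ids[j], ops[i], ths[i]),
                   gain = gains[i])
    }
  }
  best
}

#' Grow one conjunction greedily
#'
#' Starting from the empty conjunction, repeatedly appends the literal with
#' maximal FOIL gain over the still-covered grow samples until no negative
#' grow sample is covered or no literal has positive gain.  On an
#' already-pure grow set a single best-gain literal is appended before
#' stopping.  A repeated (gene, op) choice tightens the existing literal in
#' place, so no conjunction carries two literals with the same gene and
#' operator.
#'
#' @param grow_set An `expr_matrix` view with at least one positive sample.
#' @param positive_class Label of the class being covered.
#' @param params A [learner_params()] (unused fields ignored).
#' @return A conjunction (possibly empty list when no literal has positive
#'   gain on an impure grow set).
#' @export
grow_conjunction <- function(grow_set, positive_class, params = learner_params()) {
  pos <- label_key(grow_set$labels) == tolower(positive_class)
  if (!any(pos)) stop("grow set contains no positive sample", call. = FALSE)
  grow_conj_impl(grow_set$values, pos, grow_set$gene_ids)
}

grow_conj_impl <- function(values, pos, gene_ids) {
  conj <- list()
  covered <- rep(TRUE, length(pos))
  repeat {
    if (length(conj) > 0 && !any(!pos & covered)) break
    cand <- best_literal(values, pos, covered, gene_ids)
    if (is.null(cand)) break
    pure_entry <- length(conj) == 0 && !any(!pos & covered)
    if (!pure_entry && cand$gain <= 0) break
    lit <- cand$literal
    same <- which(vapply(conj, function(l)
      l$gene == lit$gene && l$op == lit$op, TRUE))
    if (length(same) == 1) {
      old <- conj[[same]]
      conj[[same]]$threshold <- if (lit$op == "<")
        min(old$threshold, lit$threshold) else max(old$threshold, lit$threshold)
    } else {
      conj[[length(conj) + 1L]] <- lit
    }
    covered <- covered & conj_cover(list(lit), values, gene_ids)
    if (pure_entry) break
  }
  conj
}

#' Prune a conjunction against a prune set
#'
#' Repeatedly deletes the final literal while deletion does not decrease
#' the worth metric v = (p - n)/(p + n) on the prune set (p, n = covered
#' positives/negatives; a conjunction covering nothing scores -1; the empty
#' conjunction covers everything).  Equal worth prefers the shorter
#' conjunction.  May return the empty conjunction, which callers discard.
#'
#' @param conj A non-empty conjunction.
#' @param prune_set An `expr_matrix` view.
#' @param positive_class Label of the covered class.
#' @return The possibly shortened conjunction.
#' @export
prune_conjunction <- function(conj, prune_set, positive_class) {
  pos <- label_key(prune_set$labels) == tolower(positive_class)
  prune_conj_impl(conj, prune_set$values, pos, prune_set$gene_ids)
}

prune_conj_impl <- function(conj, values, pos, gene_ids) {
  if (length(conj) == 0 || length(pos) == 0) return(conj)
  worth <- function(k) {
    cov <- if (k == 0) rep(TRUE, length(pos)) else
      conj_cover(conj[seq_len(k)], values, gene_ids)
    p <- sum(pos & cov); n <- sum(!pos & cov)
    if (p + n == 0) -1 else (p - n) / (p + n)
  }
  k <- length(conj)
  while (k > 0 && worth(k - 1) >= worth(k)) k <- k - 1L
  conj[seq_len(k)]
}

# description length -----------------------------------------------------

log2ch <- function(n, k) lchoose(n, k) / log(2)

# bits to encode one rule of k literals out of n_cond possible conditions;
# halved per the standard redundancy correction.  Only relative values
# matter: the learner compares description lengths, never interprets them.
rule_dl <- function(k, n_cond) {
  if (k == 0) return(0)
  0.5 * (log2(k) + k * log2(max(n_cond, 2)))
}

# bits to encode the exceptions of a ruleset on the training data
data_dl <- function(cover, pos) {
  n <- length(pos)
  ncov <- sum(cover)
  fp <- sum(cover & !pos)
  fn <- sum(!cover & pos)
  log2(n + 1) + log2ch(ncov, fp) + log2ch(n - ncov, fn)
}

total_dl <- function(conjs, values, pos, gene_ids, n_cond) {
  cov <- rep(FALSE, length(pos))
  bits <- 0
  for (cj in conjs) {
    cov <- cov | conj_cover(cj, values, gene_ids)
    bits <- bits + rule_dl(length(cj), n_cond)
  }
  bits + data_dl(cov, pos)
}

# stratified split of indices into grow/prune; all samples go to grow when
# the subset is too small to hold out a prune sample per class
split_grow_prune <- function(pos, frac) {
  idx_p <- which(pos); idx_n <- which(!pos)
  take <- function(idx) {
    if (length(idx) < 2) return(list(grow = idx, prune = integer()))
    sh <- idx[sample.int(length(idx))]
    ng <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    list(grow = sh[seq_len(ng)], prune = sh[-seq_len(ng)])
  }
  sp <- take(idx_p); sn <- take(idx_n)
  list(grow = sort(c(sp$grow, sn$grow)), prune = sort(c(sp$prune, sn$prune)))
}

resolve_positive_class <- function(labels, positive_class) {
  key <- label_key(labels)
  shown <- labels[!duplicated(key)]
  names(shown) <- key[!duplicated(key)]
  if (length(shown) < 2) stop("single-class input: '", labels[1], "'", call. = FALSE)
  if (identical(positive_class, "auto")) {
    cnt <- table(key)
    k <- names(cnt)[order(cnt, names(cnt))][1]  # minority; ties lexicographic
    return(unname(shown[k]))
  }
  k <- tolower(positive_class)
  if (!k %in% names(shown))
    stop("positive class '", positive_class, "' absent from labels", call. = FALSE)
  unname(shown[k])
}

default_class_for <- function(labels, positive_class) {
  key <- label_key(labels)
  shown <- labels[!duplicated(key)]
  names(shown) <- key[!duplicated(key)]
  others <- shown[names(shown) != tolower(positive_class)]
  if (length(others) == 0) stop("no default class available", call. = FALSE)
  cnt <- table(key)
  cnt <- cnt[names(others)]
  unname(others[order(-as.integer(cnt), names(others))][1])  # majority other
}

#' Learn a rule model (RIPPER-style)
#'
#' IREP* sequential covering: stratified grow/prune split, FOIL-gain
#' growing, worth-metric pruning, MDL-gated rule addition (stop when the
#' ruleset description length exceeds the best seen plus `mdl_slack`
#' bits), removal of covered samples, then `opt_passes` optimization
#' passes in which each conjunction is revised and replaced and the
#' MDL-best variant kept, and a final sweep deleting conjunctions whose
#' removal shortens the description.  Deterministic given
#' `params$seed`.
#'
#' @param train An `expr_matrix` with >= 2 classes.
#' @param params A [learner_params()].
#' @return A `rule_model`; empty (no conjunctions) when no rule survives
#'   pruning and the MDL gate, in which case it always predicts the
#'   default class.
#' @export
learn_model <- function(train, params = learner_params()) {
  positive <- resolve_positive_class(train$labels, params$positive_class)
  default <- default_class_for(train$labels, positive)
  values <- train$values; gene_ids <- train$gene_ids
  pos <- label_key(train$labels) == tolower(positive)
  with_seed(params$seed, {
    n_cond <- 0L
    for (j in seq_along(gene_ids))
      n_cond <- n_cond + 2L * nrow(threshold_counts(values[, j], pos))
    conjs <- list()
    remaining <- rep(TRUE, length(pos))
    dl_best <- total_dl(conjs, values, pos, gene_ids, n_cond)
    while (any(pos & remaining) && length(conjs) < length(pos)) {
      sub <- which(remaining)
      sp <- split_grow_prune(pos[sub], params$split_frac)
      gi <- sub[sp$grow]; pi <- sub[sp$prune]
      if (!any(pos[gi])) break
      conj <- grow_conj_impl(values[gi, , drop = FALSE], pos[gi], gene_ids)
      if (length(conj) == 0) break
      if (length(pi) > 0)
        conj <- prune_conj_impl(conj, values[pi, , drop = FALSE], pos[pi], gene_ids)
      if (length(conj) == 0) break
      cand <- c(conjs, list(conj))
      dl <- total_dl(cand, values, pos, gene_ids, n_cond)
      if (dl > dl_best + params$mdl_slack) break
      conjs <- cand
      dl_best <- min(dl_best, dl)
      cov <- conj_cover(conj, values, gene_ids)
      if (!any(cov & remaining)) break
      remaining <- remaining & !cov
    }
    if (params$opt_passes > 0 && length(conjs) > 0) {
      for (pass in seq_len(params$opt_passes)) {
        conjs <- optimize_pass(conjs, values, pos, gene_ids, n_cond, params)
        if (length(conjs) == 0) break
      }
    }
    # final sweep: drop conjunctions whose removal does not lengthen the DL,
    # and any conjunction covering no positive training sample
    if (length(conjs) > 0) {
      keep_pos <- vapply(conjs, function(cj)
        any(conj_cover(cj, values, gene_ids) & pos), TRUE)
      conjs <- conjs[keep_pos]
      i <- length(conjs)
      while (i >= 1 && length(conjs) > 0) {
        dl_with <- total_dl(conjs, values, pos, gene_ids, n_cond)
        dl_without <- total_dl(conjs[-i], values, pos, gene_ids, n_cond)
        if (dl_without <= dl_with) conjs <- conjs[-i]
        i <- i - 1L
      }
    }
    # single-literal floor: the returned model is never worse, on training
    # F-measure, than the best single threshold literal.  On tiny matrices
    # the grow/prune split can starve or tie away a good literal; this
    # selection step restores the guarantee without touching the ruleset in
    # the usual case where sequential covering wins.
    train_f <- function(cs) {
      cov <- rep(FALSE, length(pos))
      for (cj in cs) cov <- cov | conj_cover(cj, values, gene_ids)
      met <- metrics_from_counts(sum(cov & pos), sum(cov & !pos),
                                 sum(!cov & pos), sum(!cov & !pos))
      met$f_measure
    }
    floor_lit <- best_single_literal(values, pos, gene_ids)
    if (!is.null(floor_lit) &&
        train_f(list(list(floor_lit))) > train_f(conjs)) {
      conjs <- list(list(floor_lit))
    }
    rule_model(positive, default, conjs)
  })
}

# one optimization pass: for each conjunction build a replacement (grown
# from scratch) and a revision (grown from the current literals) on the
# samples not covered by the other conjunctions, and keep the variant with
# the smallest total description length (dropping the conjunction is also a
# variant, via an empty result).
optimize_pass <- function(conjs, values, pos, gene_ids, n_cond, params) {
  for (i in seq_along(conjs)) {
    if (i > length(conjs)) break
    others <- conjs[-i]
    cov_others <- rep(FALSE, length(pos))
    for (cj in others) cov_others <- cov_others | conj_cover(cj, values, gene_ids)
    avail <- which(!cov_others)
    if (length(avail) < 2 || !any(pos[avail])) next
    sp <- split_grow_prune(pos[avail], params$split_frac)
    gi <- avail[sp$grow]; pi <- avail[sp$prune]
    if (!any(pos[gi])) next
    variants <- list(conjs[[i]])
    repl <- grow_conj_impl(values[gi, , drop = FALSE], pos[gi], gene_ids)
    if (length(pi) > 0 && length(repl) > 0)
      repl <- prune_conj_impl(repl, values[pi, , drop = FALSE], pos[pi], gene_ids)
    variants <- c(variants, list(repl))
    revn <- grow_revision(conjs[[i]], values[gi, , drop = FALSE], pos[gi], gene_ids)
    if (length(pi) > 0 && length(revn) > 0)
      revn <- prune_conj_impl(revn, values[pi, , drop = FALSE], pos[pi], gene_ids)
    variants <- c(variants, list(revn))
    dls <- vapply(variants, function(v) {
      cand <- conjs
      if (length(v) == 0) cand <- cand[-i] else cand[[i]] <- v
      total_dl(cand, values, pos, gene_ids, n_cond)
    }, 0)
    best <- which.min(dls)
    if (best > 1) {
      v <- variants[[best]]
      if (length(v) == 0) {
        conjs <- conjs[-i]
      } else {
        conjs[[i]] <- v
      }
    }
  }
  conjs
}

# extend an existing conjunction with further greedy literals
grow_revision <- function(conj, values, pos, gene_ids) {
  covered <- conj_cover(conj, values, gene_ids)
  if (!any(covered & pos)) return(list())
  extra <- grow_from(conj, covered, values, pos, gene_ids)
  extra
}

grow_from <- function(conj, covered, values, pos, gene_ids) {
  repeat {
    if (!any(!pos & covered)) break
    cand <- best_literal(values, pos, covered, gene_ids)
    if (is.null(cand) || cand$gain <= 0) break
    lit <- cand$literal
    same <- which(vapply(conj, function(l)
      l$gene == lit$gene && l$op == lit$op, TRUE))
    if (length(same) == 1) {
      old <- conj[[same]]
      newt <- if (lit$op == "<") min(old$threshold, lit$threshold) else
        max(old$threshold, lit$threshold)
      if (newt == old$threshold) break  # no tightening possible
      conj[[same]]$threshold <- newt
    } else {
      conj[[length(conj) + 1L]] <- lit
    }
    covered <- covered & conj_cover(list(lit), values, gene_ids)
  }
  conj
}

# best single literal by training F-measure over all genes and candidate
# thresholds; ties resolved like best_literal (gene index, '<', threshold)
best_single_literal <- function(values, pos, gene_ids) {
  P <- sum(pos)
  if (P == 0) return(NULL)
  best <- NULL; best_f <- 0
  f_of <- function(tp, fp) {
    prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    rec <- tp / P
    ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  }
  for (j in seq_along(gene_ids)) {
    tc <- threshold_counts(values[, j], pos)
    if (nrow(tc) == 0) next
    fs <- c(f_of(tc$p_lt, tc$n_lt), f_of(P - tc$p_lt, sum(!pos) - tc$n_lt))
    ops <- rep(c("<", ">="), each = nrow(tc))
    ths <- c(tc$threshold, tc$threshold)
    i <- which.max(fs)
    if (fs[i] > best_f) {
      best_f <- fs[i]
      best <- new_literal(gene_ids[j], ops[i], ths[i])
    }
  }
  best
}

# metrics ----------------------------------------------------------------

metrics_from_counts <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       tn = as.integer(tn), precision = precision, recall = recall,
       f_measure = f, accuracy = accuracy)
}

#' Evaluate a model on a labeled matrix
#'
#' Confusion counts take the model's positive class as the positive label
#' (case-insensitive match); precision, recall, F-measure and accuracy
#' follow (empty denominators score 0).
#'
#' @param model A `rule_model` whose genes all occur in `m`.
#' @param m An `expr_matrix`.
#' @return A list: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f_measure`, `accuracy`.
#' @export
evaluate_model <- function(model, m) {
  cov <- model_cover(model, m$values, m$gene_ids)
  truth <- label_key(m$labels) == tolower(model$positive_class)
  metrics_from_counts(sum(cov & truth), sum(cov & !truth),
                      sum(!cov & truth), sum(!cov & !truth))
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class under `params$seed`; one model is learned
#' per fold (per-fold seeds drawn from the master seed) and confusion
#' counts are pooled over the held-out folds before deriving metrics.
#' Deterministic given the seed.
#'
#' @param m An `expr_matrix`; every class must have at least
#'   `params$k_folds` samples.
#' @param params A [learner_params()].
#' @return Pooled metrics as for [evaluate_model()].
#' @export
cross_validate <- function(m, params = learner_params()) {
  k <- params$k_folds
  positive <- resolve_positive_class(m$labels, params$positive_class)
  key <- label_key(m$labels)
  if (any(table(key) < k))
    stop("every class needs at least k = ", k, " samples", call. = FALSE)
  with_seed(params$seed, {
    fold <- integer(length(key))
    for (cl in unique(key)) {
      idx <- which(key == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
    fold_seeds <- sample.int(.Machine$integer.max - 1L, k)
    tp <- fp <- fn <- tn <- 0L
    for (f in seq_len(k)) {
      train <- subset_samples(m, fold != f)
      test <- subset_samples(m, fold == f)
      p2 <- params; p2$seed <- fold_seeds[f]; p2$positive_class <- positive
      mod <- learn_model(train, p2)
      pred <- predict(mod, test)
      truth <- label_key(test$labels) == tolower(positive)
      hit <- label_key(pred) == tolower(positive)
      tp <- tp + sum(hit & truth); fp <- fp + sum(hit & !truth)
      fn <- fn + sum(!hit & truth); tn <- tn + sum(!hit & !truth)
    }
    metrics_from_counts(tp, fp, fn, tn)
  })
}
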