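#' Specification for a synthetic case-control FPKM matrix
#'
#' The generator emulates desk-scale FPKM matrices: background genes are
#' i.i.d. log-normal and class-independent; each informative gene's tumoral
#' values are shifted on the log scale by `shift` background standard
#' deviations (direction `"up"` or `"down"`), which preserves
#' non-negativity and the heavy right tail of FPKM data.  Redundancy is
#' planted as independent shifted genes, the simplest construction under
#' which alternative, near-equivalent single-gene models exist.
#'
#' @param n_samples Total number of samples.
#' @param balance Fraction of tumoral samples, in (0,1); the tumoral count
#'   is `round(n_samples * balance)`.
#' @param n_genes Total number of gene columns.
#' @param groups List of informative groups, each
#'   `list(size =, shift =, direction = "up"|"down")`; `shift` is in units
#'   of the background log-sigma; group sizes must sum to at most
#'   `n_genes`.
#' @param log_mean,log_sigma Background log-normal parameters (defaults 2
#'   and 1).
#' @param seed Integer seed; the same spec and seed yield identical output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, balance = 0.5, n_genes = 30,
                           groups = list(), log_mean = 2, log_sigma = 1,
                           seed = 1L) {
  sizes <- vapply(groups, function(g) as.integer(g$size), 0L)
  if (sum(sizes) > n_genes)
    stop("informative group sizes exceed n_genes", call. = FALSE)
  if (any(vapply(groups, function(g) g$shift < 0, TRUE)))
    stop("shift must be >= 0", call. = FALSE)
  if (balance <= 0 || balance >= 1) stop("balance must be in (0,1)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), balance = balance,
                 n_genes = as.integer(n_genes), groups = groups,
                 log_mean = log_mean, log_sigma = log_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled expression matrix with ground truth
#'
#' Labels are `"Tumoral"` / `"Normal"`; gene columns are randomly permuted
#' so informative genes do not cluster at fixed positions.  The ground
#' truth records, per informative gene, its group, direction and achieved
#' class-conditional separation (absolute difference of class means of
#' log1p values divided by the pooled log1p standard deviation).
#'
#' @param spec A [synthetic_spec()].
#' @return `list(matrix = expr_matrix, truth = data.frame(gene, group,
#'   direction, separation))`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; g <- spec$n_genes
    n_tum <- round(n * spec$balance)
    if (n_tum < 1 || n_tum >= n)
      stop("balance leaves a class empty", call. = FALSE)
    labels <- c(rep("Tumoral", n_tum), rep("Normal", n - n_tum))
    tum <- labels == "Tumoral"
    lv <- matrix(stats::rnorm(n * g, spec$log_mean, spec$log_sigma), n, g)
    info <- data.frame(col = integer(), group = integer(),
                       direction = character(), stringsAsFactors = FALSE)
    nxt <- 1L
    for (gi in seq_along(spec$groups)) {
      grp <- spec$groups[[gi]]
      dir <- match.arg(grp$direction, c("up", "down"))
      for (k in seq_len(grp$size)) {
        delta <- grp$shift * spec$log_sigma * if (dir == "up") 1 else -1
        lv[tum, nxt] <- lv[tum, nxt] + delta
        info <- rbind(info, data.frame(col = nxt, group = gi, direction = dir,
                                       stringsAsFactors = FALSE))
        nxt <- nxt + 1L
      }
    }
    values <- exp(lv)
    perm <- sample.int(g)
    values <- values[, perm, drop = FALSE]
    gene_ids <- sprintf("GENE%04d", seq_len(g))
    sample_ids <- sprintf("SAMPLE%04d", seq_len(n))
    m <- expression_matrix(values, sample_ids, gene_ids, labels)
    truth <- if (nrow(info) == 0) {
      data.frame(gene = character(), group = integer(), direction = character(),
                 separation = double(), stringsAsFactors = FALSE)
    } else {
      new_col <- match(info$col, perm)
      sep <- vapply(new_col, function(j) {
        x <- log1p(values[, j])
        s <- stats::sd(x)
        if (s == 0) 0 else abs(mean(x[tum]) - mean(x[!tum])) / s
      }, 0)
      data.frame(gene = gene_ids[new_col], group = info$group,
                 direction = info$direction, separation = sep,
                 stringsAsFactors = FALSE)
    }
    list(matrix = m, truth = truth[order(truth$gene), , drop = FALSE])
  })
}

# canonical fixture specs used across the test suite and acceptance script
fixture_spec <- function(name, seed = 20240101L) {
  switch(name,
         chol_shape = synthetic_spec(45, balance = 0.8, n_genes = 30,
                                     groups = list(list(size = 1, shift = 6,
                                                        direction = "up")),
                                     seed = seed),
         redundant6 = synthetic_spec(60, balance = 0.5, n_genes = 40,
                                     groups = lapply(1:6, function(i)
                                       list(size = 1, shift = 6,
                                            direction = if (i %% 2) "up" else "down")),
                                     seed = seed),
         null60 = synthetic_spec(60, balance = 0.5, n_genes = 30,
                                 groups = list(), seed = seed),
         stop("unknown fixture '", name, "'", call. = FALSE))
}

# the 3x3 worked-example matrix (sample ids and classes as printed in the
# reference layout; expression values are illustrative FPKMs)
table1_toy_matrix <- function() {
  expression_matrix(
    values = rbind(c(9.787, 2338, 0.141),
                   c(0.0323, 1.4725, 0.62107),
                   c(0.0622, 38.7757, 0.4818)),
    sample_ids = c("TCGA-4G..", "TCGA-W5..", "TCGA-ZH.."),
    gene_ids = c("ENSG00000130309.9", "ENSG00000101189.6", "ENSG00000260597.1"),
    labels = c("Tumoral", "Normal", "Tumoral"))
}

#' Write a named canonical fixture to disk
#'
#' Fixtures: `table1_toy` (the 3-sample, 3-gene worked-example layout),
#' `chol_shape` (45 samples, 36 tumoral / 9 normal, one planted gene),
#' `redundant6` (60 samples, 6 independently separating planted genes),
#' `null60` (60 samples, no informative gene).  Same name and seed give
#' byte-identical files.
#'
#' @param name One of `"table1_toy"`, `"chol_shape"`, `"redundant6"`,
#'   `"null60"`.
#' @param dir Output directory.
#' @param seed Generator seed (ignored for `table1_toy`).
#' @return Paths written: `$data` (CSV) and, for generated fixtures,
#'   `$truth` (JSON ground truth).
#' @export
make_fixture <- function(name, dir = ".", seed = 20240101L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_path <- file.path(dir, paste0(name, ".csv"))
  if (name == "table1_toy") {
    write_matrix(table1_toy_matrix(), data_path)
    return(invisible(list(data = data_path)))
  }
  ds <- generate_dataset(fixture_spec(name, seed))
  write_matrix(ds$matrix, data_path)
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  writeLines(jsonlite::toJSON(ds$truth, dataframe = "columns",
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             truth_path)
  invisible(list(data = data_path, truth = truth_path))
}
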