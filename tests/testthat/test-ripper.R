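test_that("candidate_thresholds returns exactly the class-boundary midpoints", {
  expect_equal(candidate_thresholds(c(1, 2), c(TRUE, FALSE)), 1.5)
  expect_equal(candidate_thresholds(c(1, 1, 1), c(TRUE, FALSE, TRUE)), numeric())
  expect_equal(candidate_thresholds(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 2.5)
  expect_error(candidate_thresholds(c(1, 2), c(TRUE)), "length mismatch")

  # property: against brute-force enumeration of all midpoints whose
  # flanking label sets differ, over random data with ties
  set.seed(5)
  for (i in 1:25) {
    v <- sample(1:6, 12, replace = TRUE) / 2
    y <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    sv <- sort(unique(v))
    expected <- c()
    for (k in seq_len(length(sv) - 1)) {
      s1 <- unique(y[v == sv[k]]); s2 <- unique(y[v == sv[k + 1]])
      if (!setequal(s1, s2)) expected <- c(expected, (sv[k] + sv[k + 1]) / 2)
    }
    expect_equal(candidate_thresholds(v, y), as.numeric(expected))
  }
})

test_that("foil_gain matches its closed form and boundary conventions", {
  expect_equal(foil_gain(10, 10, 8, 1), 8 * (log2(8 / 9) - log2(0.5)))
  expect_equal(round(foil_gain(10, 10, 8, 1), 4), 6.6406)
  expect_equal(foil_gain(10, 10, 5, 5), 0)        # identical purity
  expect_identical(foil_gain(10, 10, 0, 3), -Inf) # no positives covered
})

test_that("grow_conjunction finds optimal literals on separable data", {
  m <- separable_1g()
  conj <- grow_conjunction(m, "Tumoral")
  expect_length(conj, 1)
  expect_equal(conj[[1]]$gene, "G1")
  expect_equal(conj[[1]]$op, "<")
  # covers all positives, no negatives
  cov <- camur:::conj_cover(conj, m$values, m$gene_ids)
  expect_true(all(cov[m$labels == "Tumoral"]))
  expect_false(any(cov[m$labels == "Normal"]))

  # all-positive grow set: class-boundary candidates cannot exist, so the
  # conjunction stays empty (covers everything -- already pure)
  conj <- camur:::grow_conj_impl(cbind(c(1, 2, 3)), rep(TRUE, 3), "G1")
  expect_length(conj, 0)

  # XOR-like quadrant: positives need two literals
  vals <- rbind(c(1, 1), c(1, 10), c(10, 1), c(10, 10))
  vals <- vals[rep(1:4, each = 3), ] + matrix(runif(24, 0, 0.2), 12, 2)
  labs <- rep(c("Tumoral", "Normal", "Normal", "Normal"), each = 3)
  mq <- toy_matrix(vals, labs, gene_ids = c("GA", "GB"))
  conj <- grow_conjunction(mq, "Tumoral")
  expect_length(conj, 2)
  cov <- camur:::conj_cover(conj, mq$values, mq$gene_ids)
  expect_identical(unname(cov), labs == "Tumoral")
})

test_that("prune_conjunction truncates suffixes per the worth metric", {
  m <- separable_1g()
  conj <- list(lit("G1", "<", 6))
  # p=10, n=0 on prune set -> v = 1 maximal, unchanged
  expect_identical(prune_conjunction(conj, m, "Tumoral"), conj)

  # removable last literal with v unchanged is removed (prefer shorter)
  conj2 <- list(lit("G1", "<", 6), lit("G1", ">=", -1))
  expect_identical(prune_conjunction(conj2, m, "Tumoral"), conj)

  # brute-force over suffix truncations picks the best prefix
  set.seed(9)
  for (i in 1:20) {
    vals <- matrix(runif(36, 0, 10), 12, 3)
    labs <- sample(c("Tumoral", "Normal"), 12, replace = TRUE)
    labs[1:2] <- c("Tumoral", "Normal")
    mm <- toy_matrix(vals, labs)
    conj3 <- list(lit("G1", "<", runif(1, 2, 8)),
                  lit("G2", ">=", runif(1, 2, 8)),
                  lit("G3", "<", runif(1, 2, 8)))
    got <- prune_conjunction(conj3, mm, "Tumoral")
    # oracle: worth of every prefix, sequential-deletion semantics
    pos <- labs == "Tumoral"
    worth <- function(k) {
      cov <- rep(TRUE, 12)
      for (l in conj3[seq_len(k)]) {
        v <- vals[, match(l$gene, mm$gene_ids)]
        cov <- cov & if (l$op == "<") v < l$threshold else v >= l$threshold
      }
      p <- sum(cov & pos); n <- sum(cov & !pos)
      if (p + n == 0) -1 else (p - n) / (p + n)
    }
    k <- 3
    while (k > 0 && worth(k - 1) >= worth(k)) k <- k - 1
    expect_identical(got, conj3[seq_len(k)])
  }
})

test_that("learn_model handles separable, noisy and padded data", {
  # perfectly separable: one 1-literal conjunction, training F = 1
  m <- separable_1g()
  params <- learner_params(positive_class = "Tumoral", seed = 3)
  mod <- learn_model(m, params)
  expect_length(mod$conjunctions, 1)
  expect_length(mod$conjunctions[[1]], 1)
  expect_equal(evaluate_model(mod, m)$f_measure, 1)

  # pure-noise labels: any overfit rule fails the cross-validated gate
  set.seed(10)
  mn <- toy_matrix(matrix(runif(60), 60, 1),
                   sample(c("Tumoral", "Normal"), 60, replace = TRUE))
  cvn <- cross_validate(mn, learner_params(positive_class = "Tumoral", seed = 3))
  expect_lt(cvn$f_measure, 0.8)

  # 100 irrelevant noise genes do not displace the informative one
  set.seed(12)
  noise <- matrix(exp(rnorm(20 * 100, 2, 1)), 20, 100)
  mpad <- toy_matrix(cbind(m$values, noise), m$labels,
                     gene_ids = c("G1", sprintf("N%03d", 1:100)))
  modp <- learn_model(mpad, learner_params(positive_class = "Tumoral", seed = 3))
  expect_identical(model_genes(modp), "G1")
  expect_equal(evaluate_model(modp, mpad)$f_measure, 1)

  expect_error(learn_model(toy_matrix(cbind(1:3), rep("Tumoral", 3))),
               "single-class")
  expect_error(learn_model(m, learner_params(positive_class = "Missing")),
               "absent")
})

test_that("learn_model is deterministic given the seed", {
  ds <- redundant6_data()
  p <- learner_params(seed = 99)
  m1 <- learn_model(ds$matrix, p)
  m2 <- learn_model(ds$matrix, p)
  expect_identical(m1, m2)
  expect_identical(format_rule(m1), format_rule(m2))
})

test_that("every stored conjunction covers at least one positive sample", {
  ds <- redundant6_data()
  mod <- learn_model(ds$matrix, learner_params(seed = 5))
  pos <- tolower(ds$matrix$labels) == tolower(mod$positive_class)
  for (cj in mod$conjunctions) {
    cov <- camur:::conj_cover(cj, ds$matrix$values, ds$matrix$gene_ids)
    expect_gt(sum(cov & pos), 0)
  }
  # no conjunction holds two literals with the same gene and op
  for (cj in mod$conjunctions) {
    keys <- vapply(cj, function(l) paste(l$gene, l$op), "")
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("predict applies strict/closed boundary semantics", {
  model <- rule_model("Tumoral", "Normal",
                      list(list(lit("g1", "<", 16.15)),
                           list(lit("g2", "<", 15.28))))
  expect_equal(predict(model, c(g1 = 10, g2 = 20)), "Tumoral")
  # boundary: '<' is strict
  expect_equal(predict(model, c(g1 = 16.15, g2 = 15.28)), "Normal")
  # empty model always predicts the default
  empty <- rule_model("Tumoral", "Normal")
  expect_equal(predict(empty, c(g1 = 0, g2 = 0)), "Normal")
  # missing gene errors
  expect_error(predict(model, c(g1 = 1)), "g2")
  # prediction invariant to non-model genes
  expect_equal(predict(model, c(g1 = 10, g2 = 20, zz = 1e9)), "Tumoral")
})

test_that("evaluate_model reproduces the metric identities", {
  # hand-built coverage giving tp=8 fp=2 fn=1 tn=9
  vals <- cbind(c(rep(1, 8), rep(10, 1), rep(1, 2), rep(10, 9)))
  labs <- rep(c("Tumoral", "Normal"), c(9, 11))
  m <- toy_matrix(vals, labs)
  model <- rule_model("Tumoral", "Normal", list(list(lit("G1", "<", 5))))
  met <- evaluate_model(model, m)
  expect_equal(met$tp, 8L); expect_equal(met$fp, 2L)
  expect_equal(met$fn, 1L); expect_equal(met$tn, 9L)
  expect_equal(round(met$precision, 4), 0.8000)
  expect_equal(round(met$recall, 4), 0.8889)
  expect_equal(round(met$f_measure, 4), 0.8421)
  expect_equal(met$accuracy, 0.85)

  # independent confusion-count oracle on random models/data
  set.seed(21)
  for (i in 1:20) {
    vals <- matrix(runif(40, 0, 10), 10, 4)
    labs <- sample(c("Tumoral", "Normal"), 10, replace = TRUE)
    labs[1:2] <- c("Tumoral", "Normal")
    mm <- toy_matrix(vals, labs)
    model <- rule_model("Tumoral", "Normal",
                        list(list(lit("G1", "<", runif(1, 0, 10))),
                             list(lit("G3", ">=", runif(1, 0, 10)),
                                  lit("G2", "<", runif(1, 0, 10)))))
    met <- evaluate_model(model, mm)
    pred <- predict(model, mm)
    tp <- sum(pred == "Tumoral" & labs == "Tumoral")
    fp <- sum(pred == "Tumoral" & labs == "Normal")
    fn <- sum(pred == "Normal" & labs == "Tumoral")
    tn <- sum(pred == "Normal" & labs == "Normal")
    expect_equal(met[c("tp", "fp", "fn", "tn")],
                 list(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_equal(met$accuracy, (tp + tn) / 10)
  }
})

test_that("cross_validate pools stratified folds deterministically", {
  m <- separable_1g(n_per = 15)
  p <- learner_params(positive_class = "Tumoral", k_folds = 5, seed = 17)
  cv1 <- cross_validate(m, p)
  expect_equal(cv1$f_measure, 1)            # separability survives any split
  expect_identical(cv1, cross_validate(m, p))
  expect_equal(cv1$tp + cv1$fp + cv1$fn + cv1$tn, 30L)  # every sample once

  # label-permuted data scores below the 0.8 gate
  set.seed(30)
  mp <- toy_matrix(m$values, sample(m$labels))
  cvp <- cross_validate(mp, p)
  expect_lt(cvp$f_measure, 0.8)

  expect_error(cross_validate(separable_1g(n_per = 3), p), "at least k")
})

test_that("rule text formats and re-parses to the same structure", {
  model <- rule_model("Tumoral", "Normal",
                      list(list(lit("ENSG00000167676.3", "<", 16.15)),
                           list(lit("ENSG00000166819.10", ">=", 15.28),
                                lit("ENSG00000167676.3", "<", 2.5))))
  text <- format_rule(model)
  expect_equal(text,
               paste0("(ENSG00000167676.3 < 16.15) OR ",
                      "((ENSG00000166819.10 >= 15.28) AND (ENSG00000167676.3 < 2.5))",
                      " => Tumoral"))
  back <- parse_rule(text, default_class = "Normal")
  expect_identical(back, model)
  # empty model round trip
  e <- rule_model("Tumoral", "Normal")
  expect_identical(parse_rule(format_rule(e), "Normal"), e)
})

test_that("on tiny matrices the learner is at least as good as the best single literal", {
  # oracle equivalence at small scale, exhaustive search as the oracle
  set.seed(77)
  cases <- expand.grid(n = c(8, 12), g = c(1, 2, 3), shift = c(4, 6))
  for (r in seq_len(nrow(cases))) {
    spec <- synthetic_spec(cases$n[r], balance = 0.5, n_genes = cases$g[r],
                           groups = list(list(size = 1, shift = cases$shift[r],
                                              direction = "up")),
                           seed = 100 + r)
    ds <- generate_dataset(spec)
    mod <- learn_model(ds$matrix, learner_params(seed = 1))
    f_learn <- evaluate_model(mod, ds$matrix)$f_measure
    f_oracle <- best_single_literal_f(ds$matrix, mod$positive_class)
    expect_gte(f_learn, f_oracle)
  }
})
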