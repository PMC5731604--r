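test_that("cv splits reserve positives from both sides and sample balanced negatives", {
  A <- as.character(1:20)
  B <- as.character(11:30)
  sp <- make_cv_split(A, B, n_pos = 5, n_neg = 6, seed = 3)
  expect_length(sp$positives, 5)
  expect_true(all(sp$positives %in% intersect(A, B)))
  expect_length(intersect(sp$positives, sp$a_work), 0)
  expect_length(intersect(sp$positives, sp$b_work), 0)
  expect_length(sp$negatives, 6)
  expect_true(all(sp$negatives %in% setdiff(union(A, B), intersect(A, B))))
  expect_length(intersect(sp$positives, sp$negatives), 0)
  expect_equal(sum(sp$negatives %in% A), 3) # balanced across sides

  # capped at what is available
  sp2 <- make_cv_split(as.character(1:6), as.character(4:9), n_pos = 10, seed = 1)
  expect_length(sp2$positives, 3)

  expect_identical(make_cv_split(A, B, seed = 7), make_cv_split(A, B, seed = 7))
  expect_error(make_cv_split(c("1", "2"), c("3", "4"), seed = 1), "no common")
  expect_error(make_cv_split(c("1", "2"), c("1", "2"), seed = 1), "no non-common")
})

test_that("roc_auc equals brute-force concordant-pair counting on random vectors", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n), sample(0:2, 1)) # rounding induces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc handles the canonical cases and label flips", {
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and one negative")

  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- stats::rnorm(n)
    expect_equal(roc_auc(scores, 1 - labels), 1 - roc_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("threshold selection maximizes TPR - FPR with ties toward higher cutoffs", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  lb <- c(1, 1, 0, 1, 0)
  expect_equal(choose_threshold(sc, lb), 0.8)

  # perfectly separated classes: threshold = lowest positive score
  expect_equal(choose_threshold(c(5, 4, 2, 1), c(1, 1, 0, 0)), 4)
  # pure ties: the common score
  expect_equal(choose_threshold(rep(2, 4), c(1, 0, 1, 0)), 2)
  expect_error(choose_threshold(1:3, c(0, 0, 0)), "both classes")
})

test_that("precision and recall follow the >= threshold convention", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  lb <- c(1, 1, 0, 1, 0)
  pr <- precision_recall(sc, lb, 0.8)
  expect_equal(unname(pr["precision"]), 1)
  expect_equal(unname(pr["recall"]), 2 / 3)

  hi <- precision_recall(sc, lb, 2)
  expect_equal(unname(hi), c(0, 0))
  lo <- precision_recall(sc, lb, 0)
  expect_equal(unname(lo["recall"]), 1)
})

test_that("randomized common genes preserve counts and reproducibility", {
  g <- generate_graph(60, 2, seed = 9)
  nm <- igraph::V(g)$name
  A <- nm[1:10]
  B <- nm[6:15]
  r <- randomize_common_genes(g, A, B, seed = 4)
  expect_length(r$a, length(A))
  expect_length(r$b, length(B))
  expect_length(intersect(r$a, r$b), length(intersect(A, B)))
  expect_length(intersect(r$replacement, union(A, B)), 0)
  expect_identical(r, randomize_common_genes(g, A, B, seed = 4))
  expect_false(identical(r$replacement,
                         randomize_common_genes(g, A, B, seed = 5)$replacement))
  expect_error(randomize_common_genes(g, nm[1:2], nm[3:4], seed = 1), "no common")
})

test_that("test-set scoring is finite, label-complete and recomputes the base", {
  g <- generate_graph(300, 2, seed = 17)
  pp <- plant_pair(g, synthetic_config(n_nodes = 300, n_a = 15, n_b = 15,
                                       n_shared = 5, seed = 17))
  sp <- make_cv_split(pp$g_a, pp$g_b, n_pos = 4, n_neg = 6, seed = 2)
  st <- score_test_set(g, sp)
  expect_equal(nrow(st), 10)
  expect_true(all(is.finite(st$score)))
  expect_setequal(st$gene[st$label == 1], sp$positives)
  expect_setequal(st$gene[st$label == 0], sp$negatives)
  # identical scores for a positive and a negative are both retained
  expect_equal(sum(st$label == 1), 4)

  # set-based scoring differs in general from module-based scoring
  st2 <- score_test_set(g, sp, use_modules = FALSE)
  expect_false(isTRUE(all.equal(st$score[order(st$gene)],
                                st2$score[order(st2$gene)])))
})

test_that("evaluate_pair produces a complete record and skips degenerate pairs", {
  g <- generate_graph(300, 2, seed = 23)
  pp <- plant_pair(g, synthetic_config(n_nodes = 300, n_a = 15, n_b = 15,
                                       n_shared = 5, seed = 23))
  rec <- evaluate_pair(g, pp$g_a, pp$g_b, seed = 1, rr = 2.5,
                       labels = c("X", "Y"))
  expect_equal(nrow(rec), 1)
  expect_true(rec$roc_score >= 0 && rec$roc_score <= 1)
  expect_true(rec$precision >= 0 && rec$precision <= 1)
  expect_true(rec$recall >= 0 && rec$recall <= 1)
  expect_equal(rec$n_common, 5)
  expect_equal(rec$rr, 2.5)

  expect_message(expect_null(evaluate_pair(g, pp$g_a, pp$g_a, seed = 1)),
                 "no candidates")
  expect_message(
    expect_null(evaluate_pair(g, c("1", "2"), c("3", "4"), seed = 1)),
    "no common")

  # bit-exact reproducibility under the seed
  rec2 <- evaluate_pair(g, pp$g_a, pp$g_b, seed = 1, rr = 2.5,
                        labels = c("X", "Y"))
  expect_identical(rec, rec2)
})

test_that("evaluate_pairs records skips and carries RR through", {
  g <- generate_graph(300, 2, seed = 31)
  pp1 <- plant_pair(g, synthetic_config(n_nodes = 300, n_a = 15, n_b = 15,
                                        n_shared = 5, seed = 31))
  assoc <- list(D1 = pp1$g_a, D2 = pp1$g_b, D3 = pp1$g_a)
  pairs <- data.frame(disease_a = c("D1", "D2", "D1", "D9"),
                      disease_b = c("D2", "D1", "D3", "D1"),
                      rr = c(1.5, 2.5, 3.5, 4.5))
  rec <- suppressMessages(evaluate_pairs(g, assoc, pairs, seed = 1))
  expect_equal(nrow(rec), 2)       # D1-D3 identical sets, D9 unknown
  expect_equal(rec$rr, c(1.5, 2.5))
  sk <- attr(rec, "skipped")
  expect_equal(nrow(sk), 2)
  expect_setequal(sk$reason, c("all genes common", "disease not in association table"))
})

test_that("stratified report bins by RR and common-gene count", {
  records <- data.frame(
    roc_score = c(0.9, 0.8, 0.7, 0.95),
    precision = c(1, 0.5, 0.25, 1),
    recall = c(1, 1, 0.5, 0.75),
    rr = c(0.5, 1.5, 2.5, NA),
    n_common = c(3L, 7L, 12L, 20L))
  rep <- stratified_report(records)
  overall <- rep[rep$stratum == "overall", ]
  expect_equal(overall$n, 4)
  expect_equal(overall$roc_mean, mean(records$roc_score))
  expect_equal(overall$roc_sd, stats::sd(records$roc_score))

  rr01 <- rep[rep$stratum == "rr" & rep$bin == "[0,1)", ]
  expect_equal(rr01$n, 1)
  expect_equal(rr01$roc_mean, 0.9)
  expect_true(is.na(rr01$roc_sd))

  rr3 <- rep[rep$stratum == "rr" & rep$bin == ">=3", ]
  expect_equal(rr3$n, 0)          # the NA-RR record lands in no RR bin
  expect_true(is.na(rr3$roc_mean))

  cg <- rep[rep$stratum == "n_common", ]
  expect_equal(cg$n, rep(1, 4))
  expect_equal(sum(rep$n[rep$stratum == "n_common"]), 4)
})

test_that("cumulative ROC histogram decreases from 1", {
  records <- data.frame(roc_score = c(0.95, 0.85, 0.55))
  h <- roc_score_histogram(records, breaks = c(0, 0.5, 0.9, 1))
  expect_equal(h$fraction_ge, c(1, 1, 1 / 3, 0))
})
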