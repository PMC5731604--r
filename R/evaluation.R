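#' Build a seeded cross-validation split for one disease pair
#'
#' Reserves up to `n_pos` known common genes of the pair as held-out positive
#' test examples and up to `n_neg` non-common genes as negatives.  Reserved
#' positives are removed from *both* working gene sets, so that scoring them
#' re-discovers genuinely missing common genes; negatives keep their single
#' membership and are only labeled.  Negatives are drawn from the symmetric
#' difference, balanced across the two sides when both have enough members.
#'
#' @param a,b Character vectors: the full associated gene sets of the pair.
#' @param n_pos,n_neg Requested numbers of positive / negative test genes
#'   (defaults 10; capped at what is available).
#' @param seed Integer seed; the split is a deterministic function of it.
#' @param labels Character vector of length 2 with the disease labels.
#' @return Object of class `cv_split`: list with `pair`, `positives`,
#'   `negatives`, `a_work`, `b_work` (the working sets after removing the
#'   held-out positives) and `seed`.
#' @export
make_cv_split <- function(a, b, n_pos = 10L, n_neg = 10L, seed = 1L,
                          labels = c("A", "B")) {
  a <- sort_ids(unique(as.character(a)))
  b <- sort_ids(unique(as.character(b)))
  common <- sort_ids(intersect(a, b))
  only_a <- sort_ids(setdiff(a, b))
  only_b <- sort_ids(setdiff(b, a))
  if (length(common) == 0L) stop("no common genes to hold out", call. = FALSE)
  if (length(only_a) + length(only_b) == 0L) {
    stop("no non-common genes to sample negatives from", call. = FALSE)
  }
  withr::with_seed(seed, {
    pos <- sample_ids(common, min(n_pos, length(common)))
    n_neg_eff <- min(n_neg, length(only_a) + length(only_b))
    take_a <- min(length(only_a), ceiling(n_neg_eff / 2))
    take_b <- min(length(only_b), n_neg_eff - take_a)
    take_a <- min(length(only_a), n_neg_eff - take_b)
    neg <- c(sample_ids(only_a, take_a), sample_ids(only_b, take_b))
  })
  structure(list(pair = labels, positives = pos, negatives = neg,
                 a_work = sort_ids(setdiff(a, pos)),
                 b_work = sort_ids(setdiff(b, pos)),
                 seed = seed),
            class = "cv_split")
}

#' Score held-out test genes of a cross-validation split
#'
#' Computes the base separation of the working pair and, for every test gene
#' x (positive or negative), the prediction score
#' \eqn{s(x) = S_{AB} - S_{AB}[+x]} with x marked as shared (added to both
#' gene sets).
#'
#' With `use_modules = TRUE` the separation is computed between the *disease
#' modules* -- the largest connected components induced by each working gene
#' set -- which are re-extracted after the candidate is added.  A gene whose
#' sharing does not touch either module then scores exactly 0, while a gene
#' that attaches to the modules changes their separation.  With
#' `use_modules = FALSE` the raw gene sets are compared.  The default
#' (`NULL`) mirrors the two reported pipelines: nearest-distance separation
#' is module-based, while the all-pair-average variant \eqn{S_{<AB>}}
#' averages over all distinct gene pairs of the full sets -- which is what
#' makes it insensitive to a single gene's classification.
#'
#' @param g Interactome graph.
#' @param split A `cv_split` from [make_cv_split()].
#' @param method Distance averaging method, see [separation()].
#' @param use_modules Logical or `NULL`; score against extracted modules or
#'   raw gene sets.  `NULL` (default) resolves to `TRUE` for
#'   `method = "nearest"` and `FALSE` for `method = "all_pair_average"`.
#' @return Data frame with columns `gene`, `score`, `label` (1 = held-out
#'   common gene, 0 = negative), ordered by descending score.
#' @export
score_test_set <- function(g, split, method = c("nearest", "all_pair_average"),
                           use_modules = NULL) {
  method <- match.arg(method)
  if (is.null(use_modules)) use_modules <- method == "nearest"
  stopifnot(inherits(split, "cv_split"))
  a <- check_gene_set(g, split$a_work, "a_work", min_size = 2L)
  b <- check_gene_set(g, split$b_work, "b_work", min_size = 2L)
  test <- c(split$positives, split$negatives)
  label <- c(rep(1L, length(split$positives)), rep(0L, length(split$negatives)))
  missing <- setdiff(test, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("test gene(s) absent from the interactome: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  D <- node_distance_matrix(g, unique(c(a, b, test)))
  base <- sep_value(g, D, a, b, method, use_modules)
  score <- vapply(test, function(x) {
    base - sep_value(g, D, union(a, x), union(b, x), method, use_modules)
  }, numeric(1))
  out <- data.frame(gene = test, score = unname(score), label = label,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Rank-based AUROC (the normalized Mann-Whitney U statistic): the probability
#' that a uniformly drawn positive outscores a uniformly drawn negative, with
#' ties credited 0.5.
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels Vector of 0/1 (or logical) class labels, same length.
#' @return Numeric scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-style threshold from the ROC curve
#'
#' Returns the prediction score of the test example at the ROC point farthest
#' above the diagonal, i.e. the observed score maximizing TPR - FPR when
#' examples with `score >= threshold` are called positive.  Ties are resolved
#' towards the higher threshold (fewer predicted positives).
#'
#' @inheritParams roc_auc
#' @return Numeric scalar threshold.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("threshold selection needs both classes", call. = FALSE)
  }
  th <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(th, function(t) {
    mean(scores[labels == 1L] >= t) - mean(scores[labels == 0L] >= t)
  }, numeric(1))
  th[which.max(j)] # th descending: which.max picks the highest tied threshold
}

#' Precision and recall at a score threshold
#'
#' Test examples with `score >= threshold` are predicted positive.  Precision
#' is reported as 0 when nothing is predicted positive.
#'
#' @inheritParams roc_auc
#' @param threshold Numeric scalar cutoff.
#' @return Named numeric vector `c(precision = ..., recall = ...)`.
#' @export
precision_recall <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("precision/recall need both classes", call. = FALSE)
  }
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  c(precision = if (tp + fp == 0L) 0 else tp / (tp + fp),
    recall = tp / (tp + fn))
}

#' Randomized-common-gene baseline
#'
#' Null model for the prediction task: the shared genes of the pair are
#' removed from both sets and replaced by an equal number of genes sampled
#' uniformly without replacement from the interactome nodes outside
#' \eqn{G_A \cup G_B}, inserted into both sets.  Set sizes and the common-gene
#' count are preserved exactly; the interactome topology and the locations of
#' the non-shared genes are untouched.
#'
#' @inheritParams make_cv_split
#' @param g Interactome graph.
#' @return List with `a`, `b` (the randomized sets) and `replacement` (the
#'   sampled stand-in common genes).
#' @export
randomize_common_genes <- function(g, a, b, seed = 1L) {
  stopifnot(igraph::is_igraph(g))
  a <- sort_ids(unique(as.character(a)))
  b <- sort_ids(unique(as.character(b)))
  common <- sort_ids(intersect(a, b))
  if (length(common) == 0L) stop("pair has no common genes to randomize", call. = FALSE)
  pool <- sort_ids(setdiff(igraph::V(g)$name, union(a, b)))
  if (length(pool) < length(common)) {
    stop("not enough interactome genes outside the pair to replace the common genes",
         call. = FALSE)
  }
  repl <- withr::with_seed(seed, sample_ids(pool, length(common)))
  list(a = sort_ids(c(setdiff(a, common), repl)),
       b = sort_ids(c(setdiff(b, common), repl)),
       replacement = sort_ids(repl))
}

#' Cross-validated evaluation of one disease pair
#'
#' Composes [make_cv_split()], [score_test_set()], [roc_auc()],
#' [choose_threshold()] and [precision_recall()] into a single evaluation
#' record.  Pairs without any common gene, or with all genes common (empty
#' candidate pool), cannot be evaluated and are skipped: the function reports
#' the reason via [message()] and returns `NULL`.
#'
#' @inheritParams score_test_set
#' @inheritParams make_cv_split
#' @param rr Optional comorbidity relative risk carried into the record.
#' @param repeats Number of independent splits (seeds `seed, seed + 1, ...`);
#'   metrics are averaged across them.
#' @inheritParams score_test_set
#' @return One-row data frame with columns `disease_a`, `disease_b`,
#'   `roc_score`, `threshold`, `precision`, `recall`, `rr`, `n_common`,
#'   `method`, `n_pos`, `n_neg`, `seed`; or `NULL` if the pair was skipped.
#' @export
evaluate_pair <- function(g, a, b, n_pos = 10L, n_neg = 10L, seed = 1L,
                          method = c("nearest", "all_pair_average"),
                          rr = NA_real_, labels = c("A", "B"), repeats = 1L,
                          use_modules = NULL) {
  method <- match.arg(method)
  a <- sort_ids(unique(as.character(a)))
  b <- sort_ids(unique(as.character(b)))
  n_common <- length(intersect(a, b))
  if (n_common == 0L) {
    message(sprintf("skipping pair %s-%s: no common genes", labels[1L], labels[2L]))
    return(NULL)
  }
  if (length(setdiff(union(a, b), intersect(a, b))) == 0L) {
    message(sprintf("skipping pair %s-%s: all genes common (no candidates)",
                    labels[1L], labels[2L]))
    return(NULL)
  }
  one <- function(s) {
    split <- make_cv_split(a, b, n_pos = n_pos, n_neg = n_neg, seed = s,
                           labels = labels)
    st <- score_test_set(g, split, method = method, use_modules = use_modules)
    thr <- choose_threshold(st$score, st$label)
    pr <- precision_recall(st$score, st$label, thr)
    c(roc = roc_auc(st$score, st$label), thr = thr, pr,
      n_pos = length(split$positives), n_neg = length(split$negatives))
  }
  reps <- vapply(seed + seq_len(repeats) - 1L, one, numeric(6))
  m <- rowMeans(reps)
  data.frame(disease_a = labels[1L], disease_b = labels[2L],
             roc_score = unname(m["roc"]), threshold = unname(m["thr"]),
             precision = unname(m["precision"]), recall = unname(m["recall"]),
             rr = rr, n_common = n_common, method = method,
             n_pos = as.integer(m["n_pos"]), n_neg = as.integer(m["n_neg"]),
             seed = seed, stringsAsFactors = FALSE)
}

#' Evaluate a table of disease pairs
#'
#' Runs [evaluate_pair()] for every row of a pairs table against an
#' association map, collecting the per-pair records and skipping pairs that
#' cannot be evaluated (unknown disease, no or all-common genes, working sets
#' too small); skip reasons are kept in the `"skipped"` attribute.
#'
#' @param g Interactome graph.
#' @param assoc Named list from [load_associations()].
#' @param pairs Data frame with columns `disease_a`, `disease_b` and
#'   optionally `rr`.
#' @param baseline `"none"` or `"randomized"`: with `"randomized"` each
#'   pair's common genes are first replaced via [randomize_common_genes()].
#' @inheritParams evaluate_pair
#' @param map_genes Logical; drop association genes absent from the graph
#'   before evaluating (default `TRUE`).
#' @return Data frame of evaluation records (possibly zero rows), with
#'   attribute `"skipped"` (data frame of pair labels and reasons).
#' @export
evaluate_pairs <- function(g, assoc, pairs, n_pos = 10L, n_neg = 10L,
                           seed = 1L, method = c("nearest", "all_pair_average"),
                           baseline = c("none", "randomized"), repeats = 1L,
                           map_genes = TRUE, use_modules = NULL) {
  method <- match.arg(method)
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(pairs), all(c("disease_a", "disease_b") %in% names(pairs)))
  records <- list()
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    da <- as.character(pairs$disease_a[i])
    db <- as.character(pairs$disease_b[i])
    rr <- if ("rr" %in% names(pairs)) as.numeric(pairs$rr[i]) else NA_real_
    skip <- function(reason) {
      message(sprintf("skipping pair %s-%s: %s", da, db, reason))
      skipped[[length(skipped) + 1L]] <<- data.frame(
        disease_a = da, disease_b = db, reason = reason, stringsAsFactors = FALSE)
    }
    if (!da %in% names(assoc) || !db %in% names(assoc)) {
      skip("disease not in association table")
      next
    }
    a <- assoc[[da]]
    b <- assoc[[db]]
    if (map_genes) {
      a <- suppressWarnings(map_to_graph(g, a, da)$in_graph)
      b <- suppressWarnings(map_to_graph(g, b, db)$in_graph)
    }
    if (length(intersect(a, b)) == 0L) {
      skip("no common genes")
      next
    }
    if (length(setdiff(union(a, b), intersect(a, b))) == 0L) {
      skip("all genes common")
      next
    }
    if (baseline == "randomized") {
      rnd <- randomize_common_genes(g, a, b, seed = seed + i)
      a <- rnd$a
      b <- rnd$b
    }
    rec <- tryCatch(
      suppressMessages(evaluate_pair(g, a, b, n_pos = n_pos, n_neg = n_neg,
                                     seed = seed + i, method = method, rr = rr,
                                     labels = c(da, db), repeats = repeats,
                                     use_modules = use_modules)),
      error = function(e) {
        skip(conditionMessage(e))
        NULL
      })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  out <- if (length(records) > 0L) do.call(rbind, records) else
    data.frame(disease_a = character(0), disease_b = character(0),
               roc_score = numeric(0), threshold = numeric(0),
               precision = numeric(0), recall = numeric(0), rr = numeric(0),
               n_common = integer(0), method = character(0),
               n_pos = integer(0), n_neg = integer(0), seed = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(disease_a = character(0), disease_b = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  out
}

#' Stratified summary of evaluation records
#'
#' Summarizes per-pair evaluation records overall, by comorbidity relative
#' risk (RR) bin and by common-gene-count bin: count, mean and standard
#' deviation of the ROC score, precision and recall per stratum.  Bins are
#' left-closed/right-open.
#'
#' @param records Data frame of records from [evaluate_pair()] /
#'   [evaluate_pairs()].
#' @param rr_bins Numeric vector of RR bin edges (default `c(0, 1, 2, 3, Inf)`).
#' @param common_bins Bin edges for the number of common genes
#'   (default `c(0, 5, 10, 15, Inf)`).
#' @return Data frame with columns `stratum`, `bin`, `n`, `roc_mean`,
#'   `roc_sd`, `precision_mean`, `precision_sd`, `recall_mean`, `recall_sd`.
#'   Empty bins have `n = 0` and `NA` metrics.
#' @export
stratified_report <- function(records, rr_bins = c(0, 1, 2, 3, Inf),
                              common_bins = c(0, 5, 10, 15, Inf)) {
  summarize <- function(stratum, bin, rows) {
    sub <- records[rows, , drop = FALSE]
    data.frame(
      stratum = stratum, bin = bin, n = nrow(sub),
      roc_mean = mean_or_na(sub$roc_score), roc_sd = sd_or_na(sub$roc_score),
      precision_mean = mean_or_na(sub$precision), precision_sd = sd_or_na(sub$precision),
      recall_mean = mean_or_na(sub$recall), recall_sd = sd_or_na(sub$recall),
      stringsAsFactors = FALSE)
  }
  out <- list(summarize("overall", "all", seq_len(nrow(records))))
  for (i in seq_len(length(rr_bins) - 1L)) {
    lo <- rr_bins[i]
    hi <- rr_bins[i + 1L]
    rows <- which(!is.na(records$rr) & records$rr >= lo & records$rr < hi)
    out[[length(out) + 1L]] <- summarize("rr", bin_label(lo, hi), rows)
  }
  for (i in seq_len(length(common_bins) - 1L)) {
    lo <- common_bins[i]
    hi <- common_bins[i + 1L]
    rows <- which(records$n_common >= lo & records$n_common < hi)
    out[[length(out) + 1L]] <- summarize("n_common", bin_label(lo, hi), rows)
  }
  do.call(rbind, out)
}

#' Cumulative ROC-score histogram data
#'
#' For each grid value r, the fraction of evaluated pairs whose ROC score is
#' greater than or equal to r (the curve used to display how performance is
#' distributed across pairs).
#'
#' @inheritParams stratified_report
#' @param breaks Numeric grid of ROC-score values.
#' @return Data frame with columns `roc_score` and `fraction_ge`.
#' @export
roc_score_histogram <- function(records, breaks = seq(0, 1, by = 0.05)) {
  stopifnot(nrow(records) > 0L)
  data.frame(roc_score = breaks,
             fraction_ge = vapply(breaks, function(r) mean(records$roc_score >= r),
                                  numeric(1)))
}

#' @export
print.cv_split <- function(x, ...) {
  cat(sprintf("CV split %s-%s (seed %d): %d positives held out, %d negatives\n",
              x$pair[1L], x$pair[2L], x$seed,
              length(x$positives), length(x$negatives)))
  invisible(x)
}

# -- internal -----------------------------------------------------------------

# sample `size` elements of x without replacement; safe for length-1 x
sample_ids <- function(x, size) x[sample.int(length(x), size)]

mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
sd_or_na <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

bin_label <- function(lo, hi) {
  if (is.infinite(hi)) sprintf(">=%g", lo) else sprintf("[%g,%g)", lo, hi)
}
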