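#' Candidate pool for missing common genes
#'
#' Candidates are the genes distinctly associated with exactly one disease of
#' the pair: the symmetric difference \eqn{(G_A \cup G_B) - (G_A \cap G_B)}.
#'
#' @param a,b Character vectors of gene ids.
#' @return Sorted character vector of candidate gene ids.
#' @export
candidate_set <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  cand <- sort_ids(setdiff(union(a, b), intersect(a, b)))
  if (length(cand) == 0L) {
    stop("no candidates: the two gene sets are identical", call. = FALSE)
  }
  cand
}

#' Module separation with candidate genes marked as shared
#'
#' Computes \eqn{S_{AB}[+X]}: the module separation after every gene of `x`
#' is made common to both diseases, i.e. `separation(g, union(a, x),
#' union(b, x))`.
#'
#' @inheritParams separation
#' @param x Character vector of candidate genes, a subset of
#'   [candidate_set()] of the pair (possibly empty, which reproduces the base
#'   separation).
#' @return A `separation_result` (see [separation()]).
#' @export
separation_with_shared <- function(g, a, b, x,
                                   method = c("nearest", "all_pair_average")) {
  method <- match.arg(method)
  x <- unique(as.character(x))
  if (length(x) > 0L) {
    cand <- candidate_set(a, b)
    outside <- setdiff(x, cand)
    if (length(outside) > 0L) {
      stop("gene(s) not in the candidate set (already shared or unknown): ",
           paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    }
  }
  separation(g, union(a, x), union(b, x), method = method)
}

#' Rank candidate missing common genes
#'
#' Exhaustively evaluates every candidate x in the symmetric difference of the
#' pair, computing the prediction score
#' \deqn{s(x) = S_{AB} - S_{AB}[+x],}
#' the drop in module separation when x is marked as shared.  Larger scores
#' mean marking x as common closes the gap between the two modules more; the
#' top-ranked gene is the argmin of \eqn{S_{AB}[+x]}.  Score ties are broken
#' towards the lexicographically smaller gene id.
#'
#' Breadth-first-search distances between all members of \eqn{G_A \cup G_B}
#' are computed once and reused across candidate evaluations.
#'
#' @inheritParams separation
#' @param normalize Logical; if `TRUE` scores are divided by the base
#'   \eqn{S_{AB}} (an error when the base separation is 0).
#' @param use_modules Logical; if `TRUE`, separations are computed between
#'   the extracted disease modules (largest connected components) rather than
#'   the raw gene sets (default `FALSE`).
#' @return Object of class `gene_ranking`: list with `base_s_ab`, `method`,
#'   `normalized`, `n_evaluated`, and `items`, a data frame with columns
#'   `gene`, `side` (`"A_only"`/`"B_only"`), `s_ab_plus`, `score`, sorted by
#'   descending score.
#' @export
rank_candidates <- function(g, a, b, method = c("nearest", "all_pair_average"),
                            normalize = FALSE, use_modules = FALSE) {
  method <- match.arg(method)
  a <- check_gene_set(g, a, "a", min_size = 2L)
  b <- check_gene_set(g, b, "b", min_size = 2L)
  cand <- candidate_set(a, b)
  D <- node_distance_matrix(g, union(a, b))
  base <- list(s_ab = sep_value(g, D, a, b, method, use_modules))
  if (normalize && base$s_ab == 0) {
    stop("normalized score undefined: base separation S_AB is 0", call. = FALSE)
  }
  s_plus <- vapply(cand, function(x) {
    sep_value(g, D, union(a, x), union(b, x), method, use_modules)
  }, numeric(1))
  score <- base$s_ab - s_plus
  if (normalize) score <- score / base$s_ab
  items <- data.frame(
    gene = cand,
    side = ifelse(cand %in% a, "A_only", "B_only"),
    s_ab_plus = unname(s_plus),
    score = unname(score),
    stringsAsFactors = FALSE
  )
  items <- items[order(-items$score, items$gene, method = "radix"), , drop = FALSE]
  rownames(items) <- NULL
  structure(list(base_s_ab = base$s_ab, method = method, normalized = normalize,
                 n_evaluated = length(cand), items = items),
            class = "gene_ranking")
}

#' Optimal k-subset of missing common genes
#'
#' Exhaustively minimizes \eqn{S_{AB}[+X]} over all \eqn{\binom{n}{k}}
#' subsets X of size `k` drawn from the candidate set.  Ties are broken
#' towards the lexicographically smallest sorted gene list.  The search is
#' combinatorial; `max_evaluations` guards against blow-up.
#'
#' @inheritParams rank_candidates
#' @param k Subset size, `1 <= k <=` number of candidates.
#' @param max_evaluations Maximum number of subsets that may be scored.
#' @return List of class `subset_result` with `k`, `genes` (sorted), the
#'   achieved `s_ab_plus`, `n_evaluated` and `base_s_ab`.
#' @export
best_subset <- function(g, a, b, k, method = c("nearest", "all_pair_average"),
                        max_evaluations = 2e6, use_modules = FALSE) {
  method <- match.arg(method)
  a <- check_gene_set(g, a, "a", min_size = 2L)
  b <- check_gene_set(g, b, "b", min_size = 2L)
  cand <- candidate_set(a, b)
  n <- length(cand)
  if (!(is.numeric(k) && length(k) == 1L && k >= 1 && k <= n)) {
    stop(sprintf("k must lie in [1, %d]", n), call. = FALSE)
  }
  k <- as.integer(k)
  n_subsets <- choose(n, k)
  if (n_subsets > max_evaluations) {
    stop(sprintf("C(%d, %d) = %.0f subsets exceeds the evaluation budget (%g); choose a smaller k",
                 n, k, n_subsets, max_evaluations), call. = FALSE)
  }
  D <- node_distance_matrix(g, union(a, b))
  base_s_ab <- sep_value(g, D, a, b, method, use_modules)
  best_genes <- NULL
  best_val <- Inf
  n_eval <- 0L
  # cand is sorted, so combn enumerates subsets in lexicographic order and the
  # first strict minimum seen is the lexicographic tie-winner
  utils::combn(cand, k, FUN = function(x) {
    n_eval <<- n_eval + 1L
    v <- sep_value(g, D, union(a, x), union(b, x), method, use_modules)
    if (v < best_val) {
      best_val <<- v
      best_genes <<- x
    }
    NULL
  }, simplify = FALSE)
  structure(list(k = k, genes = sort_ids(best_genes), s_ab_plus = best_val,
                 n_evaluated = n_eval, base_s_ab = base_s_ab, method = method),
            class = "subset_result")
}

#' Sequential recovery of multiple missing common genes
#'
#' Applies the single-gene argmin repeatedly: at each step the top-ranked
#' candidate is marked as shared (moved into both gene sets) and the ranking
#' is recomputed on the updated pair.  The resulting gene list may differ from
#' the jointly optimal [best_subset()] of the same size.
#'
#' @inheritParams rank_candidates
#' @param m Number of genes to recover.
#' @return Character vector of recovered genes in selection order (shorter,
#'   with a warning, if the candidate pool is exhausted early).
#' @export
iterative_recovery <- function(g, a, b, m,
                               method = c("nearest", "all_pair_average"),
                               use_modules = FALSE) {
  method <- match.arg(method)
  a <- check_gene_set(g, a, "a", min_size = 2L)
  b <- check_gene_set(g, b, "b", min_size = 2L)
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  m <- as.integer(m)
  D <- node_distance_matrix(g, union(a, b)) # A union B is invariant under recovery
  picked <- character(0)
  for (step in seq_len(m)) {
    cand <- sort_ids(setdiff(union(a, b), intersect(a, b)))
    if (length(cand) == 0L) {
      warning(sprintf("candidate set exhausted after %d of %d steps",
                      step - 1L, m), call. = FALSE)
      break
    }
    base <- sep_value(g, D, a, b, method, use_modules)
    s_plus <- vapply(cand, function(x) {
      sep_value(g, D, union(a, x), union(b, x), method, use_modules)
    }, numeric(1))
    score <- base - s_plus
    top <- cand[order(-score, cand, method = "radix")[1L]]
    picked <- c(picked, top)
    a <- union(a, top)
    b <- union(b, top)
  }
  picked
}

#' @export
print.gene_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Candidate ranking (%s%s): base S_AB = %.4f, %d candidates\n",
              x$method, if (x$normalized) ", normalized" else "",
              x$base_s_ab, x$n_evaluated))
  print(utils::head(x$items, n))
  invisible(x)
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("Best %d-subset (%s): {%s}\n  S_AB[+X] = %.4f (base %.4f), %d subsets evaluated\n",
              x$k, x$method, paste(x$genes, collapse = ", "),
              x$s_ab_plus, x$base_s_ab, x$n_evaluated))
  invisible(x)
}
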