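#' Module separation of two disease gene sets
#'
#' Quantifies the topological separation of two disease modules A and B on the
#' interactome as
#' \deqn{S_{AB} = \langle d_{AB} \rangle - \frac{\langle d_{AA}\rangle + \langle d_{BB}\rangle}{2}}
#' where the angle brackets are averages of unweighted shortest-path (hop)
#' distances.  With `method = "nearest"` (the standard definition) each gene
#' contributes its distance to the nearest *other* member of its own set
#' (within terms) and its distance to the nearest member of the other set
#' (between term, counted from each side; a gene shared by both sets
#' contributes 0 from each side).  With `method = "all_pair_average"` the
#' averages run over all distinct gene pairs instead, giving the weaker
#' comparator \eqn{S_{<AB>}}.
#'
#' Negative \eqn{S_{AB}} indicates topologically overlapping modules.  Gene
#' pairs in different components of the interactome have no finite distance;
#' such distances are excluded from the averages and the affected genes are
#' recorded in `excluded_a` / `excluded_b` (an error is raised only if an
#' average would be empty).
#'
#' @param g Interactome graph from [load_interactome()].
#' @param a,b Character vectors of gene ids (each of size >= 2, subsets of the
#'   node set).
#' @param method `"nearest"` (default) or `"all_pair_average"`.
#' @return Object of class `separation_result`: a list with numeric elements
#'   `d_aa`, `d_bb`, `d_ab`, `s_ab`, the `method`, and character vectors
#'   `excluded_a`, `excluded_b` of genes omitted for unreachability.
#' @examples
#' g <- igraph::make_graph(~ 1-2, 2-3, 3-4, 4-5)
#' separation(g, c("1", "2"), c("4", "5"))$s_ab  # 1.5
#' @export
separation <- function(g, a, b, method = c("nearest", "all_pair_average")) {
  method <- match.arg(method)
  a <- check_gene_set(g, a, "a", min_size = 2L)
  b <- check_gene_set(g, b, "b", min_size = 2L)
  D <- node_distance_matrix(g, union(a, b))
  separation_from_matrix(D, a, b, method)
}

#' Within-set nearest or all-pair distances
#'
#' Distances underlying the \eqn{\langle d_{AA}\rangle} term.  In `nearest`
#' mode each gene contributes its minimum hop distance to any other member of
#' the set; in `all_pair_average` mode every unordered distinct pair
#' contributes.
#'
#' @inheritParams separation
#' @param s Character vector of gene ids, size >= 2, subset of the node set.
#' @return List with `d` (numeric vector of finite hop distances) and
#'   `excluded` (genes with no reachable co-member / no finite pair).
#' @export
within_distances <- function(g, s, method = c("nearest", "all_pair_average")) {
  method <- match.arg(method)
  s <- check_gene_set(g, s, "s", min_size = 2L)
  D <- node_distance_matrix(g, s)
  within_from_matrix(D, s, method)
}

#' Between-set nearest or all-pair distances
#'
#' Distances underlying the \eqn{\langle d_{AB}\rangle} term.  In `nearest`
#' mode each gene of A contributes its minimum distance to any member of B and
#' vice versa (a gene present in both sets contributes 0 from each side); in
#' `all_pair_average` mode every unordered pair \{x, y\} with x in A, y in B
#' and x != y contributes once.
#'
#' @inheritParams separation
#' @return List with `d`, `excluded_a`, `excluded_b`.
#' @export
between_distances <- function(g, a, b, method = c("nearest", "all_pair_average")) {
  method <- match.arg(method)
  a <- check_gene_set(g, a, "a", min_size = 1L)
  b <- check_gene_set(g, b, "b", min_size = 1L)
  D <- node_distance_matrix(g, union(a, b))
  between_from_matrix(D, a, b, method)
}

#' Jaccard index of two gene sets
#'
#' \eqn{J = |A \cap B| / |A \cup B|}, the plain set-overlap comparator for a
#' disease pair.
#'
#' @param a,b Character vectors of gene ids; their union must be non-empty.
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0L) stop("both gene sets are empty", call. = FALSE)
  length(intersect(a, b)) / length(u)
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("Module separation (%s)\n", x$method))
  cat(sprintf("  <d_AA> = %.4f   <d_BB> = %.4f   <d_AB> = %.4f\n",
              x$d_aa, x$d_bb, x$d_ab))
  cat(sprintf("  S_AB   = %.4f\n", x$s_ab))
  if (length(x$excluded_a) + length(x$excluded_b) > 0L) {
    cat(sprintf("  excluded (unreachable): %d from A, %d from B\n",
                length(x$excluded_a), length(x$excluded_b)))
  }
  invisible(x)
}

# -- internal -----------------------------------------------------------------

check_gene_set <- function(g, s, label, min_size = 1L) {
  stopifnot(igraph::is_igraph(g))
  s <- sort_ids(unique(as.character(s)))
  if (length(s) < min_size) {
    stop(sprintf("gene set '%s' needs at least %d members, got %d",
                 label, min_size, length(s)), call. = FALSE)
  }
  missing <- setdiff(s, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop(sprintf("gene set '%s' contains ids absent from the interactome: %s",
                 label, paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  s
}

# unweighted hop-distance matrix restricted to `genes`, dimnames = gene ids
node_distance_matrix <- function(g, genes) {
  genes <- sort_ids(genes)
  igraph::distances(g, v = genes, to = genes, algorithm = "unweighted")
}

within_from_matrix <- function(D, s, method) {
  m <- D[s, s, drop = FALSE]
  if (method == "nearest") {
    diag(m) <- Inf
    d <- apply(m, 1L, min)
    excluded <- s[!is.finite(d)]
    d <- unname(d[is.finite(d)])
  } else {
    reach <- apply(m, 1L, function(r) sum(is.finite(r)) > 1L) # beyond self
    excluded <- s[!reach]
    d <- m[upper.tri(m)]
    d <- d[is.finite(d)]
  }
  if (length(d) == 0L) {
    stop("no finite within-set distance: all members mutually unreachable",
         call. = FALSE)
  }
  list(d = d, excluded = excluded)
}

between_from_matrix <- function(D, a, b, method) {
  m <- D[a, b, drop = FALSE]
  if (method == "nearest") {
    da <- apply(m, 1L, min)
    db <- apply(D[b, a, drop = FALSE], 1L, min)
    excluded_a <- a[!is.finite(da)]
    excluded_b <- b[!is.finite(db)]
    d <- c(unname(da[is.finite(da)]), unname(db[is.finite(db)]))
  } else {
    eg <- expand.grid(x = a, y = b, stringsAsFactors = FALSE)
    eg <- eg[eg$x != eg$y, , drop = FALSE]
    key <- paste(pmin(eg$x, eg$y), pmax(eg$x, eg$y), sep = "\r")
    eg <- eg[!duplicated(key), , drop = FALSE]
    dd <- D[cbind(eg$x, eg$y)]
    fin <- is.finite(dd)
    reach_a <- unique(c(eg$x[fin], eg$y[fin]))
    excluded_a <- setdiff(a, reach_a)
    excluded_b <- setdiff(b, reach_a)
    d <- dd[fin]
  }
  if (length(d) == 0L) {
    stop("no finite between-set distance: sets lie in different components",
         call. = FALSE)
  }
  list(d = d, excluded_a = excluded_a, excluded_b = excluded_b)
}

# separation value on a precomputed distance matrix, optionally between the
# disease modules (largest connected components) instead of the raw sets
sep_value <- function(g, D, a, b, method, use_modules = FALSE) {
  if (use_modules) {
    a <- largest_connected_component(g, a)$members
    b <- largest_connected_component(g, b)$members
    if (length(a) < 2L || length(b) < 2L) {
      stop("disease module smaller than 2 genes; cannot compute separation",
           call. = FALSE)
    }
  }
  separation_from_matrix(D, a, b, method)$s_ab
}

# core S_AB computation on a precomputed distance matrix covering union(a, b);
# separation(), rank_candidates() and best_subset() all funnel through here,
# so cached and uncached evaluations are identical by construction
separation_from_matrix <- function(D, a, b, method) {
  wa <- within_from_matrix(D, a, method)
  wb <- within_from_matrix(D, b, method)
  ab <- between_from_matrix(D, a, b, method)
  d_aa <- mean(wa$d)
  d_bb <- mean(wb$d)
  d_ab <- mean(ab$d)
  structure(list(
    d_aa = d_aa, d_bb = d_bb, d_ab = d_ab,
    s_ab = d_ab - (d_aa + d_bb) / 2,
    method = method,
    excluded_a = sort_ids(unique(c(wa$excluded, ab$excluded_a))),
    excluded_b = sort_ids(unique(c(wb$excluded, ab$excluded_b)))
  ), class = "separation_result")
}
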