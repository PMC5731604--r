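# Independent brute-force oracles for the separation machinery.  Everything
# here is deliberately written without igraph or any package internals:
# Floyd-Warshall over a plain edge list, explicit pair enumeration, and
# counting-based AUROC.

# all-pairs shortest-path matrix (hops) by Floyd-Warshall on a character
# edge list; Inf for unreachable pairs
oracle_apsp <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]
      b <- edges[i, 2]
      if (a != b) D[a, b] <- D[b, a] <- 1
    }
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# within-set distance list per the nearest / all-pair definitions
oracle_within <- function(D, S, method) {
  out <- numeric(0)
  if (method == "nearest") {
    for (s in S) {
      d <- min(D[s, setdiff(S, s)])
      if (is.finite(d)) out <- c(out, d)
    }
  } else {
    S <- sort(S, method = "radix")
    for (i in seq_along(S)) {
      for (j in seq_along(S)) {
        if (i < j && is.finite(D[S[i], S[j]])) out <- c(out, D[S[i], S[j]])
      }
    }
  }
  out
}

oracle_between <- function(D, A, B, method) {
  out <- numeric(0)
  if (method == "nearest") {
    for (a in A) {
      d <- min(D[a, B])
      if (is.finite(d)) out <- c(out, d)
    }
    for (b in B) {
      d <- min(D[b, A])
      if (is.finite(d)) out <- c(out, d)
    }
  } else {
    seen <- character(0)
    for (a in A) {
      for (b in B) {
        if (a == b) next
        key <- paste(sort(c(a, b)), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        if (is.finite(D[a, b])) out <- c(out, D[a, b])
      }
    }
  }
  out
}

oracle_separation <- function(D, A, B, method) {
  mean(oracle_between(D, A, B, method)) -
    (mean(oracle_within(D, A, method)) + mean(oracle_within(D, B, method))) / 2
}

# connected components of the subgraph induced by `genes`, by flood fill
oracle_components <- function(edges, genes) {
  adj <- lapply(stats::setNames(genes, genes), function(g) character(0))
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]
      b <- edges[i, 2]
      if (a %in% genes && b %in% genes && a != b) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  comps <- list()
  left <- genes
  while (length(left) > 0) {
    frontier <- left[1]
    comp <- character(0)
    while (length(frontier) > 0) {
      v <- frontier[1]
      frontier <- frontier[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      frontier <- c(frontier, setdiff(adj[[v]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp, method = "radix")
    left <- setdiff(left, comp)
  }
  comps
}

# AUROC by explicit concordant-pair counting with 0.5 tie credit
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# random connected graph: chain over a shuffled node ordering plus extra
# random edges; returns list(g = igraph, nodes, edges = character matrix)
random_connected_graph <- function(n, extra = n) {
  nodes <- as.character(seq_len(n))
  perm <- sample(nodes)
  edges <- cbind(perm[-n], perm[-1])
  if (extra > 0) {
    more <- cbind(sample(nodes, extra, replace = TRUE),
                  sample(nodes, extra, replace = TRUE))
    more <- more[more[, 1] != more[, 2], , drop = FALSE]
    edges <- rbind(edges, more)
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(nodes, method = "radix"),
                          stringsAsFactors = FALSE))
  list(g = g, nodes = nodes, edges = edges)
}

# the 5-node path graph 1-2-3-4-5 used by the worked examples
path5 <- function() {
  igraph::graph_from_data_frame(
    data.frame(from = c("1", "2", "3", "4"), to = c("2", "3", "4", "5"),
               stringsAsFactors = FALSE),
    directed = FALSE)
}

path5_edges <- function() {
  cbind(c("1", "2", "3", "4"), c("2", "3", "4", "5"))
}

# write a small tabular fixture to a temp file
write_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
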