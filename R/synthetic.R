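#' Configuration of a synthetic planted disease pair
#'
#' Bundles and validates the knobs of the synthetic benchmark: interactome
#' size and density, disease-set sizes, the number of genuinely shared genes,
#' and `locality`, the restart probability of the random walk that grows each
#' module (in (0, 1]; higher values keep the walk near its seed and give more
#' compact modules, emulating the tendency of disease genes to cluster in the
#' interactome).
#'
#' @param n_nodes Number of interactome nodes (>= 10).
#' @param attachment Edges added per new node during preferential-attachment
#'   growth (>= 1, < `n_nodes`).
#' @param n_a,n_b Disease gene-set sizes.
#' @param n_shared Number of planted common genes
#'   (`<= min(n_a, n_b)`; `n_a + n_b - n_shared <= n_nodes`).
#' @param locality Random-walk restart probability in (0, 1].
#' @param scatter Fraction (in `[0, 0.8]`) of each disease's exclusive genes
#'   placed as scattered singletons (uniform random nodes outside the cores)
#'   rather than in the connected core, emulating the associated genes that
#'   fall outside a real disease's largest connected component.
#' @param rr Optional synthetic comorbidity relative-risk value (metadata for
#'   stratification only; never used in scoring).
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 500L, attachment = 2L, n_a = 25L,
                             n_b = 25L, n_shared = 8L, locality = 0.7,
                             scatter = 0.3, rr = NA_real_, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  attachment <- as.integer(attachment)
  n_a <- as.integer(n_a)
  n_b <- as.integer(n_b)
  n_shared <- as.integer(n_shared)
  if (n_nodes < 10L) stop("n_nodes must be >= 10", call. = FALSE)
  if (attachment < 1L || n_nodes < attachment + 1L) {
    stop("need n_nodes >= attachment + 1 >= 2", call. = FALSE)
  }
  if (n_shared > min(n_a, n_b)) stop("n_shared must be <= min(n_a, n_b)", call. = FALSE)
  if (n_a + n_b - n_shared > n_nodes) {
    stop("n_a + n_b - n_shared exceeds n_nodes", call. = FALSE)
  }
  if (!(is.numeric(locality) && locality > 0 && locality <= 1)) {
    stop("locality must lie in (0, 1]", call. = FALSE)
  }
  if (!(is.numeric(scatter) && scatter >= 0 && scatter <= 0.8)) {
    stop("scatter must lie in [0, 0.8]", call. = FALSE)
  }
  structure(list(n_nodes = n_nodes, attachment = attachment, n_a = n_a,
                 n_b = n_b, n_shared = n_shared, locality = locality,
                 scatter = scatter, rr = rr, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic interactome by preferential attachment
#'
#' Grows a connected undirected graph with a heavy-tailed degree
#' distribution: starting from a clique on `attachment` nodes, each new node
#' attaches to `attachment` distinct existing nodes chosen with probability
#' proportional to their current degree.  The edge count is exactly
#' `attachment * (n_nodes - attachment) + choose(attachment, 2)`.
#'
#' @inheritParams synthetic_config
#' @return Connected [igraph::igraph] with character vertex names
#'   `"1" ... "n_nodes"`.
#' @export
generate_graph <- function(n_nodes, attachment = 2L, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  attachment <- as.integer(attachment)
  if (attachment < 1L || n_nodes < attachment + 1L) {
    stop("need n_nodes >= attachment + 1 >= 2", call. = FALSE)
  }
  withr::with_seed(seed, {
    deg <- integer(n_nodes)
    from <- integer(0)
    to <- integer(0)
    if (attachment >= 2L) {
      start <- utils::combn(seq_len(attachment), 2L)
      from <- start[1L, ]
      to <- start[2L, ]
      deg[seq_len(attachment)] <- attachment - 1L
    }
    for (v in seq.int(attachment + 1L, n_nodes)) {
      prob <- deg[seq_len(v - 1L)]
      if (sum(prob) == 0) prob <- rep(1, v - 1L) # only at the degenerate start
      targets <- sample.int(v - 1L, attachment, prob = prob)
      from <- c(from, rep.int(v, attachment))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- attachment
    }
  })
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(from), to = as.character(to),
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n_nodes)),
                          stringsAsFactors = FALSE))
}

#' Plant a disease pair on a graph
#'
#' Builds two disease gene sets with a controlled, topologically meaningful
#' overlap.  Each disease receives a compact connected *core* of exclusive
#' genes, grown from its own seed node by a random walk with restart (restart
#' probability = `locality`); the second core keeps at least two hops of
#' distance from the first (its walk never absorbs the first core or its
#' direct neighbours).  The `n_shared` common genes are then sampled from the
#' *connector* pool: nodes outside both cores that are adjacent to members of
#' both.  The shared genes therefore bridge the two modules -- emulating
#' common disease genes sitting in the topological overlap zone of two
#' otherwise separated disease neighbourhoods -- and `g_a` and `g_b`
#' intersect in exactly the planted shared set.  A `scatter` fraction of each
#' disease's exclusive genes is placed as uniform random singletons instead
#' of core members, mirroring the associated genes of real diseases that fall
#' outside the largest connected component.
#'
#' Seed pairs are drawn at hop distance >= 4 where possible, and planting is
#' retried with fresh seeds (deterministically, under `config$seed`) when the
#' connector pool is too small.
#'
#' If a disease has no exclusive genes (`n_shared = min(n_a, n_b)`), its gene
#' set is a connected cluster grown next to the other core, nested inside the
#' larger set.
#'
#' @param g Graph from [generate_graph()] (any connected interactome works).
#' @param config A [synthetic_config()]; its `seed` drives all draws.
#' @return List of class `planted_pair` with `g_a`, `g_b`, `shared` (sorted
#'   character vectors) and `config`.
#' @export
plant_pair <- function(g, config) {
  stopifnot(igraph::is_igraph(g), inherits(config, "synthetic_config"))
  n <- igraph::vcount(g)
  if (n < config$n_a + config$n_b - config$n_shared) {
    stop("graph too small for the requested gene sets", call. = FALSE)
  }
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  nm <- igraph::V(g)$name
  n_ex_a <- config$n_a - config$n_shared
  n_ex_b <- config$n_b - config$n_shared
  n_core_a <- if (n_ex_a > 0L) max(2L, round((1 - config$scatter) * n_ex_a)) else 0L
  n_core_b <- if (n_ex_b > 0L) max(2L, round((1 - config$scatter) * n_ex_b)) else 0L
  nbrs <- function(s) setdiff(sort(unique(unlist(adj[s]))), s)
  res <- withr::with_seed(config$seed, {
    out <- NULL
    for (attempt in seq_len(50L)) {
      min_sep <- if (attempt <= 25L) 4L else 2L
      seed_a <- sample.int(n, 1L)
      d_a <- as.vector(igraph::distances(g, v = seed_a, algorithm = "unweighted"))
      far <- which(d_a >= min_sep)
      if (length(far) == 0L) far <- which(d_a >= 1L)
      seed_b <- far[sample.int(length(far), 1L)]
      core_a <- tryCatch(
        grow_module(adj, seed_a, n_core_a, config$locality),
        error = function(e) NULL)
      if (is.null(core_a)) next
      buffer_a <- if (n_core_a > 0L) nbrs(core_a) else integer(0)
      core_b <- tryCatch(
        grow_module(adj, seed_b, n_core_b, config$locality,
                    avoid = c(core_a, buffer_a)),
        error = function(e) NULL)
      if (is.null(core_b)) next
      if (config$n_shared == 0L) {
        shared <- integer(0)
      } else if (n_core_a > 0L && n_core_b > 0L) {
        pool <- setdiff(intersect(nbrs(core_a), nbrs(core_b)),
                        c(core_a, core_b))
        if (length(pool) < config$n_shared) next
        shared <- pool[sample.int(length(pool), config$n_shared)]
      } else {
        # one set nested in the other: shared cluster grown beside the
        # non-empty core (or anywhere if both cores are empty)
        anchor_core <- if (n_core_a > 0L) core_a else core_b
        start <- if (length(anchor_core) > 0L) {
          cand <- nbrs(anchor_core)
          cand[sample.int(length(cand), 1L)]
        } else sample.int(n, 1L)
        shared <- tryCatch(
          grow_module(adj, start, config$n_shared, config$locality,
                      avoid = c(core_a, core_b)),
          error = function(e) NULL)
        if (is.null(shared)) next
      }
      rest <- setdiff(seq_len(n), c(core_a, core_b, shared))
      n_sc_a <- n_ex_a - n_core_a
      n_sc_b <- n_ex_b - n_core_b
      if (length(rest) < n_sc_a + n_sc_b) next
      sc_a <- rest[sample.int(length(rest), n_sc_a)]
      rest <- setdiff(rest, sc_a)
      sc_b <- rest[sample.int(length(rest), n_sc_b)]
      out <- list(g_a = c(core_a, sc_a, shared), g_b = c(core_b, sc_b, shared),
                  shared = shared)
      break
    }
    out
  })
  if (is.null(res)) {
    stop("could not plant a disease pair: connector pool too small; ",
         "lower `locality`, n_shared, or enlarge the graph", call. = FALSE)
  }
  structure(list(g_a = sort_ids(nm[res$g_a]), g_b = sort_ids(nm[res$g_b]),
                 shared = sort_ids(nm[res$shared]), config = config),
            class = "planted_pair")
}

#' Generate a full synthetic benchmark
#'
#' Generates one synthetic interactome and plants `n_pairs` independent
#' disease pairs on it (per-pair seeds derived from `seed`), drawing a
#' synthetic comorbidity RR for each pair from a log-normal distribution
#' (meanlog 0.5, sdlog 1) that spans the usual stratification bins.  With
#' `dir` given, the benchmark is also written as `graph.tsv`, `assoc.tsv` and
#' `pairs.tsv` in the package's tabular formats; identical configurations
#' yield byte-identical files.
#'
#' @param n_pairs Number of planted disease pairs (labels `D<i>A` / `D<i>B`).
#' @param config Template [synthetic_config()]; per-pair configs reuse it
#'   with seeds `seed + 1, ..., seed + n_pairs`.
#' @param seed Master seed (defaults to `config$seed`).
#' @param dir Optional output directory (created if needed).
#' @return List of class `benchmark` with `graph`, `assoc` (named list),
#'   `pairs` (data frame `disease_a`, `disease_b`, `rr`), `planted` (list of
#'   `planted_pair`) and `dir`.
#' @export
make_benchmark <- function(n_pairs = 50L, config = synthetic_config(),
                           seed = config$seed, dir = NULL) {
  n_pairs <- as.integer(n_pairs)
  stopifnot(n_pairs >= 1L, inherits(config, "synthetic_config"))
  g <- generate_graph(config$n_nodes, config$attachment, seed = seed)
  rr <- withr::with_seed(seed, round(stats::rlnorm(n_pairs, meanlog = 0.5, sdlog = 1), 4))
  planted <- vector("list", n_pairs)
  assoc <- list()
  for (i in seq_len(n_pairs)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    cfg$rr <- rr[i]
    pp <- plant_pair(g, cfg)
    planted[[i]] <- pp
    assoc[[sprintf("D%03dA", i)]] <- pp$g_a
    assoc[[sprintf("D%03dB", i)]] <- pp$g_b
  }
  pairs <- data.frame(disease_a = sprintf("D%03dA", seq_len(n_pairs)),
                      disease_b = sprintf("D%03dB", seq_len(n_pairs)),
                      rr = rr, stringsAsFactors = FALSE)
  bench <- structure(list(graph = g, assoc = assoc, pairs = pairs,
                          planted = planted, dir = dir),
                     class = "benchmark")
  if (!is.null(dir)) write_benchmark(bench, dir)
  bench
}

#' Write a benchmark to disk
#'
#' Emits `graph.tsv` (edge list), `assoc.tsv` (disease, gene) and `pairs.tsv`
#' (disease_a, disease_b, rr) into `dir` in the formats read by
#' [load_interactome()], [load_associations()] and the CLI.
#'
#' @param bench A `benchmark` from [make_benchmark()].
#' @param dir Output directory.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(graph = file.path(dir, "graph.tsv"),
             assoc = file.path(dir, "assoc.tsv"),
             pairs = file.path(dir, "pairs.tsv"))
  write_interactome(bench$graph, paths[["graph"]])
  write_associations(bench$assoc, paths[["assoc"]])
  writeLines(paste(bench$pairs$disease_a, bench$pairs$disease_b,
                   sprintf("%.4f", bench$pairs$rr), sep = "\t"),
             paths[["pairs"]])
  invisible(paths)
}

#' Read a pairs table
#'
#' Columns: `disease_a`, `disease_b` and optionally `rr`.
#'
#' @inheritParams load_interactome
#' @return Data frame.
#' @export
load_pairs <- function(path, header = FALSE) {
  fields <- read_token_lines(path, header = header, what = "pairs")
  if (length(fields$tokens) == 0L) stop("pairs file '", path, "' is empty", call. = FALSE)
  bad <- which(lengths(fields$tokens) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s' at line %d: expected at least 2 fields",
                 path, fields$line_no[bad[1L]]), call. = FALSE)
  }
  data.frame(
    disease_a = vapply(fields$tokens, function(x) x[[1L]], character(1)),
    disease_b = vapply(fields$tokens, function(x) x[[2L]], character(1)),
    rr = vapply(fields$tokens, function(x)
      if (length(x) >= 3L) as.numeric(x[[3L]]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.planted_pair <- function(x, ...) {
  cat(sprintf("Planted pair: |G_A| = %d, |G_B| = %d, %d shared (locality %.2f, seed %d)\n",
              length(x$g_a), length(x$g_b), length(x$shared),
              x$config$locality, x$config$seed))
  invisible(x)
}

#' @export
print.benchmark <- function(x, ...) {
  cat(sprintf("Synthetic benchmark: %d pairs on %d-node graph (%d edges)\n",
              nrow(x$pairs), igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

# -- internal -----------------------------------------------------------------

# random walk with restart over an integer adjacency list; collects newly
# visited nodes (outside `avoid`) until `size` members are reached.  A node is
# absorbed only when adjacent to a current member, so the member set always
# induces a connected subgraph even when the walk traverses avoided nodes.
grow_module <- function(adj, seed_node, size, locality, avoid = integer(),
                        max_steps = 200000L) {
  members <- integer(0)
  if (size < 1L) return(members)
  if (!(seed_node %in% avoid)) members <- as.integer(seed_node)
  cur <- as.integer(seed_node)
  steps <- 0L
  while (length(members) < size && steps < max_steps) {
    steps <- steps + 1L
    if (stats::runif(1) < locality) {
      cur <- as.integer(seed_node)
    } else {
      nb <- adj[[cur]]
      cur <- nb[sample.int(length(nb), 1L)]
      if (!(cur %in% members) && !(cur %in% avoid) &&
          (length(members) == 0L || any(adj[[cur]] %in% members))) {
        members <- c(members, cur)
      }
    }
  }
  if (length(members) < size) {
    stop("random walk could not reach enough distinct nodes; lower `locality` or enlarge the graph",
         call. = FALSE)
  }
  members
}
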