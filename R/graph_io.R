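#' Read an interactome edge list
#'
#' Reads an undirected, unweighted protein-protein interaction network from a
#' whitespace- or tab-separated edge list.  The first two fields of each line
#' are the endpoints; extra fields are ignored.  Lines starting with `#` are
#' comments.  Gene identifiers are treated as opaque strings (Entrez ids are
#' *not* parsed as integers).  Self-loops are discarded (the node is kept) and
#' duplicate unordered pairs are collapsed; counts of both are reported via
#' [message()].
#'
#' @param path Path to the edge-list file.
#' @param header Logical; if `TRUE` the first non-comment line is skipped.
#' @return An undirected [igraph::igraph] object whose vertices carry gene
#'   identifiers in the `name` attribute.
#' @seealso [load_associations()], [largest_connected_component()]
#' @export
load_interactome <- function(path, header = FALSE) {
  fields <- read_token_lines(path, header = header, what = "interactome")
  n_lines <- length(fields$tokens)
  if (n_lines == 0L) {
    stop("interactome file '", path, "' contains no edges", call. = FALSE)
  }
  bad <- which(lengths(fields$tokens) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s' at line %d: expected at least 2 fields",
                 path, fields$line_no[bad[1L]]), call. = FALSE)
  }
  a <- vapply(fields$tokens, function(x) x[[1L]], character(1))
  b <- vapply(fields$tokens, function(x) x[[2L]], character(1))
  nodes <- sort_ids(unique(c(a, b)))
  loop <- a == b
  n_loops <- sum(loop)
  a <- a[!loop]
  b <- b[!loop]
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  message(sprintf(
    "interactome '%s': %d lines read, %d nodes, %d edges kept, %d self-loops dropped, %d duplicates collapsed",
    path, n_lines, length(nodes), igraph::ecount(g), n_loops, n_dup))
  g
}

#' Read disease-gene associations
#'
#' Reads a two-column table (`disease<TAB>gene`, whitespace also accepted) into
#' a named list mapping each disease label to its set of associated gene
#' identifiers.  Duplicate (disease, gene) rows are collapsed and surrounding
#' whitespace in identifiers is trimmed.
#'
#' @inheritParams load_interactome
#' @return Named list of character vectors; names are disease labels, each
#'   vector the sorted set of associated gene ids.
#' @export
load_associations <- function(path, header = FALSE) {
  fields <- read_token_lines(path, header = header, what = "associations")
  if (length(fields$tokens) == 0L) {
    stop("association file '", path, "' is empty", call. = FALSE)
  }
  bad <- which(lengths(fields$tokens) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s' at line %d: expected 2 fields (disease, gene)",
                 path, fields$line_no[bad[1L]]), call. = FALSE)
  }
  disease <- trimws(vapply(fields$tokens, function(x) x[[1L]], character(1)))
  gene <- trimws(vapply(fields$tokens, function(x) x[[2L]], character(1)))
  if (any(!nzchar(gene))) {
    stop("disease '", disease[which(!nzchar(gene))[1L]],
         "' has an empty gene identifier", call. = FALSE)
  }
  keep <- !duplicated(paste(disease, gene, sep = "\r"))
  n_dup <- sum(!keep)
  assoc <- split(gene[keep], disease[keep])
  assoc <- lapply(assoc, sort_ids)
  empty <- names(assoc)[lengths(assoc) == 0L]
  if (length(empty) > 0L) {
    stop("disease '", empty[1L], "' has no parsed genes", call. = FALSE)
  }
  message(sprintf(
    "associations '%s': %d rows read, %d diseases, %d duplicate rows collapsed",
    path, length(fields$tokens), length(assoc), n_dup))
  assoc[sort_ids(names(assoc))]
}

#' Map a gene set onto the interactome
#'
#' Partitions a disease's associated genes into those present in the
#' interactome and those absent from it.  Dropped genes are reported with a
#' warning; an empty in-graph set is allowed here and rejected downstream where
#' a module or separation is actually required.
#'
#' @param g Interactome graph from [load_interactome()].
#' @param genes Character vector of gene identifiers.
#' @param disease Optional disease label carried along for reporting.
#' @return A list of class `mapped_genes` with elements `disease`, `in_graph`
#'   and `dropped` (both sorted character vectors).
#' @export
map_to_graph <- function(g, genes, disease = NA_character_) {
  stopifnot(igraph::is_igraph(g))
  genes <- sort_ids(unique(as.character(genes)))
  present <- genes %in% igraph::V(g)$name
  dropped <- genes[!present]
  if (length(dropped) > 0L) {
    warning(sprintf("%s: %d of %d genes absent from the interactome",
                    if (is.na(disease)) "gene set" else disease,
                    length(dropped), length(genes)), call. = FALSE)
  }
  structure(list(disease = disease, in_graph = genes[present], dropped = dropped),
            class = "mapped_genes")
}

#' Extract the disease module (largest connected component)
#'
#' The disease module is the largest connected component of the subgraph
#' induced on the interactome by a disease's mapped genes.  Size ties are
#' broken deterministically towards the component whose sorted member list is
#' lexicographically smallest.
#'
#' @inheritParams map_to_graph
#' @param genes Non-empty character vector of gene ids, all present in `g`.
#' @return A list of class `disease_module` with elements `disease`, `members`
#'   (sorted gene ids of the component) and `n_associated` (number of input
#'   genes).
#' @export
largest_connected_component <- function(g, genes, disease = NA_character_) {
  stopifnot(igraph::is_igraph(g))
  genes <- sort_ids(unique(as.character(genes)))
  if (length(genes) == 0L) stop("empty gene set: no module to extract", call. = FALSE)
  missing <- setdiff(genes, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("gene(s) not in interactome: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  sub <- igraph::induced_subgraph(g, genes)
  comp <- igraph::components(sub)
  max_size <- max(comp$csize)
  tied <- which(comp$csize == max_size)
  # disjoint components: the lexicographically smallest sorted member list is
  # the one containing the smallest member overall
  reps <- vapply(tied, function(i) {
    sort_ids(igraph::V(sub)$name[comp$membership == i])[1L]
  }, character(1))
  win <- tied[order(reps, method = "radix")[1L]]
  members <- sort_ids(igraph::V(sub)$name[comp$membership == win])
  structure(list(disease = disease, members = members, n_associated = length(genes)),
            class = "disease_module")
}

#' Fraction of associated genes inside the module
#'
#' The size of the largest connected component as a fraction of the number of
#' associated genes mapped onto the graph.  Used with [qualifies_as_module()]
#' as a configurable stand-in for dataset-specific module-qualification
#' thresholds.
#'
#' @param module A `disease_module` from [largest_connected_component()].
#' @return Numeric fraction in `[0, 1]`.
#' @export
module_fraction <- function(module) {
  stopifnot(inherits(module, "disease_module"))
  if (module$n_associated < 1L) stop("module has no associated genes", call. = FALSE)
  length(module$members) / module$n_associated
}

#' Does a component qualify as a disease module?
#'
#' Configurable size check: minimum absolute component size (default 2) and
#' minimum fraction of associated genes (default 0, i.e. off).
#'
#' @inheritParams module_fraction
#' @param min_size Minimum number of module members.
#' @param min_fraction Minimum value of [module_fraction()].
#' @return Logical scalar.
#' @export
qualifies_as_module <- function(module, min_size = 2L, min_fraction = 0) {
  length(module$members) >= min_size && module_fraction(module) >= min_fraction
}

#' @export
print.disease_module <- function(x, ...) {
  cat(sprintf("Disease module%s: %d members of %d associated genes (%.1f%%)\n",
              if (is.na(x$disease)) "" else paste0(" '", x$disease, "'"),
              length(x$members), x$n_associated, 100 * module_fraction(x)))
  invisible(x)
}

#' @export
print.mapped_genes <- function(x, ...) {
  cat(sprintf("Mapped gene set%s: %d in graph, %d dropped\n",
              if (is.na(x$disease)) "" else paste0(" '", x$disease, "'"),
              length(x$in_graph), length(x$dropped)))
  invisible(x)
}

#' Write an interactome edge list
#'
#' @param g Interactome graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Write a disease-gene association table
#'
#' @param assoc Named list of gene-id vectors as returned by
#'   [load_associations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  lines <- unlist(lapply(names(assoc), function(d) paste(d, assoc[[d]], sep = "\t")),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

# locale-independent deterministic ordering of identifiers
sort_ids <- function(x) sort(x, method = "radix")

# read a tabular text file into per-line token lists, skipping '#' comments,
# blank lines and (optionally) one header row; keeps original line numbers
read_token_lines <- function(path, header = FALSE, what = "file") {
  if (!file.exists(path)) {
    stop(sprintf("cannot read %s file: '%s' does not exist", what, path),
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines) > 0L) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  list(tokens = strsplit(trimws(lines), "\\s+"), line_no = line_no)
}
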