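#' Genes-only pathway graph
#'
#' A `gene_graph` is one biological pathway represented as an undirected,
#' unweighted, simple graph whose vertices are bare numeric NCBI gene
#' identifiers (organism prefixes such as `"hsa:"` are stripped on
#' construction). Compound, map and group nodes never appear; isolated genes
#' are retained because gene-level degree profiles count degree-zero
#' occurrences.
#'
#' @param edges two-column character matrix or data frame of gene-gene edges
#'   (may be `NULL` or zero-row for an edgeless graph).
#' @param nodes character vector of gene identifiers; the vertex set is the
#'   union of `nodes` and the endpoints of `edges`.
#' @param pathway_id pathway identifier string, e.g. `"hsa00220"`.
#' @param title free-text pathway title.
#' @param kegg_class top-level KEGG category (e.g. `"Metabolism"`) or `""`.
#' @return an object of class `gene_graph`: a list with fields `pathway_id`,
#'   `title`, `kegg_class` and `graph` (an undirected simple [igraph] graph
#'   with named vertices).
#' @examples
#' g <- gene_graph(edges = cbind(c("1", "2"), c("2", "3")), pathway_id = "p1")
#' gg_nodes(g)
#' @export
gene_graph <- function(edges = NULL, nodes = character(), pathway_id,
                       title = "", kegg_class = "") {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L && nrow(edges) > 0L)
    stop("`edges` must have two columns")
  storage.mode(edges) <- "character"
  labs <- unique(c(nodes, as.vector(edges)))
  labs <- strip_gene_prefix(labs)
  if (nrow(edges) > 0L) {
    edges[] <- strip_gene_prefix(as.vector(edges))
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]  # no self-loops
  }
  bad <- labs[!grepl("^[0-9]+$", labs)]
  if (length(bad))
    stop("node labels must be bare numeric gene IDs; offending: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(labs), name = labs)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, as.vector(t(edges)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(
    list(pathway_id = pathway_id, title = title, kegg_class = kegg_class,
         graph = g),
    class = "gene_graph")
}

# Strip a single "xxx:" organism/namespace prefix; mixed prefixes rejected.
strip_gene_prefix <- function(x) {
  if (!length(x)) return(x)
  pref <- sub("^([A-Za-z][A-Za-z0-9]*):.*$", "\\1", x)
  pref[pref == x] <- NA_character_
  seen <- unique(pref[!is.na(pref)])
  if (length(seen) > 1L)
    stop("mixed organism prefixes in gene IDs: ",
         paste(seen, collapse = ", "))
  sub("^[A-Za-z][A-Za-z0-9]*:", "", x)
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %s%s: %d genes, %d edges%s\n",
              x$pathway_id,
              if (nzchar(x$title)) paste0(" (", x$title, ")") else "",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (nzchar(x$kegg_class)) paste0(" [", x$kegg_class, "]")
              else ""))
  invisible(x)
}

#' Vertex and edge accessors for gene graphs
#'
#' @param x a `gene_graph`.
#' @return `gg_nodes()`: sorted character vector of gene IDs. `gg_edges()`:
#'   two-column character matrix of edges with each row ordered
#'   lexicographically and rows sorted, so two graphs have equal edge sets
#'   iff the matrices are identical.
#' @export
gg_nodes <- function(x) {
  stopifnot(inherits(x, "gene_graph"))
  sort(igraph::V(x$graph)$name)
}

#' @rdname gg_nodes
#' @export
gg_edges <- function(x) {
  stopifnot(inherits(x, "gene_graph"))
  el <- igraph::as_edgelist(x$graph, names = TRUE)
  if (nrow(el) == 0L)
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  dimnames(el) <- list(NULL, c("from", "to"))
  el
}

as_gene_graph <- function(x) {
  if (inherits(x, "gene_graph")) return(x)
  if (inherits(x, "igraph")) {
    el <- igraph::as_edgelist(x, names = TRUE)
    return(gene_graph(edges = el, nodes = igraph::V(x)$name,
                      pathway_id = "graph"))
  }
  stop("cannot interpret object of class ", class(x)[1L], " as a gene_graph")
}

#' Labeled collection of pathway graphs
#'
#' A `graph_set` groups the pathway graphs of one condition, disorder or
#' cluster under a label. Pathway IDs must be unique within a set.
#'
#' @param graphs list of [gene_graph] objects (non-empty).
#' @param label group name, e.g. `"CUD"` or `"clusterA"`.
#' @return an object of class `graph_set` with fields `label` and `graphs`
#'   (named by pathway ID).
#' @export
graph_set <- function(graphs, label) {
  stopifnot(is.list(graphs), is.character(label), length(label) == 1L)
  if (!length(graphs)) stop("a graph_set must contain at least one graph")
  ok <- vapply(graphs, inherits, logical(1L), what = "gene_graph")
  if (!all(ok)) stop("all elements of `graphs` must be gene_graph objects")
  ids <- vapply(graphs, function(g) g$pathway_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate pathway IDs in graph_set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(graphs) <- ids
  structure(list(label = label, graphs = graphs), class = "graph_set")
}

#' @export
print.graph_set <- function(x, ...) {
  nv <- vapply(x$graphs, function(g) igraph::vcount(g$graph), integer(1L))
  cat(sprintf("<graph_set> '%s': %d pathways (%d-%d genes each)\n",
              x$label, length(x$graphs), min(nv), max(nv)))
  invisible(x)
}

#' @export
length.graph_set <- function(x) length(x$graphs)

#' Pathway metadata of a graph set
#'
#' @param x a `graph_set`.
#' @return data frame with columns `pathway_id`, `title`, `kegg_class`.
#' @export
graph_set_metadata <- function(x) {
  stopifnot(inherits(x, "graph_set"))
  data.frame(
    pathway_id = vapply(x$graphs, `[[`, character(1L), "pathway_id"),
    title = vapply(x$graphs, `[[`, character(1L), "title"),
    kegg_class = vapply(x$graphs, `[[`, character(1L), "kegg_class"),
    row.names = NULL)
}

# Coerce a graph_set or bare list of gene_graph/igraph into a graph_set.
as_graph_set <- function(x, label = "set") {
  if (inherits(x, "graph_set")) return(x)
  if (is.list(x)) {
    gl <- lapply(x, as_gene_graph)
    ids <- vapply(gl, `[[`, character(1L), "pathway_id")
    dup <- duplicated(ids)
    if (any(dup))  # bare lists get positional IDs when ambiguous
      for (i in which(ids == "graph" | dup))
        gl[[i]]$pathway_id <- sprintf("%s_%03d", label, i)
    return(graph_set(gl, label))
  }
  stop("cannot interpret object of class ", class(x)[1L], " as a graph_set")
}
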