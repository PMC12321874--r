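#' Parse a KGML pathway document into a genes-only graph
#'
#' Converts a KEGG Markup Language (KGML) document into an undirected,
#' unweighted, simple gene-gene network keyed by bare NCBI gene IDs, the
#' graph contract of genes-only KGML parsers such as KNeXT:
#'
#' * every relation between entries yields an edge regardless of its subtype
#'   (activation, inhibition, binding, ...) because direction and sign are
#'   discarded anyway;
#' * `group` entries (complexes) are replaced by their component entries,
#'   each component inheriting all of the group's edges;
#' * chains of the form gene -- compound -- ... -- compound -- gene are
#'   contracted to direct gene-gene edges (transitive closure through
#'   compound-only intermediates), then compound nodes are removed;
#' * `map` and other non-gene entries are dropped together with their edges;
#' * entries naming several genes (`"hsa:10 hsa:20"`) are split into one node
#'   per gene, each inheriting every edge of the original entry;
#' * self-loops and parallel edges arising from any of the above are removed;
#' * gene entries left without edges are kept as isolated vertices.
#'
#' @param x path to a KGML file, or a KGML XML string, or an `xml2` document.
#' @return a [gene_graph]. A document with no gene entries yields an empty
#'   graph with a warning.
#' @export
parse_kgml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  if (xml2::xml_name(doc) != "pathway")
    stop("not a KGML document: root element is <", xml2::xml_name(doc), ">")
  pid <- sub("^path:", "", xml2::xml_attr(doc, "name"))
  if (is.na(pid)) pid <- ""
  title <- xml2::xml_attr(doc, "title")
  if (is.na(title)) title <- ""

  entries <- xml2::xml_find_all(doc, "./entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  comps <- lapply(entries, function(e)
    xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id"))
  names(etype) <- names(ename) <- names(comps) <- eid

  if (!any(etype == "gene")) {
    warning("KGML document '", pid, "' contains no gene entries; ",
            "returning an empty graph")
    return(gene_graph(pathway_id = pid, title = title))
  }

  rels <- xml2::xml_find_all(doc, "./relation")
  redges <- cbind(xml2::xml_attr(rels, "entry1"),
                  xml2::xml_attr(rels, "entry2"))
  redges <- redges[!is.na(redges[, 1L]) & !is.na(redges[, 2L]), ,
                   drop = FALSE]

  # Recursively resolve an entry ID to its non-group constituents.
  expand_entry <- function(id, depth = 0L) {
    if (depth > 20L) stop("cyclic group nesting in KGML")
    if (!id %in% eid) return(character())   # dangling reference: drop
    if (etype[[id]] != "group") return(id)
    unlist(lapply(comps[[id]], expand_entry, depth = depth + 1L),
           use.names = FALSE)
  }
  expansion <- lapply(eid, expand_entry)
  names(expansion) <- eid

  # Rewrite relation endpoints through group expansion (cartesian product).
  exp_edges <- matrix(character(), ncol = 2L)
  if (nrow(redges) > 0L) {
    pieces <- lapply(seq_len(nrow(redges)), function(i) {
      a <- expansion[[redges[i, 1L]]]
      b <- expansion[[redges[i, 2L]]]
      if (!length(a) || !length(b)) return(NULL)
      as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
    if (length(pieces)) exp_edges <- do.call(rbind, pieces)
  }

  keep <- eid[etype %in% c("gene", "compound")]
  exp_edges <- exp_edges[exp_edges[, 1L] %in% keep &
                         exp_edges[, 2L] %in% keep &
                         exp_edges[, 1L] != exp_edges[, 2L], , drop = FALSE]

  # Entry-level graph over gene and compound entries.
  eg <- igraph::make_empty_graph(n = 0, directed = FALSE)
  eg <- igraph::add_vertices(eg, length(keep), name = keep)
  if (nrow(exp_edges) > 0L)
    eg <- igraph::simplify(igraph::add_edges(eg, as.vector(t(exp_edges))))

  # Contract gene--compound--...--gene chains: within each connected
  # component of the compound-induced subgraph, all adjacent gene entries
  # become pairwise connected.
  cmpd <- keep[etype[keep] == "compound"]
  if (length(cmpd)) {
    sub <- igraph::induced_subgraph(eg, cmpd)
    memb <- igraph::components(sub)$membership
    new_edges <- list()
    for (cc in unique(memb)) {
      members <- names(memb)[memb == cc]
      nb <- unique(unlist(lapply(members, function(v)
        igraph::V(eg)$name[igraph::neighbors(eg, v)]), use.names = FALSE))
      nb <- setdiff(nb, cmpd)
      if (length(nb) >= 2L)
        new_edges[[length(new_edges) + 1L]] <- t(utils::combn(sort(nb), 2L))
    }
    if (length(new_edges))
      eg <- igraph::simplify(
        igraph::add_edges(eg, as.vector(t(do.call(rbind, new_edges)))))
    eg <- igraph::delete_vertices(eg, cmpd)
  }

  # Split multi-gene entries into individual gene nodes.
  genes_of <- lapply(ename[igraph::V(eg)$name],
                     function(nm) unique(strsplit(trimws(nm), "\\s+")[[1L]]))
  entry_edges <- igraph::as_edgelist(eg, names = TRUE)
  gene_edges <- matrix(character(), ncol = 2L)
  if (nrow(entry_edges) > 0L) {
    pieces <- lapply(seq_len(nrow(entry_edges)), function(i)
      as.matrix(expand.grid(genes_of[[entry_edges[i, 1L]]],
                            genes_of[[entry_edges[i, 2L]]],
                            stringsAsFactors = FALSE)))
    gene_edges <- do.call(rbind, pieces)
  }
  gene_graph(edges = gene_edges,
             nodes = unlist(genes_of, use.names = FALSE),
             pathway_id = pid, title = title)
}
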