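#' Read and write pathway graphs
#'
#' Two plain-text serializations are supported. The tab-separated edge list
#' carries one edge per line; `#`-prefixed comment lines record the pathway
#' ID, title, KEGG class and any isolated nodes so that round-trips are
#' lossless (`read(write(g))` reproduces node and edge sets exactly). Plain
#' two-column files without comments are also accepted; a first line whose
#' fields are not gene IDs is treated as a header and skipped. GraphML goes
#' through [igraph] with the pathway metadata stored as graph attributes.
#'
#' @param x a [gene_graph].
#' @param path file to write to / read from.
#' @param format `"edge_list"` or `"graphml"`; on reading, guessed from the
#'   file extension when not given.
#' @return `write_gene_graph()` returns `path` invisibly;
#'   `read_gene_graph()` returns a [gene_graph].
#' @export
write_gene_graph <- function(x, path, format = c("edge_list", "graphml")) {
  stopifnot(inherits(x, "gene_graph"))
  format <- match.arg(format)
  if (format == "edge_list") {
    el <- gg_edges(x)
    iso <- setdiff(gg_nodes(x), unique(as.vector(el)))
    lines <- c(
      paste0("# pathway_id: ", x$pathway_id),
      if (nzchar(x$title)) paste0("# title: ", x$title),
      if (nzchar(x$kegg_class)) paste0("# kegg_class: ", x$kegg_class),
      if (length(iso)) paste0("# node: ", iso),
      if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t"))
    writeLines(lines, path)
  } else {
    g <- x$graph
    g <- igraph::set_graph_attr(g, "pathway_id", x$pathway_id)
    g <- igraph::set_graph_attr(g, "title", x$title)
    g <- igraph::set_graph_attr(g, "kegg_class", x$kegg_class)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_gene_graph
#' @export
read_gene_graph <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read graph file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "kgml")) "kgml"
      else if (ext == "graphml") "graphml" else "edge_list"
  }
  default_id <- tools::file_path_sans_ext(basename(path))
  if (format == "kgml") {
    g <- parse_kgml(path)
    if (!nzchar(g$pathway_id)) g$pathway_id <- default_id
    return(g)
  }
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    ga <- igraph::graph_attr(ig)
    pid <- if (!is.null(ga$pathway_id)) ga$pathway_id else default_id
    return(gene_graph(edges = igraph::as_edgelist(ig, names = TRUE),
                      nodes = igraph::V(ig)$name, pathway_id = pid,
                      title = if (is.null(ga$title)) "" else ga$title,
                      kegg_class = if (is.null(ga$kegg_class)) ""
                                   else ga$kegg_class))
  }
  lines <- readLines(path)
  com <- grepl("^\\s*#", lines)
  meta <- sub("^\\s*#\\s*", "", lines[com])
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1L])) else ""
  }
  iso <- trimws(sub("^node:", "", grep("^node:", meta, value = TRUE)))
  body <- lines[!com & nzchar(trimws(lines))]
  edges <- NULL
  if (length(body)) {
    parts <- strsplit(body, "[\t ]+")
    bad <- lengths(parts) < 2L
    if (any(bad)) stop("malformed edge list line in ", path, ": ",
                       body[which(bad)[1L]])
    edges <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
    # optional header row: fields that cannot be gene IDs
    is_id <- function(v) grepl("^([A-Za-z][A-Za-z0-9]*:)?[0-9]+$", v)
    if (!all(is_id(edges[1L, ])) && nrow(edges) >= 1L)
      edges <- edges[-1L, , drop = FALSE]
  }
  pid <- field("pathway_id")
  gene_graph(edges = edges, nodes = iso,
             pathway_id = if (nzchar(pid)) pid else default_id,
             title = field("title"), kegg_class = field("kegg_class"))
}

#' Load a labeled collection of pathway graphs from files
#'
#' Accepts any mix of KGML (`.xml`/`.kgml`), tab-separated edge list, and
#' GraphML files, or a directory containing them. An optional metadata table
#' attaches KEGG class (and title) per pathway; pathways missing from the
#' table keep an empty class with a warning.
#'
#' @param paths character vector of file paths, or a single directory.
#' @param label group label for the resulting set.
#' @param metadata optional data frame with columns `pathway_id`,
#'   `kegg_class` and optionally `title`.
#' @return a [graph_set].
#' @export
load_graph_set <- function(paths, label, metadata = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, full.names = TRUE,
                             pattern = "\\.(xml|kgml|graphml|tsv|txt|edges)$"))
  if (!length(paths)) stop("no graph files to load")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("cannot read graph file: ", missing[1L])
  graphs <- lapply(paths, read_gene_graph)
  if (!is.null(metadata)) {
    stopifnot(all(c("pathway_id", "kegg_class") %in% names(metadata)))
    for (i in seq_along(graphs)) {
      j <- match(graphs[[i]]$pathway_id, metadata$pathway_id)
      if (is.na(j)) {
        warning("no metadata for pathway ", graphs[[i]]$pathway_id,
                "; kegg_class left empty")
      } else {
        graphs[[i]]$kegg_class <- as.character(metadata$kegg_class[j])
        if ("title" %in% names(metadata) &&
            !is.na(metadata$title[j]) && nzchar(metadata$title[j]))
          graphs[[i]]$title <- as.character(metadata$title[j])
      }
    }
  }
  graph_set(graphs, label)
}
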