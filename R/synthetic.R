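# Synthetic gene IDs live at >= 900000 (backgrounds) and >= 990000
# (planted genes) so fixtures can never collide with real NCBI gene IDs.
SYNTH_GENE_BASE <- 900000L
PLANTED_GENE_BASE <- 990000L

#' Sample a set of graphs from a named random-graph model
#'
#' Seeded generator for the graph collections used to study the spectral
#' tests and clusterings: independent draws from one of five standard
#' models. Vertices are labeled with synthetic gene IDs (900001, 900002,
#' ...) so generated sets plug into every pathway-level operation.
#'
#' Models and their parameters:
#' * `erdos_renyi`: `n`, edge probability `p`;
#' * `k_regular`: `n`, degree `k` (`n * k` must be even);
#' * `watts_strogatz`: `n`, `k` nearest neighbors per side (degree `2k`),
#'   rewiring probability `p`;
#' * `ring_lattice`: `n`, `k` neighbors per side (a Watts-Strogatz graph
#'   with `p = 0`; deterministic);
#' * `barabasi_albert`: `n`, `m` edges attached per incoming vertex.
#'
#' @param model model name (see above).
#' @param n_graphs number of independent draws.
#' @param n vertices per graph.
#' @param p,k,m model parameters as described above.
#' @param seed integer seed; draws are bit-reproducible given
#'   `(model parameters, seed)` and the caller's RNG is untouched.
#' @param label set label; pathway IDs are `<label>_001`, ...
#' @return a [graph_set] of `n_graphs` [gene_graph]s.
#' @export
sample_graph_set <- function(model = c("erdos_renyi", "k_regular",
                                       "watts_strogatz", "barabasi_albert",
                                       "ring_lattice"),
                             n_graphs, n, p = NULL, k = NULL, m = NULL,
                             seed = 1L, label = model) {
  model <- match.arg(model)
  label <- label[1L]
  stopifnot(n_graphs >= 1L, n >= 1L)
  draw <- switch(model,
    erdos_renyi = {
      stopifnot(!is.null(p), p >= 0, p <= 1)
      function() igraph::sample_gnp(n, p)
    },
    k_regular = {
      stopifnot(!is.null(k), k >= 0, k < n)
      if ((n * k) %% 2L != 0L)
        stop("k-regular graph infeasible: n * k must be even")
      function() igraph::sample_k_regular(n, k)
    },
    watts_strogatz = {
      stopifnot(!is.null(k), k >= 1, !is.null(p), p >= 0, p <= 1)
      function() igraph::sample_smallworld(1L, n, k, p)
    },
    ring_lattice = {
      stopifnot(!is.null(k), k >= 1)
      function() igraph::sample_smallworld(1L, n, k, 0)
    },
    barabasi_albert = {
      stopifnot(!is.null(m), m >= 1)
      function() igraph::sample_pa(n, m = m, directed = FALSE)
    })
  ids <- as.character(SYNTH_GENE_BASE + seq_len(n))
  graphs <- with_seed(seed, function() {
    lapply(seq_len(n_graphs), function(i) {
      g <- igraph::simplify(draw())
      igraph::V(g)$name <- ids
      gene_graph(edges = igraph::as_edgelist(g, names = TRUE), nodes = ids,
                 pathway_id = sprintf("%s_%03d", label, i))
    })
  })
  graph_set(graphs, label)
}

#' Two-cluster pathway collection with planted distinctive genes
#'
#' Builds the ground-truthed fixture for gene prioritization: two clusters
#' of Erdős–Rényi "pathways" over one shared background gene pool, plus
#' `n_planted` extra genes whose degree is pinned at `degree_a` in every
#' cluster-A pathway that hosts them and `degree_b` in cluster B. Each
#' planted gene appears in the first pathway of each cluster (which hosts
#' *all* planted genes) and in the even-numbered pathways, so host and
#' non-host pathways both exist and each planted gene accrues several
#' degree observations per cluster. Planted genes attach to a uniform
#' random sample of background nodes of exactly the target size, leaving
#' the background structure intact.
#'
#' @param n_pathways pathways per cluster (default 8).
#' @param n background genes per pathway (default 30).
#' @param p background edge probability (default 0.15, a sparse
#'   pathway-like density).
#' @param n_planted number of planted genes (default 1).
#' @param degree_a,degree_b planted-gene degree in clusters A and B
#'   (defaults 2 and 12; equal values give the null construction with
#'   identical profiles and hence zero distinctiveness).
#' @param seed integer seed.
#' @return list with [graph_set]s `a` and `b` and `truth`: list of
#'   `planted_genes`, `host_pathways_a`, `host_pathways_b` (pathways
#'   containing planted genes; the first hosts all of them).
#' @export
build_planted_collection <- function(n_pathways = 8L, n = 30L, p = 0.15,
                                     n_planted = 1L, degree_a = 2L,
                                     degree_b = 12L, seed = 1L) {
  stopifnot(n_pathways >= 2L, n >= 2L, n_planted >= 1L)
  if (max(degree_a, degree_b) > n)
    stop("planted degree target exceeds the number of background genes")
  bg <- as.character(SYNTH_GENE_BASE + seq_len(n))
  planted <- as.character(PLANTED_GENE_BASE + seq_len(n_planted))
  hosts <- c(1L, seq(2L, n_pathways, by = 2L))
  build_cluster <- function(lab, target) {
    graphs <- lapply(seq_len(n_pathways), function(i) {
      g <- igraph::sample_gnp(n, p)
      igraph::V(g)$name <- bg
      el <- igraph::as_edgelist(g, names = TRUE)
      nodes <- bg
      if (i %in% hosts && target > 0L) {
        for (pg in planted) {
          anchors <- sample(bg, target)
          el <- rbind(el, cbind(rep(pg, target), anchors))
        }
        nodes <- c(bg, planted)
      } else if (i %in% hosts) nodes <- c(bg, planted)
      gene_graph(edges = el, nodes = nodes,
                 pathway_id = sprintf("%s_%03d", lab, i))
    })
    graph_set(graphs, lab)
  }
  res <- with_seed(seed, function()
    list(a = build_cluster("plantedA", degree_a),
         b = build_cluster("plantedB", degree_b)))
  host_ids <- function(gs) names(gs$graphs)[hosts]
  list(a = res$a, b = res$b,
       truth = list(planted_genes = planted,
                    host_pathways_a = host_ids(res$a),
                    host_pathways_b = host_ids(res$b)))
}

#' Miniature KGML document with its expected parsed graph
#'
#' Emits a well-formed KGML string that exercises every construct the
#' parser must normalize — chained gene relations, gene-compound-gene
#' bridges, group (complex) entries, and multi-gene entries — together with
#' the exactly expected genes-only [gene_graph]. Entry and relation order
#' are shuffled under `seed`, so re-parsing with different seeds checks
#' order independence of the construction.
#'
#' Layout: `n_genes` single-gene entries chained in a path; each compound
#' bridge adds two genes joined only through a compound; each group adds two
#' component genes that inherit the group's relation to the first chain
#' gene; each multi-gene entry adds two genes sharing one entry related to
#' the first chain gene.
#'
#' @param n_genes chain length (>= 1).
#' @param n_compound_bridges,n_groups,n_multi counts of each construct
#'   (>= 0).
#' @param seed shuffle seed.
#' @param pathway_id identifier embedded in the document.
#' @return list with `kgml` (XML string) and `expected` ([gene_graph]).
#' @export
synth_kgml <- function(n_genes = 4L, n_compound_bridges = 1L, n_groups = 1L,
                       n_multi = 1L, seed = 1L, pathway_id = "hsa90001") {
  stopifnot(n_genes >= 1L)
  next_gene <- SYNTH_GENE_BASE
  new_genes <- function(k) {
    ids <- as.character(next_gene + seq_len(k))
    next_gene <<- next_gene + k
    ids
  }
  entries <- list(); relations <- list(); eid <- 0L
  exp_edges <- NULL
  add_entry <- function(type, name, components = NULL) {
    eid <<- eid + 1L
    entries[[length(entries) + 1L]] <<-
      list(id = as.character(eid), type = type, name = name,
           components = components)
    as.character(eid)
  }
  add_rel <- function(a, b)
    relations[[length(relations) + 1L]] <<- c(a, b)

  chain <- new_genes(n_genes)
  chain_ids <- vapply(chain, function(g)
    add_entry("gene", paste0("hsa:", g)), character(1L))
  if (n_genes >= 2L)
    for (i in seq_len(n_genes - 1L)) {
      add_rel(chain_ids[i], chain_ids[i + 1L])
      exp_edges <- rbind(exp_edges, c(chain[i], chain[i + 1L]))
    }
  for (b in seq_len(max(n_compound_bridges, 0L))) {
    gs <- new_genes(2L)
    ga <- add_entry("gene", paste0("hsa:", gs[1L]))
    gb <- add_entry("gene", paste0("hsa:", gs[2L]))
    cp <- add_entry("compound", sprintf("cpd:C%05d", b))
    add_rel(ga, cp); add_rel(cp, gb)
    exp_edges <- rbind(exp_edges, gs)
  }
  for (grp in seq_len(max(n_groups, 0L))) {
    gs <- new_genes(2L)
    c1 <- add_entry("gene", paste0("hsa:", gs[1L]))
    c2 <- add_entry("gene", paste0("hsa:", gs[2L]))
    gid <- add_entry("group", "undefined", components = c(c1, c2))
    add_rel(gid, chain_ids[1L])
    exp_edges <- rbind(exp_edges, c(gs[1L], chain[1L]),
                       c(gs[2L], chain[1L]))
  }
  for (mm in seq_len(max(n_multi, 0L))) {
    gs <- new_genes(2L)
    me <- add_entry("gene", paste0("hsa:", gs, collapse = " "))
    add_rel(me, chain_ids[1L])
    exp_edges <- rbind(exp_edges, c(gs[1L], chain[1L]),
                       c(gs[2L], chain[1L]))
  }

  all_genes <- as.character(SYNTH_GENE_BASE +
                            seq_len(next_gene - SYNTH_GENE_BASE))
  ord <- with_seed(seed, function()
    list(e = sample(seq_along(entries)), r = sample(seq_along(relations))))
  entry_xml <- vapply(entries[ord$e], function(e) {
    comp <- if (!is.null(e$components))
      paste0("\n    <component id=\"", e$components, "\"/>", collapse = "")
    else ""
    sprintf("  <entry id=\"%s\" name=\"%s\" type=\"%s\">%s\n  </entry>",
            e$id, e$name, e$type, comp)
  }, character(1L))
  rel_xml <- vapply(relations[ord$r], function(r)
    sprintf(paste0("  <relation entry1=\"%s\" entry2=\"%s\" ",
                   "type=\"PPrel\">\n    <subtype name=\"activation\" ",
                   "value=\"--&gt;\"/>\n  </relation>"), r[1L], r[2L]),
    character(1L))
  kgml <- paste0(
    "<?xml version=\"1.0\"?>\n",
    sprintf("<pathway name=\"path:%s\" org=\"hsa\" number=\"90001\" title=\"synthetic fixture\">\n",
            pathway_id),
    paste(c(entry_xml, rel_xml), collapse = "\n"),
    "\n</pathway>\n")
  list(kgml = kgml,
       expected = gene_graph(edges = exp_edges, nodes = all_genes,
                             pathway_id = pathway_id,
                             title = "synthetic fixture"))
}
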