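#' Pairwise spectral (JS) distance matrix for a graph collection
#'
#' Each graph's adjacency spectrum is smoothed on one grid shared by the
#' pooled collection; the distance between two graphs is the Jensen-Shannon
#' *distance* (square root of the JS divergence, nats) between their
#' spectral densities.
#'
#' @param graphs a [graph_set] (or list of graphs) with at least 2 members.
#' @param n_points spectral grid resolution (default 512).
#' @param scale compare `1/sqrt(n)`-scaled spectra if `TRUE`.
#' @return symmetric numeric matrix with zero diagonal; `dimnames` are the
#'   pathway IDs.
#' @export
spectral_distance_matrix <- function(graphs, n_points = 512L, scale = FALSE) {
  gs <- as_graph_set(graphs)
  if (length(gs) < 2L) stop("need at least 2 graphs for a distance matrix")
  pd <- pooled_density_matrix(unname(gs$graphs), n_points = n_points,
                              scale = scale)
  prob_distance_matrix(pd$probs, names(gs$graphs))
}

prob_distance_matrix <- function(P, ids) {
  n <- ncol(P)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- sqrt(max(js_prob(P[, i], P[, j]), 0))
  D
}

#' Connectivity-baseline distance matrices
#'
#' Baselines against which spectral clustering is compared: per graph, the
#' node-level distribution of a connectivity index, with pairwise JS
#' distances between those distributions. `degree` uses the exact pmf on the
#' pooled integer degree support; `betweenness` and `closeness` are binned
#' into `n_bins` equal-width histograms over the pooled value range.
#' Closeness is computed within connected components; isolated vertices get
#' closeness 0. `scalar_summary = TRUE` instead reduces each graph to the
#' mean node value and uses absolute differences — the alternative reading
#' of an "average centrality" baseline.
#'
#' @param graphs a [graph_set] (or list of graphs), >= 2 members.
#' @param metric `"degree"`, `"betweenness"`, or `"closeness"`.
#' @param n_bins histogram resolution for the continuous metrics.
#' @param scalar_summary use per-graph mean values instead of distributions.
#' @return symmetric distance matrix as in [spectral_distance_matrix()].
#' @export
feature_distance_matrix <- function(graphs,
                                    metric = c("degree", "betweenness",
                                               "closeness"),
                                    n_bins = 50L, scalar_summary = FALSE) {
  metric <- match.arg(metric)
  gs <- as_graph_set(graphs)
  if (length(gs) < 2L) stop("need at least 2 graphs for a distance matrix")
  vals <- lapply(gs$graphs, function(g) node_metric(g$graph, metric))
  ids <- names(gs$graphs)
  if (scalar_summary) {
    m <- vapply(vals, mean, numeric(1L))
    D <- abs(outer(m, m, "-"))
    dimnames(D) <- list(ids, ids)
    return(D)
  }
  if (metric == "degree") {
    support <- 0:max(unlist(vals))
    P <- vapply(vals, function(v)
      tabulate(v + 1L, nbins = length(support)) / length(v),
      numeric(length(support)))
  } else {
    rng <- range(unlist(vals))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    P <- vapply(vals, function(v) {
      h <- findInterval(v, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
      tabulate(h, nbins = n_bins) / length(v)
    }, numeric(n_bins))
  }
  prob_distance_matrix(P, ids)
}

node_metric <- function(g, metric) {
  switch(metric,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE,
                                      normalized = TRUE),
    closeness = closeness_by_component(g))
}

# closeness within each connected component; isolated vertices score 0
closeness_by_component <- function(g) {
  memb <- igraph::components(g)$membership
  out <- numeric(igraph::vcount(g))
  for (cc in unique(memb)) {
    vs <- which(memb == cc)
    if (length(vs) == 1L) { out[vs] <- 0; next }
    sub <- igraph::induced_subgraph(g, vs)
    out[vs] <- igraph::closeness(sub, normalized = TRUE)
  }
  out
}

#' Agglomerative clustering of a distance matrix
#'
#' Complete-linkage (by default) hierarchical clustering via
#' [stats::hclust()], cut into `k` flat clusters.
#'
#' @param D symmetric distance matrix with IDs as dimnames (as produced by
#'   [spectral_distance_matrix()] or [feature_distance_matrix()]).
#' @param k number of flat clusters, `1 <= k <= nrow(D)` (default 2).
#' @param linkage agglomeration method passed to `hclust` (default
#'   `"complete"`).
#' @return object of class `cluster_labels`: list with `ids`, `labels`
#'   (integer assignments named by ID), `k`, `linkage` and `merge_tree` (the
#'   underlying `hclust` object).
#' @export
hierarchical_cluster <- function(D, k = 2L, linkage = "complete") {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  if (k < 1L || k > n) stop("`k` must be between 1 and the number of graphs")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(ids = rownames(D), labels = labels, k = as.integer(k),
                 linkage = linkage, merge_tree = hc),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> %d items in %d clusters (%s linkage)\n",
              length(x$labels), x$k, x$linkage))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings under the permutation
#' model; 1 for identical partitions (up to relabeling), about 0 for random
#' assignments, and possibly negative for worse-than-random agreement.
#' Delegates to [mclust::adjustedRandIndex()].
#'
#' @param labels_true,labels_pred equal-length label vectors (any type
#'   coercible to factor).
#' @return scalar ARI, at most 1.
#' @export
adjusted_rand_index <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors must have equal length")
  ari <- mclust::adjustedRandIndex(labels_true, labels_pred)
  # the denominator vanishes only when both partitions are all-singletons
  # or both a single cluster, i.e. identical pair structure: ARI = 1
  if (is.nan(ari)) 1 else ari
}

#' Compare spectral clustering against connectivity baselines
#'
#' Clusters the same pooled collection with the spectral JS distance and
#' with each of the degree / betweenness / closeness baseline distances,
#' under identical linkage and `k`, and scores each flat clustering against
#' the known group labels by ARI.
#'
#' @param graphs a [graph_set] or list of graphs (the pooled collection).
#' @param labels_true ground-truth group label per graph, in graph order.
#' @param k number of clusters (default 2).
#' @param linkage agglomeration method (default `"complete"`).
#' @param n_points,n_bins resolution parameters of the distances.
#' @return data frame with columns `method` and `ari`, sorted by descending
#'   ARI. If `labels_true` has a single distinct value the ARI is undefined
#'   and returned as `NA` with a warning.
#' @export
compare_methods <- function(graphs, labels_true, k = 2L,
                            linkage = "complete", n_points = 512L,
                            n_bins = 50L) {
  gs <- as_graph_set(graphs)
  if (length(labels_true) != length(gs))
    stop("`labels_true` must have one label per graph")
  degenerate <- length(unique(labels_true)) < 2L
  if (degenerate)
    warning("ground truth has a single group; ARI is undefined")
  mats <- c(
    list(spectral = spectral_distance_matrix(gs, n_points = n_points)),
    stats::setNames(lapply(c("degree", "betweenness", "closeness"),
                           function(m)
                             feature_distance_matrix(gs, m, n_bins = n_bins)),
                    c("degree", "betweenness", "closeness")))
  ari <- vapply(mats, function(D) {
    if (degenerate) return(NA_real_)
    cl <- hierarchical_cluster(D, k = k, linkage = linkage)
    adjusted_rand_index(labels_true, cl$labels)
  }, numeric(1L))
  out <- data.frame(method = names(ari), ari = unname(ari),
                    row.names = NULL)
  out[order(-out$ari), , drop = FALSE]
}
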