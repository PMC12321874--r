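# degrees of one gene across the pathways of a cluster that contain it
gene_degrees_in_cluster <- function(gene, cluster) {
  unlist(lapply(cluster$graphs, function(g) {
    if (gene %in% igraph::V(g$graph)$name)
      unname(igraph::degree(g$graph, v = gene))
  }), use.names = FALSE)
}

#' Per-cluster degree profile of a gene
#'
#' The empirical distribution of a gene's degree across the pathways of one
#' cluster that contain it, laid out on a shared integer support (normally
#' the union of degree values the gene attains in all clusters being
#' compared) and additively smoothed with `alpha` pseudocounts per support
#' point so every support value keeps positive mass — divergences against
#' this profile are then always finite.
#'
#' @param gene NCBI gene ID string.
#' @param cluster a [graph_set] (the pathways of one cluster).
#' @param support ordered integer degree support; defaults to the values
#'   observed in this cluster alone.
#' @param alpha pseudocount per support point (default 0.5).
#' @return object of class `degree_profile`: list with `gene`, `cluster`,
#'   `support`, `probabilities` (sums to one), `n_pathways`.
#' @export
gene_degree_profile <- function(gene, cluster, support = NULL, alpha = 0.5) {
  cluster <- as_graph_set(cluster)
  degs <- gene_degrees_in_cluster(gene, cluster)
  if (!length(degs))
    stop("gene ", gene, " is absent from every pathway of cluster '",
         cluster$label, "'")
  if (is.null(support)) support <- sort(unique(degs))
  if (!all(degs %in% support))
    stop("observed degrees outside the supplied support")
  counts <- vapply(support, function(s) sum(degs == s), numeric(1L))
  probs <- (counts + alpha) / sum(counts + alpha)
  structure(list(gene = gene, cluster = cluster$label, support = support,
                 probabilities = probs, n_pathways = length(degs)),
            class = "degree_profile")
}

#' Directional KL divergence of a gene's degree profile between two clusters
#'
#' Measures how distinctive gene `g`'s connectivity is in cluster `k`
#' relative to cluster `l`: the Kullback-Leibler divergence (nats) between
#' the gene's smoothed degree profiles in the two clusters, on the union of
#' the degree values it attains in either. Directional — swap the clusters
#' for the reverse comparison.
#'
#' @param gene NCBI gene ID string (must appear in both clusters).
#' @param cluster_k,cluster_l [graph_set]s.
#' @param alpha smoothing pseudocount (default 0.5).
#' @return non-negative scalar `KL_g[k, l]`.
#' @export
gene_kl <- function(gene, cluster_k, cluster_l, alpha = 0.5) {
  cluster_k <- as_graph_set(cluster_k); cluster_l <- as_graph_set(cluster_l)
  dk <- gene_degrees_in_cluster(gene, cluster_k)
  dl <- gene_degrees_in_cluster(gene, cluster_l)
  if (!length(dk) || !length(dl))
    stop("gene ", gene, " must be present in both clusters")
  support <- sort(unique(c(dk, dl)))
  pk <- gene_degree_profile(gene, cluster_k, support, alpha)
  pl <- gene_degree_profile(gene, cluster_l, support, alpha)
  kl_divergence(pk$probabilities, pl$probabilities)
}

#' Gene distinctiveness scores across clusters
#'
#' For every gene of every cluster, computes the KL divergence of its degree
#' profile against each other cluster and the distinctiveness score
#' `D^g[k] = min over l != k of KL_g[k, l]` — a gene is distinctive for its
#' cluster only if its connectivity differs from *every* other cluster. With
#' two clusters the minimum is the single available KL.
#'
#' Genes absent from some opposing cluster have no finite divergence there;
#' by default (`absent = "exclude"`) they are left out of the ranking. With
#' `absent = "unique"` a gene missing from *all* opposing clusters is
#' treated as maximally distinctive and assigned the largest finite score
#' plus `1`, flagged in the `unique_gene` column.
#'
#' @param clusters named list of [graph_set]s (>= 2).
#' @param alpha smoothing pseudocount (default 0.5).
#' @param absent policy for genes missing from opposing clusters.
#' @return data frame of class `gene_scores` with columns `gene`, `cluster`,
#'   `distinctiveness`, `unique_gene`, and one `kl_<label>` column per
#'   cluster (NA where not applicable).
#' @export
gene_scores <- function(clusters, alpha = 0.5,
                        absent = c("exclude", "unique")) {
  absent <- match.arg(absent)
  stopifnot(is.list(clusters), length(clusters) >= 2L)
  clusters <- lapply(clusters, as_graph_set)
  labs <- vapply(clusters, `[[`, character(1L), "label")
  if (anyDuplicated(labs)) stop("cluster labels must be unique")
  names(clusters) <- labs
  # gene -> degrees, per cluster, computed once
  degtab <- lapply(clusters, function(cl) {
    per_gene <- list()
    for (g in cl$graphs) {
      d <- igraph::degree(g$graph)
      for (gene in names(d))
        per_gene[[gene]] <- c(per_gene[[gene]], unname(d[[gene]]))
    }
    per_gene
  })
  rows <- list()
  for (k in labs) {
    others <- setdiff(labs, k)
    for (gene in sort(names(degtab[[k]]))) {
      kl <- stats::setNames(rep(NA_real_, length(others)), others)
      for (l in others) {
        dl <- degtab[[l]][[gene]]
        if (is.null(dl)) next
        dk <- degtab[[k]][[gene]]
        support <- sort(unique(c(dk, dl)))
        cnt <- function(d) vapply(support, function(s) sum(d == s),
                                  numeric(1L))
        pk <- (cnt(dk) + alpha) / sum(cnt(dk) + alpha)
        pl <- (cnt(dl) + alpha) / sum(cnt(dl) + alpha)
        kl[[l]] <- sum(pk * (log(pk) - log(pl)))
      }
      uniq <- all(is.na(kl))
      if (uniq && absent == "exclude") next
      kl_all <- stats::setNames(rep(NA_real_, length(labs)),
                                paste0("kl_", labs))
      kl_all[paste0("kl_", others)] <- kl
      rows[[length(rows) + 1L]] <- c(
        list(gene = gene, cluster = k,
             distinctiveness = if (uniq) NA_real_
                               else min(kl, na.rm = TRUE),
             unique_gene = uniq),
        as.list(kl_all))
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(gene = character(), cluster = character(),
                      distinctiveness = numeric(), unique_gene = logical())
  if (absent == "unique" && any(out$unique_gene)) {
    top <- suppressWarnings(max(out$distinctiveness, na.rm = TRUE))
    if (!is.finite(top)) top <- 0
    out$distinctiveness[out$unique_gene] <- top + 1
  }
  rownames(out) <- NULL
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Driving genes of a cluster
#'
#' Selects the set `D_k` of most distinctive genes of one cluster: the top
#' `n` by descending `D^g`, ordering ties by ascending gene ID and keeping
#' *all* genes tied with the score at the cutoff (so the set can exceed `n`).
#'
#' @param scores a `gene_scores` data frame from [gene_scores()].
#' @param cluster cluster label to select for.
#' @param n target set size (default 10).
#' @return object of class `driving_gene_set`: list with `cluster`, `genes`
#'   (character vector, ranked), `selection_rule`.
#' @export
top_driving_genes <- function(scores, cluster, n = 10L) {
  stopifnot(inherits(scores, "data.frame"))
  sc <- scores[scores$cluster == cluster & !is.na(scores$distinctiveness), ,
               drop = FALSE]
  if (!nrow(sc)) stop("no scored genes for cluster '", cluster, "'")
  sc <- sc[order(-sc$distinctiveness, sc$gene), , drop = FALSE]
  rule <- sprintf("top_n=%d", n)
  if (nrow(sc) <= n) {
    if (nrow(sc) < n)
      warning("cluster '", cluster, "' has only ", nrow(sc),
              " scored genes (requested ", n, "); returning all")
    genes <- sc$gene
  } else {
    cutoff <- sc$distinctiveness[n]
    keep <- sc$distinctiveness >= cutoff
    genes <- sc$gene[keep]
    if (sum(keep) > n)
      rule <- sprintf("top_n=%d (+%d tied at cutoff)", n, sum(keep) - n)
  }
  structure(list(cluster = cluster, genes = genes, selection_rule = rule),
            class = "driving_gene_set")
}

#' @export
print.driving_gene_set <- function(x, ...) {
  cat(sprintf("<driving_gene_set> cluster '%s' (%s): %s\n", x$cluster,
              x$selection_rule, paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Jaccard similarity between a driving-gene set and a pathway
#'
#' `J(D_k, S_k) = |D_k intersect S_k| / |D_k union S_k|`, where `S_k` is the
#' pathway's gene set. Both sets empty is defined as 0 with a warning.
#'
#' @param driving a [driving_gene_set] or character vector of gene IDs.
#' @param pathway a [gene_graph] (or character vector of gene IDs).
#' @return scalar in `[0, 1]`.
#' @export
pathway_jaccard <- function(driving, pathway) {
  d <- if (inherits(driving, "driving_gene_set")) driving$genes
       else as.character(driving)
  s <- if (inherits(pathway, "gene_graph")) gg_nodes(pathway)
       else as.character(pathway)
  u <- union(d, s)
  if (!length(u)) {
    warning("both gene sets empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(d, s)) / length(u)
}

#' Pathway fingerprint of a clustered collection
#'
#' The "network fingerprint" of a cluster: every pathway scored by the
#' Jaccard similarity between its gene set and the cluster's driving-gene
#' set `D_k`, one row per pathway, sorted by KEGG class and then descending
#' Jaccard. Pathways attaining the maximum Jaccard within their cluster are
#' flagged (the ones a figure would set in bold).
#'
#' @param clusters named list of [graph_set]s, one per cluster.
#' @param scores optional precomputed [gene_scores()] result; computed here
#'   when omitted.
#' @param metadata optional data frame (`pathway_id`, `kegg_class`)
#'   overriding the classes carried by the graphs; pathways with no class
#'   anywhere get `"unknown"`.
#' @param top_n driving-set size per cluster (default 10).
#' @param alpha,absent passed to [gene_scores()] when `scores` is omitted.
#' @return data frame of class `fingerprint` with columns `pathway_id`,
#'   `cluster`, `kegg_class`, `jaccard`, `flagged`, plus the driving sets in
#'   attribute `"driving"`.
#' @export
fingerprint <- function(clusters, scores = NULL, metadata = NULL,
                        top_n = 10L, alpha = 0.5, absent = "exclude") {
  clusters <- lapply(clusters, as_graph_set)
  labs <- vapply(clusters, `[[`, character(1L), "label")
  names(clusters) <- labs
  if (is.null(scores))
    scores <- gene_scores(clusters, alpha = alpha, absent = absent)
  driving <- lapply(labs, function(k) top_driving_genes(scores, k, top_n))
  names(driving) <- labs
  rows <- do.call(rbind, lapply(labs, function(k) {
    gs <- clusters[[k]]
    data.frame(
      pathway_id = names(gs$graphs),
      cluster = k,
      kegg_class = vapply(gs$graphs, `[[`, character(1L), "kegg_class"),
      jaccard = vapply(gs$graphs, function(g)
        pathway_jaccard(driving[[k]], g), numeric(1L)),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (!is.null(metadata)) {
    j <- match(rows$pathway_id, metadata$pathway_id)
    rows$kegg_class[!is.na(j)] <-
      as.character(metadata$kegg_class[j[!is.na(j)]])
  }
  rows$kegg_class[!nzchar(rows$kegg_class)] <- "unknown"
  mx <- stats::ave(rows$jaccard, rows$cluster, FUN = max)
  rows$flagged <- rows$jaccard == mx & rows$jaccard > 0
  rows <- rows[order(rows$kegg_class, -rows$jaccard, rows$pathway_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "driving") <- driving
  class(rows) <- c("fingerprint", "data.frame")
  rows
}

#' Difference between two pathway fingerprints
#'
#' Compares two fingerprints (e.g. two disorders scored against the same
#' reference): per shared pathway the signed (`a - b`) and absolute Jaccard
#' difference, sorted by magnitude, plus a per-KEGG-class aggregate (mean of
#' member differences).
#'
#' @param fp_a,fp_b [fingerprint()] results.
#' @return list with data frames `pathways` (`pathway_id`, `kegg_class`,
#'   `jaccard_a`, `jaccard_b`, `difference`, `abs_difference`) and `classes`
#'   (`kegg_class`, `mean_difference`, `mean_abs_difference`, `n`). Empty
#'   with a warning when the fingerprints share no pathway.
#' @export
fingerprint_difference <- function(fp_a, fp_b) {
  shared <- intersect(fp_a$pathway_id, fp_b$pathway_id)
  if (!length(shared)) {
    warning("fingerprints share no pathways; empty difference table")
    empty <- data.frame(pathway_id = character(), kegg_class = character(),
                        jaccard_a = numeric(), jaccard_b = numeric(),
                        difference = numeric(), abs_difference = numeric())
    return(list(pathways = empty,
                classes = data.frame(kegg_class = character(),
                                     mean_difference = numeric(),
                                     mean_abs_difference = numeric(),
                                     n = integer())))
  }
  ia <- match(shared, fp_a$pathway_id); ib <- match(shared, fp_b$pathway_id)
  pw <- data.frame(
    pathway_id = shared,
    kegg_class = fp_a$kegg_class[ia],
    jaccard_a = fp_a$jaccard[ia],
    jaccard_b = fp_b$jaccard[ib],
    stringsAsFactors = FALSE)
  pw$difference <- pw$jaccard_a - pw$jaccard_b
  pw$abs_difference <- abs(pw$difference)
  pw <- pw[order(-pw$abs_difference, pw$pathway_id), , drop = FALSE]
  rownames(pw) <- NULL
  agg <- do.call(rbind, lapply(split(pw, pw$kegg_class), function(d)
    data.frame(kegg_class = d$kegg_class[1L],
               mean_difference = mean(d$difference),
               mean_abs_difference = mean(d$abs_difference),
               n = nrow(d), stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$mean_abs_difference), , drop = FALSE]
  rownames(agg) <- NULL
  list(pathways = pw, classes = agg)
}
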