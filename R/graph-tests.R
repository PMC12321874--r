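# Per-graph spectral densities of a pooled collection on one shared grid.
# Returns the grid and a (n_points x n_graphs) matrix of probability
# vectors (densities times quadrature weights, renormalized). The grid is
# computed once from the pooled eigenvalues; permutation procedures must
# reuse it so that relabeled groups stay exchangeable.
pooled_density_matrix <- function(graphs, n_points = 512L, scale = FALSE) {
  eigs <- lapply(graphs, adjacency_spectrum, scale = scale)
  gr <- spectral_grid(eigs, n_points = n_points)
  P <- vapply(seq_along(eigs), function(i)
    as_prob(spectral_density(eigs[[i]], gr$grid, gr$bandwidths[i])),
    numeric(n_points))
  list(grid = gr$grid, probs = P)
}

# JS divergence between two probability vectors (no object wrapping),
# with a tiny floor so near-disjoint spectra keep finite log-ratios.
js_prob <- function(pv, qv, floor_at = 1e-12) {
  pv <- pmax(pv, floor_at); pv <- pv / sum(pv)
  qv <- pmax(qv, floor_at); qv <- qv / sum(qv)
  m <- (pv + qv) / 2
  (sum(pv * (log(pv) - log(m))) + sum(qv * (log(qv) - log(m)))) / 2
}

group_mean_probs <- function(P, idx) {
  if (length(idx) == 1L) P[, idx] else rowMeans(P[, idx, drop = FALSE])
}

new_graph_test <- function(method, statistic, p_value, n_permutations,
                           seed, group_sizes, null_statistics) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed,
                 group_sizes = group_sizes,
                 null_statistics = null_statistics),
            class = "graph_test")
}

#' @export
print.graph_test <- function(x, ...) {
  cat(sprintf(
    "<graph_test> %s: JS statistic = %.6g, p = %.4g (%d permutations, seed %d)\n",
    x$method, x$statistic, x$p_value, x$n_permutations, x$seed))
  cat("  group sizes:", paste(x$group_sizes, collapse = ", "), "\n")
  invisible(x)
}

# Run fn with a private, seeded RNG stream; the caller's RNG is untouched.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Two-set spectral permutation test
#'
#' Tests whether two sets of graphs are generated by the same random process.
#' The statistic is the Jensen-Shannon divergence (nats) between the mean
#' spectral densities of the two sets on a grid shared by the pooled
#' collection. The null distribution re-partitions the pooled graphs into
#' groups of the original sizes; per-graph densities are computed once, so a
#' permutation only re-averages columns. The p-value uses the add-one
#' estimator `p = (1 + #(perm >= obs)) / (n_permutations + 1)` and is never
#' zero.
#'
#' @param a,b [graph_set]s (or lists of graphs), each with at least 2 graphs.
#' @param n_permutations number of random re-partitions (default 1000).
#' @param seed integer seed for the permutation stream (default 1); the
#'   caller's RNG state is left untouched.
#' @param n_points spectral grid resolution.
#' @param scale pass `TRUE` to compare `1/sqrt(n)`-scaled spectra.
#' @return object of class `graph_test` with fields `statistic`, `p_value`,
#'   `n_permutations`, `seed`, `group_sizes`, `null_statistics`.
#' @export
takahashi_test <- function(a, b, n_permutations = 1000L, seed = 1L,
                           n_points = 512L, scale = FALSE) {
  a <- as_graph_set(a, "A"); b <- as_graph_set(b, "B")
  if (length(a) < 2L || length(b) < 2L)
    stop("each graph set must contain at least 2 graphs")
  na <- length(a); nb <- length(b)
  pd <- pooled_density_matrix(c(unname(a$graphs), unname(b$graphs)),
                              n_points = n_points, scale = scale)
  idx_a <- seq_len(na)
  obs <- js_prob(group_mean_probs(pd$probs, idx_a),
                 group_mean_probs(pd$probs, setdiff(seq_len(na + nb), idx_a)))
  null_stats <- with_seed(seed, function() {
    vapply(seq_len(n_permutations), function(i) {
      pa <- sample.int(na + nb, na)
      js_prob(group_mean_probs(pd$probs, pa),
              group_mean_probs(pd$probs, setdiff(seq_len(na + nb), pa)))
    }, numeric(1L))
  })
  p <- (1 + sum(null_stats >= obs)) / (n_permutations + 1)
  new_graph_test("takahashi", obs, p, as.integer(n_permutations),
                 as.integer(seed), c(na, nb), null_stats)
}

#' Multi-group spectral permutation test (analysis of graph variability)
#'
#' Generalizes [takahashi_test()] to `k >= 2` groups: the statistic is the
#' mean over groups of the JS divergence between each group's mean spectral
#' density and the grand mean density of the pooled collection. The null
#' shuffles group labels over the pooled graphs preserving group sizes.
#'
#' @param sets list of [graph_set]s (>= 2 groups, each >= 2 graphs).
#' @inheritParams takahashi_test
#' @return a `graph_test` object.
#' @export
anogva <- function(sets, n_permutations = 1000L, seed = 1L,
                   n_points = 512L, scale = FALSE) {
  stopifnot(is.list(sets))
  if (length(sets) < 2L) stop("anogva needs at least 2 groups")
  sets <- lapply(sets, as_graph_set)
  sizes <- vapply(sets, length, integer(1L))
  if (any(sizes < 2L)) stop("each group must contain at least 2 graphs")
  graphs <- unlist(lapply(sets, function(s) unname(s$graphs)),
                   recursive = FALSE)
  pd <- pooled_density_matrix(graphs, n_points = n_points, scale = scale)
  grand <- group_mean_probs(pd$probs, seq_len(sum(sizes)))
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  stat_for <- function(order_idx) {
    mean(vapply(seq_along(sizes), function(k)
      js_prob(group_mean_probs(pd$probs, order_idx[starts[k]:ends[k]]),
              grand), numeric(1L)))
  }
  obs <- stat_for(seq_len(sum(sizes)))
  null_stats <- with_seed(seed, function() {
    vapply(seq_len(n_permutations), function(i)
      stat_for(sample.int(sum(sizes))), numeric(1L))
  })
  p <- (1 + sum(null_stats >= obs)) / (n_permutations + 1)
  new_graph_test("anogva", obs, p, as.integer(n_permutations),
                 as.integer(seed), sizes, null_stats)
}
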