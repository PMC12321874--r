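#' Adjacency spectrum of a pathway graph
#'
#' Full (exact) eigendecomposition of the graph's adjacency matrix. For a
#' simple graph the eigenvalues are real, sum to zero (zero trace) and their
#' squares sum to twice the edge count.
#'
#' @param x a [gene_graph] or [igraph] graph with at least one vertex.
#' @param scale if `TRUE`, eigenvalues are divided by `sqrt(n)` so spectra of
#'   graphs of different orders live on comparable ranges; the default keeps
#'   raw adjacency eigenvalues.
#' @return numeric vector of `n` eigenvalues in ascending order.
#' @export
adjacency_spectrum <- function(x, scale = FALSE) {
  g <- if (inherits(x, "gene_graph")) x$graph else x
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n == 0L) stop("cannot compute the spectrum of an empty graph")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)
  if (scale) ev <- ev / sqrt(n)
  ev
}

#' Silverman's rule-of-thumb kernel bandwidth
#'
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`. When the IQR collapses to zero
#' on heavily tied samples the standard deviation is used instead (the usual
#' rule-of-thumb fallback chain); a fully constant sample gets the
#' documented floor bandwidth `1e-3` with a warning.
#'
#' @param x numeric sample (at least 2 values).
#' @return positive bandwidth.
#' @export
silverman_bandwidth <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  lo <- min(s, iqr / 1.34)
  if (lo == 0) lo <- s
  if (lo == 0) {
    warning("constant sample: falling back to bandwidth 1e-3")
    return(1e-3)
  }
  0.9 * lo * length(x)^(-1 / 5)
}

#' Kernel-smoothed spectral density on a fixed grid
#'
#' Gaussian kernel density estimate of a set of eigenvalues, evaluated on a
#' shared grid and renormalized so that its trapezoid-rule integral over the
#' grid equals one. Sharing the grid across every graph in a comparison is
#' what makes densities directly comparable by information divergences.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param grid strictly increasing numeric evaluation grid.
#' @param bandwidth positive kernel bandwidth (typically
#'   [silverman_bandwidth()] of the eigenvalues).
#' @return an object of class `spectral_density`: list with `grid`,
#'   `density`, `bandwidth`, `n_eigenvalues`.
#' @seealso [spectral_grid()] to build a pooled grid for a comparison set.
#' @export
spectral_density <- function(eigenvalues, grid, bandwidth) {
  stopifnot(is.numeric(eigenvalues), length(eigenvalues) >= 1L)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("`bandwidth` must be a positive scalar")
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing")
  z <- outer(grid, eigenvalues, "-") / bandwidth
  d <- rowSums(exp(-0.5 * z * z)) /
    (length(eigenvalues) * bandwidth * sqrt(2 * pi))
  total <- trapz(grid, d)
  if (total <= 0) stop("degenerate density: zero mass on the grid")
  structure(list(grid = grid, density = d / total, bandwidth = bandwidth,
                 n_eigenvalues = length(eigenvalues)),
            class = "spectral_density")
}

trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Shared evaluation grid for a pooled set of spectra
#'
#' @param eigenvalue_lists list of eigenvalue vectors (one per graph).
#' @param bandwidths per-graph bandwidths; by default Silverman's rule per
#'   graph.
#' @param n_points number of grid points (default 512).
#' @param pad grid extension beyond the pooled eigenvalue range, in units of
#'   the largest bandwidth (default 3, covering essentially all kernel mass).
#' @return list with `grid` (length `n_points`) and `bandwidths`. Bandwidths
#'   are floored at the grid spacing so that even a near-degenerate spectrum
#'   (e.g. an edgeless graph, all eigenvalues zero) keeps resolvable kernel
#'   mass on the shared grid.
#' @export
spectral_grid <- function(eigenvalue_lists, bandwidths = NULL,
                          n_points = 512L, pad = 3) {
  stopifnot(is.list(eigenvalue_lists), length(eigenvalue_lists) >= 1L)
  if (is.null(bandwidths))
    bandwidths <- vapply(eigenvalue_lists, function(e)
      if (length(e) < 2L) 1e-3
      else suppressWarnings(silverman_bandwidth(e)), numeric(1L))
  pooled <- unlist(eigenvalue_lists, use.names = FALSE)
  hmax <- max(bandwidths)
  grid <- seq(min(pooled) - pad * hmax, max(pooled) + pad * hmax,
              length.out = n_points)
  list(grid = grid, bandwidths = pmax(bandwidths, grid[2L] - grid[1L]))
}

#' Pointwise mean of spectral densities on a common grid
#'
#' @param densities list of [spectral_density] objects sharing one grid.
#' @return a `spectral_density` (renormalized mean; bandwidth is the mean of
#'   the constituents' bandwidths, kept for bookkeeping only).
#' @export
mean_density <- function(densities) {
  stopifnot(is.list(densities), length(densities) >= 1L)
  g0 <- densities[[1L]]$grid
  same <- vapply(densities, function(d) isTRUE(all.equal(d$grid, g0)),
                 logical(1L))
  if (!all(same)) stop("all densities must share an identical grid")
  m <- rowMeans(vapply(densities, `[[`, numeric(length(g0)), "density"))
  structure(list(grid = g0, density = m / trapz(g0, m),
                 bandwidth = mean(vapply(densities, `[[`, numeric(1L),
                                         "bandwidth")),
                 n_eigenvalues = sum(vapply(densities, `[[`, numeric(1L),
                                            "n_eigenvalues"))),
            class = "spectral_density")
}

#' Discrete probability distribution on an explicit support
#'
#' @param support ordered labels or numeric support points.
#' @param probabilities non-negative weights; normalized to sum to one.
#' @return object of class `discrete_distribution`.
#' @export
discrete_distribution <- function(support, probabilities) {
  stopifnot(length(support) == length(probabilities),
            all(probabilities >= 0), sum(probabilities) > 0)
  structure(list(support = support,
                 probabilities = probabilities / sum(probabilities)),
            class = "discrete_distribution")
}

# Extract a bare probability vector from the shapes divergences accept.
as_prob <- function(p, floor = 0) {
  v <- if (inherits(p, "discrete_distribution")) p$probabilities
    else if (inherits(p, "spectral_density")) {
      # trapezoid quadrature weights turn a gridded density into point masses
      w <- c(diff(p$grid), 0) / 2 + c(0, diff(p$grid)) / 2
      p$density * w
    } else if (is.numeric(p)) p
    else stop("cannot interpret object of class ", class(p)[1L],
              " as a probability distribution")
  if (any(v < 0)) stop("negative probabilities")
  if (floor > 0) v <- pmax(v, floor)
  v / sum(v)
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' `KL(p, q) = sum p * log(p / q)` in nats (or bits with `base = 2`); terms
#' with `p = 0` contribute zero. Errors when `q` has zero mass where `p` does
#' not — smooth `q` first (see [gene_degree_profile()] for the pseudocount
#' scheme used in gene scoring).
#'
#' @param p,q probability vectors, [discrete_distribution]s, or
#'   [spectral_density] objects on one common grid/support.
#' @param base logarithm base; `exp(1)` (nats, default) or `2` (bits).
#' @return non-negative scalar divergence.
#' @export
kl_divergence <- function(p, q, base = exp(1)) {
  pv <- as_prob(p); qv <- as_prob(q)
  if (length(pv) != length(qv))
    stop("distributions must share a common support")
  act <- pv > 0
  if (any(qv[act] == 0))
    stop("q has zero mass where p > 0; smooth q before computing KL")
  sum(pv[act] * (log(pv[act], base = base) - log(qv[act], base = base)))
}

#' Jensen-Shannon divergence and distance
#'
#' `JS(p, q) = KL(p, m)/2 + KL(q, m)/2` with `m = (p + q)/2`; symmetric,
#' bounded by `log(2)` in the chosen base, zero iff `p == q`. The JS
#' *distance* is its square root and satisfies the triangle inequality.
#' Gridded spectral densities are floored at `1e-12` before normalization so
#' near-disjoint spectra keep finite log-ratios.
#'
#' @inheritParams kl_divergence
#' @return scalar in `[0, log(2, base)]` (`js_divergence`) or its square
#'   root (`js_distance`).
#' @export
js_divergence <- function(p, q, base = exp(1)) {
  floor_at <- if (inherits(p, "spectral_density") ||
                  inherits(q, "spectral_density")) 1e-12 else 0
  pv <- as_prob(p, floor = floor_at)
  qv <- as_prob(q, floor = floor_at)
  if (length(pv) != length(qv))
    stop("distributions must share a common support")
  m <- (pv + qv) / 2
  js_terms(pv, m, base) / 2 + js_terms(qv, m, base) / 2
}

js_terms <- function(pv, m, base) {
  act <- pv > 0
  sum(pv[act] * (log(pv[act], base = base) - log(m[act], base = base)))
}

#' @rdname js_divergence
#' @export
js_distance <- function(p, q, base = exp(1)) {
  sqrt(max(js_divergence(p, q, base = base), 0))
}

#' Serialize a spectral density as a two-column CSV
#'
#' @param x a [spectral_density].
#' @param path output file.
#' @export
write_spectral_density <- function(x, path) {
  stopifnot(inherits(x, "spectral_density"))
  utils::write.csv(data.frame(grid = x$grid, density = x$density),
                   path, row.names = FALSE)
  invisible(path)
}
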