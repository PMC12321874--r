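# Named small graphs on numeric gene IDs 1..n.
make_complete <- function(n, id = paste0("K", n)) {
  gene_graph(edges = t(utils::combn(as.character(seq_len(n)), 2L)),
             pathway_id = id)
}
make_edgeless <- function(n, id = paste0("E", n)) {
  gene_graph(nodes = as.character(seq_len(n)), pathway_id = id)
}
make_path <- function(n, id = paste0("P", n)) {
  gene_graph(edges = cbind(as.character(seq_len(n - 1L)),
                           as.character(2:n)), pathway_id = id)
}
make_cycle <- function(n, id = paste0("C", n)) {
  gene_graph(edges = cbind(as.character(seq_len(n)),
                           as.character(c(2:n, 1L))), pathway_id = id)
}
make_star <- function(n, id = paste0("S", n)) {
  gene_graph(edges = cbind("1", as.character(2:n)), pathway_id = id)
}

random_gene_graph <- function(n, p, id) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  gene_graph(edges = igraph::as_edgelist(g, names = TRUE),
             nodes = as.character(seq_len(n)), pathway_id = id)
}

# Independent brute-force oracles -----------------------------------------

# direct per-kernel Gaussian summation (no vectorized shortcut)
kde_naive <- function(eigs, grid, h) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (e in eigs) s <- s + stats::dnorm((grid[i] - e) / h)
    out[i] <- s / (length(eigs) * h)
  }
  # trapezoid renormalization, mirroring the density contract
  w <- sum(diff(grid) * (out[-1] + out[-length(out)])) / 2
  out / w
}

kl_naive <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  s
}

js_naive <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl_naive(p, m) / 2 + kl_naive(q, m) / 2
}

# pair-counting adjusted Rand index
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)   # both partitions trivial
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# all set partitions of 1..n as integer label vectors
set_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    k <- max(p)
    for (lab in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, lab)
  }
  out
}
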