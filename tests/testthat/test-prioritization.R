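# two tiny clusters where gene "5" is degree-shifted and gene "1" is stable
two_tiny_clusters <- function() {
  pa1 <- gene_graph(edges = rbind(c("1", "2"), c("1", "5")),
                    nodes = c("3"), pathway_id = "a1")
  pa2 <- gene_graph(edges = rbind(c("1", "3"), c("1", "5")),
                    pathway_id = "a2")
  pb1 <- gene_graph(edges = rbind(c("1", "2"), c("5", "1"), c("5", "2"),
                                  c("5", "3")), pathway_id = "b1")
  pb2 <- gene_graph(edges = rbind(c("1", "3"), c("5", "1"), c("5", "2"),
                                  c("5", "3")), pathway_id = "b2")
  list(a = graph_set(list(pa1, pa2), "A"),
       b = graph_set(list(pb1, pb2), "B"))
}

test_that("degree profiles count, share support and smooth correctly", {
  cl <- two_tiny_clusters()
  # gene 5 has degree 1 in both cluster-A pathways: point mass pre-smoothing
  p <- gene_degree_profile("5", cl$a, alpha = 0)
  expect_equal(p$support, 1)
  expect_equal(p$probabilities, 1)
  expect_equal(p$n_pathways, 2L)
  # two distinct degrees -> (0.5, 0.5) pre-smoothing
  g <- gene_graph(edges = rbind(c("7", "1"), c("7", "2")),
                  pathway_id = "x1")
  h <- gene_graph(edges = rbind(c("7", "1"), c("7", "2"), c("7", "3"),
                                c("7", "4")), pathway_id = "x2")
  p2 <- gene_degree_profile("7", graph_set(list(g, h), "X"), alpha = 0)
  expect_equal(p2$support, c(2, 4))
  expect_equal(p2$probabilities, c(0.5, 0.5))
  # smoothing keeps every support point positive
  p3 <- gene_degree_profile("5", cl$a, support = 0:5, alpha = 0.5)
  expect_true(all(p3$probabilities > 0))
  expect_equal(sum(p3$probabilities), 1, tolerance = 1e-12)
  expect_error(gene_degree_profile("99", cl$a), "absent")
  expect_error(gene_degree_profile("5", cl$a, support = c(0, 2)),
               "outside the supplied support")
})

test_that("gene KL matches the hand-computed smoothed two-point value", {
  # gene always degree 1 in k (2 pathways), always degree 10 in l (2)
  mk <- function(deg, id) {
    others <- as.character(100 + seq_len(deg))
    gene_graph(edges = cbind("7", others),
               nodes = as.character(100 + 1:10), pathway_id = id)
  }
  k <- graph_set(list(mk(1, "k1"), mk(1, "k2")), "k")
  l <- graph_set(list(mk(10, "l1"), mk(10, "l2")), "l")
  # support {1,10}; smoothed profiles (2.5, 0.5)/3 and (0.5, 2.5)/3
  pk <- c(2.5, 0.5) / 3; pl <- c(0.5, 2.5) / 3
  expected <- sum(pk * log(pk / pl))
  expect_equal(gene_kl("7", k, l), expected, tolerance = 1e-12)
  # directionality: generally KL[k,l] != KL[l,k]
  k2 <- graph_set(list(mk(1, "k1"), mk(2, "k2"), mk(2, "k3")), "k2")
  l2 <- graph_set(list(mk(1, "l1"), mk(1, "l2"), mk(3, "l3")), "l2")
  expect_false(isTRUE(all.equal(gene_kl("7", k2, l2),
                                gene_kl("7", l2, k2))))
  # identical profiles across clusters diverge by exactly zero
  expect_equal(gene_kl("7", k, graph_set(list(mk(1, "m1"), mk(1, "m2")),
                                         "m")), 0, tolerance = 1e-12)
  expect_error(gene_kl("7", k, graph_set(list(make_complete(3)), "z")),
               "present in both")
})

test_that("distinctiveness is the minimum KL over opposing clusters", {
  cl <- two_tiny_clusters()
  sc <- gene_scores(list(cl$a, cl$b))
  expect_s3_class(sc, "data.frame")
  # two-cluster case: D^g equals the single directional KL
  for (g in c("1", "5")) {
    row <- sc[sc$gene == g & sc$cluster == "A", ]
    expect_equal(row$distinctiveness, gene_kl(g, cl$a, cl$b),
                 tolerance = 1e-12)
  }
  # the shifted gene is the most distinctive in both clusters
  for (k in c("A", "B")) {
    sck <- sc[sc$cluster == k, ]
    expect_equal(sck$gene[which.max(sck$distinctiveness)], "5")
  }
  expect_true(all(sc$distinctiveness >= 0))
  # three clusters: D^g = min of the pairwise KLs
  cl3 <- c(cl, list(c = graph_set(list(
    gene_graph(edges = rbind(c("1", "2"), c("5", "3")), pathway_id = "c1"),
    gene_graph(edges = rbind(c("1", "3"), c("5", "2")), pathway_id = "c2")),
    "C")))
  sc3 <- gene_scores(cl3)
  row <- sc3[sc3$gene == "5" & sc3$cluster == "A", ]
  expect_equal(row$distinctiveness, min(row$kl_B, row$kl_C),
               tolerance = 1e-12)
})

test_that("absent-gene policy excludes by default, can mark unique genes", {
  a <- graph_set(list(gene_graph(edges = rbind(c("1", "2"), c("8", "1")),
                                 pathway_id = "a1"),
                      gene_graph(edges = rbind(c("1", "2"), c("8", "2")),
                                 pathway_id = "a2")), "A")
  b <- graph_set(list(gene_graph(edges = rbind(c("1", "2")),
                                 pathway_id = "b1"),
                      gene_graph(edges = rbind(c("1", "2")),
                                 pathway_id = "b2")), "B")
  sc <- gene_scores(list(a, b))
  expect_false("8" %in% sc$gene[sc$cluster == "A"])
  scu <- gene_scores(list(a, b), absent = "unique")
  row <- scu[scu$gene == "8" & scu$cluster == "A", ]
  expect_true(row$unique_gene)
  expect_equal(row$distinctiveness,
               max(sc$distinctiveness, na.rm = TRUE) + 1)
})

test_that("driving-gene selection applies size, ties and warnings", {
  sc <- data.frame(
    gene = sprintf("%d", 1:12), cluster = "A",
    distinctiveness = c(5, 4, 3, 3, 3, 2, 2, 2, 2, 1, 1, 0.5),
    unique_gene = FALSE)
  d <- top_driving_genes(sc, "A", n = 10)
  # rank-10 score is 1; gene 11 ties at the cutoff and is included
  expect_length(d$genes, 11L)
  expect_match(d$selection_rule, "tied at cutoff")
  expect_equal(d$genes[1], "1")
  d3 <- top_driving_genes(sc, "A", n = 3)
  expect_equal(d3$genes, c("1", "2", "3", "4", "5"))  # cutoff ties kept
  expect_warning(dd <- top_driving_genes(sc[1:3, ], "A", n = 10),
                 "only 3")
  expect_length(dd$genes, 3L)
  expect_identical(top_driving_genes(sc, "A", n = 10)$genes, d$genes)
  expect_error(top_driving_genes(sc, "Z"), "no scored genes")
})

test_that("tie-breaking within equal scores is by ascending gene ID", {
  sc <- data.frame(gene = c("30", "4", "100"), cluster = "A",
                   distinctiveness = c(2, 2, 2), unique_gene = FALSE)
  d <- top_driving_genes(sc, "A", n = 2)
  expect_equal(d$genes, c("100", "30", "4"))  # all tied at cutoff, ID order
})

test_that("pathway Jaccard follows the set formula", {
  expect_equal(pathway_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(pathway_jaccard(c("1", "2"), make_complete(2)), 1)
  expect_equal(pathway_jaccard(c("9", "10"), make_complete(2)), 0)
  expect_equal(pathway_jaccard(c("b", "a"), c("a", "b")),
               pathway_jaccard(c("a", "b"), c("b", "a")))
  expect_warning(z <- pathway_jaccard(character(), character()),
                 "both gene sets empty")
  expect_equal(z, 0)
})

test_that("fingerprints conserve rows, sort by class and flag maxima", {
  cl <- two_tiny_clusters()
  cl$a$graphs[["a1"]]$kegg_class <- "Metabolism"
  fp <- fingerprint(list(cl$a, cl$b), top_n = 2)
  expect_equal(nrow(fp), 4L)
  expect_setequal(fp$pathway_id, c("a1", "a2", "b1", "b2"))
  expect_true(all(fp$jaccard >= 0 & fp$jaccard <= 1))
  expect_equal(fp$kegg_class[fp$pathway_id == "a1"], "Metabolism")
  expect_true(all(fp$kegg_class[fp$pathway_id != "a1"] == "unknown"))
  # within (cluster, class) blocks rows sort by descending jaccard
  expect_false(is.unsorted(fp$kegg_class[fp$cluster == "A"] == "unknown"))
  for (k in unique(fp$cluster)) {
    sub <- fp[fp$cluster == k, ]
    expect_true(all(sub$jaccard[sub$flagged] == max(sub$jaccard)))
  }
  # metadata argument overrides carried classes
  fp2 <- fingerprint(list(cl$a, cl$b), top_n = 2,
                     metadata = data.frame(pathway_id = "b1",
                                           kegg_class = "Human Diseases"))
  expect_equal(fp2$kegg_class[fp2$pathway_id == "b1"], "Human Diseases")
})

test_that("adding a pathway without driving genes never lifts other Jaccards", {
  cl <- two_tiny_clusters()
  fp1 <- fingerprint(list(cl$a, cl$b), top_n = 2)
  extra <- gene_graph(edges = rbind(c("700", "701")), pathway_id = "a9")
  a2 <- graph_set(c(cl$a$graphs, list(a9 = extra)), "A")
  sc <- gene_scores(list(cl$a, cl$b))   # same scores, same driving genes
  fp2 <- fingerprint(list(a2, cl$b), scores = sc, top_n = 2)
  for (pid in fp1$pathway_id)
    expect_lte(fp2$jaccard[fp2$pathway_id == pid],
               fp1$jaccard[fp1$pathway_id == pid] + 1e-12)
})

test_that("fingerprint differences subtract, aggregate and warn", {
  cl <- two_tiny_clusters()
  fp <- fingerprint(list(cl$a, cl$b), top_n = 2)
  d0 <- fingerprint_difference(fp, fp)
  expect_true(all(d0$pathways$difference == 0))
  expect_true(all(d0$classes$mean_abs_difference == 0))
  fpb <- fp; fpb$jaccard[fpb$pathway_id == "a1"] <- fp$jaccard[
    fp$pathway_id == "a1"] - 0.3
  d <- fingerprint_difference(fp, fpb)
  expect_equal(d$pathways$difference[d$pathways$pathway_id == "a1"], 0.3,
               tolerance = 1e-12)
  expect_equal(d$pathways$pathway_id[1], "a1")  # sorted by magnitude
  # class aggregate equals the mean of member differences
  for (cls in d$classes$kegg_class) {
    mem <- d$pathways[d$pathways$kegg_class == cls, ]
    expect_equal(d$classes$mean_difference[d$classes$kegg_class == cls],
                 mean(mem$difference), tolerance = 1e-12)
  }
  other <- fp; other$pathway_id <- paste0("z", other$pathway_id)
  expect_warning(dn <- fingerprint_difference(fp, other), "share no")
  expect_equal(nrow(dn$pathways), 0L)
})

test_that("planted degree shifts are recovered end to end", {
  hits <- 0L
  for (i in 1:10) {
    pc <- build_planted_collection(seed = 100 + i)
    sc <- gene_scores(list(pc$a, pc$b))
    ska <- sc[sc$cluster == "plantedA", ]
    top <- ska$gene[which.max(ska$distinctiveness)]
    fp <- fingerprint(list(pc$a, pc$b), scores = sc)
    fa <- fp[fp$cluster == "plantedA", ]
    best <- fa$pathway_id[which.max(fa$jaccard)]
    if (top == pc$truth$planted_genes[1] &&
        best %in% pc$truth$host_pathways_a) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
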