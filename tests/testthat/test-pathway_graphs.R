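test_that("a minimal two-gene KGML document parses to one edge", {
  kgml <- paste0(
    '<pathway name="path:hsa00001" title="mini">',
    '<entry id="1" name="hsa:1234" type="gene"/>',
    '<entry id="2" name="hsa:5678" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '</pathway>')
  g <- parse_kgml(kgml)
  expect_equal(gg_nodes(g), c("1234", "5678"))
  expect_equal(gg_edges(g),
               matrix(c("1234", "5678"), 1,
                      dimnames = list(NULL, c("from", "to"))))
  expect_equal(g$pathway_id, "hsa00001")
  expect_equal(g$title, "mini")
})

test_that("gene-compound-gene chains contract to direct edges", {
  kgml <- paste0(
    '<pathway name="path:hsa00002">',
    '<entry id="1" name="hsa:11" type="gene"/>',
    '<entry id="2" name="cpd:C00001" type="compound"/>',
    '<entry id="3" name="hsa:22" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PCrel"/>',
    '<relation entry1="2" entry2="3" type="PCrel"/>',
    '</pathway>')
  g <- parse_kgml(kgml)
  expect_equal(gg_nodes(g), c("11", "22"))
  expect_equal(unname(gg_edges(g)[1, ]), c("11", "22"))
})

test_that("multi-compound chains contract and isolated compounds vanish", {
  kgml <- paste0(
    '<pathway name="path:hsa00003">',
    '<entry id="1" name="hsa:11" type="gene"/>',
    '<entry id="2" name="cpd:C1" type="compound"/>',
    '<entry id="3" name="cpd:C2" type="compound"/>',
    '<entry id="4" name="hsa:22" type="gene"/>',
    '<entry id="5" name="cpd:C3" type="compound"/>',
    '<relation entry1="1" entry2="2"/>',
    '<relation entry1="2" entry2="3"/>',
    '<relation entry1="3" entry2="4"/>',
    '</pathway>')
  g <- parse_kgml(kgml)
  expect_equal(gg_nodes(g), c("11", "22"))
  expect_equal(nrow(gg_edges(g)), 1L)
})

test_that("multi-gene entries split with each gene inheriting entry edges", {
  kgml <- paste0(
    '<pathway name="path:hsa00004">',
    '<entry id="1" name="hsa:10 hsa:20" type="gene"/>',
    '<entry id="2" name="hsa:30" type="gene"/>',
    '<relation entry1="1" entry2="2"/>',
    '</pathway>')
  g <- parse_kgml(kgml)
  expect_equal(gg_nodes(g), c("10", "20", "30"))
  expect_equal(gg_edges(g),
               matrix(c("10", "20", "30", "30"), 2,
                      dimnames = list(NULL, c("from", "to"))))
})

test_that("group entries expand to components inheriting group edges", {
  kgml <- paste0(
    '<pathway name="path:hsa00005">',
    '<entry id="1" name="hsa:1" type="gene"/>',
    '<entry id="2" name="hsa:2" type="gene"/>',
    '<entry id="3" name="undefined" type="group">',
    '<component id="1"/><component id="2"/></entry>',
    '<entry id="4" name="hsa:3" type="gene"/>',
    '<relation entry1="3" entry2="4"/>',
    '</pathway>')
  g <- parse_kgml(kgml)
  expect_equal(gg_nodes(g), c("1", "2", "3"))
  expect_equal(gg_edges(g),
               matrix(c("1", "2", "3", "3"), 2,
                      dimnames = list(NULL, c("from", "to"))))
})

test_that("map entries are dropped and isolated genes retained", {
  kgml <- paste0(
    '<pathway name="path:hsa00006">',
    '<entry id="1" name="hsa:1" type="gene"/>',
    '<entry id="2" name="path:hsa00010" type="map"/>',
    '<entry id="3" name="hsa:9" type="gene"/>',
    '<relation entry1="1" entry2="2"/>',
    '</pathway>')
  g <- parse_kgml(kgml)
  expect_equal(gg_nodes(g), c("1", "9"))   # isolated genes survive
  expect_equal(nrow(gg_edges(g)), 0L)
})

test_that("degenerate and malformed documents are handled", {
  expect_warning(g <- parse_kgml('<pathway name="path:hsa99999"/>'),
                 "no gene entries")
  expect_length(gg_nodes(g), 0L)
  expect_error(parse_kgml("<notkgml/>"), "not a KGML")
  expect_error(parse_kgml("<pathway><entry"), ".")
})

test_that("mixed organism prefixes are rejected", {
  expect_error(
    gene_graph(edges = cbind("hsa:1", "mmu:2"), pathway_id = "x"),
    "mixed organism")
})

test_that("parser output matches the generator expectation across fixture shapes", {
  shapes <- expand.grid(genes = c(2L, 5L), bridges = 0:2, groups = 0:1,
                        multi = 0:1)
  for (i in seq_len(nrow(shapes))) {
    sk <- synth_kgml(shapes$genes[i], shapes$bridges[i], shapes$groups[i],
                     shapes$multi[i], seed = i)
    g <- parse_kgml(sk$kgml)
    expect_identical(gg_nodes(g), gg_nodes(sk$expected),
                     info = paste("shape", i))
    expect_identical(gg_edges(g), gg_edges(sk$expected),
                     info = paste("shape", i))
  }
})

test_that("entry order never changes the parsed graph", {
  base <- parse_kgml(synth_kgml(4, 2, 1, 1, seed = 1)$kgml)
  for (s in 2:6) {
    g <- parse_kgml(synth_kgml(4, 2, 1, 1, seed = s)$kgml)
    expect_identical(gg_nodes(g), gg_nodes(base))
    expect_identical(gg_edges(g), gg_edges(base))
  }
})

test_that("round-trip serialization is lossless in both formats", {
  g50 <- random_gene_graph(50, 0.08, "hsa12345")
  g50$title <- "a title"; g50$kegg_class <- "Metabolism"
  empty <- gene_graph(pathway_id = "hsa00000")
  k3 <- make_complete(3, "hsa33333")
  for (g in list(g50, empty, k3)) {
    for (fmt in c("edge_list", "graphml")) {
      f <- tempfile(fileext = if (fmt == "graphml") ".graphml" else ".tsv")
      write_gene_graph(g, f, format = fmt)
      g2 <- read_gene_graph(f)
      expect_identical(gg_nodes(g2), gg_nodes(g))
      expect_identical(gg_edges(g2), gg_edges(g))
      expect_identical(g2$pathway_id, g$pathway_id)
      unlink(f)
    }
  }
})

test_that("K_3 writes a three-line edge list body", {
  f <- tempfile(fileext = ".tsv")
  write_gene_graph(make_complete(3), f)
  body <- grep("^#", readLines(f), invert = TRUE, value = TRUE)
  expect_length(body, 3L)
  unlink(f)
})

test_that("plain headered edge lists read without metadata comments", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "1\t2", "2\t3"), f)
  g <- read_gene_graph(f)
  expect_equal(gg_nodes(g), c("1", "2", "3"))
  expect_equal(nrow(gg_edges(g)), 2L)
  unlink(f)
})

test_that("load_graph_set mixes formats, applies metadata, rejects problems", {
  d <- tempfile(); dir.create(d)
  write_gene_graph(make_complete(3, "hsa01"), file.path(d, "a.tsv"))
  write_gene_graph(make_path(4, "hsa02"), file.path(d, "b.graphml"),
                   format = "graphml")
  writeLines(synth_kgml(3, 0, 0, 0, pathway_id = "hsa03")$kgml,
             file.path(d, "c.xml"))
  meta <- data.frame(pathway_id = c("hsa01", "hsa02"),
                     kegg_class = c("Metabolism", "Human Diseases"))
  expect_warning(gs <- load_graph_set(d, "mix", metadata = meta),
                 "no metadata")
  expect_s3_class(gs, "graph_set")
  expect_length(gs, 3L)
  expect_equal(gs$graphs[["hsa01"]]$kegg_class, "Metabolism")
  expect_equal(gs$graphs[["hsa03"]]$kegg_class, "")
  expect_error(load_graph_set(file.path(d, "missing.tsv"), "x"),
               "cannot read")
  # duplicate pathway IDs rejected at set construction
  write_gene_graph(make_complete(3, "hsa01"), file.path(d, "dup.tsv"))
  expect_error(load_graph_set(d, "dup"), "duplicate")
  unlink(d, recursive = TRUE)
})

test_that("gene_graph enforces the simple-graph invariants", {
  g <- gene_graph(edges = rbind(c("1", "2"), c("2", "1"), c("3", "3")),
                  nodes = c("4"), pathway_id = "x")
  expect_equal(gg_nodes(g), c("1", "2", "3", "4"))
  expect_equal(nrow(gg_edges(g)), 1L)   # loop and duplicate removed
  expect_error(gene_graph(edges = cbind("a", "b"), pathway_id = "x"),
               "numeric")
})
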