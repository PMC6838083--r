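test_that("edges require strictly p < cutoff and testability", {
  genes <- c("A", "B", "C", "D")
  p <- c(0.3, 0.1, NA, 0.29, 0.9, 0.05)  # AB, AC, AD, BC, BD, CD
  g <- build_graph(make_pairs_table(genes, p), cutoff = 0.3)
  expect_equal(nrow(g$edges), 3L)  # 0.3 itself excluded, NA untestable
  expect_false(any(g$edges$gene_a == "A" & g$edges$gene_b == "B"))
  all_one <- build_graph(make_pairs_table(genes, rep(1, 6)), 0.5)
  expect_equal(nrow(all_one$edges), 0L)
  # path A-B-C-D from 3 significant pairs
  path <- build_graph(make_pairs_table(
    genes, c(0.01, 0.9, 0.9, 0.01, 0.9, 0.01)), 0.3)
  expect_equal(nrow(path$edges), 3L)
  expect_equal(sort_cliques(maximal_cliques(path)),
               sort_cliques(list(c("A", "B"), c("B", "C"), c("C", "D"))))
})

test_that("maximal cliques cover the degenerate and complete cases", {
  empty <- build_graph(make_pairs_table(c("A", "B", "C"), rep(0.9, 3)), 0.3)
  expect_equal(maximal_cliques(empty), list("A", "B", "C"))
  k4 <- build_graph(make_pairs_table(LETTERS[1:4], rep(0.01, 6)), 0.3)
  expect_equal(nrow(k4$edges), 6L)  # N(N-1)/2 edges for the 4-clique
  expect_equal(maximal_cliques(k4), list(LETTERS[1:4]))
})

test_that("clique enumeration matches brute force and igraph on random graphs", {
  set.seed(901)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    g <- build_graph(random_pairs_table(n, runif(1, 0.1, 0.7)), 0.5)
    mine <- sort_cliques(maximal_cliques(g))
    expect_identical(mine, brute_force_cliques(g))
    ig <- igraph::graph_from_data_frame(
      g$edges[, 1:2], directed = FALSE,
      vertices = data.frame(name = g$nodes))
    ig_cl <- lapply(igraph::max_cliques(ig),
                    function(v) igraph::V(ig)$name[v])
    expect_identical(mine, sort_cliques(ig_cl))
  }
})

test_that("selection intersects maximum cliques and flags the edge cases", {
  # single maximum clique is taken whole and is reliable at size 4
  one <- build_graph(make_pairs_table(LETTERS[1:5], c(
    0.01, 0.01, 0.01, 0.9,   # AB AC AD AE
    0.01, 0.01, 0.9,         # BC BD BE
    0.01, 0.9, 0.9)), 0.3)   # CD CE DE
  sel <- select_reference_genes(one)
  expect_equal(sel$selected, c("A", "B", "C", "D"))
  expect_true(sel$reliable)
  expect_equal(sel$isolated, "E")  # E joins no pair
  expect_false(sel$ambiguous)
  # two maximum cliques (ABC, ABD) sharing an edge: intersection selected
  shared <- build_graph(make_pairs_table(LETTERS[1:4], c(
    0.01, 0.01, 0.01,  # AB AC AD
    0.01, 0.01,        # BC BD
    0.9)), 0.3)        # CD
  sel2 <- select_reference_genes(shared)
  expect_equal(lengths(sel2$maximum_cliques), c(3L, 3L))
  expect_equal(sel2$selected, c("A", "B"))
  expect_false(sel2$reliable)  # maximum clique below 4
  # two disjoint triangles: empty intersection, flagged ambiguous
  tri <- build_graph(make_pairs_table(LETTERS[1:6], {
    p <- rep(0.9, 15)
    idx <- function(a, b) which(apply(utils::combn(LETTERS[1:6], 2), 2,
                                      paste, collapse = "") == paste0(a, b))
    for (e in list(c("A","B"), c("A","C"), c("B","C"),
                   c("D","E"), c("D","F"), c("E","F")))
      p[idx(e[1], e[2])] <- 0.01
    p
  }), 0.3)
  sel3 <- select_reference_genes(tri)
  expect_true(sel3$ambiguous)
  expect_equal(sel3$selected, character(0))
  # isolated nodes are reported and disjoint from any selection
  iso <- build_graph(make_pairs_table(LETTERS[1:4], c(
    0.01, 0.01, 0.9, 0.01, 0.9, 0.9)), 0.3)
  sel4 <- select_reference_genes(iso)
  expect_equal(sel4$isolated, "D")
  expect_false("D" %in% sel4$selected)
})

test_that("graph edges and maximum clique size grow monotonically with cutoff", {
  set.seed(902)
  pairs <- random_pairs_table(8, 0.5)
  pairs$p_tost <- runif(nrow(pairs))
  sizes <- integer(0); edges <- integer(0)
  for (cut in c(0.05, 0.2, 0.5, 0.9)) {
    g <- build_graph(pairs, cut)
    edges <- c(edges, nrow(g$edges))
    sizes <- c(sizes, select_reference_genes(g)$maximum_size)
  }
  expect_true(all(diff(edges) >= 0))
  expect_true(all(diff(sizes) >= 0))
})

test_that("every pair inside the selected set is connected", {
  set.seed(903)
  for (i in 1:20) {
    g <- build_graph(random_pairs_table(9, 0.4), 0.5)
    sel <- select_reference_genes(g)
    if (length(sel$selected) >= 2) {
      edge_key <- paste(g$edges$gene_a, g$edges$gene_b)
      cmb <- utils::combn(sel$selected, 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        expect_true(paste(a, b) %in% edge_key || paste(b, a) %in% edge_key)
      }
    }
  }
})

test_that("delta profile orders gene entry and saturates for huge delta", {
  set.seed(904)
  spec <- synthetic_spec(n_genes = 6, group_sizes = c(10, 10),
                         group_effects = c(0, 0, 0, 1.2, -1.2, 2.4),
                         planted_set = 1:3, delta_design = 1,
                         inter_individual_sd = 0.2, analytical_sd = 0,
                         n_replicates = 1, seed = 904)
  m <- average_triplicates(generate_cq(spec)$table)
  prof <- delta_profile(m, c(0.3, 0.6, 1.0, 50), cutoff = 0.3)
  planted <- sprintf("G%02d", 1:3)
  entry <- stats::setNames(prof$entry$entry_delta, prof$entry$gene)
  # the planted stable genes enter at the smallest delta of any gene
  expect_true(all(entry[planted] == min(entry, na.rm = TRUE)))
  # an absurdly wide region declares everything equivalent
  expect_equal(prof$selections[[4]]$selected, colnames(m$cq))
  # entry deltas never decrease information: once selected at some delta,
  # the gene has a finite entry
  expect_true(all(is.finite(entry[prof$selections[[1]]$selected])))
})

test_that("graph export formats carry nodes, classes and p-values", {
  g <- build_graph(make_pairs_table(c("A", "B", "C"),
                                    c(0.01, 0.9, 0.02)), 0.3)
  sel <- select_reference_genes(g)
  dot <- tempfile(fileext = ".dot")
  export_graph(g, sel, "dot", dot)
  dl <- readLines(dot)
  expect_length(grep(" -- ", dl), 2L)
  tsv <- tempfile(fileext = ".tsv")
  export_graph(g, sel, "edge_tsv", tsv)
  ed <- utils::read.delim(tsv)
  expect_equal(nrow(ed), 2L)
  expect_equal(ed$p_tost, c(0.01, 0.02))
  gml <- tempfile(fileext = ".graphml")
  export_graph(g, sel, "graphml", gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("A", "B", "C"))
  expect_equal(igraph::ecount(back), 2L)
  back_edges <- igraph::as_edgelist(back)
  canon <- apply(back_edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(canon, c("A-B", "B-C"))
  expect_error(export_graph(g, sel, "nonsense", tempfile()))
})
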