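# Disease sets, risk-network extraction, topology and enrichment.

test_that("disease annotations union evidence flags per feature and class", {
  ann <- assemble_disease_sets(gwas_circ = c("c1", "c2"),
                               de_circ = c("c1"),
                               known_mirna = "m1",
                               gwas_gene = "g1", known_gene = "g1")
  c1 <- ann[ann$feature_id == "c1" & ann$feature_class == "circRNA", ]
  expect_equal(nrow(c1), 1L)
  expect_true(c1$gwas && c1$de && !c1$known)
  g1 <- ann[ann$feature_id == "g1" & ann$feature_class == "gene", ]
  expect_true(g1$gwas && g1$known)
  expect_equal(unname(attr(ann, "counts")),
               c(2L, 1L, 1L))
  expect_equal(nrow(assemble_disease_sets()), 0L)
})

test_that("annotation class counts match inclusion-exclusion on random sets", {
  set.seed(401)
  for (i in 1:20) {
    ids <- sprintf("x%02d", 1:30)
    gw <- sample(ids, sample(0:10, 1))
    kn <- sample(ids, sample(0:10, 1))
    de <- sample(ids, sample(0:10, 1))
    ann <- assemble_disease_sets(gwas_circ = gw, known_circ = kn, de_circ = de)
    expect_equal(sum(ann$feature_class == "circRNA"),
                 length(union(union(gw, kn), de)))
  }
})

test_that("risk extraction keeps exactly the pairs with an annotated endpoint", {
  pairs <- data.frame(circ_id = c("c1", "c2", "c3"),
                      gene_id = c("g1", "g2", "g3"),
                      n_shared = 3L, shared_mirnas = "m1,m2,m3",
                      stringsAsFactors = FALSE)
  ann <- assemble_disease_sets(gwas_circ = "c1", de_gene = "g2")
  net <- extract_risk_network(pairs, ann)
  expect_setequal(paste(net$edges$circ_id, net$edges$gene_id),
                  c("c1 g1", "c2 g2"))
  # fully annotated -> everything retained; no annotation -> nothing
  all_ann <- assemble_disease_sets(gwas_circ = pairs$circ_id)
  expect_equal(extract_risk_network(pairs, all_ann)$summary$n_edges, 3L)
  expect_equal(extract_risk_network(pairs, assemble_disease_sets())$summary$n_edges, 0L)
})

test_that("risk extraction agrees with a brute-force filter on random inputs", {
  set.seed(402)
  for (i in 1:30) {
    edges <- random_pair_edges(10, 15, 0.2)
    ac <- sample(sprintf("c%02d", 1:10), sample(0:5, 1))
    ag <- sample(sprintf("g%02d", 1:15), sample(0:5, 1))
    ann <- assemble_disease_sets(gwas_circ = ac, de_gene = ag)
    net <- extract_risk_network(edges, ann)
    keep <- edges$circ_id %in% ac | edges$gene_id %in% ag
    expect_setequal(paste(net$edges$circ_id, net$edges$gene_id),
                    paste(edges$circ_id[keep], edges$gene_id[keep]))
    expect_equal(sum(node_degree(net$edges)$value), 2 * sum(keep))
  }
})

test_that("degree and betweenness have the closed-form values on small graphs", {
  # path g1 - c1 - g2
  path_edges <- data.frame(circ_id = c("c1", "c1"), gene_id = c("g1", "g2"),
                           n_shared = 3L, shared_mirnas = "m1,m2,m3",
                           stringsAsFactors = FALSE)
  deg <- node_degree(path_edges)
  expect_equal(deg$value[deg$id == "c1"], 2)
  bw <- node_betweenness(path_edges)
  expect_equal(bw$value[bw$id == "c1"], 1)
  expect_equal(bw$value[bw$id != "c1"], c(0, 0))
  # 4-cycle c1-g1-c2-g2-c1: every node carries 0.5
  cyc <- data.frame(circ_id = c("c1", "c1", "c2", "c2"),
                    gene_id = c("g1", "g2", "g1", "g2"),
                    n_shared = 3L, shared_mirnas = "m1,m2,m3",
                    stringsAsFactors = FALSE)
  expect_equal(node_betweenness(cyc)$value, rep(0.5, 4))
})

test_that("betweenness matches the all-pairs path-counting oracle on random graphs", {
  set.seed(403)
  for (i in 1:15) {
    edges <- random_pair_edges(sample(3:8, 1), sample(3:8, 1), runif(1, 0.2, 0.6))
    if (!nrow(edges)) next
    got <- node_betweenness(edges)
    adj <- bipartite_adj(edges)
    exp <- oracle_betweenness(adj)
    got_by_id <- setNames(got$value, got$id)
    expect_equal(unname(got_by_id[rownames(adj)]), exp, tolerance = 1e-9)
  }
})

test_that("topology comparison detects a shift and is calibrated without one", {
  mw <- mann_whitney_greater(c(10, 11, 12), c(1, 2, 3))
  expect_equal(mw$p_value, 1 / 20)       # exact: U = 9, P[U >= 9] = 1/20
  same <- mann_whitney_greater(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_lt(abs(same$p_value - 0.5), 0.1)

  edges <- data.frame(circ_id = c("c1", "c1", "c1", "c2"),
                      gene_id = c("g1", "g2", "g3", "g3"),
                      n_shared = 3L, shared_mirnas = "m1,m2,m3",
                      stringsAsFactors = FALSE)
  tc <- compare_topology(edges, c("c1"), "degree")
  expect_s3_class(tc, "topology_comparison")
  expect_true(tc$p_value >= 0 && tc$p_value <= 1)
  expect_error(compare_topology(edges, character(), "degree"), "non-empty")
})

test_that("hypergeometric enrichment matches hand-computed and enumerated tails", {
  universe <- sprintf("g%02d", 1:10)
  res <- enrich(universe[1:4], list(term = universe[1:5]), universe,
                enrich_fdr = 0.05)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)  # C(5,4)C(5,0)/C(10,4)
  expect_equal(res$overlap_k, 4L)
  # zero overlap is never significant: P[X >= 0] = 1
  res0 <- enrich(universe[6:9], list(term = universe[1:5]), universe)
  expect_equal(res0$p_value, 1)
  expect_error(enrich("g01", list(t = "g01"), character()), "universe")
  expect_error(enrich("zz", list(t = "g01"), universe), "zz")

  set.seed(404)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), oracle_hyper(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("GraphML export writes a readable graph with class attributes", {
  edges <- data.frame(circ_id = "c1", gene_id = "g1", n_shared = 3L,
                      shared_mirnas = "m1,m2,m3", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".graphml")
  write_graphml(edges, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_setequal(igraph::V(g)$class, c("circRNA", "gene"))
})
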