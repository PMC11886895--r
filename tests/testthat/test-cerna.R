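# Competitive pair and triplet enumeration.

test_that("bipartite projection collapses repeated edges to set membership", {
  inter <- data.frame(
    source_id = c("c1", "c1", "c1", "m1"),
    source_type = c("circRNA", "circRNA", "circRNA", "miRNA"),
    target_id = c("m1", "m2", "m1", "g1"),
    target_type = c("miRNA", "miRNA", "miRNA", "mRNA"),
    confidence = 0.5, stringsAsFactors = FALSE)
  maps <- build_bipartite(inter)
  expect_equal(maps$circ, list(c1 = c("m1", "m2")))
  expect_equal(maps$gene, list(g1 = "m1"))
  empty <- build_bipartite(inter[0, ])
  expect_length(empty$circ, 0)
  expect_length(empty$gene, 0)
})

test_that("pair enumeration applies the shared-miRNA threshold exactly", {
  circ <- list(c1 = c("m1", "m2", "m3"), c2 = c("m1", "m2"))
  gene <- list(g1 = c("m1", "m2", "m3"), g2 = c("m1", "m2"))
  got <- enumerate_cerna_pairs(circ, gene, min_shared = 3)
  expect_equal(nrow(got), 1L)
  expect_equal(got$circ_id, "c1")
  expect_equal(got$gene_id, "g1")
  expect_equal(got$n_shared, 3L)
  expect_equal(got$shared_mirnas, "m1,m2,m3")
})

test_that("enumeration matches the all-pairs intersection oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    maps <- random_maps(sample(2:50, 1), sample(3:60, 1), sample(2:50, 1),
                        runif(1, 0.05, 0.3))
    ms <- sample(1:4, 1)
    expect_identical(enumerate_cerna_pairs(maps$circ, maps$gene, ms),
                     oracle_pairs(maps$circ, maps$gene, ms))
  }
})

test_that("pair sets shrink monotonically as the shared-miRNA threshold rises", {
  set.seed(102)
  for (i in 1:20) {
    maps <- random_maps(20, 30, 20, 0.2)
    for (k in 1:4) {
      a <- enumerate_cerna_pairs(maps$circ, maps$gene, k)
      b <- enumerate_cerna_pairs(maps$circ, maps$gene, k + 1L)
      expect_true(all(paste(b$circ_id, b$gene_id) %in%
                        paste(a$circ_id, a$gene_id)))
    }
  }
})

test_that("shared counts agree whether computed from the circRNA or the gene side", {
  set.seed(103)
  maps <- random_maps(20, 30, 20, 0.2)
  pairs <- enumerate_cerna_pairs(maps$circ, maps$gene, 2)
  for (i in seq_len(nrow(pairs))) {
    via_circ <- intersect(maps$circ[[pairs$circ_id[i]]],
                          maps$gene[[pairs$gene_id[i]]])
    via_gene <- intersect(maps$gene[[pairs$gene_id[i]]],
                          maps$circ[[pairs$circ_id[i]]])
    expect_equal(pairs$n_shared[i], length(via_circ))
    expect_equal(length(via_circ), length(via_gene))
  }
})

test_that("triplet expansion yields one triplet per shared miRNA", {
  pairs <- data.frame(circ_id = "c1", gene_id = "g1", n_shared = 3L,
                      shared_mirnas = "m1,m2,m3", stringsAsFactors = FALSE)
  tr <- expand_triplets(pairs)
  expect_equal(nrow(tr), 3L)
  expect_setequal(tr$mirna_id, c("m1", "m2", "m3"))
  expect_equal(nrow(expand_triplets(pairs[0, ])), 0L)
})

test_that("network summary counts distinct entities, not repeated mentions", {
  pairs <- data.frame(circ_id = c("c1", "c2"), gene_id = c("g1", "g2"),
                      n_shared = c(3L, 3L),
                      shared_mirnas = c("m1,m2,m3", "m1,m2,m3"),
                      stringsAsFactors = FALSE)
  s <- network_summary(pairs)
  expect_equal(s, list(n_pairs = 2L, n_triplets = 6L, n_circ = 2L,
                       n_mirna = 3L, n_gene = 2L))
  one <- network_summary(pairs[1, ])
  expect_equal(one$n_pairs, 1L)
  expect_equal(one$n_triplets, 3L)
  expect_equal(one$n_mirna, 3L)
})
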