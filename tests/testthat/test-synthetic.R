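# Synthetic generators: planted structure, determinism, self-consistency.

test_that("planted pairs are wired through at least min_shared dedicated miRNAs", {
  gen <- generate_interactome(10, 30, 15, background_edge_prob = 0.1,
                              n_planted_pairs = 5, min_shared = 3, seed = 11)
  maps <- build_bipartite(gen$interactions)
  for (i in seq_len(nrow(gen$truth$planted_pairs))) {
    ci <- gen$truth$planted_pairs$circ_id[i]
    gi <- gen$truth$planted_pairs$gene_id[i]
    expect_gte(length(intersect(maps$circ[[ci]], maps$gene[[gi]])), 3)
  }
  expect_error(generate_interactome(2, 5, 2, 0, 4, 3, 1), "dedicated")
  expect_error(generate_interactome(2, 5, 2, 0, 5, 3, 1), "possible pairs")
})

test_that("with zero background the planted pairs are recovered exactly", {
  gen <- generate_interactome(10, 30, 15, background_edge_prob = 0,
                              n_planted_pairs = 5, min_shared = 3, seed = 12)
  maps <- build_bipartite(gen$interactions)
  pairs <- enumerate_cerna_pairs(maps$circ, maps$gene, 3)
  truth <- gen$truth$planted_pairs
  expect_setequal(paste(pairs$circ_id, pairs$gene_id),
                  paste(truth$circ_id, truth$gene_id))
  expect_true(all(pairs$n_shared == 3L))
  expect_equal(nrow(expand_triplets(pairs)), 15L)
})

test_that("genome generator plants the stated number of inside-variants", {
  gen <- generate_genome_and_variants(20, 10, 1000000L, window_bp = 10000L,
                                      n_inside_hits = 1, seed = 13)
  feats <- gen$features
  expect_true(all(feats$end > feats$start))
  # no overlaps within a chromosome
  f <- feats[order(feats$start), ]
  expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  hits <- variants_on_circrnas(gen$variants, feats)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rsid, gen$truth$inside$rsid)
  expect_equal(hits$circ_id, gen$truth$inside$feature_id)
  # degenerate window: within-window truth reduces to pure containment
  gen0 <- generate_genome_and_variants(20, 10, 1000000L, window_bp = 0L,
                                       n_inside_hits = 2, seed = 14)
  contain <- do.call(rbind, lapply(seq_len(nrow(gen0$variants)), function(i) {
    v <- gen0$variants[i, ]
    f <- gen0$features
    hit <- f$chrom == v$chrom & f$start <= v$pos & v$pos < f$end
    if (any(hit)) data.frame(rsid = v$rsid, feature_id = f$id[hit]) else NULL
  }))
  expect_setequal(paste(gen0$truth$within_window$rsid,
                        gen0$truth$within_window$feature_id),
                  paste(contain$rsid, contain$feature_id))
  # the planted circRNA hits are among them
  expect_true(all(paste(gen0$truth$inside$rsid,
                        gen0$truth$inside$feature_id) %in%
                    paste(contain$rsid, contain$feature_id)))
  expect_error(generate_genome_and_variants(4, 2, 100L, n_inside_hits = 1,
                                            seed = 1),
               "too small")
})

test_that("expression generator plants unbiased log2 effects", {
  diffs <- replicate(100, {
    gen <- generate_expression(10, 10, 10, n_de = 5, effect_log2 = 2,
                               noise_sd = 0.5, seed = sample.int(1e6, 1))
    v <- gen$matrix$values
    lab <- gen$matrix$labels
    d <- rowMeans(v[, lab == "case", drop = FALSE]) -
      rowMeans(v[, lab == "control", drop = FALSE])
    mean(d[gen$truth$feature_id] * sign(gen$truth$effect_log2))
  })
  expect_lt(abs(mean(diffs) - 2), 0.5)
  expect_equal(nrow(generate_expression(10, 5, 5, n_de = 0, seed = 1)$truth), 0L)
  a <- generate_expression(10, 5, 5, 3, seed = 9)$matrix$values
  b <- generate_expression(10, 5, 5, 3, seed = 9)$matrix$values
  expect_identical(a, b)
})

test_that("program generator separates designated common genes from the rest", {
  pool <- sprintf("g%04d", 1:3000)
  gen <- generate_programs(13, 300, pool, n_common = 20,
                           min_program_count = 6, seed = 15)
  expect_length(gen$programs, 13)
  expect_true(all(lengths(gen$programs) == 300))
  expect_setequal(common_genes(gen$programs, 6), gen$truth)
  expect_length(gen$truth, 20)
  expect_error(generate_programs(13, 300, pool, 20, 14, 1), "exceeds")
  expect_error(generate_programs(3, 50, sprintf("g%d", 1:60), 5, 2, 1),
               "too small")
})

test_that("a bundle is byte-identical under the same seed and self-consistent", {
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- generate_bundle(d1, seed = 42)
  b2 <- generate_bundle(d2, seed = 42)
  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     info = nm)
  }
  d3 <- tempfile()
  b3 <- generate_bundle(d3, seed = 43)
  expect_false(identical(readLines(b1$paths$interactions),
                         readLines(b3$paths$interactions)))

  # self-consistency: every referenced id exists in the feature universe
  inter <- read_interactions(b1$paths$interactions, 0)
  circ <- read_bed(b1$paths$circ_features, "circRNA")
  gene <- read_bed(b1$paths$gene_features, "gene")
  expect_true(all(inter$source_id[inter$source_type == "circRNA"] %in% circ$id))
  expect_true(all(inter$target_id[inter$target_type == "mRNA"] %in% gene$id))
  progs <- read_gmt(b1$paths$programs)
  expect_true(all(unlist(progs) %in% gene$id))
  expect_true(all(read_id_list(b1$paths$known_circ) %in% circ$id))
  expect_true(all(read_id_list(b1$paths$known_gene) %in% gene$id))
  truth <- read_truth(b1$paths$truth)
  expect_true(all(truth$planted_pairs$circ_id %in% circ$id))
  expect_true(all(truth$planted_common_genes %in% gene$id))
})
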