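# Program frequency, common genes and circuit chains.

test_that("program frequency tallies membership per gene", {
  progs <- setNames(lapply(1:6, function(i) c("gA", sprintf("x%d", i))),
                    sprintf("P%d", 1:6))
  freq <- program_frequency(progs)
  expect_equal(freq$count[freq$gene_id == "gA"], 6L)
  expect_equal(freq$program_names[freq$gene_id == "gA"], "P1,P2,P3,P4,P5,P6")
  disjoint <- list(P1 = c("a", "b"), P2 = c("c", "d"))
  expect_true(all(program_frequency(disjoint)$count == 1L))
  # counts equal the brute-force tally on random collections
  set.seed(501)
  for (i in 1:20) {
    sets <- lapply(1:8, function(j) sample(sprintf("g%02d", 1:25),
                                           sample(1:15, 1)))
    names(sets) <- sprintf("S%d", 1:8)
    freq <- program_frequency(sets)
    for (g in freq$gene_id) {
      expect_equal(freq$count[freq$gene_id == g],
                   sum(vapply(sets, function(s) g %in% s, TRUE)))
    }
  }
})

test_that("common-gene selection is threshold-exact and anti-monotone", {
  progs <- c(setNames(lapply(1:7, function(i) c("gA", "gB")),
                      sprintf("P%d", 1:7)),
             list(P8 = c("gB", "gC")))
  expect_setequal(common_genes(progs, 6), c("gA", "gB"))
  expect_setequal(common_genes(progs, 8), "gB")
  expect_setequal(common_genes(progs, 1), c("gA", "gB", "gC"))
  expect_length(common_genes(progs, 9), 0)
  for (k in 1:8)
    expect_true(all(common_genes(progs, k + 1) %in% common_genes(progs, k)))
})

test_that("EC subnetwork applies the conjunctive gene-and-miRNA filter", {
  triplets <- data.frame(circ_id = c("c1", "c1", "c2"),
                         mirna_id = c("m1", "m9", "m1"),
                         gene_id = c("gA", "gA", "gZ"),
                         stringsAsFactors = FALSE)
  progs <- setNames(lapply(1:6, function(i) "gA"), sprintf("P%d", 1:6))
  ec <- ec_subnetwork(triplets, common_gene_set = "gA",
                      known_cad_mirnas = "m1", programs = progs)
  expect_equal(nrow(ec$chains), 1L)   # (c1, m9, gA) and (c2, m1, gZ) dropped
  expect_equal(ec$chains$circ_id, "c1")
  expect_equal(ec$chains$programs, "P1;P2;P3;P4;P5;P6")
  expect_equal(ec$summary, list(n_circ = 1L, n_mirna = 1L, n_gene = 1L))
})

test_that("EC filtering agrees with brute force on random triplet sets", {
  set.seed(502)
  for (i in 1:40) {
    triplets <- data.frame(
      circ_id = sample(sprintf("c%d", 1:8), 30, TRUE),
      mirna_id = sample(sprintf("m%d", 1:10), 30, TRUE),
      gene_id = sample(sprintf("g%d", 1:12), 30, TRUE),
      stringsAsFactors = FALSE)
    triplets <- triplets[!duplicated(triplets), ]
    cg <- sample(sprintf("g%d", 1:12), sample(0:6, 1))
    km <- sample(sprintf("m%d", 1:10), sample(0:6, 1))
    ec <- ec_subnetwork(triplets, cg, km, programs = list())
    keep <- triplets$gene_id %in% cg & triplets$mirna_id %in% km
    expect_setequal(paste(ec$chains$circ_id, ec$chains$mirna_id,
                          ec$chains$gene_id),
                    paste(triplets$circ_id[keep], triplets$mirna_id[keep],
                          triplets$gene_id[keep]))
  }
})

test_that("variant linking duplicates chains per matching inside-variant", {
  chains <- data.frame(rsid = NA_character_,
                       circ_id = c("c1", "c2"), mirna_id = "m1",
                       gene_id = "gA", programs = "P1",
                       stringsAsFactors = FALSE)
  overlaps <- data.frame(rsid = c("rs1", "rs2"), circ_id = c("c1", "c1"),
                         stringsAsFactors = FALSE)
  linked <- link_variants(chains, overlaps)
  expect_equal(nrow(linked), 3L)                       # c1 x 2 variants + c2
  expect_setequal(linked$rsid[linked$circ_id == "c1"], c("rs1", "rs2"))
  expect_true(is.na(linked$rsid[linked$circ_id == "c2"]))
  no_ov <- link_variants(chains, overlaps[0, ])
  expect_true(all(is.na(no_ov$rsid)))
})

test_that("circuit report ranks circRNAs by distinct target-gene count", {
  chains <- data.frame(
    rsid = c(NA, NA, "rs9"),
    circ_id = c("c1", "c1", "c2"),
    mirna_id = c("m1", "m2", "m1"),
    gene_id = c("g1", "g2", "g1"),
    programs = c("P1;P2", "P2;P3", "P1"), stringsAsFactors = FALSE)
  rep <- circuit_report(chains)
  expect_equal(rep$circ_id, c("c1", "c2"))
  expect_equal(rep$n_genes, c(2L, 1L))
  expect_equal(rep$programs[1], "P1;P2;P3")
  expect_equal(rep$variants[2], "rs9")
  expect_equal(nrow(circuit_report(chains[0, ])), 0L)
})
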