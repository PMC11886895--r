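# ceRNA pair and triplet enumeration.
#
# A circRNA and an mRNA compete for the same miRNA pool when they bind
# overlapping miRNA sets; a pair sharing at least `min_shared` miRNAs is
# called competitively regulated. Enumeration goes through a miRNA-indexed
# join (inverted index) rather than all-pairs set intersection, so it scales
# to interactomes with hundreds of circRNAs and thousands of genes.

#' Project the interaction table onto its two bipartite maps
#'
#' Splits a filtered interaction table into the circRNA -> miRNA-set map and
#' the gene -> miRNA-set map used for competitive-pair enumeration. Repeated
#' edges collapse to set membership.
#'
#' @param interactions Data.frame from [read_interactions()] (already
#'   confidence-filtered).
#' @return List with `circ` and `gene`: named lists mapping each id to its
#'   sorted character vector of interacting miRNA ids.
#' @export
build_bipartite <- function(interactions) {
  cm <- interactions[interactions$source_type == "circRNA", , drop = FALSE]
  mg <- interactions[interactions$source_type == "miRNA", , drop = FALSE]
  circ <- lapply(split(cm$target_id, cm$source_id), function(v) sort(unique(v)))
  gene <- lapply(split(mg$source_id, mg$target_id), function(v) sort(unique(v)))
  list(circ = circ, gene = gene)
}

#' Enumerate competitively regulated circRNA-mRNA pairs
#'
#' Returns every (circRNA, gene) pair whose miRNA sets intersect in at least
#' `min_shared` elements, together with the full shared-miRNA set. Implemented
#' by joining the two maps on the miRNA axis and counting co-occurrences per
#' pair; shared sets are materialized only for pairs passing the threshold.
#'
#' @param circ_map,gene_map Named lists (id -> miRNA id vector) as produced by
#'   [build_bipartite()].
#' @param min_shared Minimum shared-miRNA count (>= 1).
#' @return Data.frame with columns `circ_id`, `gene_id`, `n_shared`,
#'   `shared_mirnas` (comma-joined, sorted), ordered by (circ_id, gene_id).
#' @export
enumerate_cerna_pairs <- function(circ_map, gene_map, min_shared = 3L) {
  min_shared <- as.integer(min_shared)
  if (min_shared < 1L) stop("min_shared must be >= 1", call. = FALSE)
  empty <- data.frame(circ_id = character(), gene_id = character(),
                      n_shared = integer(), shared_mirnas = character(),
                      stringsAsFactors = FALSE)
  if (!length(circ_map) || !length(gene_map)) return(empty)
  cm <- data.table::data.table(
    circ_id = rep(names(circ_map), lengths(circ_map)),
    mirna_id = unlist(circ_map, use.names = FALSE))
  mg <- data.table::data.table(
    gene_id = rep(names(gene_map), lengths(gene_map)),
    mirna_id = unlist(gene_map, use.names = FALSE))
  joined <- merge(cm, mg, by = "mirna_id", allow.cartesian = TRUE)
  if (!nrow(joined)) return(empty)
  mirna_id <- circ_id <- gene_id <- n_shared <- NULL # R CMD check NSE guards
  pairs <- joined[, list(
    n_shared = .N,
    shared_mirnas = paste(sort(mirna_id), collapse = ",")),
    by = c("circ_id", "gene_id")]
  pairs <- pairs[pairs$n_shared >= min_shared]
  data.table::setorderv(pairs, c("circ_id", "gene_id"))
  data.table::setDF(pairs)
  pairs
}

#' Expand pairs into circRNA-miRNA-gene triplets
#'
#' One triplet per (pair, shared miRNA): the triplet count equals the sum of
#' shared-miRNA counts over all pairs.
#'
#' @param pairs Data.frame from [enumerate_cerna_pairs()].
#' @return Data.frame with columns `circ_id`, `mirna_id`, `gene_id`.
#' @export
expand_triplets <- function(pairs) {
  if (!nrow(pairs))
    return(data.frame(circ_id = character(), mirna_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  shared <- strsplit(pairs$shared_mirnas, ",", fixed = TRUE)
  n <- lengths(shared)
  data.frame(circ_id = rep(pairs$circ_id, n),
             mirna_id = unlist(shared, use.names = FALSE),
             gene_id = rep(pairs$gene_id, n),
             stringsAsFactors = FALSE)
}

#' Summarize a ceRNA pair network
#'
#' Distinct-entity counts over a pair list: number of pairs, total triplets
#' (sum of shared-miRNA counts), and distinct circRNAs, miRNAs and genes.
#'
#' @param pairs Data.frame from [enumerate_cerna_pairs()].
#' @return Named list `n_pairs`, `n_triplets`, `n_circ`, `n_mirna`, `n_gene`.
#' @export
network_summary <- function(pairs) {
  if (!nrow(pairs))
    return(list(n_pairs = 0L, n_triplets = 0L, n_circ = 0L, n_mirna = 0L,
                n_gene = 0L))
  mir <- unique(unlist(strsplit(pairs$shared_mirnas, ",", fixed = TRUE),
                       use.names = FALSE))
  list(n_pairs = nrow(pairs),
       n_triplets = as.integer(sum(pairs$n_shared)),
       n_circ = length(unique(pairs$circ_id)),
       n_mirna = length(mir),
       n_gene = length(unique(pairs$gene_id)))
}

#' Write a pair table
#' @param pairs Data.frame from [enumerate_cerna_pairs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) .write_tsv(pairs, path)
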