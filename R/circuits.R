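# Endothelial-cell-specific circuit derivation.
#
# Genes present in many EC gene programs ("common program genes") anchor the
# terminal circuits: risk-network triplets are kept when their gene is a
# common program gene AND their miRNA is a curated disease miRNA; chains then
# pick up the GWAS variants lying inside their circRNA, yielding
# variant -> circRNA -> miRNA -> gene -> program chains.

#' Per-gene program membership frequency
#'
#' @param programs Named list of gene sets (from [read_gmt()]).
#' @return Data.frame with columns `gene_id`, `program_names` (comma-joined,
#'   sorted), `count`, one row per gene appearing in >= 1 program, ordered by
#'   decreasing count then gene id.
#' @export
program_frequency <- function(programs) {
  if (!length(programs))
    return(data.frame(gene_id = character(), program_names = character(),
                      count = integer(), stringsAsFactors = FALSE))
  long <- data.frame(gene_id = unlist(programs, use.names = FALSE),
                     program = rep(names(programs), lengths(programs)),
                     stringsAsFactors = FALSE)
  byg <- split(long$program, long$gene_id)
  out <- data.frame(gene_id = names(byg),
                    program_names = vapply(byg, function(p)
                      paste(sort(unique(p)), collapse = ","), ""),
                    count = vapply(byg, function(p) length(unique(p)), 0L),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes shared by many programs
#'
#' @param programs Named list of gene sets.
#' @param min_program_count Minimum number of programs (>= 1) a gene must
#'   belong to.
#' @return Sorted character vector of gene ids.
#' @export
common_genes <- function(programs, min_program_count = 6L) {
  if (min_program_count < 1L)
    stop("min_program_count must be >= 1", call. = FALSE)
  freq <- program_frequency(programs)
  sort(freq$gene_id[freq$count >= min_program_count])
}

#' Derive the EC-specific circRNA regulatory subnetwork
#'
#' Conjunctive filter over triplets: the gene must be a common program gene
#' and the miRNA a curated disease miRNA. Each retained chain is annotated
#' with the programs containing its gene.
#'
#' @param triplets Data.frame from [expand_triplets()] (typically of the risk
#'   network).
#' @param common_gene_set Character vector from [common_genes()].
#' @param known_cad_mirnas Character vector of curated disease miRNA ids.
#' @param programs Named list of gene sets (for the program annotation).
#' @return List with `chains` (data.frame `rsid` (NA), `circ_id`, `mirna_id`,
#'   `gene_id`, `programs` semicolon-joined) and `summary` (`n_circ`,
#'   `n_mirna`, `n_gene`).
#' @export
ec_subnetwork <- function(triplets, common_gene_set, known_cad_mirnas,
                          programs) {
  keep <- triplets$gene_id %in% common_gene_set &
    triplets$mirna_id %in% known_cad_mirnas
  tr <- triplets[keep, , drop = FALSE]
  freq <- program_frequency(programs)
  prog_of <- setNames(gsub(",", ";", freq$program_names, fixed = TRUE),
                      freq$gene_id)
  chains <- data.frame(rsid = rep(NA_character_, nrow(tr)),
                       circ_id = tr$circ_id, mirna_id = tr$mirna_id,
                       gene_id = tr$gene_id,
                       programs = unname(prog_of[tr$gene_id]),
                       stringsAsFactors = FALSE)
  chains$programs[is.na(chains$programs)] <- ""
  chains <- chains[order(chains$circ_id, chains$mirna_id, chains$gene_id), ,
                   drop = FALSE]
  rownames(chains) <- NULL
  list(chains = chains,
       summary = list(n_circ = length(unique(chains$circ_id)),
                      n_mirna = length(unique(chains$mirna_id)),
                      n_gene = length(unique(chains$gene_id))))
}

#' Attach inside-variants to circuit chains
#'
#' Chains whose circRNA contains a GWAS variant are emitted once per matching
#' variant with the rsid attached; chains without overlaps pass through with
#' `rsid = NA`.
#'
#' @param chains Chain data.frame from [ec_subnetwork()].
#' @param variant_circ_overlaps Data.frame from [variants_on_circrnas()].
#' @return Chain data.frame with `rsid` filled where applicable.
#' @export
link_variants <- function(chains, variant_circ_overlaps) {
  if (!nrow(chains)) return(chains)
  rows <- lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, , drop = FALSE]
    hits <- variant_circ_overlaps$rsid[
      variant_circ_overlaps$circ_id == ch$circ_id]
    if (!length(hits)) return(ch)
    out <- ch[rep(1L, length(hits)), , drop = FALSE]
    out$rsid <- sort(hits)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-circRNA circuit report
#'
#' Aggregates chains per circRNA: number of distinct target genes and miRNAs,
#' attached variants, and the union of programs; ranked by target-gene count
#' descending with ties broken by circRNA id.
#'
#' @param chains Chain data.frame (from [ec_subnetwork()] or
#'   [link_variants()]).
#' @return Data.frame with columns `circ_id`, `n_genes`, `n_mirnas`,
#'   `variants` (comma-joined rsids or ""), `programs` (semicolon-joined
#'   union).
#' @export
circuit_report <- function(chains) {
  if (!nrow(chains))
    return(data.frame(circ_id = character(), n_genes = integer(),
                      n_mirnas = integer(), variants = character(),
                      programs = character(), stringsAsFactors = FALSE))
  byc <- split(chains, chains$circ_id)
  rows <- lapply(byc, function(ch) {
    progs <- unique(unlist(strsplit(ch$programs, ";", fixed = TRUE),
                           use.names = FALSE))
    progs <- sort(progs[nzchar(progs)])
    vars <- sort(unique(ch$rsid[!is.na(ch$rsid)]))
    data.frame(circ_id = ch$circ_id[1],
               n_genes = length(unique(ch$gene_id)),
               n_mirnas = length(unique(ch$mirna_id)),
               variants = paste(vars, collapse = ","),
               programs = paste(progs, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_genes, out$circ_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
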