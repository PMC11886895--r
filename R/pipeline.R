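# End-to-end orchestration: interactions -> ceRNA pairs/triplets -> GWAS
# proximity -> differential expression -> disease sets -> risk network ->
# topology + enrichment -> EC circuits -> report.
#
# Every stage runs behind a named wrapper so failures abort with the stage
# name; all outputs are plain text written with fixed formatting, so a run
# with the same seed and inputs is byte-identical (checksummed manifest).

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

.bundle_input_paths <- function(input_dir) {
  nm <- c(interactions = "interactions.tsv",
          circ_features = "circ_features.bed",
          gene_features = "gene_features.bed",
          variants = "variants.tsv",
          expr_circ = "expr_circ.tsv", expr_circ_labels = "expr_circ_labels.tsv",
          expr_mrna = "expr_mrna.tsv", expr_mrna_labels = "expr_mrna_labels.tsv",
          programs = "programs.gmt", go_terms = "go_terms.gmt",
          known_circ = "known_circ.txt", known_mirna = "known_mirna.txt",
          known_gene = "known_gene.txt")
  as.list(setNames(file.path(input_dir, nm), names(nm)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on an input bundle (see
#' [generate_bundle()] for the expected file layout) and writes all stage
#' outputs, a markdown report and a checksummed run manifest into `out_dir`.
#' With `synthetic = TRUE` the input bundle is first generated under
#' `out_dir/input` with the given preset and seed.
#'
#' @param config A [cerna_config()].
#' @param input_dir Directory holding the input bundle (ignored when
#'   `synthetic = TRUE`).
#' @param out_dir Output directory (created if needed).
#' @param synthetic Generate the inputs with [generate_bundle()] first?
#' @param preset Synthetic preset passed to [bundle_params()].
#' @param overrides Parameter overrides for the synthetic generator.
#' @return An object of class `cerna_run`: list with `config`, `summary`
#'   (named counts and p-values), `paths` (stage outputs), `manifest`.
#' @export
run_pipeline <- function(config = cerna_config(), input_dir = NULL,
                         out_dir, synthetic = FALSE, preset = "small",
                         overrides = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (synthetic) {
    input_dir <- file.path(out_dir, "input")
    .stage("synthetic_data",
           generate_bundle(input_dir, seed = config$rng_seed,
                           params = bundle_params(preset),
                           overrides = overrides))
  }
  if (is.null(input_dir)) stop("input_dir is required", call. = FALSE)
  inp <- .bundle_input_paths(input_dir)
  missing_f <- !vapply(inp, file.exists, TRUE)
  if (any(missing_f))
    stop("stage 'inputs': missing input file: ",
         inp[[which(missing_f)[1]]], call. = FALSE)
  message("[inputs] reading bundle from ", input_dir)

  interactions <- .stage("read_interactions",
                         read_interactions(inp$interactions,
                                           config$min_confidence))
  message("[cerna] ", nrow(interactions), " filtered interactions")
  maps <- .stage("cerna", build_bipartite(interactions))
  pairs <- .stage("cerna", enumerate_cerna_pairs(maps$circ, maps$gene,
                                                 config$min_shared_mirnas))
  net_sum <- network_summary(pairs)
  message("[cerna] ", net_sum$n_pairs, " pairs, ", net_sum$n_triplets,
          " triplets")

  circ_feat <- .stage("gwas", read_bed(inp$circ_features, "circRNA"))
  gene_feat <- .stage("gwas", read_bed(inp$gene_features, "gene"))
  features <- rbind(circ_feat, gene_feat)
  variants <- .stage("gwas", read_variants(inp$variants))
  gwas <- .stage("gwas", collect_gwas_features(variants, features, config))
  overlaps <- .stage("gwas", variants_on_circrnas(variants, circ_feat))
  message("[gwas] ", length(gwas$circ_ids), " nearby circRNAs, ",
          length(gwas$gene_ids), " nearby genes, ", nrow(overlaps),
          " inside-circRNA variants")

  de_circ <- .stage("diffexpr", call_de(
    read_expression(inp$expr_circ, inp$expr_circ_labels), config))
  de_mrna <- .stage("diffexpr", call_de(
    read_expression(inp$expr_mrna, inp$expr_mrna_labels), config))
  message("[diffexpr] ", sum(de_circ$is_de), " DE circRNAs, ",
          sum(de_mrna$is_de), " DE genes")

  ann <- .stage("disease_sets", assemble_disease_sets(
    gwas_circ = gwas$circ_ids, gwas_gene = gwas$gene_ids,
    known_circ = read_id_list(inp$known_circ),
    known_mirna = read_id_list(inp$known_mirna),
    known_gene = read_id_list(inp$known_gene),
    de_circ = de_circ$feature_id[de_circ$is_de],
    de_gene = de_mrna$feature_id[de_mrna$is_de]))
  risk <- .stage("risk_network", extract_risk_network(pairs, ann))
  message("[risk_network] ", risk$summary$n_edges, " edges, ",
          risk$summary$n_circ, " circRNAs, ", risk$summary$n_gene, " genes")

  flagged <- ann[(ann$gwas | ann$known | ann$de) &
                   ann$feature_class %in% c("circRNA", "gene"), ]
  topo <- .stage("topology", {
    deg <- node_degree(pairs)
    n_dis <- sum(deg$id %in% flagged$feature_id)
    if (nrow(pairs) && n_dis > 0L && n_dis < nrow(deg)) {
      list(degree = compare_topology(pairs, flagged$feature_id, "degree"),
           betweenness = compare_topology(pairs, flagged$feature_id,
                                          "betweenness"))
    } else NULL
  })
  go_sets <- .stage("enrichment", read_gmt(inp$go_terms))
  universe <- unique(pairs$gene_id)
  risk_genes <- unique(risk$edges$gene_id)
  enr <- .stage("enrichment", {
    if (length(universe)) enrich(risk_genes, go_sets, universe,
                                 config$enrich_fdr)
    else NULL
  })
  message("[enrichment] ", if (is.null(enr)) 0L else sum(enr$significant),
          " terms at FDR < ", config$enrich_fdr)

  programs <- .stage("ec_circuits", read_gmt(inp$programs))
  common <- .stage("ec_circuits", common_genes(programs,
                                               config$min_program_count))
  risk_triplets <- expand_triplets(risk$edges)
  ec <- .stage("ec_circuits", ec_subnetwork(
    risk_triplets, common, read_id_list(inp$known_mirna), programs))
  chains <- .stage("ec_circuits", link_variants(ec$chains, overlaps))
  report_tab <- circuit_report(chains)
  message("[ec_circuits] ", nrow(chains), " chains over ", ec$summary$n_circ,
          " circRNAs")

  out <- function(x) file.path(out_dir, x)
  paths <- list(pairs = out("pairs.tsv"), triplets = out("triplets.tsv"),
                gwas_assignments = out("gwas_assignments.tsv"),
                variant_overlaps = out("variant_circ_overlaps.tsv"),
                de_circ = out("de_circ.tsv"), de_mrna = out("de_mrna.tsv"),
                annotations = out("disease_annotations.tsv"),
                risk_edges = out("risk_edges.tsv"),
                risk_graphml = out("risk_network.graphml"),
                enrichment = out("enrichment.tsv"),
                chains = out("ec_chains.tsv"),
                circuit_report = out("circuit_report.tsv"),
                report = out("report.md"),
                manifest = out("run_manifest.json"))
  .stage("write_outputs", {
    write_pairs(pairs, paths$pairs)
    .write_tsv(expand_triplets(pairs), paths$triplets)
    .write_tsv(gwas$assignments, paths$gwas_assignments)
    .write_tsv(overlaps, paths$variant_overlaps)
    .write_tsv(as.data.frame(de_circ), paths$de_circ)
    .write_tsv(as.data.frame(de_mrna), paths$de_mrna)
    .write_tsv(ann, paths$annotations)
    .write_tsv(risk$edges, paths$risk_edges)
    if (nrow(risk$edges)) write_graphml(risk, paths$risk_graphml)
    if (!is.null(enr)) .write_tsv(enr, paths$enrichment)
    .write_tsv(chains, paths$chains)
    .write_tsv(report_tab, paths$circuit_report)
  })

  summary <- list(
    n_interactions = nrow(interactions),
    n_pairs = net_sum$n_pairs, n_triplets = net_sum$n_triplets,
    n_circ = net_sum$n_circ, n_mirna = net_sum$n_mirna,
    n_gene = net_sum$n_gene,
    n_gwas_circ = length(gwas$circ_ids),
    n_gwas_gene = length(gwas$gene_ids),
    n_variant_inside = nrow(overlaps),
    n_de_circ = sum(de_circ$is_de), n_de_mrna = sum(de_mrna$is_de),
    n_annotated_circ = sum(ann$feature_class == "circRNA"),
    n_annotated_mirna = sum(ann$feature_class == "miRNA"),
    n_annotated_gene = sum(ann$feature_class == "gene"),
    n_risk_edges = risk$summary$n_edges,
    n_risk_circ = risk$summary$n_circ, n_risk_gene = risk$summary$n_gene,
    topology_degree_p = if (is.null(topo)) NA_real_ else topo$degree$p_value,
    topology_betweenness_p = if (is.null(topo)) NA_real_ else
      topo$betweenness$p_value,
    n_enriched_terms = if (is.null(enr)) 0L else sum(enr$significant),
    n_common_genes = length(common),
    n_ec_chains = nrow(chains),
    n_ec_circ = ec$summary$n_circ, n_ec_mirna = ec$summary$n_mirna,
    n_ec_gene = ec$summary$n_gene,
    n_variant_linked_circ = length(unique(chains$circ_id[!is.na(chains$rsid)])))

  run <- structure(list(config = config, summary = summary, paths = paths,
                        input_dir = input_dir, out_dir = out_dir),
                   class = "cerna_run")
  writeLines(pipeline_report(run), paths$report, useBytes = TRUE)
  data_out <- paths[setdiff(names(paths), "manifest")]
  data_out <- data_out[vapply(data_out, file.exists, TRUE)]
  input_files <- .bundle_input_paths(input_dir)
  manifest <- list(
    config = unclass(config),
    inputs = lapply(input_files, function(pth)
      list(path = basename(pth), md5 = unname(tools::md5sum(pth)))),
    outputs = lapply(data_out, function(pth)
      list(path = basename(pth), md5 = unname(tools::md5sum(pth)))),
    summary = summary)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  run$manifest <- manifest
  run
}

#' Render a run report
#'
#' Human-readable markdown tabulating the headline numbers of a run: network
#' sizes, GWAS proximity counts, DE counts, risk-network size, topology
#' p-values, enrichment and circuit counts. Sections with zero results are
#' rendered with an explicit zero rather than omitted.
#'
#' @param run A `cerna_run` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(run) {
  s <- run$summary
  fmt_p <- function(p) if (is.na(p)) "NA" else sprintf("%.4g", p)
  c("# ceRNA risk-network run report",
    "",
    "## Global ceRNA network",
    sprintf("- retained interactions: %d", s$n_interactions),
    sprintf("- competitive circRNA-mRNA pairs: %d", s$n_pairs),
    sprintf("- circRNA-miRNA-mRNA triplets: %d", s$n_triplets),
    sprintf("- entities: %d circRNAs, %d miRNAs, %d genes",
            s$n_circ, s$n_mirna, s$n_gene),
    "",
    "## GWAS proximity",
    sprintf("- nearby circRNAs: %d", s$n_gwas_circ),
    sprintf("- nearby genes: %d", s$n_gwas_gene),
    sprintf("- variants inside circRNAs: %d", s$n_variant_inside),
    "",
    "## Differential expression",
    sprintf("- DE circRNAs: %d", s$n_de_circ),
    sprintf("- DE genes: %d", s$n_de_mrna),
    "",
    "## Disease-associated features",
    sprintf("- circRNAs: %d, miRNAs: %d, genes: %d",
            s$n_annotated_circ, s$n_annotated_mirna, s$n_annotated_gene),
    "",
    "## Risk network",
    sprintf("- edges: %d (%d circRNAs, %d genes)",
            s$n_risk_edges, s$n_risk_circ, s$n_risk_gene),
    sprintf("- degree, disease vs background (one-sided Mann-Whitney p): %s",
            fmt_p(s$topology_degree_p)),
    sprintf("- betweenness, disease vs background (one-sided Mann-Whitney p): %s",
            fmt_p(s$topology_betweenness_p)),
    sprintf("- enriched gene sets (FDR < %.3g): %d",
            run$config$enrich_fdr, s$n_enriched_terms),
    "",
    "## EC-specific circuits",
    sprintf("- common program genes (>= %d programs): %d",
            run$config$min_program_count, s$n_common_genes),
    sprintf("- circuit chains: %d (%d circRNAs, %d miRNAs, %d genes)",
            s$n_ec_chains, s$n_ec_circ, s$n_ec_mirna, s$n_ec_gene),
    sprintf("- variant-linked circRNAs: %d", s$n_variant_linked_circ))
}

#' @export
print.cerna_run <- function(x, ...) {
  cat(paste(pipeline_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.cerna_run <- function(object, ...) object$summary
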