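# Disease-risk subnetwork extraction, topology and enrichment.
#
# Disease annotations flag features as GWAS-nearby, curated-known, or
# differentially expressed. The risk network keeps exactly the ceRNA pairs
# with at least one annotated endpoint (circRNA or gene; miRNA annotations
# are carried for the circuit stage but do not drive edge retention).

#' Assemble per-feature disease annotations
#'
#' Unions the three evidence channels (GWAS proximity, curated-known,
#' differential expression) into one record per (feature, class) with logical
#' flags. Features with no evidence are not stored.
#'
#' @param gwas_circ,gwas_gene Character vectors of GWAS-nearby ids.
#' @param known_circ,known_mirna,known_gene Curated disease-association ids.
#' @param de_circ,de_gene Differentially expressed ids.
#' @return Data.frame with columns `feature_id`, `feature_class` (`circRNA`,
#'   `miRNA` or `gene`), `gwas`, `known`, `de` (logical), one row per
#'   annotated feature per class, plus a `counts` attribute with per-class
#'   totals.
#' @export
assemble_disease_sets <- function(gwas_circ = character(),
                                  gwas_gene = character(),
                                  known_circ = character(),
                                  known_mirna = character(),
                                  known_gene = character(),
                                  de_circ = character(),
                                  de_gene = character()) {
  one_class <- function(class, gwas, known, de) {
    ids <- sort(unique(c(gwas, known, de)))
    if (!length(ids)) return(NULL)
    data.frame(feature_id = ids, feature_class = class,
               gwas = ids %in% gwas, known = ids %in% known,
               de = ids %in% de, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, c(list(
    one_class("circRNA", gwas_circ, known_circ, de_circ),
    one_class("miRNA", character(), known_mirna, character()),
    one_class("gene", gwas_gene, known_gene, de_gene)),
    list(data.frame(feature_id = character(), feature_class = character(),
                    gwas = logical(), known = logical(), de = logical(),
                    stringsAsFactors = FALSE))))
  rownames(ann) <- NULL
  attr(ann, "counts") <- vapply(c(circRNA = "circRNA", miRNA = "miRNA",
                                  gene = "gene"),
                                function(cl) sum(ann$feature_class == cl), 0L)
  ann
}

#' Extract the disease-risk ceRNA subnetwork
#'
#' Retains exactly the pairs with at least one annotated endpoint: the
#' circRNA carries any flag in the circRNA class or the gene carries any flag
#' in the gene class.
#'
#' @param pairs Data.frame from [enumerate_cerna_pairs()].
#' @param annotations Data.frame from [assemble_disease_sets()].
#' @return Object of class `risk_network`: list with `edges` (the retained
#'   pairs), `nodes` (id, class, flags) and `summary` (n_edges, n_circ,
#'   n_gene).
#' @export
extract_risk_network <- function(pairs, annotations) {
  flagged <- annotations[annotations$gwas | annotations$known | annotations$de, ,
                         drop = FALSE]
  ann_circ <- flagged$feature_id[flagged$feature_class == "circRNA"]
  ann_gene <- flagged$feature_id[flagged$feature_class == "gene"]
  keep <- pairs$circ_id %in% ann_circ | pairs$gene_id %in% ann_gene
  edges <- pairs[keep, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- c(unique(edges$circ_id), unique(edges$gene_id))
  cls <- c(rep("circRNA", length(unique(edges$circ_id))),
           rep("gene", length(unique(edges$gene_id))))
  flag_of <- function(id, class, col) {
    m <- match(paste(class, id), paste(flagged$feature_class,
                                       flagged$feature_id))
    out <- flagged[[col]][m]
    out[is.na(out)] <- FALSE
    out
  }
  nodes <- data.frame(id = ids, class = cls,
                      gwas = flag_of(ids, cls, "gwas"),
                      known = flag_of(ids, cls, "known"),
                      de = flag_of(ids, cls, "de"),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes,
                 summary = list(n_edges = nrow(edges),
                                n_circ = sum(nodes$class == "circRNA"),
                                n_gene = sum(nodes$class == "gene"))),
            class = "risk_network")
}

#' @export
print.risk_network <- function(x, ...) {
  cat(sprintf("risk ceRNA network: %d edges, %d circRNAs, %d genes\n",
              x$summary$n_edges, x$summary$n_circ, x$summary$n_gene))
  invisible(x)
}

# circRNA and gene namespaces stay distinct in the graph: vertex names are
# class-prefixed so a circRNA named after its host gene never collapses onto
# the gene node.
.as_igraph <- function(x) {
  edges <- if (inherits(x, "risk_network")) x$edges else x
  if (!nrow(edges)) return(igraph::make_empty_graph(0, directed = FALSE))
  el <- cbind(paste0("circRNA|", edges$circ_id),
              paste0("gene|", edges$gene_id))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

.strip_ns <- function(nm) sub("^(circRNA|gene)\\|", "", nm)

.node_table <- function(g, value) {
  if (igraph::vcount(g) == 0L)
    return(data.frame(id = character(), class = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  nm <- igraph::V(g)$name
  out <- data.frame(id = .strip_ns(nm),
                    class = sub("\\|.*$", "", nm),
                    value = unname(value), stringsAsFactors = FALSE)
  out[order(out$class, out$id), , drop = FALSE]
}

#' Node degree of a ceRNA network
#'
#' Incident-edge count on the undirected simple bipartite graph.
#'
#' @param network A `risk_network` or a pair data.frame (edges).
#' @return Data.frame with columns `id`, `class`, `value`.
#' @export
node_degree <- function(network) {
  g <- .as_igraph(network)
  res <- .node_table(g, igraph::degree(g))
  rownames(res) <- NULL
  res
}

#' Shortest-path betweenness of a ceRNA network
#'
#' Unnormalized betweenness centrality: for each node v, the sum over
#' unordered node pairs s != t != v of the fraction of shortest s-t paths
#' passing through v.
#'
#' @param network A `risk_network` or a pair data.frame (edges).
#' @return Data.frame with columns `id`, `class`, `value`.
#' @export
node_betweenness <- function(network) {
  g <- .as_igraph(network)
  res <- .node_table(g, igraph::betweenness(g, directed = FALSE))
  rownames(res) <- NULL
  res
}

#' Compare topology of disease nodes against the background
#'
#' Computes the chosen per-node metric on the supplied network and tests
#' whether disease-annotated nodes have stochastically larger values than the
#' remaining (background) nodes with a one-sided Mann-Whitney U test
#' (exact null for small tie-free samples, otherwise normal approximation
#' with tie correction, as in [stats::wilcox.test()]).
#'
#' @param network A `risk_network` or pair data.frame; typically the full
#'   background ceRNA network.
#' @param disease_node_ids Character vector of disease node ids (matched
#'   against the unprefixed id).
#' @param metric `"degree"` or `"betweenness"`.
#' @return Object of class `topology_comparison`: list with `metric`,
#'   `disease_values`, `background_values`, `u_statistic`, `p_value`.
#' @export
compare_topology <- function(network, disease_node_ids,
                             metric = c("degree", "betweenness")) {
  metric <- match.arg(metric)
  tab <- if (metric == "degree") node_degree(network) else
    node_betweenness(network)
  disease <- tab$value[tab$id %in% disease_node_ids]
  background <- tab$value[!tab$id %in% disease_node_ids]
  if (!length(disease) || !length(background))
    stop("compare_topology: both groups must be non-empty", call. = FALSE)
  mw <- mann_whitney_greater(disease, background)
  structure(list(metric = metric, disease_values = disease,
                 background_values = background,
                 u_statistic = mw$u_statistic, p_value = mw$p_value),
            class = "topology_comparison")
}

#' One-sided Mann-Whitney U test (first group greater)
#'
#' Wraps [stats::wilcox.test()] with `alternative = "greater"`: the exact U
#' null distribution for small tie-free samples, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (x tested as stochastically greater).
#' @return List with `u_statistic` and `p_value`.
#' @export
mann_whitney_greater <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Hypergeometric upper-tail probability
#'
#' P[X >= k] for X ~ Hypergeom(N, K, n): the over-representation p-value for
#' drawing k or more marked genes when n genes are drawn from a universe of N
#' containing K marked ones.
#'
#' @param k Observed overlap.
#' @param K Marked (term) genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return Tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: disease (n=%d, median %.3g) vs background (n=%d, median %.3g), U=%.4g, one-sided p=%.3g\n",
    x$metric, length(x$disease_values), stats::median(x$disease_values),
    length(x$background_values), stats::median(x$background_values),
    x$u_statistic, x$p_value))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query genes over-represent the set
#' within the universe: p = P[X >= k] with X ~ Hypergeom(N, K, n), where N is
#' the universe size, K the in-universe set size, n the query size and k the
#' overlap. FDR across terms by Benjamini-Hochberg.
#'
#' @param query_genes Character vector, must be a subset of `universe`.
#' @param term_sets Named list of character vectors (e.g. from [read_gmt()]);
#'   each set is intersected with the universe before testing.
#' @param universe Character vector defining the background gene universe.
#' @param enrich_fdr FDR threshold flagging significant terms.
#' @return Data.frame with columns `term`, `overlap_k`, `term_size_K`,
#'   `query_size_n`, `universe_N`, `p_value`, `fdr`, `significant`, ordered by
#'   increasing p then term.
#' @export
enrich <- function(query_genes, term_sets, universe, enrich_fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("enrich: empty universe", call. = FALSE)
  query_genes <- unique(query_genes)
  out_of <- setdiff(query_genes, universe)
  if (length(out_of))
    stop("enrich: query gene '", out_of[1], "' not in universe", call. = FALSE)
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(term_sets), function(term) {
    set <- intersect(term_sets[[term]], universe)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- hypergeom_tail(k, K, n, N)
    data.frame(term = term, overlap_k = k, term_size_K = K, query_size_n = n,
               universe_N = N, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), overlap_k = integer(),
                      term_size_K = integer(), query_size_n = integer(),
                      universe_N = integer(), p_value = numeric(),
                      fdr = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- res$fdr < enrich_fdr
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export a network as GraphML
#'
#' Writes the undirected bipartite graph (class-prefixed vertex names, with
#' `id` and `class` vertex attributes) for external viewers such as Cytoscape.
#'
#' @param network A `risk_network` or pair data.frame.
#' @param path Output GraphML path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- .as_igraph(network)
  igraph::V(g)$label <- .strip_ns(igraph::V(g)$name)
  igraph::V(g)$class <- sub("\\|.*$", "", igraph::V(g)$name)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
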