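# Synthetic input bundles with planted ground truth.
#
# Every generator is fully seeded and emits the exact formats the readers in
# this package consume, so each downstream stage can be checked against a
# known planted truth without any database download. Planted ceRNA pairs are
# wired through dedicated miRNAs (never reused across planted pairs), so with
# zero background edges the enumeration stage recovers exactly the planted
# pairs.

.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + k)
}

.ids <- function(prefix, n) sprintf("%s_%05d", prefix, seq_len(n))

#' Generate a circRNA-miRNA-mRNA interactome with planted ceRNA pairs
#'
#' Each planted (circRNA, gene) pair is wired through exactly `min_shared`
#' dedicated miRNAs; background circRNA-miRNA and miRNA-mRNA edges are drawn
#' independently with probability `background_edge_prob`. All emitted edges
#' get confidences drawn uniformly from (0.31, 1.0) so none fall to the
#' default confidence filter.
#'
#' @param n_circ,n_mirna,n_gene Universe sizes.
#' @param background_edge_prob Per-possible-edge background probability.
#' @param n_planted_pairs Number of planted competitive pairs.
#' @param min_shared Dedicated shared miRNAs per planted pair.
#' @param seed Integer seed.
#' @return List with `interactions` (data.frame in [read_interactions()]
#'   layout), `truth` (list with `planted_pairs` data.frame) and the id
#'   universes (`circ_ids`, `mirna_ids`, `gene_ids`).
#' @export
generate_interactome <- function(n_circ, n_mirna, n_gene,
                                 background_edge_prob = 0.05,
                                 n_planted_pairs = 5L, min_shared = 3L,
                                 seed = 1L) {
  if (n_planted_pairs > n_circ * n_gene)
    stop("n_planted_pairs exceeds the number of possible pairs", call. = FALSE)
  if (min_shared > n_mirna)
    stop("min_shared exceeds n_mirna", call. = FALSE)
  if (n_planted_pairs * min_shared > n_mirna)
    stop("not enough miRNAs for dedicated wiring (need n_planted_pairs * min_shared)",
         call. = FALSE)
  set.seed(seed)
  circ <- .ids("circ", n_circ)
  mir <- .ids("mir", n_mirna)
  gene <- .ids("gene", n_gene)
  # planted pairs: distinct (circ, gene) combinations
  pair_idx <- sample.int(n_circ * n_gene, n_planted_pairs)
  pc <- circ[(pair_idx - 1L) %% n_circ + 1L]
  pg <- gene[(pair_idx - 1L) %/% n_circ + 1L]
  ded <- sample(mir, n_planted_pairs * min_shared)
  ded_by_pair <- split(ded, rep(seq_len(n_planted_pairs), each = min_shared))
  cm <- data.frame(source_id = rep(pc, each = min_shared),
                   target_id = unlist(ded_by_pair, use.names = FALSE),
                   stringsAsFactors = FALSE)
  mg <- data.frame(source_id = unlist(ded_by_pair, use.names = FALSE),
                   target_id = rep(pg, each = min_shared),
                   stringsAsFactors = FALSE)
  if (background_edge_prob > 0) {
    draw <- function(src, tgt) {
      hit <- which(runif(length(src) * length(tgt)) < background_edge_prob)
      data.frame(source_id = src[(hit - 1L) %% length(src) + 1L],
                 target_id = tgt[(hit - 1L) %/% length(src) + 1L],
                 stringsAsFactors = FALSE)
    }
    cm <- rbind(cm, draw(circ, mir))
    mg <- rbind(mg, draw(mir, gene))
  }
  cm <- cm[!duplicated(cm), , drop = FALSE]
  mg <- mg[!duplicated(mg), , drop = FALSE]
  edges <- rbind(
    data.frame(source_id = cm$source_id, source_type = "circRNA",
               target_id = cm$target_id, target_type = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(source_id = mg$source_id, source_type = "miRNA",
               target_id = mg$target_id, target_type = "mRNA",
               stringsAsFactors = FALSE))
  edges <- edges[order(edges$source_type, edges$source_id, edges$target_id), ,
                 drop = FALSE]
  edges$confidence <- round(runif(nrow(edges), 0.31, 1.0), 6)
  rownames(edges) <- NULL
  truth <- list(planted_pairs = data.frame(circ_id = pc, gene_id = pg,
                                           stringsAsFactors = FALSE))
  list(interactions = edges, truth = truth,
       circ_ids = circ, mirna_ids = mir, gene_ids = gene)
}

#' Generate non-overlapping genomic features and GWAS variants
#'
#' Features (circRNAs and genes) are placed without overlap on `n_chrom`
#' chromosomes of length `chrom_length`. Exactly `n_inside_hits` variants are
#' placed strictly inside distinct circRNA intervals; the remaining variants
#' are placed uniformly outside every circRNA (rejection sampling), so the
#' planted inside set is exact. The truth records inside and within-window
#' relations computed directly from the interval definition.
#'
#' @param n_features Total feature count (used when `feature_ids` is NULL;
#'   types then alternate circRNA/gene).
#' @param n_variants Number of variants.
#' @param chrom_length Chromosome length in bp.
#' @param window_bp Window half-width recorded in the truth.
#' @param n_inside_hits Variants planted inside circRNAs.
#' @param seed Integer seed.
#' @param feature_ids,feature_types Optional explicit feature universe.
#' @param n_chrom Number of chromosomes.
#' @param circ_len_range,gene_len_range Feature length ranges (bp).
#' @return List with `features`, `variants` and `truth` (list with `inside`
#'   and `within_window` data.frames).
#' @export
generate_genome_and_variants <- function(n_features, n_variants, chrom_length,
                                         window_bp = 500000L,
                                         n_inside_hits = 1L, seed = 1L,
                                         feature_ids = NULL,
                                         feature_types = NULL, n_chrom = 1L,
                                         circ_len_range = c(200L, 5000L),
                                         gene_len_range = c(1000L, 50000L)) {
  set.seed(seed)
  if (is.null(feature_ids)) {
    feature_types <- rep(c("circRNA", "gene"), length.out = n_features)
    feature_ids <- ifelse(feature_types == "circRNA",
                          .ids("circ", n_features),
                          .ids("gene", n_features))
  } else {
    n_features <- length(feature_ids)
    stopifnot(length(feature_types) == n_features)
  }
  n_circ <- sum(feature_types == "circRNA")
  if (n_inside_hits > min(n_variants, n_circ))
    stop("n_inside_hits exceeds min(n_variants, number of circRNAs)",
         call. = FALSE)
  lens <- integer(n_features)
  lens[feature_types == "circRNA"] <-
    sample(circ_len_range[1]:circ_len_range[2], n_circ, replace = TRUE)
  lens[feature_types == "gene"] <-
    sample(gene_len_range[1]:gene_len_range[2], n_features - n_circ,
           replace = TRUE)
  chrom_of <- sample.int(n_chrom, n_features, replace = TRUE)
  feat <- vector("list", n_chrom)
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    idx <- sample(idx)                       # random along-chromosome order
    free <- chrom_length - sum(lens[idx])
    if (free < 0)
      stop("chrom_length too small to place features without overlap",
           call. = FALSE)
    gaps <- sort(sample.int(free + 1L, length(idx), replace = TRUE) - 1L)
    starts <- gaps + c(0L, cumsum(lens[idx]))[seq_along(idx)]
    feat[[ch]] <- data.frame(
      id = feature_ids[idx], feature_type = feature_types[idx],
      chrom = paste0("chr", ch), start = as.integer(starts),
      end = as.integer(starts + lens[idx]),
      strand = sample(c("+", "-"), length(idx), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feat)
  features <- features[order(features$chrom, features$start, features$id), ,
                       drop = FALSE]
  rownames(features) <- NULL
  circ_feat <- features[features$feature_type == "circRNA", , drop = FALSE]
  # planted inside variants, one per distinct circRNA
  host <- circ_feat[sample.int(nrow(circ_feat), n_inside_hits), , drop = FALSE]
  inside_pos <- host$start +
    vapply(host$end - host$start, function(L) sample.int(L, 1L) - 1L, 1L)
  n_rest <- n_variants - n_inside_hits
  rest_chrom <- integer(0); rest_pos <- integer(0)
  while (length(rest_pos) < n_rest) {
    need <- n_rest - length(rest_pos)
    ch <- sample.int(n_chrom, need, replace = TRUE)
    ps <- vapply(ch, function(x) sample.int(chrom_length, 1L) - 1L, 1L)
    chn <- paste0("chr", ch)
    in_circ <- vapply(seq_len(need), function(i) {
      any(circ_feat$chrom == chn[i] & circ_feat$start <= ps[i] &
            ps[i] < circ_feat$end)
    }, TRUE)
    rest_chrom <- c(rest_chrom, ch[!in_circ])
    rest_pos <- c(rest_pos, ps[!in_circ])
  }
  variants <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n_variants)),
    chrom = c(host$chrom, paste0("chr", rest_chrom)),
    pos = as.integer(c(inside_pos, rest_pos)),
    stringsAsFactors = FALSE)
  truth <- list(
    inside = data.frame(rsid = variants$rsid[seq_len(n_inside_hits)],
                        feature_id = host$id, stringsAsFactors = FALSE),
    within_window = .window_truth(variants, features, window_bp))
  list(features = features, variants = variants, truth = truth)
}

# within-window truth computed directly from the interval definition
.window_truth <- function(variants, features, window_bp) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    f <- features[features$chrom == v$chrom, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    inside <- f$start <= v$pos & v$pos < f$end
    d <- pmin(abs(v$pos - (f$end - 1L)), abs(v$pos - f$start))
    d[inside] <- 0L
    hit <- d <= window_bp
    if (!any(hit)) return(NULL)
    data.frame(rsid = v$rsid, feature_id = f$id[hit],
               distance_bp = as.integer(d[hit]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(rsid = character(), feature_id = character(),
               distance_bp = integer(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Generate a two-group log2 expression matrix with planted effects
#'
#' Null features are Normal(mu_f, noise_sd) in both groups on the log2 scale;
#' `n_de` planted features have the case mean shifted by `+/- effect_log2`
#' (sign randomized per feature).
#'
#' @param n_features Feature count (ignored when `feature_ids` given).
#' @param n_case,n_control Group sizes (>= 2 each).
#' @param n_de Number of planted differential features.
#' @param effect_log2 Absolute planted shift on the log2 scale.
#' @param noise_sd Per-observation Gaussian noise SD (> 0).
#' @param seed Integer seed.
#' @param feature_ids Optional explicit feature ids.
#' @param sample_prefix Prefix for generated sample ids.
#' @return List with `matrix` (an `expr_matrix`) and `truth` (data.frame
#'   `feature_id`, `effect_log2` of the planted features, signed).
#' @export
generate_expression <- function(n_features, n_case, n_control, n_de,
                                effect_log2 = 2, noise_sd = 0.5, seed = 1L,
                                feature_ids = NULL, sample_prefix = "s") {
  if (n_case < 2L || n_control < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- .ids("feat", n_features)
  n_features <- length(feature_ids)
  if (n_de > n_features) stop("n_de exceeds n_features", call. = FALSE)
  set.seed(seed)
  mu <- runif(n_features, 4, 10)
  vals <- matrix(rnorm(n_features * (n_case + n_control), mean = mu,
                       sd = noise_sd),
                 nrow = n_features)
  de_idx <- if (n_de > 0) sort(sample.int(n_features, n_de)) else integer()
  sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric()
  if (n_de > 0)
    vals[de_idx, seq_len(n_case)] <- vals[de_idx, seq_len(n_case)] +
      sign * effect_log2
  dimnames(vals) <- list(feature_ids,
                         c(sprintf("%s_case_%03d", sample_prefix,
                                   seq_len(n_case)),
                           sprintf("%s_ctrl_%03d", sample_prefix,
                                   seq_len(n_control))))
  mat <- structure(list(values = round(vals, 6),
                        labels = c(rep("case", n_case),
                                   rep("control", n_control))),
                   class = "expr_matrix")
  truth <- data.frame(feature_id = feature_ids[de_idx],
                      effect_log2 = sign * effect_log2,
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}

#' Generate overlapping gene programs with designated common genes
#'
#' Exactly `n_common` designated genes are each placed in at least
#' `min_program_count` programs; every other member appears in fewer than
#' `min_program_count` programs; every program has exactly
#' `genes_per_program` members.
#'
#' @param n_programs Number of programs.
#' @param genes_per_program Members per program.
#' @param gene_pool Character vector to draw members from.
#' @param n_common Number of designated high-frequency genes.
#' @param min_program_count Membership threshold the designated genes must
#'   reach (and the others must stay below).
#' @param seed Integer seed.
#' @return List with `programs` (named list of character vectors) and `truth`
#'   (character vector of the designated common genes, sorted).
#' @export
generate_programs <- function(n_programs = 13L, genes_per_program = 300L,
                              gene_pool, n_common = 20L,
                              min_program_count = 6L, seed = 1L) {
  if (n_common > genes_per_program)
    stop("n_common exceeds genes_per_program", call. = FALSE)
  if (min_program_count > n_programs)
    stop("min_program_count exceeds n_programs", call. = FALSE)
  if (length(gene_pool) < genes_per_program)
    stop("gene pool smaller than genes_per_program", call. = FALSE)
  set.seed(seed)
  prog_names <- sprintf("P%02d", seq_len(n_programs))
  common <- sample(gene_pool, n_common)
  members <- setNames(vector("list", n_programs), prog_names)
  for (g in common) {
    k <- sample(min_program_count:n_programs, 1L)
    for (p in sample(prog_names, k)) members[[p]] <- c(members[[p]], g)
  }
  others <- setdiff(gene_pool, common)
  usage <- setNames(integer(length(others)), others)
  cap <- min_program_count - 1L
  for (p in prog_names) {
    need <- genes_per_program - length(members[[p]])
    eligible <- names(usage)[usage < cap]
    if (length(eligible) < need)
      stop("gene pool too small to fill programs without exceeding the ",
           "membership cap", call. = FALSE)
    pick <- sample(eligible, need)
    usage[pick] <- usage[pick] + 1L
    members[[p]] <- c(members[[p]], pick)
  }
  list(programs = lapply(members, sort), truth = sort(common))
}

# --- bundle assembly ---------------------------------------------------------

#' Preset parameter sets for synthetic bundles
#'
#' `"small"` is a seconds-scale bundle for unit tests. `"paper"` mirrors the
#' shape of the published study inputs: 500 circRNAs x 300 miRNAs x 10,000
#' genes, 307 GWAS variants on a 22-chromosome genome, circRNA expression
#' with 24 case / 7 control samples, mRNA expression with 6 case / 9 control
#' samples, and 13 endothelial programs of 300 genes each with 20 designated
#' common genes.
#'
#' @param preset `"small"` or `"paper"`.
#' @return Named list of generator parameters.
#' @export
bundle_params <- function(preset = c("small", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    list(n_circ = 500L, n_mirna = 300L, n_gene = 10000L,
         background_edge_prob = 0.05, n_planted_pairs = 50L, min_shared = 3L,
         n_variants = 307L, n_inside_hits = 2L, n_chrom = 22L,
         chrom_length = 120000000L, window_bp = 500000L,
         circ_len_range = c(200L, 5000L), gene_len_range = c(1000L, 50000L),
         n_case_circ = 24L, n_control_circ = 7L, n_de_circ = 50L,
         n_case_mrna = 6L, n_control_mrna = 9L, n_de_mrna = 500L,
         effect_log2 = 2, noise_sd = 0.5,
         n_programs = 13L, genes_per_program = 300L, n_common = 20L,
         min_program_count = 6L,
         n_known_circ = 29L, n_known_mirna = 60L, n_known_gene = 54L,
         n_go_terms = 100L, go_size_range = c(30L, 150L))
  } else {
    list(n_circ = 30L, n_mirna = 40L, n_gene = 80L,
         background_edge_prob = 0.05, n_planted_pairs = 5L, min_shared = 3L,
         n_variants = 20L, n_inside_hits = 2L, n_chrom = 1L,
         chrom_length = 50000000L, window_bp = 500000L,
         circ_len_range = c(200L, 1000L), gene_len_range = c(500L, 3000L),
         n_case_circ = 10L, n_control_circ = 8L, n_de_circ = 5L,
         n_case_mrna = 8L, n_control_mrna = 8L, n_de_mrna = 10L,
         effect_log2 = 2, noise_sd = 0.5,
         n_programs = 13L, genes_per_program = 20L, n_common = 5L,
         min_program_count = 6L,
         n_known_circ = 5L, n_known_mirna = 10L, n_known_gene = 8L,
         n_go_terms = 20L, go_size_range = c(5L, 20L))
  }
}

#' Generate a complete synthetic input bundle
#'
#' Emits every file the pipeline consumes — interaction table, feature BEDs,
#' variant table, two expression matrices with labels, program and GO-style
#' GMT collections, curated-known id lists — plus `truth.json` (the planted
#' ground truth) and `manifest.json` (seed, parameters, file checksums).
#' Identical seed and parameters yield a byte-identical bundle.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param params Parameter list from [bundle_params()].
#' @param overrides Named list overriding individual parameters.
#' @return Invisible list with `paths` (named file paths), `truth`, `params`.
#' @export
generate_bundle <- function(out_dir, seed = 1L,
                            params = bundle_params("small"),
                            overrides = list()) {
  params[names(overrides)] <- overrides
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- params
  inter <- generate_interactome(p$n_circ, p$n_mirna, p$n_gene,
                                p$background_edge_prob, p$n_planted_pairs,
                                p$min_shared, seed = .subseed(seed, 1L))
  feature_ids <- c(inter$circ_ids, inter$gene_ids)
  feature_types <- c(rep("circRNA", p$n_circ), rep("gene", p$n_gene))
  geno <- generate_genome_and_variants(
    length(feature_ids), p$n_variants, p$chrom_length,
    window_bp = p$window_bp, n_inside_hits = p$n_inside_hits,
    seed = .subseed(seed, 2L), feature_ids = feature_ids,
    feature_types = feature_types, n_chrom = p$n_chrom,
    circ_len_range = p$circ_len_range, gene_len_range = p$gene_len_range)
  expr_circ <- generate_expression(
    p$n_circ, p$n_case_circ, p$n_control_circ, p$n_de_circ,
    effect_log2 = p$effect_log2, noise_sd = p$noise_sd,
    seed = .subseed(seed, 3L), feature_ids = inter$circ_ids,
    sample_prefix = "circ")
  expr_mrna <- generate_expression(
    p$n_gene, p$n_case_mrna, p$n_control_mrna, p$n_de_mrna,
    effect_log2 = p$effect_log2, noise_sd = p$noise_sd,
    seed = .subseed(seed, 4L), feature_ids = inter$gene_ids,
    sample_prefix = "mrna")
  progs <- generate_programs(p$n_programs, p$genes_per_program,
                             gene_pool = inter$gene_ids,
                             n_common = p$n_common,
                             min_program_count = p$min_program_count,
                             seed = .subseed(seed, 5L))
  set.seed(.subseed(seed, 6L))
  known_circ <- sort(sample(inter$circ_ids, p$n_known_circ))
  known_mirna <- sort(sample(inter$mirna_ids, p$n_known_mirna))
  known_gene <- sort(sample(inter$gene_ids, p$n_known_gene))
  go_sizes <- sample(p$go_size_range[1]:p$go_size_range[2], p$n_go_terms,
                     replace = TRUE)
  go <- setNames(lapply(go_sizes, function(s) sort(sample(inter$gene_ids, s))),
                 sprintf("GO%04d", seq_len(p$n_go_terms)))

  f <- function(x) file.path(out_dir, x)
  paths <- list(
    interactions = f("interactions.tsv"),
    circ_features = f("circ_features.bed"),
    gene_features = f("gene_features.bed"),
    variants = f("variants.tsv"),
    expr_circ = f("expr_circ.tsv"), expr_circ_labels = f("expr_circ_labels.tsv"),
    expr_mrna = f("expr_mrna.tsv"), expr_mrna_labels = f("expr_mrna_labels.tsv"),
    programs = f("programs.gmt"), go_terms = f("go_terms.gmt"),
    known_circ = f("known_circ.txt"), known_mirna = f("known_mirna.txt"),
    known_gene = f("known_gene.txt"),
    truth = f("truth.json"), manifest = f("manifest.json"))
  write_interactions(inter$interactions, paths$interactions)
  feats <- geno$features
  write_bed(feats[feats$feature_type == "circRNA", ], paths$circ_features)
  write_bed(feats[feats$feature_type == "gene", ], paths$gene_features)
  write_variants(geno$variants, paths$variants)
  .write_expr <- function(em, path, labels_path) {
    df <- data.frame(feature_id = rownames(em$values),
                     em$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_tsv(df, path)
    .write_tsv(data.frame(sample_id = colnames(em$values), group = em$labels,
                          stringsAsFactors = FALSE), labels_path)
  }
  .write_expr(expr_circ$matrix, paths$expr_circ, paths$expr_circ_labels)
  .write_expr(expr_mrna$matrix, paths$expr_mrna, paths$expr_mrna_labels)
  write_gmt(progs$programs, paths$programs)
  write_gmt(go, paths$go_terms)
  write_id_list(known_circ, paths$known_circ)
  write_id_list(known_mirna, paths$known_mirna)
  write_id_list(known_gene, paths$known_gene)

  truth <- list(
    planted_pairs = inter$truth$planted_pairs,
    planted_de_circ = expr_circ$truth,
    planted_de_mrna = expr_mrna$truth,
    planted_variant_hits = geno$truth$inside,
    planted_within_window = geno$truth$within_window,
    planted_common_genes = progs$truth,
    known_circ = known_circ, known_mirna = known_mirna,
    known_gene = known_gene)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data_files <- paths[setdiff(names(paths), c("truth", "manifest"))]
  manifest <- list(
    seed = seed, params = params,
    files = lapply(data_files, function(pth)
      list(path = basename(pth), md5 = unname(tools::md5sum(pth)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, params = params))
}

#' Read a bundle's planted truth
#' @param path Path to `truth.json`.
#' @return The planted-truth list (data.frames restored).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tabular <- c("planted_pairs", "planted_de_circ", "planted_de_mrna",
               "planted_variant_hits", "planted_within_window")
  for (nm in intersect(tabular, names(tr))) {
    if (is.list(tr[[nm]]))
      tr[[nm]] <- as.data.frame(tr[[nm]], stringsAsFactors = FALSE)
  }
  tr
}
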