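# Variant-to-feature proximity mapping.
#
# A variant is assigned to (a) every same-chromosome feature within the
# +/- window and (b) the k closest features lying entirely on each side,
# regardless of distance — computed separately for circRNAs and genes.
# Distance is the gap to the nearest interval boundary base (0 when the
# variant lies inside the half-open interval), strand ignored.

.relation_levels <- c("inside", "within_window", "closest_rank_k")

#' Distance between a variant and a genomic feature
#'
#' 0 when `start <= pos < end` (containment under half-open coordinates),
#' otherwise the base-pair gap to the nearest boundary base of the interval.
#'
#' @param variant One-row data.frame (or list) with `chrom` and `pos`.
#' @param feature One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @return Non-negative integer distance.
#' @export
feature_distance <- function(variant, feature) {
  if (variant$chrom != feature$chrom)
    stop("feature_distance: chromosome mismatch (", variant$chrom, " vs ",
         feature$chrom, ")", call. = FALSE)
  .feature_dist_vec(variant$pos, feature$start, feature$end)
}

.feature_dist_vec <- function(pos, start, end) {
  inside <- start <= pos & pos < end
  d <- pmin(abs(pos - (end - 1L)), abs(pos - start))
  d[inside] <- 0L
  as.integer(d)
}

#' Map one variant to nearby features
#'
#' Union of the window rule and the per-side closest rule, applied separately
#' per feature type. Each assignment is labeled with its strongest relation:
#' `inside` (containment) beats `within_window` (distance <= `window_bp`)
#' beats `closest_rank_k` (kept only by the per-side ranking). Features
#' containing the variant are excluded from the left/right ranking (they are
#' already included at distance 0). Ranking ties break by (distance, start,
#' id).
#'
#' @param variant One-row data.frame with `rsid`, `chrom`, `pos`.
#' @param features Feature data.frame (see [read_bed()]); may mix types.
#' @param window_bp Window half-width in bp (boundary inclusive).
#' @param n_closest_per_side Closest features kept per side and type.
#' @return Data.frame with columns `rsid`, `feature_id`, `feature_type`,
#'   `relation`, `distance_bp`, ordered by (feature_type, distance_bp,
#'   feature_id).
#' @export
map_variant <- function(variant, features, window_bp = 500000L,
                        n_closest_per_side = 2L) {
  out <- lapply(split(features, features$feature_type), function(ft) {
    .map_variant_one_type(variant, ft, window_bp, n_closest_per_side)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(.empty_assignments())
  res <- res[order(res$feature_type, res$distance_bp, res$feature_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_assignments <- function() {
  data.frame(rsid = character(), feature_id = character(),
             feature_type = character(), relation = character(),
             distance_bp = integer(), stringsAsFactors = FALSE)
}

.map_variant_one_type <- function(variant, ft, window_bp, n_closest_per_side) {
  ft <- ft[ft$chrom == variant$chrom, , drop = FALSE]
  if (!nrow(ft)) return(NULL)
  pos <- variant$pos
  d <- .feature_dist_vec(pos, ft$start, ft$end)
  inside <- d == 0L
  keep <- d <= window_bp
  # per-side ranking over features lying entirely left / right of pos
  for (side in c("left", "right")) {
    cand <- if (side == "left") ft$end <= pos else ft$start > pos
    cand <- which(cand & !inside)
    if (length(cand)) {
      ord <- cand[order(d[cand], ft$start[cand], ft$id[cand])]
      keep[head(ord, n_closest_per_side)] <- TRUE
    }
  }
  idx <- which(keep)
  if (!length(idx)) return(NULL)
  relation <- ifelse(inside[idx], "inside",
                     ifelse(d[idx] <= window_bp, "within_window",
                            "closest_rank_k"))
  data.frame(rsid = variant$rsid, feature_id = ft$id[idx],
             feature_type = ft$feature_type[idx], relation = relation,
             distance_bp = d[idx], stringsAsFactors = FALSE)
}

#' Map a full variant set and collect nearby feature sets
#'
#' Applies [map_variant()] to every variant and splits the resulting feature
#' universe by type.
#'
#' @param variants Data.frame from [read_variants()].
#' @param features Feature data.frame (circRNAs and genes together).
#' @param config A [cerna_config()] (uses `window_bp`, `n_closest_per_side`).
#' @return List with `circ_ids` (character), `gene_ids` (character) and
#'   `assignments` (row-bound [map_variant()] output).
#' @export
collect_gwas_features <- function(variants, features, config = cerna_config()) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    map_variant(variants[i, , drop = FALSE], features,
                window_bp = config$window_bp,
                n_closest_per_side = config$n_closest_per_side)
  })
  asg <- do.call(rbind, c(rows, list(.empty_assignments())))
  rownames(asg) <- NULL
  list(circ_ids = sort(unique(asg$feature_id[asg$feature_type == "circRNA"])),
       gene_ids = sort(unique(asg$feature_id[asg$feature_type == "gene"])),
       assignments = asg)
}

#' Variants lying inside circRNA intervals
#'
#' Strict containment under half-open coordinates: `start <= pos < end`.
#'
#' @param variants Data.frame from [read_variants()].
#' @param circ_features Feature data.frame restricted to circRNAs.
#' @return Data.frame with columns `rsid`, `circ_id`, ordered by (rsid,
#'   circ_id).
#' @export
variants_on_circrnas <- function(variants, circ_features) {
  circ_features <- circ_features[circ_features$feature_type == "circRNA", ,
                                 drop = FALSE]
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hit <- circ_features$chrom == v$chrom & circ_features$start <= v$pos &
      v$pos < circ_features$end
    if (!any(hit)) return(NULL)
    data.frame(rsid = v$rsid, circ_id = circ_features$id[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(rsid = character(), circ_id = character(),
               stringsAsFactors = FALSE))))
  out <- out[order(out$rsid, out$circ_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
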