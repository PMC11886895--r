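#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the published analysis protocol: interactions are kept when
#' their confidence score strictly exceeds 0.3; a circRNA-mRNA pair is called
#' competitively regulated when it shares at least three miRNAs; GWAS variants
#' are mapped to the two closest features on either side plus everything
#' within +/- 500 kb; differential expression requires adjusted p < 0.05 and a
#' linear fold change above 1.5; enrichment and the endothelial program filter
#' use FDR < 0.05 and membership in at least six programs.
#'
#' @param min_confidence Minimum interaction confidence; kept edges satisfy
#'   `confidence > min_confidence` (strict).
#' @param min_shared_mirnas Minimum number of shared miRNAs for a
#'   competitively regulated circRNA-mRNA pair.
#' @param window_bp Half-width (bp) of the symmetric window around a variant.
#' @param n_closest_per_side Number of closest features kept on each side of a
#'   variant regardless of distance.
#' @param de_alpha Adjusted-p threshold for differential expression (strict `<`).
#' @param de_fc_threshold Linear fold-change threshold (strict `>`, applied as
#'   `|log2fc| > log2(de_fc_threshold)`); must exceed 1.
#' @param enrich_fdr FDR threshold flagging enriched gene sets.
#' @param min_program_count Minimum number of endothelial programs a gene must
#'   belong to in order to count as a common program gene.
#' @param rng_seed Integer seed used by stochastic stages.
#' @return An object of class `cerna_config` (a validated named list).
#' @examples
#' cfg <- cerna_config()
#' cfg$min_shared_mirnas
#' @export
cerna_config <- function(min_confidence = 0.3,
                         min_shared_mirnas = 3L,
                         window_bp = 500000L,
                         n_closest_per_side = 2L,
                         de_alpha = 0.05,
                         de_fc_threshold = 1.5,
                         enrich_fdr = 0.05,
                         min_program_count = 6L,
                         rng_seed = 1L) {
  cfg <- list(
    min_confidence = as.numeric(min_confidence),
    min_shared_mirnas = as.integer(min_shared_mirnas),
    window_bp = as.integer(window_bp),
    n_closest_per_side = as.integer(n_closest_per_side),
    de_alpha = as.numeric(de_alpha),
    de_fc_threshold = as.numeric(de_fc_threshold),
    enrich_fdr = as.numeric(enrich_fdr),
    min_program_count = as.integer(min_program_count),
    rng_seed = as.integer(rng_seed)
  )
  num <- c("min_confidence", "min_shared_mirnas", "window_bp",
           "n_closest_per_side", "de_alpha", "de_fc_threshold",
           "enrich_fdr", "min_program_count")
  for (k in num) {
    v <- cfg[[k]]
    if (length(v) != 1L || is.na(v) || v <= 0)
      stop("config field '", k, "' must be a single strictly positive value",
           call. = FALSE)
  }
  if (cfg$de_fc_threshold <= 1)
    stop("config field 'de_fc_threshold' must exceed 1 (linear scale)",
         call. = FALSE)
  structure(cfg, class = "cerna_config")
}

#' Read a configuration file
#'
#' Reads a flat YAML file whose keys mirror the arguments of [cerna_config()];
#' absent keys fall back to the defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A `cerna_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cerna_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(cerna_config, vals)
}

#' @export
print.cerna_config <- function(x, ...) {
  cat("ceRNA pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
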