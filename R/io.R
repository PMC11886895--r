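#' @importFrom stats pt phyper rbinom rnorm runif setNames wilcox.test p.adjust
#' @importFrom utils read.delim write.table head
NULL

# All readers reject malformed rows with an error naming the offending line;
# coordinates are 0-based half-open (BED convention) throughout.

.valid_edge_types <- function(st, tt) {
  (st == "circRNA" & tt == "miRNA") | (st == "miRNA" & tt == "mRNA")
}

#' Read a scored RNA-RNA interaction table
#'
#' Reads a tab-separated interaction table with columns `source_id`,
#' `source_type`, `target_id`, `target_type`, `confidence` holding
#' circRNA-miRNA and miRNA-mRNA binding relations, deduplicates repeated
#' (source, target) edges keeping the maximum confidence, and retains only
#' edges whose confidence strictly exceeds `min_confidence`.
#'
#' @param path Path to the TSV file (with header).
#' @param min_confidence Confidence threshold; kept rows satisfy
#'   `confidence > min_confidence`.
#' @return A data.frame with the five columns above, one row per retained
#'   deduplicated interaction, ordered by (source_id, target_id).
#' @export
read_interactions <- function(path, min_confidence = 0.3) {
  if (!file.exists(path)) stop("interaction file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = TRUE,
                          showProgress = FALSE)
  req <- c("source_id", "source_type", "target_id", "target_type", "confidence")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("interaction file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  conf <- suppressWarnings(as.numeric(dt$confidence))
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad))
    stop("confidence outside [0,1] (or non-numeric) at data row ", bad[1],
         " of ", path, call. = FALSE)
  dt$confidence <- conf
  ok <- .valid_edge_types(dt$source_type, dt$target_type)
  if (any(!ok))
    stop("malformed interaction type pair at data row ", which(!ok)[1], " of ",
         path, " (expected circRNA->miRNA or miRNA->mRNA)", call. = FALSE)
  # dedup: keep max confidence per (source, target)
  data.table::setorderv(dt, c("source_id", "target_id", "confidence"),
                        order = c(1L, 1L, -1L))
  dt <- dt[!duplicated(dt, by = c("source_id", "target_id"))]
  dt <- dt[dt$confidence > min_confidence]
  data.table::setorderv(dt, c("source_id", "target_id"))
  data.table::setDF(dt)
  dt[, req]
}

#' Write an interaction table
#' @param interactions Data.frame as returned by [read_interactions()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  .write_tsv(interactions, path)
}

.write_tsv <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read genomic features from a BED file
#'
#' Parses BED3+ (chrom, start, end, and optionally name, score, strand) with
#' 0-based half-open coordinates into a feature table. The BED format carries
#' no feature class, so the class (`"circRNA"` or `"gene"`) is supplied by the
#' caller and applied to every record in the file.
#'
#' @param path Path to a BED file (no header).
#' @param feature_type Either `"circRNA"` or `"gene"`.
#' @return A data.frame with columns `id`, `feature_type`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_bed <- function(path, feature_type = c("gene", "circRNA")) {
  feature_type <- match.arg(feature_type)
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("BED file ", path, " has fewer than 3 columns", call. = FALSE)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-numeric coordinate at line ", bad[1], " of ", path, call. = FALSE)
  inv <- which(start >= end | start < 0)
  if (length(inv))
    stop("invalid interval (need 0 <= start < end) at line ", inv[1], " of ",
         path, call. = FALSE)
  id <- if (ncol(raw) >= 4L) raw[[4]] else paste0("feat_", seq_len(nrow(raw)))
  strand <- if (ncol(raw) >= 6L) raw[[6]] else rep(".", nrow(raw))
  badstr <- which(!strand %in% c("+", "-", "."))
  if (length(badstr))
    stop("invalid strand at line ", badstr[1], " of ", path, call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate feature id '", id[duplicated(id)][1], "' in ", path,
         call. = FALSE)
  data.frame(id = id, feature_type = feature_type, chrom = raw[[1]],
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write genomic features as BED6
#' @param features Feature data.frame as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  bed <- data.frame(features$chrom, features$start, features$end,
                    features$id, 0L, features$strand)
  .write_tsv(bed, path, col.names = FALSE)
}

#' Read a gene-set collection (GMT)
#'
#' Standard GMT: one set per line as `name<TAB>description<TAB>member...`.
#' Duplicate set names and empty member lists are rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " of ", path,
         " has no members (need name, description, >=1 member)", call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name '", nm[duplicated(nm)][1], "' in ", path,
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write a gene-set collection (GMT)
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("gene-set collection must have unique names", call. = FALSE)
  if (any(vapply(collection, length, 1L) == 0L))
    stop("gene-set collection contains an empty set", call. = FALSE)
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an expression matrix with sample labels
#'
#' Reads a features-by-samples TSV (first column holds feature ids) and a
#' two-column label file (`sample_id`, `group` with values `case`/`control`).
#' Values are expected on the log2 scale; if the input is declared linear with
#' `log2_input = FALSE`, `log2(x + pseudocount)` is applied.
#'
#' @param path Expression matrix TSV.
#' @param labels_path Two-column label TSV.
#' @param log2_input Is the matrix already log2-transformed?
#' @param pseudocount Pseudocount added before log2 for linear input.
#' @return An object of class `expr_matrix`: list with `values` (numeric
#'   matrix, features x samples), `labels` (character vector, `case`/`control`,
#'   aligned to columns).
#' @export
read_expression <- function(path, labels_path, log2_input = TRUE,
                            pseudocount = 1) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("expression matrix ", path, " needs >=2 sample columns", call. = FALSE)
  feats <- raw[[1]]
  if (anyDuplicated(feats))
    stop("duplicate feature id '", feats[duplicated(feats)][1], "' in ", path,
         call. = FALSE)
  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at feature '", feats[idx[1]],
         "', sample '", colnames(vals)[idx[2]], "' in ", path, call. = FALSE)
  }
  dimnames(num) <- list(feats, colnames(raw)[-1])
  lab <- read.delim(labels_path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(lab)))
    stop("label file ", labels_path, " needs columns sample_id, group",
         call. = FALSE)
  missing_s <- setdiff(colnames(num), lab$sample_id)
  if (length(missing_s))
    stop("sample '", missing_s[1], "' in ", path, " is missing from ",
         labels_path, call. = FALSE)
  grp <- setNames(lab$group, lab$sample_id)[colnames(num)]
  badg <- which(!grp %in% c("case", "control"))
  if (length(badg))
    stop("label for sample '", colnames(num)[badg[1]],
         "' must be 'case' or 'control'", call. = FALSE)
  if (!log2_input) num <- log2(num + pseudocount)
  if (min(table(factor(grp, levels = c("case", "control")))) < 2L)
    stop("need at least 2 samples per group in ", path, call. = FALSE)
  structure(list(values = num, labels = unname(grp)), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d features x %d samples (%d case, %d control), log2 scale\n",
              nrow(x$values), ncol(x$values), sum(x$labels == "case"),
              sum(x$labels == "control")))
  invisible(x)
}

#' Read a GWAS variant table
#'
#' TSV with header columns `rsid`, `chrom`, `pos` (0-based position) and an
#' optional `pvalue` column.
#'
#' @param path Path to the variant TSV.
#' @return A data.frame with columns `rsid`, `chrom`, `pos`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  req <- c("rsid", "chrom", "pos")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("variant file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pos <- suppressWarnings(as.numeric(raw$pos))
  bad <- which(is.na(pos) | pos < 0 | pos != floor(pos))
  if (length(bad))
    stop("invalid position at data row ", bad[1], " of ", path, call. = FALSE)
  if (anyDuplicated(raw$rsid))
    stop("duplicate rsid '", raw$rsid[duplicated(raw$rsid)][1], "' in ", path,
         call. = FALSE)
  data.frame(rsid = raw$rsid, chrom = raw$chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Write a variant table
#' @param variants Data.frame with columns `rsid`, `chrom`, `pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) .write_tsv(variants, path)

#' Read a plain-text id list
#'
#' One id per line; blank lines ignored; duplicates rejected.
#'
#' @param path Path to the list file.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("id list not found: ", path, call. = FALSE)
  ids <- readLines(path, encoding = "UTF-8")
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop("duplicate id '", ids[duplicated(ids)][1], "' in ", path, call. = FALSE)
  ids
}

#' Write a plain-text id list
#' @param ids Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path, useBytes = TRUE)
  invisible(path)
}
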