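#' Construct a validated ASV count table
#'
#' Bundles an ASV-by-sample integer count matrix with per-sample metadata and
#' optional per-ASV taxonomy into the container used throughout the package.
#'
#' @param counts Non-negative integer matrix, ASVs as rows, samples as columns.
#'   Both dimensions must carry unique names.
#' @param metadata Data frame of per-sample records. Must contain a
#'   `sample_id` column (or row names) covering every column of `counts`;
#'   a `state` column (e.g. `"BT"`/`"AT"`) and a `subject` column are used by
#'   the paired-cohort stages when present.
#' @param taxonomy Optional named character vector mapping ASV ids to
#'   rank-delimited lineage strings.
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `metadata`, `taxonomy`.
#' @export
count_table <- function(counts, metadata, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite and numeric")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"

  metadata <- as.data.frame(metadata)
  if (!("sample_id" %in% names(metadata))) {
    if (is.null(rownames(metadata)))
      stop("metadata needs a sample_id column or row names")
    metadata$sample_id <- rownames(metadata)
  }
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing) > 0)
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- metadata$sample_id

  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), rownames(counts))]
    if (length(taxonomy) == 0) taxonomy <- NULL
  }

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d ASVs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if ("state" %in% names(x$metadata))
    cat("  states:", paste(names(table(x$metadata$state)),
                           table(x$metadata$state), collapse = ", "), "\n")
  if (!is.null(x$taxonomy)) cat("  taxonomy for", length(x$taxonomy), "ASVs\n")
  invisible(x)
}

#' Read a count table and metadata from TSV
#'
#' The count TSV has ASVs as rows (first column holds ASV ids), samples as
#' columns; an optional final `taxonomy` column holds rank-delimited lineage
#' strings.  The metadata TSV holds one row per sample with a `sample_id`
#' column.
#'
#' @param path Count table TSV path.
#' @param metadata_path Metadata TSV path.
#' @return A [count_table].
#' @export
read_count_table <- function(path, metadata_path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata not found: ", metadata_path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1, quote = "", comment.char = "")
  taxonomy <- NULL
  if ("taxonomy" %in% colnames(tab)) {
    taxonomy <- stats::setNames(as.character(tab[["taxonomy"]]), rownames(tab))
    tab <- tab[, setdiff(colnames(tab), "taxonomy"), drop = FALSE]
  }
  counts <- as.matrix(tab)
  if (!is.numeric(counts)) stop("non-numeric counts in ", path)
  metadata <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                                check.names = FALSE, quote = "",
                                comment.char = "", stringsAsFactors = FALSE)
  count_table(counts, metadata, taxonomy = taxonomy)
}

#' Write a count table (and its metadata) to TSV
#'
#' Column order is the table's sample order, so write/read round-trips are
#' exact.
#'
#' @param table A [count_table].
#' @param path Count TSV destination.
#' @param metadata_path Optional metadata TSV destination.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(table, path, metadata_path = NULL) {
  stopifnot(inherits(table, "count_table"))
  out <- data.frame(asv_id = rownames(table$counts), table$counts,
                    check.names = FALSE)
  if (!is.null(table$taxonomy))
    out$taxonomy <- unname(table$taxonomy[rownames(table$counts)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(table$metadata, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter low-prevalence, low-abundance ASVs
#'
#' Retains ASVs detected (count > 0) in at least `min_prevalence` of samples
#' or whose mean relative abundance across samples exceeds
#' `min_total_relabund` (`rule = "or"`, the default); `rule = "and"` requires
#' both.  Presence means count > 0: ASV tables are already denoised, so no
#' pseudo-detection threshold is applied.
#'
#' @param table A [count_table].
#' @param min_prevalence Fraction of samples an ASV must be detected in.
#' @param min_total_relabund Mean relative abundance threshold.
#' @param rule `"or"` (default) or `"and"` combination of the two criteria.
#' @return The filtered [count_table]; number of removed ASVs is reported via
#'   `message()`.
#' @export
filter_asvs <- function(table, min_prevalence = 0.20,
                        min_total_relabund = 0.025, rule = c("or", "and")) {
  stopifnot(inherits(table, "count_table"))
  rule <- match.arg(rule)
  stopifnot(min_prevalence >= 0, min_prevalence <= 1,
            min_total_relabund >= 0, min_total_relabund <= 1)
  if (min_prevalence == 0 && min_total_relabund == 0) return(table)
  x <- table$counts
  prev <- rowMeans(x > 0)
  totals <- colSums(x)
  rel <- sweep(x, 2, ifelse(totals > 0, totals, 1), "/")
  mean_rel <- rowMeans(rel)
  keep <- if (rule == "or") {
    prev >= min_prevalence | mean_rel > min_total_relabund
  } else {
    prev >= min_prevalence & mean_rel > min_total_relabund
  }
  if (!any(keep)) warning("filter removed every ASV")
  message(sprintf("filter_asvs: kept %d / %d ASVs (prevalence >= %.3g %s mean rel. abundance > %.3g)",
                  sum(keep), nrow(x), min_prevalence, rule, min_total_relabund))
  out <- table
  out$counts <- x[keep, , drop = FALSE]
  if (!is.null(out$taxonomy))
    out$taxonomy <- out$taxonomy[intersect(names(out$taxonomy), rownames(out$counts))]
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param table A [count_table] or a plain ASV-by-sample matrix.
#' @return A `rel_abundance` object: list with `proportions` (columns sum to
#'   1; all-zero samples stay all-zero and are flagged in `zero_samples`) and
#'   the originating metadata when available.
#' @export
to_relative <- function(table) {
  x <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  totals <- colSums(x)
  zero <- totals == 0
  if (any(zero))
    warning("all-zero samples left as zero: ",
            paste(colnames(x)[zero], collapse = ", "))
  props <- sweep(x, 2, ifelse(zero, 1, totals), "/")
  structure(list(proportions = props,
                 zero_samples = colnames(x)[zero],
                 metadata = if (inherits(table, "count_table")) table$metadata else NULL),
            class = "rel_abundance")
}

#' TMM normalization of a count table
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack): the
#' reference sample is the one whose upper-quartile count fraction is closest
#' to the mean, per-sample factors are precision-weighted means of log ratios
#' (M) after trimming `trim_m` of M and `trim_a` of A, and factors are
#' rescaled to geometric mean 1.  Computation is delegated to
#' `edgeR::calcNormFactors()`.
#'
#' @param table A [count_table].
#' @param trim_m Fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A values trimmed from each tail (default 0.05).
#' @return A `normalized_table`: list with `values` (counts per million of
#'   effective library size), `norm_factors`, `lib_sizes`, `metadata`.
#' @export
tmm_normalize <- function(table, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(table, "count_table"))
  x <- table$counts
  lib <- colSums(x)
  if (sum(lib > 0) < 2) stop("TMM needs at least 2 samples with nonzero totals")
  nf <- edgeR::calcNormFactors(x, lib.size = lib, method = "TMM",
                               logratioTrim = trim_m, sumTrim = trim_a)
  eff <- lib * nf
  values <- sweep(x, 2, ifelse(eff > 0, eff, 1), "/") * 1e6
  structure(list(values = values, norm_factors = nf, lib_sizes = lib,
                 metadata = table$metadata),
            class = "normalized_table")
}
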