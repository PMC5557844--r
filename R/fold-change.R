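STRESS_TYPES <- c("drought", "cold", "heat", "submergence", "none")

#' Validate a sample-metadata table
#'
#' Metadata carries one row per sample: `sample_id`, `series_id`,
#' `stress_type` (drought/cold/heat/submergence/none), `condition`
#' (stress/mock), `replicate`, and for time-course samples `stage`, `day`
#' and the even clock `hour` (0-22).
#'
#' @param metadata A data frame of sample annotations.
#' @param em Optional `expr_matrix`; if given, every matrix sample must have
#'   exactly one metadata row.
#' @return The metadata, invisibly, with columns coerced to canonical types.
#' @export
validate_metadata <- function(metadata, em = NULL) {
  need <- c("sample_id", "series_id", "stress_type", "condition", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    dc_stop("metadata lacks column(s): %s", paste(miss, collapse = ", "),
            class = "dielcross_format_error")
  if (anyDuplicated(metadata$sample_id))
    dc_stop("duplicated sample_id in metadata",
            class = "dielcross_format_error")
  bad <- setdiff(unique(metadata$stress_type), STRESS_TYPES)
  if (length(bad))
    dc_stop("unknown stress_type: %s", paste(bad, collapse = ", "),
            class = "dielcross_format_error")
  bad <- setdiff(unique(metadata$condition), c("stress", "mock"))
  if (length(bad))
    dc_stop("condition must be 'stress' or 'mock', got: %s",
            paste(bad, collapse = ", "), class = "dielcross_format_error")
  if ("hour" %in% names(metadata)) {
    h <- metadata$hour[!is.na(metadata$hour)]
    if (length(h) && any(h %% 2 != 0 | h < 0 | h > 22))
      dc_stop("metadata hours must be even and within 0-22",
              class = "dielcross_validation_error")
  }
  if (!is.null(em)) {
    missing_meta <- setdiff(sample_ids(em), metadata$sample_id)
    if (length(missing_meta))
      dc_stop("samples without metadata: %s",
              paste(utils::head(missing_meta, 5L), collapse = ", "),
              class = "dielcross_validation_error")
  }
  invisible(metadata)
}

#' Stress-versus-MOCK log2 fold-change profiles
#'
#' For every stressed sample, finds its matched MOCK control (same series,
#' same replicate index) and records the per-replicate log2 fold change
#' `log2(stress) - log2(mock)`. Condition means average the pairs of each
#' stress type.
#'
#' @param em An `expr_matrix` on the log2 scale.
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param stress_types Stress types to include; defaults to every stressed
#'   type present.
#' @return A `fold_change_profile`: list with `log2fc` (genes x pairs
#'   matrix), `pairs` (pairing table), and `condition_means` (genes x
#'   stress-type matrix).
#' @export
fold_change <- function(em, metadata, stress_types = NULL) {
  dc_assert(inherits(em, "expr_matrix"), "`em` must be an expr_matrix",
            class = "dielcross_format_error")
  if (em$scale != "log2")
    dc_stop("fold_change requires a log2-scale matrix; run log2_normalize()",
            class = "dielcross_validation_error")
  validate_metadata(metadata, em)
  md <- metadata[match(sample_ids(em), metadata$sample_id), , drop = FALSE]
  stressed <- md[md$condition == "stress", , drop = FALSE]
  if (!is.null(stress_types))
    stressed <- stressed[stressed$stress_type %in% stress_types, , drop = FALSE]
  if (nrow(stressed) == 0L)
    dc_stop("no stressed samples found", class = "dielcross_validation_error")
  # deterministic pair order: series, then replicate
  stressed <- stressed[order(stressed$series_id, stressed$replicate), ,
                       drop = FALSE]
  mock <- md[md$condition == "mock", , drop = FALSE]
  key <- function(d) paste(d$series_id, d$replicate, sep = "\r")
  mock_idx <- match(key(stressed), key(mock))
  if (anyNA(mock_idx)) {
    orphan <- stressed$sample_id[is.na(mock_idx)]
    dc_stop("stress sample(s) without a matched MOCK in the same series/replicate: %s",
            paste(utils::head(orphan, 5L), collapse = ", "),
            class = "dielcross_pairing_error")
  }
  pairs <- data.frame(
    pair_id = paste0(stressed$series_id, ".r", stressed$replicate),
    series_id = stressed$series_id,
    stress_type = stressed$stress_type,
    replicate = stressed$replicate,
    stress_sample = stressed$sample_id,
    mock_sample = mock$sample_id[mock_idx],
    stringsAsFactors = FALSE)
  lfc <- em$values[, pairs$stress_sample, drop = FALSE] -
    em$values[, pairs$mock_sample, drop = FALSE]
  colnames(lfc) <- pairs$pair_id
  types <- sort(unique(pairs$stress_type))
  cm <- vapply(types, function(st) {
    rowMeans(lfc[, pairs$stress_type == st, drop = FALSE])
  }, numeric(nrow(lfc)))
  cm <- matrix(cm, nrow = nrow(lfc),
               dimnames = list(rownames(lfc), types))
  structure(list(log2fc = lfc, pairs = pairs, condition_means = cm),
            class = "fold_change_profile")
}

#' @export
print.fold_change_profile <- function(x, ...) {
  cat(sprintf("<fold_change_profile> %d genes x %d replicate pairs (%s)\n",
              nrow(x$log2fc), ncol(x$log2fc),
              paste(colnames(x$condition_means), collapse = ", ")))
  invisible(x)
}

#' Filter fold-change profiles for clustering
#'
#' Drops genes whose fold-change row exceeds the missingness budget and
#' mean-imputes any remaining absent entries so the K-means engine sees a
#' complete matrix.
#'
#' @param fcp A `fold_change_profile`.
#' @param max_missing Maximum tolerated fraction of absent entries per gene.
#' @return A complete numeric genes-x-pairs matrix.
#' @export
complete_profiles <- function(fcp, max_missing = 0.2) {
  x <- fcp$log2fc
  frac_na <- rowMeans(is.na(x))
  x <- x[frac_na <= max_missing, , drop = FALSE]
  if (anyNA(x)) {
    rm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm[idx[, 1L]]
  }
  x
}

#' Write a fold-change profile to TSV
#' @param fcp A `fold_change_profile`.
#' @param path Output path for the genes x pairs log2 fold-change table.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fcp, path) {
  df <- data.frame(gene_id = rownames(fcp$log2fc), fcp$log2fc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
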