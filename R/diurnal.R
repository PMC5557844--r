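PHASE_ORDER <- c("predawn", "midday", "lateday", "midnight")

#' Diurnal phase windows
#'
#' The four clock windows a gene's expression peak is assigned to:
#' midday 08:00-16:00, lateday 18:00-20:00, midnight 22:00-02:00 (wrapping
#' across 0), predawn 04:00-06:00, with inclusive even-hour membership.
#' Together they partition the twelve even sampling hours.
#'
#' @return Named list of even-hour vectors, in the fixed tie-break order
#'   predawn, midday, lateday, midnight.
#' @export
phase_windows <- function() {
  list(predawn = c(4, 6),
       midday = c(8, 10, 12, 14, 16),
       lateday = c(18, 20),
       midnight = c(22, 0, 2))
}

# Windows must partition the observed even hours; asserted wherever
# windows meet data.
validate_windows <- function(windows, hours = seq(0, 22, by = 2)) {
  all_h <- unlist(windows, use.names = FALSE)
  if (anyDuplicated(all_h))
    dc_stop("phase windows overlap at hour(s) %s",
            paste(unique(all_h[duplicated(all_h)]), collapse = ", "),
            class = "dielcross_argument_error")
  uncovered <- setdiff(unique(hours %% 24), all_h)
  if (length(uncovered))
    dc_stop("sampled hour(s) not covered by any phase window: %s",
            paste(uncovered, collapse = ", "),
            class = "dielcross_argument_error")
  invisible(TRUE)
}

hour_to_window <- function(hours, windows = phase_windows()) {
  validate_windows(windows, hours)
  out <- rep(NA_character_, length(hours))
  for (w in names(windows)) out[(hours %% 24) %in% windows[[w]]] <- w
  out
}

#' Cosinor rhythmicity score
#'
#' Least-squares fit of a fixed-period 24-h cosinor,
#' `y = m + a cos(2 pi t / 24) + b sin(2 pi t / 24)`, returning the
#' fraction of variance it explains. A constant series scores 0 by
#' convention. Requires at least 6 timepoints spanning at least 24 h.
#'
#' @param y Numeric series of (log2) expression values.
#' @param times Sampling times in hours (may exceed 24 across days).
#' @return R-squared in `[0, 1]`.
#' @export
rhythmicity_score <- function(y, times) {
  dc_assert(length(y) == length(times), "`y` and `times` differ in length",
            class = "dielcross_argument_error")
  dc_assert(length(y) >= 6L, "need at least 6 timepoints",
            class = "dielcross_argument_error")
  dc_assert(diff(range(times)) >= 24, "timepoints must span at least 24 h",
            class = "dielcross_argument_error")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  w <- 2 * pi * times / 24
  fit <- stats::lm.fit(cbind(1, cos(w), sin(w)), y)
  r2 <- 1 - sum(fit$residuals^2) / tss
  min(max(r2, 0), 1)
}

#' Assign the peak phase window
#'
#' Averages the series within each phase window (pooling days and stages)
#' and returns the window with the highest mean. Exact ties are broken by
#' the fixed order predawn, midday, lateday, midnight.
#'
#' @param y Numeric series of expression values.
#' @param hours Clock hour of each sample (even, 0-22).
#' @param windows Phase windows; see [phase_windows()].
#' @return List with `phase` (window name) and `window_means` (named
#'   numeric of the four window averages).
#' @export
assign_phase <- function(y, hours, windows = phase_windows()) {
  dc_assert(length(y) == length(hours), "`y` and `hours` differ in length",
            class = "dielcross_argument_error")
  wmap <- hour_to_window(hours, windows)
  wm <- vapply(names(windows), function(w) {
    sel <- wmap == w
    if (!any(sel))
      dc_stop("phase window '%s' has no samples", w,
              class = "dielcross_argument_error")
    mean(y[sel])
  }, numeric(1))
  wm <- wm[PHASE_ORDER[PHASE_ORDER %in% names(wm)]]
  list(phase = names(wm)[which.max(wm)], window_means = wm)
}

#' Cluster diurnal time-courses
#'
#' Median-centers each gene's log2 profile (so clusters group by shape,
#' not expression level) and runs the package's K-means engine with the
#' default of seven groups.
#'
#' @param em A log2-scale `expr_matrix` of the diurnal course.
#' @param k Number of clusters (default 7).
#' @param seed Integer seed.
#' @param ... Passed to [kmeans_profiles()].
#' @return A `kmeans_result`.
#' @export
cluster_diurnal <- function(em, k = 7, seed = 1, ...) {
  dc_assert(inherits(em, "expr_matrix"), "`em` must be an expr_matrix",
            class = "dielcross_argument_error")
  if (em$scale != "log2")
    dc_stop("diurnal clustering expects a log2 matrix",
            class = "dielcross_validation_error")
  x <- median_center(em$values)
  kmeans_profiles(x, k = k, seed = seed, ...)
}

median_center <- function(x) x - apply(x, 1L, stats::median)

#' Call diurnally rhythmic genes and their peak phase
#'
#' Clusters median-centered diurnal profiles, scores each cluster centroid
#' with the 24-h cosinor, and marks every member of a cluster rhythmic when
#' the centroid's R-squared reaches `r2_threshold` (set
#' `mode = "gene"` to score genes individually instead). Rhythmic genes
#' are assigned the phase window in which their own pooled window mean
#' peaks.
#'
#' @param em A log2-scale `expr_matrix` of the diurnal course.
#' @param metadata Sample metadata with `day` and `hour` columns.
#' @param k Number of clusters (default 7).
#' @param seed Integer seed.
#' @param r2_threshold Cosinor R-squared at or above which a cluster (or
#'   gene) is called rhythmic; default 0.3.
#' @param mode `"cluster"` (default) scores cluster centroids; `"gene"`
#'   scores individual genes.
#' @param windows Phase windows; see [phase_windows()].
#' @param stages Optional stage subset; default uses all stages.
#' @param ... Passed to [kmeans_profiles()].
#' @return A data frame (`diurnal_calls`) with `gene_id`, `cluster`,
#'   `rhythmic`, `rhythmicity_r2`, `phase` (NA for arrhythmic genes) and
#'   the four window means.
#' @export
call_diurnal <- function(em, metadata, k = 7, seed = 1, r2_threshold = 0.3,
                         mode = c("cluster", "gene"),
                         windows = phase_windows(), stages = NULL, ...) {
  mode <- match.arg(mode)
  dc_assert(inherits(em, "expr_matrix"), "`em` must be an expr_matrix",
            class = "dielcross_argument_error")
  if (em$scale != "log2")
    dc_stop("call_diurnal expects a log2 matrix",
            class = "dielcross_validation_error")
  validate_metadata(metadata, em)
  md <- metadata[match(sample_ids(em), metadata$sample_id), , drop = FALSE]
  dc_assert(!anyNA(md$hour), "every sample needs a clock hour",
            class = "dielcross_argument_error")
  if (!is.null(stages)) {
    keep <- md$stage %in% stages
    dc_assert(any(keep), "no samples in the requested stages",
              class = "dielcross_argument_error")
    em <- expression_matrix(em$values[, keep, drop = FALSE], "log2")
    md <- md[keep, , drop = FALSE]
  }
  day <- if ("day" %in% names(md) && !anyNA(md$day)) md$day else 1L
  times <- (day - 1L) * 24 + md$hour

  x <- median_center(em$values)
  km <- kmeans_profiles(x, k = k, seed = seed, ...)

  if (mode == "cluster") {
    cent_r2 <- vapply(seq_len(km$k), function(j)
      rhythmicity_score(km$centroids[j, ], times), numeric(1))
    r2 <- cent_r2[km$assignments]
  } else {
    r2 <- vapply(seq_len(nrow(x)), function(i)
      rhythmicity_score(x[i, ], times), numeric(1))
  }
  rhythmic <- r2 >= r2_threshold

  # pooled window means for every gene, vectorized as x %*% weights
  wmap <- hour_to_window(md$hour, windows)
  wnames <- PHASE_ORDER[PHASE_ORDER %in% names(windows)]
  wt <- vapply(wnames, function(w) {
    sel <- wmap == w
    if (!any(sel))
      dc_stop("phase window '%s' has no samples", w,
              class = "dielcross_argument_error")
    sel / sum(sel)
  }, numeric(ncol(x)))
  wm <- x %*% wt
  phase <- wnames[max.col(wm, ties.method = "first")]
  phase[!rhythmic] <- NA_character_

  out <- data.frame(gene_id = rownames(x),
                    cluster = unname(km$assignments),
                    rhythmic = rhythmic,
                    rhythmicity_r2 = r2,
                    phase = phase,
                    stringsAsFactors = FALSE)
  wm_df <- as.data.frame(wm)
  names(wm_df) <- paste0("mean_", wnames)
  out <- cbind(out, wm_df)
  rownames(out) <- NULL
  attr(out, "kmeans") <- km
  class(out) <- c("diurnal_calls", "data.frame")
  out
}

#' Summarize drought / diurnal crosstalk
#'
#' Joins drought-response labels with diurnal calls and reports, per
#' direction, how many genes are also diurnally rhythmic (percentage to
#' one decimal) and how the rhythmic ones distribute over the four phase
#' windows (percentages to two decimals).
#'
#' @param labels Response-label table ([label_clusters()]).
#' @param calls Diurnal-call table ([call_diurnal()]).
#' @return A `crosstalk_summary`: list with one element per direction
#'   (`up`, `down`) carrying `n`, `n_diurnal`, `pct_diurnal`,
#'   `phase_pct`, plus `n_diurnal_total`.
#' @export
crosstalk_summary <- function(labels, calls) {
  miss <- setdiff(labels$gene_id, calls$gene_id)
  if (length(miss))
    dc_stop("gene(s) in labels missing from diurnal calls: %s",
            paste(utils::head(miss, 5L), collapse = ", "),
            class = "dielcross_argument_error")
  calls_idx <- match(labels$gene_id, calls$gene_id)
  rhythmic <- calls$rhythmic[calls_idx]
  phase <- calls$phase[calls_idx]
  per_direction <- function(direction) {
    in_dir <- labels$drought_class == direction
    n <- sum(in_dir)
    n_di <- sum(in_dir & rhythmic)
    pct <- if (n == 0L) NA_real_ else round(100 * n_di / n, 1)
    ph <- factor(phase[in_dir & rhythmic], levels = PHASE_ORDER)
    phase_pct <- if (n_di == 0L) {
      stats::setNames(rep(NA_real_, length(PHASE_ORDER)), PHASE_ORDER)
    } else {
      round(100 * table(ph) / n_di, 2)
    }
    list(n = n, n_diurnal = n_di, pct_diurnal = pct,
         phase_pct = c(phase_pct))
  }
  out <- list(up = per_direction("up"), down = per_direction("down"))
  out$n_diurnal_total <- out$up$n_diurnal + out$down$n_diurnal
  class(out) <- "crosstalk_summary"
  out
}

#' @export
print.crosstalk_summary <- function(x, ...) {
  for (d in c("up", "down")) {
    s <- x[[d]]
    cat(sprintf("%-5s: %d/%d diurnal (%s%%)\n", d, s$n_diurnal, s$n,
                format(s$pct_diurnal)))
    pp <- s$phase_pct
    cat("       phase %:", paste(sprintf("%s %.2f", names(pp), pp),
                                 collapse = ", "), "\n")
  }
  cat(sprintf("total diurnal crosstalk genes: %d\n", x$n_diurnal_total))
  invisible(x)
}

#' Write a crosstalk summary to TSV
#' @param x A `crosstalk_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosstalk_summary <- function(x, path) {
  rows <- do.call(rbind, lapply(c("up", "down"), function(d) {
    s <- x[[d]]
    data.frame(direction = d, n = s$n, n_diurnal = s$n_diurnal,
               pct_diurnal = s$pct_diurnal,
               t(s$phase_pct), stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
}
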