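#' Relative quantification by the comparative Ct method
#'
#' Implements 2^-ddCt: per replicate, dCt = Ct(target) - Ct(reference);
#' ddCt = mean dCt(treatment) - mean dCt(control); fold = 2^-ddCt.
#' Per-replicate folds (2^-(dCt - mean control dCt)) are retained for
#' error bars, with the standard error computed on the linear scale by
#' default or on the log2 scale (`se_scale = "log"`). When both groups
#' have at least two replicates a Welch test on the dCt values supplies
#' the two-tailed P value and its significance stars.
#'
#' @param ct_table Data frame with columns `sample_group` (`treatment` /
#'   `control`), `replicate`, `gene` (`target` / `reference`), `ct`
#'   (cycles, positive). Every (group, replicate) needs both the target
#'   and the reference Ct.
#' @param se_scale Scale on which the replicate standard error of the
#'   treatment folds is computed.
#' @return A `relquant` list: `delta_ct` (per-replicate table), `ddct`,
#'   `fold`, `rep_folds`, `se`, `welch` (`t`, `df`, `p`), `stars`.
#' @export
ddct_fold <- function(ct_table, se_scale = c("linear", "log")) {
  se_scale <- match.arg(se_scale)
  need <- c("sample_group", "replicate", "gene", "ct")
  dc_assert(all(need %in% names(ct_table)),
            "Ct table needs columns sample_group, replicate, gene, ct",
            class = "dielcross_format_error")
  bad <- setdiff(unique(ct_table$sample_group), c("treatment", "control"))
  if (length(bad))
    dc_stop("sample_group must be 'treatment' or 'control', got: %s",
            paste(bad, collapse = ", "), class = "dielcross_format_error")
  bad <- setdiff(unique(ct_table$gene), c("target", "reference"))
  if (length(bad))
    dc_stop("gene must be 'target' or 'reference', got: %s",
            paste(bad, collapse = ", "), class = "dielcross_format_error")
  dc_assert(all(is.finite(ct_table$ct)) && all(ct_table$ct > 0),
            "Ct values must be positive cycles",
            class = "dielcross_validation_error")

  wide <- merge(
    ct_table[ct_table$gene == "target",
             c("sample_group", "replicate", "ct")],
    ct_table[ct_table$gene == "reference",
             c("sample_group", "replicate", "ct")],
    by = c("sample_group", "replicate"), suffixes = c("_target", "_ref"),
    all = TRUE)
  orphan <- is.na(wide$ct_target) | is.na(wide$ct_ref)
  if (any(orphan))
    dc_stop("replicate(s) missing a target or reference Ct: %s",
            paste(paste0(wide$sample_group[orphan], "/r",
                         wide$replicate[orphan]), collapse = ", "),
            class = "dielcross_pairing_error")
  wide$delta_ct <- wide$ct_target - wide$ct_ref
  wide <- wide[order(wide$sample_group, wide$replicate), , drop = FALSE]
  rownames(wide) <- NULL

  dct_tr <- wide$delta_ct[wide$sample_group == "treatment"]
  dct_ct <- wide$delta_ct[wide$sample_group == "control"]
  dc_assert(length(dct_tr) >= 1L && length(dct_ct) >= 1L,
            "need at least one replicate per group",
            class = "dielcross_argument_error")
  ddct <- mean(dct_tr) - mean(dct_ct)
  fold <- 2^(-ddct)
  wide$rep_fold <- 2^(-(wide$delta_ct - mean(dct_ct)))

  tr_folds <- wide$rep_fold[wide$sample_group == "treatment"]
  se <- if (length(tr_folds) >= 2L) {
    if (se_scale == "linear")
      stats::sd(tr_folds) / sqrt(length(tr_folds))
    else
      stats::sd(log2(tr_folds)) / sqrt(length(tr_folds))
  } else NA_real_

  welch <- if (length(dct_tr) >= 2L && length(dct_ct) >= 2L &&
               (stats::var(dct_tr) + stats::var(dct_ct)) > 0) {
    welch_test(dct_tr, dct_ct)
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  structure(list(delta_ct = wide, ddct = ddct, fold = fold,
                 rep_folds = tr_folds, se = se, welch = welch,
                 stars = if (is.na(welch$p)) NA_character_
                         else stars(welch$p)),
            class = "relquant")
}

#' @export
print.relquant <- function(x, ...) {
  cat(sprintf("<relquant> ddCt = %.4g, fold = 2^-ddCt = %.4g", x$ddct, x$fold))
  if (!is.na(x$welch$p))
    cat(sprintf(", Welch p = %.3g %s", x$welch$p, x$stars))
  cat("\n")
  invisible(x)
}

#' Welch's unequal-variance t test
#'
#' Two-sample t test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), two-tailed.
#'
#' @param values_a,values_b Numeric vectors, each with at least two
#'   values; at least one group must have nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(values_a, values_b) {
  dc_assert(length(values_a) >= 2L && length(values_b) >= 2L,
            "each group needs at least 2 values",
            class = "dielcross_argument_error")
  dc_assert(all(is.finite(values_a)) && all(is.finite(values_b)),
            "non-finite values in input", class = "dielcross_argument_error")
  if (stats::var(values_a) + stats::var(values_b) == 0)
    dc_stop("both groups are constant; Welch statistic undefined",
            class = "dielcross_argument_error")
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Significance stars for P values
#'
#' Inclusive thresholds: `****` at P <= 1e-4, `***` at P <= 1e-3, `**` at
#' P <= 1e-2, `*` at P <= 0.05, otherwise the empty string.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
stars <- function(p) {
  dc_assert(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
            "P values must lie in [0, 1]", class = "dielcross_argument_error")
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 0.05, "*", ""))))
}
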