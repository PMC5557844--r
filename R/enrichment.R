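#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes in a query of size `n` sampled without
#' replacement from a background of `N` genes of which `K` carry the term.
#' Evaluated in log space for numerical stability.
#'
#' @param k Observed annotated genes in the query.
#' @param K Term size in the background.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail probability, in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N))
    dc_assert(is.numeric(v) && length(v) == 1L && is.finite(v) &&
                abs(v - round(v)) < 1e-8 && v >= 0,
              "counts must be single non-negative integers",
              class = "dielcross_argument_error")
  if (K > N || n > N || k > min(n, K))
    dc_stop("inconsistent counts: need 0 <= k <= min(n, K) <= N",
            class = "dielcross_argument_error")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Fold enrichment of a term in a query
#'
#' Observed over expected: `k / (n * K / N)`, the ratio of the query count
#' to the count expected under the background proportion of the term.
#'
#' @inheritParams hypergeom_upper_tail
#' @return The fold-enrichment ratio (0 when `k = 0`).
#' @export
fold_enrichment <- function(k, K, n, N) {
  dc_assert(K > 0 && n > 0, "fold enrichment needs K > 0 and n > 0",
            class = "dielcross_argument_error")
  if (K > N || n > N || k > min(n, K) || k < 0)
    dc_stop("inconsistent counts: need 0 <= k <= min(n, K) <= N",
            class = "dielcross_argument_error")
  k / (n * K / N)
}

#' Term enrichment of a query gene set
#'
#' Tests every annotation term carried by at least one query gene:
#' fold enrichment (observed/expected) plus the upper-tail hypergeometric
#' P value, with the pass flag applying the two-threshold filter
#' (fold at or above `min_fold` and P at or below `alpha`). P values are
#' reported raw by default; set `adjust = TRUE` for an additional
#' Benjamini-Hochberg column.
#'
#' @param query Character vector of query gene ids (non-empty, all in the
#'   background).
#' @param annotations Data frame with columns `gene_id`, `term_id`;
#'   duplicated pairs are collapsed.
#' @param background Background gene universe; defaults to all annotated
#'   genes (the array background).
#' @param min_fold Minimum fold enrichment to pass (default 2).
#' @param alpha Maximum P value to pass (default 0.05).
#' @param min_term_size,max_term_size Term-size bounds applied before
#'   testing; defaults 2 and `N/2`.
#' @param adjust Add a Benjamini-Hochberg adjusted P column.
#' @return A data frame sorted by fold enrichment (descending) with
#'   columns `term_id`, `k`, `K`, `n`, `N`, `expected`, `fold`, `p_hyper`,
#'   `passes` (and `p_bh` when `adjust`).
#' @export
enrich <- function(query, annotations, background = NULL, min_fold = 2,
                   alpha = 0.05, min_term_size = 2, max_term_size = NULL,
                   adjust = FALSE) {
  dc_assert(length(query) > 0, "empty query",
            class = "dielcross_argument_error")
  need <- c("gene_id", "term_id")
  dc_assert(all(need %in% names(annotations)),
            "annotations need columns gene_id, term_id",
            class = "dielcross_format_error")
  ann <- unique(annotations[, need])
  background <- unique(background %||% ann$gene_id)
  query <- unique(query)
  out_of_bg <- setdiff(query, background)
  if (length(out_of_bg))
    dc_stop("query gene(s) absent from background: %s",
            paste(utils::head(out_of_bg, 5L), collapse = ", "),
            class = "dielcross_argument_error")
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(query)
  max_term_size <- max_term_size %||% floor(N / 2)

  term_genes <- split(ann$gene_id, ann$term_id)
  sizes <- lengths(term_genes)
  term_genes <- term_genes[sizes >= min_term_size & sizes <= max_term_size]
  if (length(term_genes) == 0L)
    return(empty_enrichment(adjust))
  K <- lengths(term_genes)
  k <- vapply(term_genes, function(g) sum(g %in% query), integer(1))
  keep <- k >= 1L
  if (!any(keep)) return(empty_enrichment(adjust))
  K <- K[keep]; k <- k[keep]
  expected <- n * K / N
  fold <- k / expected
  p <- vapply(seq_along(k), function(i)
    hypergeom_upper_tail(k[i], K[i], n, N), numeric(1))
  res <- data.frame(term_id = names(K), k = unname(k), K = unname(K),
                    n = n, N = N, expected = unname(expected),
                    fold = unname(fold), p_hyper = unname(p),
                    stringsAsFactors = FALSE)
  if (adjust) res$p_bh <- stats::p.adjust(res$p_hyper, method = "BH")
  res$passes <- res$fold >= min_fold & res$p_hyper <= alpha
  res <- res[order(-res$fold, res$p_hyper, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_enrichment <- function(adjust) {
  res <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                    n = integer(0), N = integer(0), expected = numeric(0),
                    fold = numeric(0), p_hyper = numeric(0),
                    stringsAsFactors = FALSE)
  if (adjust) res$p_bh <- numeric(0)
  res$passes <- logical(0)
  res
}
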