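#' Expression matrix container
#'
#' A genes-by-samples matrix of expression values together with the scale
#' the values live on. Linear-scale values are raw (positive) intensities;
#' `log2` marks values already log2-transformed. Missing measurements are
#' `NA`, never zero.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `scale`.
#' @examples
#' m <- matrix(2^rnorm(6, 8), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- expression_matrix(m, "linear")
#' log2_normalize(em)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  dc_assert(is.matrix(values) && is.numeric(values),
            "`values` must be a numeric matrix",
            class = "dielcross_format_error")
  gid <- rownames(values)
  sid <- colnames(values)
  dc_assert(!is.null(gid) && !is.null(sid),
            "`values` must have gene row names and sample column names",
            class = "dielcross_format_error")
  if (anyDuplicated(gid))
    dc_stop("duplicated gene ids: %s",
            paste(unique(gid[duplicated(gid)]), collapse = ", "),
            class = "dielcross_format_error")
  if (anyDuplicated(sid))
    dc_stop("duplicated sample ids: %s",
            paste(unique(sid[duplicated(sid)]), collapse = ", "),
            class = "dielcross_format_error")
  if (scale == "linear") {
    bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      cells <- paste0(gid[bad[, 1]], "/", sid[bad[, 2]])
      dc_stop("nonpositive linear intensities at %d cell(s): %s%s",
              nrow(bad), paste(utils::head(cells, 5L), collapse = ", "),
              if (nrow(bad) > 5L) ", ..." else "",
              class = "dielcross_validation_error")
    }
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param em An `expr_matrix`.
#' @return Character vector of identifiers, in matrix order.
#' @export
gene_ids <- function(em) rownames(em$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(em) colnames(em$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Empty cells and `NA` are recorded as missing. With
#' `scale_hint = "linear"` any nonpositive value is a validation error
#' (imputing or flooring would silently corrupt downstream fold changes).
#'
#' @param path Path to a tab-delimited file.
#' @param scale_hint Scale the values are on, `"linear"` or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale_hint = c("linear", "log2")) {
  scale_hint <- match.arg(scale_hint)
  dc_assert(file.exists(path), "file not found: %s", path,
            class = "dielcross_format_error")
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    dc_stop("ragged TSV: rows have %s fields", paste(unique(nf), collapse = "/"),
            class = "dielcross_format_error")
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  dc_assert(ncol(df) >= 2L, "expected a gene-id column plus sample columns",
            class = "dielcross_format_error")
  gid <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gid
  expression_matrix(vals, scale_hint)
}

#' Write an expression matrix to TSV
#'
#' First column `gene_id`, one column per sample. The inverse of
#' [read_expression_matrix()] up to numeric formatting precision.
#'
#' @param em An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene_id = gene_ids(em), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Log2-normalize linear intensities
#'
#' Replaces every linear intensity with its log2. Already-log2 matrices are
#' rejected rather than double-transformed; nonpositive values are an error
#' rather than being floored.
#'
#' @param em An `expr_matrix` on the linear scale.
#' @return An `expr_matrix` on the log2 scale.
#' @export
log2_normalize <- function(em) {
  dc_assert(inherits(em, "expr_matrix"), "`em` must be an expr_matrix",
            class = "dielcross_format_error")
  if (em$scale != "linear")
    dc_stop("matrix is already on the %s scale", em$scale,
            class = "dielcross_validation_error")
  if (any(!is.na(em$values) & em$values <= 0))
    dc_stop("nonpositive intensities cannot be log2-transformed",
            class = "dielcross_validation_error")
  expression_matrix(log2(em$values), "log2")
}
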