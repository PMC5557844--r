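REGULATOR_RELATIONS <- c("bound", "direct_target", "regulated_up",
                         "regulated_down")

#' Pearson correlation with defined-variance checks
#'
#' Sample Pearson correlation of two equal-length vectors. At least three
#' observations and nonzero variance in both vectors are required;
#' correlation with a constant profile is undefined and raises an error
#' rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  dc_assert(length(x) == length(y), "`x` and `y` differ in length",
            class = "dielcross_argument_error")
  dc_assert(length(x) >= 3L, "need at least 3 observations",
            class = "dielcross_argument_error")
  dc_assert(!anyNA(x) && !anyNA(y), "missing values in input",
            class = "dielcross_argument_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    dc_stop("correlation with a constant vector is undefined",
            class = "dielcross_undefined_cor_error")
  stats::cor(x, y)
}

# Clean an interaction table: drop self loops, collapse duplicate
# unordered pairs (keeping the first record), validate confidences.
clean_interactions <- function(interactions) {
  need <- c("gene_a", "gene_b", "confidence")
  dc_assert(all(need %in% names(interactions)),
            "interactions need columns gene_a, gene_b, confidence",
            class = "dielcross_format_error")
  conf <- interactions$confidence
  if (any(is.na(conf) | conf <= 0 | conf > 1))
    dc_stop("interaction confidence values must lie in (0, 1]",
            class = "dielcross_validation_error")
  n_in <- nrow(interactions)
  self <- interactions$gene_a == interactions$gene_b
  interactions <- interactions[!self, , drop = FALSE]
  key <- ifelse(interactions$gene_a < interactions$gene_b,
                paste(interactions$gene_a, interactions$gene_b, sep = "\r"),
                paste(interactions$gene_b, interactions$gene_a, sep = "\r"))
  dup <- duplicated(key)
  interactions <- interactions[!dup, , drop = FALSE]
  attr(interactions, "n_self_loops") <- sum(self)
  attr(interactions, "n_duplicates") <- sum(dup)
  attr(interactions, "n_input") <- n_in
  interactions
}

#' Build a pathway-centered interaction network
#'
#' Nodes are the pathway genes plus every interaction partner; pathway
#' genes with no interactions are retained as isolated nodes. Each edge
#' carries its interolog confidence and, where the expression matrix
#' covers both endpoints, the Pearson correlation of their log2 profiles;
#' edges with `pcc > pcc_threshold` are flagged `high_pcc`. Node flags
#' (drought class, diurnal rhythmicity, functional bin, prior
#' characterization) are joined from the supplied tables.
#'
#' @param pathway_genes Character vector of pathway member gene ids
#'   (non-empty).
#' @param interactions Data frame `gene_a`, `gene_b`, `confidence` in
#'   `(0, 1]`; self loops and duplicate unordered pairs are removed (and
#'   counted in the network log), as are edges touching no pathway gene.
#' @param expression Optional `expr_matrix` used for edge correlations;
#'   linear matrices are log2-normalized first. Edges with an endpoint
#'   missing from the matrix, or with a constant profile, carry `NA`
#'   correlation and are never `high_pcc`.
#' @param labels Optional response-label table; fills node `drought_class`.
#' @param calls Optional diurnal-call table; fills node `diurnal`.
#' @param pcc_threshold Correlation above which an edge is flagged
#'   (default 0.5).
#' @param bins Optional named character vector gene -> functional bin.
#' @param characterized Optional character vector of previously
#'   characterized genes.
#' @return An `interaction_network`: list with `nodes`, `edges`,
#'   `regulators` (empty until [overlay_regulator()]), `pcc_threshold`,
#'   and a `log` of filtering counts.
#' @export
build_network <- function(pathway_genes, interactions, expression = NULL,
                          labels = NULL, calls = NULL, pcc_threshold = 0.5,
                          bins = NULL, characterized = NULL) {
  pathway_genes <- unique(as.character(pathway_genes))
  dc_assert(length(pathway_genes) > 0, "empty pathway gene list",
            class = "dielcross_argument_error")
  edges <- clean_interactions(interactions)
  log <- list(n_input = attr(edges, "n_input"),
              n_self_loops = attr(edges, "n_self_loops"),
              n_duplicates = attr(edges, "n_duplicates"))
  touches <- edges$gene_a %in% pathway_genes |
    edges$gene_b %in% pathway_genes
  log$n_outside_pathway <- sum(!touches)
  edges <- edges[touches, , drop = FALSE]
  log$n_edges <- nrow(edges)

  node_ids <- unique(c(pathway_genes, edges$gene_a, edges$gene_b))
  nodes <- data.frame(gene_id = node_ids,
                      in_pathway = node_ids %in% pathway_genes,
                      functional_bin = NA_character_,
                      drought_class = NA_character_,
                      diurnal = NA,
                      characterized = FALSE,
                      stringsAsFactors = FALSE)
  if (!is.null(bins)) {
    hit <- match(nodes$gene_id, names(bins))
    nodes$functional_bin <- unname(bins[hit])
  }
  if (!is.null(labels)) {
    hit <- match(nodes$gene_id, labels$gene_id)
    nodes$drought_class <- labels$drought_class[hit]
  }
  if (!is.null(calls)) {
    hit <- match(nodes$gene_id, calls$gene_id)
    nodes$diurnal <- calls$rhythmic[hit]
  }
  if (!is.null(characterized))
    nodes$characterized <- nodes$gene_id %in% characterized

  pcc <- rep(NA_real_, nrow(edges))
  if (!is.null(expression) && nrow(edges) > 0) {
    dc_assert(inherits(expression, "expr_matrix"),
              "`expression` must be an expr_matrix",
              class = "dielcross_argument_error")
    if (expression$scale == "linear")
      expression <- log2_normalize(expression)
    vals <- expression$values
    covered <- edges$gene_a %in% rownames(vals) &
      edges$gene_b %in% rownames(vals)
    for (i in which(covered)) {
      a <- vals[edges$gene_a[i], ]
      b <- vals[edges$gene_b[i], ]
      if (anyNA(a) || anyNA(b) || stats::sd(a) == 0 || stats::sd(b) == 0)
        next  # undefined correlation stays NA, never high_pcc
      pcc[i] <- stats::cor(a, b)
    }
  }
  edges$pcc <- pcc
  edges$high_pcc <- !is.na(pcc) & pcc > pcc_threshold
  attr(edges, "n_self_loops") <- NULL
  attr(edges, "n_duplicates") <- NULL
  attr(edges, "n_input") <- NULL
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges,
                 regulators = empty_regulators(),
                 pcc_threshold = pcc_threshold, log = log),
            class = "interaction_network")
}

empty_regulators <- function() {
  data.frame(regulator = character(0), target = character(0),
             relation = character(0), stringsAsFactors = FALSE)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d nodes (%d in pathway), %d edges (%d high-PCC), %d regulator edges\n",
    nrow(x$nodes), sum(x$nodes$in_pathway), nrow(x$edges),
    sum(x$edges$high_pcc), nrow(x$regulators)))
  invisible(x)
}

#' Overlay transcription-factor regulator relations
#'
#' Appends directed regulator edges (relations `bound`, `direct_target`,
#' `regulated_up`, `regulated_down`, as for the OsbZIP23 regulon) to a
#' network. Exact duplicate records are dropped with a warning; regulators
#' or targets absent from the network are added as nodes and counted in
#' the log.
#'
#' @param network An `interaction_network`.
#' @param regulator_table Data frame `regulator`, `target`, `relation`.
#' @return The augmented `interaction_network`.
#' @export
overlay_regulator <- function(network, regulator_table) {
  dc_assert(inherits(network, "interaction_network"),
            "`network` must be an interaction_network",
            class = "dielcross_argument_error")
  if (nrow(regulator_table) == 0L) return(network)
  need <- c("regulator", "target", "relation")
  dc_assert(all(need %in% names(regulator_table)),
            "regulator table needs columns regulator, target, relation",
            class = "dielcross_format_error")
  bad <- setdiff(unique(regulator_table$relation), REGULATOR_RELATIONS)
  if (length(bad))
    dc_stop("unknown regulator relation(s): %s (allowed: %s)",
            paste(bad, collapse = ", "),
            paste(REGULATOR_RELATIONS, collapse = ", "),
            class = "dielcross_format_error")
  reg <- regulator_table[, need]
  dup <- duplicated(reg)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate regulator record(s)", sum(dup)))
    reg <- reg[!dup, , drop = FALSE]
  }
  new_nodes <- setdiff(unique(c(reg$regulator, reg$target)),
                       network$nodes$gene_id)
  if (length(new_nodes)) {
    network$nodes <- rbind(network$nodes, data.frame(
      gene_id = new_nodes, in_pathway = FALSE,
      functional_bin = NA_character_, drought_class = NA_character_,
      diurnal = NA, characterized = FALSE, stringsAsFactors = FALSE))
    network$log$n_regulator_added_nodes <-
      (network$log$n_regulator_added_nodes %||% 0L) + length(new_nodes)
  }
  network$regulators <- rbind(network$regulators, reg)
  rownames(network$regulators) <- NULL
  network
}
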