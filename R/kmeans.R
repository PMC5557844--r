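#' K-means clustering of expression profiles (Lloyd's algorithm)
#'
#' Deterministic K-means with squared-Euclidean distance. Small instances
#' (at most 120 distinct k-subsets of points) run Lloyd from every
#' distinct subset, which is deterministic and independent of row order;
#' larger instances use best-of-`nstart` seeded k-means++ restarts. Empty
#' clusters arising during iteration are repaired by reseeding the
#' centroid at the point farthest from its current centroid. The
#' within-cluster sum of squares (WCSS) is non-increasing over iterations
#' and the full history is recorded.
#'
#' With `distance = "pearson"` rows are z-scored first, so squared
#' Euclidean distance becomes a monotone function of (1 - Pearson r) and
#' clusters group profiles by shape rather than level.
#'
#' @param x Numeric matrix, observations (genes) in rows; no missing values.
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer seed; the same seed always yields the same result.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Relative WCSS improvement below which iteration stops.
#' @param nstart Number of independent k-means++ starts; the restart with
#'   the lowest final WCSS is returned.
#' @param distance `"euclidean"` (on the values as given) or `"pearson"`
#'   (on row z-scores).
#' @return A `kmeans_result`: list with `k`, `assignments` (named integer
#'   vector), `centroids`, `wcss`, `wcss_history`, `n_iter`, `seed`,
#'   `distance`.
#' @export
kmeans_profiles <- function(x, k, seed, max_iter = 100L, tol = 1e-8,
                            nstart = 25L,
                            distance = c("euclidean", "pearson")) {
  distance <- match.arg(distance)
  dc_assert(is.matrix(x) && is.numeric(x), "`x` must be a numeric matrix",
            class = "dielcross_argument_error")
  if (anyNA(x))
    dc_stop("`x` contains missing values; filter with complete_profiles() first",
            class = "dielcross_argument_error")
  n <- nrow(x)
  dc_assert(is_count(k), "`k` must be a positive integer",
            class = "dielcross_argument_error")
  if (k > n)
    dc_stop("k = %d exceeds the number of profiles (%d)", k, n,
            class = "dielcross_argument_error")
  if (distance == "pearson") {
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0))
      dc_stop("constant rows have undefined Pearson distance",
              class = "dielcross_argument_error")
    x <- (x - rowMeans(x)) / sds
  }
  k <- as.integer(k)
  best <- NULL
  # On small instances every distinct k-subset of points is tried as a
  # start (deterministic and robust to row order); larger instances use
  # seeded k-means++ restarts.
  if (choose(n, k) <= 120) {
    subsets <- utils::combn(n, k)
    runs <- lapply(seq_len(ncol(subsets)), function(j)
      kmeans_once(x, k, max_iter, tol,
                  centers = x[subsets[, j], , drop = FALSE]))
  } else {
    runs <- with_seed(seed, {
      lapply(seq_len(max(1L, as.integer(nstart))), function(i) {
        kmeans_once(x, k, max_iter, tol)
      })
    })
  }
  for (run in runs) {
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }
  rn <- rownames(x) %||% as.character(seq_len(n))
  names(best$assignments) <- rn
  structure(list(k = k, assignments = best$assignments,
                 centroids = best$centroids, wcss = best$wcss,
                 wcss_history = best$wcss_history, n_iter = best$n_iter,
                 seed = seed, distance = distance),
            class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("<kmeans_result> k = %d, n = %d, wcss = %.6g, %d iteration(s)\n",
              x$k, length(x$assignments), x$wcss, x$n_iter))
  invisible(x)
}

# One Lloyd run from the given centers (k-means++ drawn from the current
# RNG stream when centers are not supplied).
kmeans_once <- function(x, k, max_iter, tol, centers = NULL) {
  n <- nrow(x)
  if (is.null(centers)) centers <- kmeanspp_init(x, k)
  wcss_history <- numeric(0)
  assign <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_matrix(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    # repair empty clusters: reseed each at the point farthest from its
    # current centroid, claiming that point outright so progress is
    # guaranteed even with duplicated rows
    repeat {
      sizes <- tabulate(assign, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      dmin <- d2[cbind(seq_len(n), assign)]
      far <- which.max(dmin)
      centers[empty[1L], ] <- x[far, , drop = FALSE]
      d2[, empty[1L]] <- rowSums((x - matrix(centers[empty[1L], ], n,
                                             ncol(x), byrow = TRUE))^2)
      assign <- max.col(-d2, ties.method = "first")
      assign[far] <- empty[1L]
    }
    wcss <- sum(d2[cbind(seq_len(n), assign)])
    # update step
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    d2new <- dist2_matrix(x, centers)
    wcss_new <- sum(d2new[cbind(seq_len(n), assign)])
    wcss_history <- c(wcss_history, wcss_new)
    if (iter > 1L) {
      prev <- wcss_history[iter - 1L]
      if (prev - wcss_new <= tol * max(prev, .Machine$double.eps)) break
    }
  }
  # final assignment consistent with final centroids
  d2 <- dist2_matrix(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  for (j in seq_len(k))
    if (any(assign == j))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  d2 <- dist2_matrix(x, centers)
  wcss <- sum(d2[cbind(seq_len(n), assign)])
  list(assignments = assign, centroids = centers, wcss = wcss,
       wcss_history = c(wcss_history, wcss), n_iter = length(wcss_history))
}

# squared Euclidean distances, n x k
dist2_matrix <- function(x, centers) {
  cross <- x %*% t(centers)
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(centers)) -
    2 * cross +
    matrix(rowSums(centers^2), nrow(x), nrow(centers), byrow = TRUE)
  pmax(d2, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, later
# centers drawn with probability proportional to squared distance to the
# nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2L:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Label clusters as drought up / down / unresponsive
#'
#' Each cluster's mean drought log2 fold change (over all member genes and
#' all drought replicate pairs) decides the label every member inherits:
#' `up` at or above `up_threshold`, `down` at or below `-down_threshold`,
#' otherwise `none`.
#'
#' @param km A `kmeans_result` over fold-change profiles.
#' @param fcp The `fold_change_profile` the clustering was run on.
#' @param up_threshold,down_threshold Positive log2 cutoffs (default 1.0,
#'   i.e. two-fold).
#' @return A data frame with `gene_id`, `drought_class`, `source_cluster`,
#'   `cluster_mean_drought_log2fc`.
#' @export
label_clusters <- function(km, fcp, up_threshold = 1, down_threshold = 1) {
  dc_assert(inherits(km, "kmeans_result"), "`km` must be a kmeans_result",
            class = "dielcross_argument_error")
  dc_assert(up_threshold > 0 && down_threshold > 0,
            "thresholds must be positive", class = "dielcross_argument_error")
  dr <- fcp$pairs$stress_type == "drought"
  if (!any(dr))
    dc_stop("fold-change profile has no drought replicate pairs",
            class = "dielcross_argument_error")
  genes <- names(km$assignments)
  miss <- setdiff(genes, rownames(fcp$log2fc))
  if (length(miss))
    dc_stop("clustered gene(s) absent from fold-change profile: %s",
            paste(utils::head(miss, 5L), collapse = ", "),
            class = "dielcross_argument_error")
  gene_mean <- rowMeans(fcp$log2fc[genes, dr, drop = FALSE])
  cl_mean <- tapply(gene_mean, km$assignments, mean)
  lab <- ifelse(cl_mean >= up_threshold, "up",
                ifelse(cl_mean <= -down_threshold, "down", "none"))
  data.frame(
    gene_id = genes,
    drought_class = unname(lab[as.character(km$assignments)]),
    source_cluster = unname(km$assignments),
    cluster_mean_drought_log2fc = unname(cl_mean[as.character(km$assignments)]),
    stringsAsFactors = FALSE)
}

#' Count genes per drought-response class
#' @param labels A response-label table from [label_clusters()].
#' @return Named integer vector `(n_up, n_down, n_none)`.
#' @export
response_counts <- function(labels) {
  cls <- factor(labels$drought_class, levels = c("up", "down", "none"))
  cnt <- table(cls)
  c(n_up = unname(cnt["up"]), n_down = unname(cnt["down"]),
    n_none = unname(cnt["none"]))
}

#' One-call drought classification
#'
#' Filters fold-change profiles, clusters them with [kmeans_profiles()],
#' and labels every gene with [label_clusters()].
#'
#' @inheritParams kmeans_profiles
#' @inheritParams label_clusters
#' @param fcp A `fold_change_profile`.
#' @param max_missing Per-gene missingness budget before exclusion.
#' @return The labeled gene table (see [label_clusters()]), with the
#'   `kmeans_result` attached as attribute `"kmeans"`.
#' @export
classify_drought <- function(fcp, k = 10, seed = 1, up_threshold = 1,
                             down_threshold = 1, max_missing = 0.2, ...) {
  x <- complete_profiles(fcp, max_missing)
  km <- kmeans_profiles(x, k = k, seed = seed, ...)
  labels <- label_clusters(km, fcp, up_threshold, down_threshold)
  attr(labels, "kmeans") <- km
  labels
}
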