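# Independent brute-force / textbook oracles used to cross-check the
# package implementations. These deliberately avoid the code paths they
# verify.

# Global minimum WCSS over every assignment of n points into at most k
# clusters, by exhaustive enumeration.
oracle_kmeans_wcss <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 1e6)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    wcss <- 0
    for (j in unique(assign)) {
      xj <- x[assign == j, , drop = FALSE]
      ctr <- colMeans(xj)
      wcss <- wcss + sum(sweep(xj, 2L, ctr)^2)
    }
    if (wcss < best) best <- wcss
    # increment base-k counter
    i <- 1L
    while (i <= n) {
      assign[i] <- assign[i] + 1L
      if (assign[i] <= k) break
      assign[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# Upper-tail hypergeometric probability by direct binomial-coefficient
# enumeration.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Welch's t statistic, Welch-Satterthwaite df and two-tailed p from the
# textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson correlation from the covariance definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / ((n - 1) * sd(x) * sd(y))
}

# Small deterministic fixtures -----------------------------------------

toy_expression <- function(values, scale = "log2") {
  expression_matrix(values, scale)
}

# Two-series stress fixture: series A (drought) and B (cold), one
# replicate pair each, values chosen by hand.
toy_stress_fixture <- function() {
  vals <- matrix(c(9, 8, 7, 7,
                   10, 8, 8, 8,
                   5, 6, 6, 6), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("A_stress_r1", "A_mock_r1",
                                   "B_stress_r1", "B_mock_r1")))
  md <- data.frame(
    sample_id = colnames(vals),
    series_id = rep(c("A", "B"), each = 2),
    stress_type = rep(c("drought", "cold"), each = 2),
    condition = rep(c("stress", "mock"), 2),
    replicate = 1L, stage = NA_integer_, day = NA_integer_,
    hour = NA_integer_, stringsAsFactors = FALSE)
  list(em = expression_matrix(vals, "log2"), metadata = md)
}

toy_network_inputs <- function() {
  interactions <- data.frame(
    gene_a = c("p1", "p1", "p2", "x1", "p2"),
    gene_b = c("x1", "x2", "x1", "p1", "p2"),  # dup pair + self loop
    confidence = c(0.9, 0.4, 0.7, 0.8, 0.5),
    stringsAsFactors = FALSE)
  prof <- matrix(c(1, 2, 3, 4, 5,
                   1.1, 2.2, 2.9, 4.2, 5.1,
                   5, 4, 3, 2, 1,
                   2, 2, 2, 2, 2), nrow = 4, byrow = TRUE,
                 dimnames = list(c("p1", "x1", "x2", "p2"),
                                 paste0("s", 1:5)))
  list(pathway = c("p1", "p2", "p3"), interactions = interactions,
       expression = expression_matrix(prof, "log2"))
}
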