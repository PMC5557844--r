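# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed abort so callers/tests can distinguish failure modes without
# matching message text.
dc_stop <- function(msg, ..., class = "dielcross_error") {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "dielcross_error", "error", "condition")))
}

dc_assert <- function(cond, msg, ..., class = "dielcross_error") {
  if (!isTRUE(cond)) dc_stop(msg, ..., class = class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package funnel through
# this so a recorded seed fully determines the output.
with_seed <- function(seed, expr) {
  dc_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "`seed` must be a single finite number",
            class = "dielcross_config_error")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Deterministic TSV writer used for every tabular output.
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
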