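# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores \code{.Random.seed} so that seeded generators are
#' pure functions of their arguments and do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a master seed and a stage label.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483646L) + 1L
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name))
  invisible(x)
}

# Plain TSV writers/readers used for all tabular interfaces.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Safe sampling from an explicit vector (avoids the sample(n, 1) trap
# when the candidate set has length one).
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Two-group label checks shared by the testing functions.
check_two_groups <- function(groups, min_per_group = 2L) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("exactly two groups are required, got: ", paste(lev, collapse = ", "))
  n <- table(factor(groups, levels = lev))
  if (any(n < min_per_group))
    stop(sprintf("each group needs at least %d samples (got %s)",
                 min_per_group, paste(n, collapse = " vs ")))
  lev
}
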