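# Shared fixtures, built in code.

# Independent reverse complement for constructing expected reads.
revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

tiny_genome <- function(seed = 1L, len = 1e5, n_genes = 50L,
                        n_islands = 10L, ...) {
  generate_genome(genome_config(chr_lengths = c(chr1 = len),
                                n_genes = n_genes, n_islands = n_islands,
                                ...),
                  seed = seed)
}

two_group_labels <- function(n1 = 4L, n2 = 3L) {
  stats::setNames(c(rep("ERpos", n1), rep("ERneg", n2)),
                  paste0("s", seq_len(n1 + n2)))
}

# Log2 expression matrix with a planted between-group shift of `shift`
# log2 units on the first n_shift genes (split symmetrically around the
# shared baseline, as differential expression is).
separated_matrix <- function(n_genes = 2000L, n_shift = 300L, shift = 4,
                             n1 = 4L, n2 = 3L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes)
  sh <- seq_len(n_shift)
  m[sh, seq_len(n1)] <- m[sh, seq_len(n1)] + shift / 2
  m[sh, n1 + seq_len(n2)] <- m[sh, n1 + seq_len(n2)] - shift / 2
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n1 + n2)))
  m
}

# A single-sample log-ratio track with an optional planted step.
toy_track <- function(n = 100L, step_at = NULL, step = 0, sd = 0.2,
                      seed = 1L, window = 1e4) {
  set.seed(seed)
  x <- rnorm(n, 0, sd)
  if (!is.null(step_at)) x[step_at] <- x[step_at] + step
  structure(data.frame(chrom = "chr1",
                       start = (seq_len(n) - 1L) * window,
                       end = seq_len(n) * window,
                       tumor = NA_integer_, ref = NA_integer_,
                       log2ratio = x, stringsAsFactors = FALSE),
            class = c("log_ratio_track", "data.frame"))
}

# Brute-force recurrent-region oracle on a unit grid: for every
# integer position, the set of samples carrying a same-direction CNA.
brute_recurrent <- function(intervals, min_samples, lim) {
  pos <- seq.int(0L, lim - 1L)
  out <- list()
  for (cls in unique(intervals$class)) {
    iv <- intervals[intervals$class == cls, , drop = FALSE]
    supp <- lapply(pos, function(p)
      sort(unique(iv$sample[iv$start <= p & iv$end > p])))
    qual <- vapply(supp, length, integer(1)) >= min_samples
    r <- rle(vapply(supp, paste, character(1), collapse = ","))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!qual[starts[j]]) next
      out[[length(out) + 1L]] <- data.frame(
        start = pos[starts[j]], end = pos[ends[j]] + 1L,
        class = cls, samples = r$values[j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
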