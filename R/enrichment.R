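# Gene set enrichment: phenotype-permutation GSEA (weighted
# Kolmogorov-Smirnov running sum, NES, nominal p, pooled FDR q) and
# hypergeometric over-representation.

#' Rank genes by a two-class signal-to-noise score
#'
#' Scores each gene as (mean1 - mean2) / (sd1 + sd2) with each class
#' standard deviation floored at 0.2 |mean| (0.2 when the mean is
#' zero), the usual convention that keeps low-variance genes from
#' dominating the ranking.  Ties are broken deterministically by gene
#' id.
#'
#' @param expr numeric matrix genes x samples (log scale).
#' @param labels two-class phenotype per sample.
#' @param levels optional explicit class ordering.
#' @param metric "s2n" (default) or "t" (ordinary two-sample t).
#' @return data.frame (gene, score) sorted by decreasing score.
#' @export
rank_genes <- function(expr, labels, levels = NULL,
                       metric = c("s2n", "t")) {
  metric <- match.arg(metric)
  lev <- check_two_groups(labels)
  if (!is.null(levels)) lev <- levels
  labels <- as.character(labels)
  x1 <- expr[, labels == lev[1], drop = FALSE]
  x2 <- expr[, labels == lev[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- apply(x1, 1L, stats::sd); s2 <- apply(x2, 1L, stats::sd)
  if (metric == "s2n") {
    floor_sd <- function(s, m) pmax(s, ifelse(m == 0, 0.2, 0.2 * abs(m)))
    score <- (m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2))
  } else {
    n1 <- ncol(x1); n2 <- ncol(x2)
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    score <- (m1 - m2) / sqrt(pmax(sp2, .Machine$double.eps) *
                                (1 / n1 + 1 / n2))
  }
  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  o <- order(-score, ids)
  data.frame(gene = ids[o], score = unname(score[o]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating |score|^p / (sum over hits) at
#' set members and -1/(N - Nh) elsewhere; the enrichment score is the
#' running sum's maximum deviation from zero (signed).
#'
#' @param ranked data.frame (gene, score) from \code{\link{rank_genes}}.
#' @param set character vector of member gene ids; members absent from
#'   the ranking are dropped (and counted in the result).
#' @param p hit weight exponent (default 1; p = 0 gives the classic KS
#'   statistic).
#' @return list: \code{es}, \code{running} (the running sum),
#'   \code{hits} (logical per rank), \code{n_dropped}.
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  hits <- ranked$gene %in% set
  n_dropped <- length(setdiff(set, ranked$gene))
  nh <- sum(hits)
  if (nh == 0L) stop("gene set is empty after intersection with the ranking")
  N <- nrow(ranked)
  if (nh == N) stop("gene set covers the whole ranking")
  w <- abs(ranked$score)^p
  inc <- ifelse(hits, w / sum(w[hits]), -1 / (N - nh))
  # degenerate: all hit weights zero (p>0, all-zero scores in set)
  if (!is.finite(sum(w[hits])) || sum(w[hits]) == 0)
    inc[hits] <- 1 / nh
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hits = hits, n_dropped = n_dropped)
}

# All distinct two-class label assignments (up to group swap the ES is
# recomputed anyway); returns a matrix with one permuted label vector
# per column, excluding the observed assignment.
permute_labels <- function(labels, lev, n_perm, seed) {
  n <- length(labels)
  idx1 <- which(labels == lev[1])
  all_n <- choose(n, length(idx1))
  if (n_perm >= all_n - 1) {
    combs <- utils::combn(n, length(idx1))
    keep <- apply(combs, 2L, function(cc) !setequal(cc, idx1))
    combs <- combs[, keep, drop = FALSE]
    perms <- apply(combs, 2L, function(cc) {
      l <- rep(lev[2], n); l[cc] <- lev[1]; l
    })
  } else {
    perms <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample(labels), character(n))
    })
  }
  perms
}

#' Gene set enrichment analysis with phenotype permutation
#'
#' For each gene set, computes the weighted-KS enrichment score on the
#' observed ranking, then re-ranks the genes under permuted phenotype
#' labels to build the null.  The normalized enrichment score (NES) is
#' the observed ES divided by the mean |null ES| of the same sign; the
#' nominal p-value is the same-sign permutation tail; the FDR q-value
#' compares each set's NES with the pooled null NES distribution over
#' all sets, normalized by the observed NES distribution.  When the
#' requested permutation count reaches the number of distinct label
#' assignments, the null is enumerated exhaustively instead of sampled.
#'
#' @param expr numeric matrix genes x samples.
#' @param labels two-class phenotype per sample.
#' @param sets named list of gene sets (see \code{\link{read_gmt}}).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param weight hit weight exponent (default 1).
#' @param metric ranking metric (see \code{\link{rank_genes}}).
#' @param size_range admissible set sizes after intersection with the
#'   expression universe (default c(15, 500)); sets outside the bounds
#'   are dropped with an audit.
#' @param levels optional explicit class ordering.
#' @return data.frame of class \code{gsea_result}: set, size, es, nes,
#'   p, q, leading_edge (comma-joined); dropped sets in
#'   \code{attr(, "dropped")}.
#' @export
gsea <- function(expr, labels, sets, n_perm = 1000L, seed = 1L,
                 weight = 1, metric = "s2n", size_range = c(15L, 500L),
                 levels = NULL) {
  lev <- check_two_groups(labels)
  if (!is.null(levels)) lev <- levels
  universe <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  sizes <- vapply(sets, function(s) length(intersect(s, universe)),
                  integer(1))
  ok <- sizes >= size_range[1] & sizes <= size_range[2]
  dropped <- names(sets)[!ok]
  sets <- sets[ok]
  if (!length(sets)) stop("no gene set within the size bounds")

  ranked <- rank_genes(expr, labels, levels = lev, metric = metric)
  obs <- lapply(sets, function(s) enrichment_score(ranked, s, p = weight))
  es <- vapply(obs, `[[`, numeric(1), "es")

  perms <- permute_labels(as.character(labels), lev, n_perm, seed)
  null_es <- matrix(NA_real_, nrow = length(sets), ncol = ncol(perms),
                    dimnames = list(names(sets), NULL))
  for (j in seq_len(ncol(perms))) {
    rj <- rank_genes(expr, perms[, j], levels = lev, metric = metric)
    for (k in seq_along(sets))
      null_es[k, j] <- enrichment_score(rj, sets[[k]], p = weight)$es
  }

  nes <- numeric(length(sets)); pval <- numeric(length(sets))
  null_nes <- null_es
  for (k in seq_along(sets)) {
    pos <- null_es[k, null_es[k, ] >= 0]
    neg <- null_es[k, null_es[k, ] < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    null_nes[k, ] <- ifelse(null_es[k, ] >= 0,
                            null_es[k, ] / mpos,
                            null_es[k, ] / mneg)
    if (es[k] >= 0) {
      nes[k] <- es[k] / mpos
      pval[k] <- if (length(pos)) mean(pos >= es[k]) else NA_real_
    } else {
      nes[k] <- -abs(es[k]) / mneg
      pval[k] <- if (length(neg)) mean(neg <= es[k]) else NA_real_
    }
  }

  pool <- as.numeric(null_nes)
  qval <- vapply(seq_along(sets), function(k) {
    if (is.na(nes[k])) return(NA_real_)
    if (nes[k] >= 0) {
      num_d <- sum(pool >= 0)
      num <- if (num_d) sum(pool >= nes[k]) / num_d else NA_real_
      den_d <- sum(nes >= 0)
      den <- if (den_d) sum(nes >= nes[k]) / den_d else NA_real_
    } else {
      num_d <- sum(pool < 0)
      num <- if (num_d) sum(pool <= nes[k]) / num_d else NA_real_
      den_d <- sum(nes < 0)
      den <- if (den_d) sum(nes <= nes[k]) / den_d else NA_real_
    }
    min(1, num / den)
  }, numeric(1))

  leading <- vapply(seq_along(sets), function(k) {
    o <- obs[[k]]
    peak <- which.max(abs(o$running))
    le <- if (o$es >= 0) ranked$gene[seq_len(peak)][o$hits[seq_len(peak)]]
          else ranked$gene[peak:nrow(ranked)][o$hits[peak:nrow(ranked)]]
    paste(le, collapse = ",")
  }, character(1))

  out <- data.frame(set = names(sets), size = sizes[ok], es = es,
                    nes = nes, p = pval, q = qval,
                    leading_edge = leading, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "dropped") <- dropped
  attr(out, "n_perm") <- ncol(perms)
  class(out) <- c("gsea_result", class(out))
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a focus gene list and a pathway, drawn from a finite
#' universe.
#'
#' @param focus character vector of focus genes (must lie in the
#'   universe).
#' @param universe character vector, the reference list.
#' @param pathway character vector of pathway members.
#' @return list: \code{p}, \code{overlap}, \code{expected}.
#' @export
hypergeometric_enrichment <- function(focus, universe, pathway) {
  focus <- unique(focus); universe <- unique(universe)
  if (!all(focus %in% universe))
    stop("focus genes must be a subset of the universe")
  path_u <- intersect(unique(pathway), universe)
  if (!length(path_u)) {
    warning("pathway does not intersect the universe; p = 1")
    return(list(p = 1, overlap = 0L, expected = 0))
  }
  k <- length(intersect(focus, path_u))
  N <- length(universe); K <- length(path_u); n <- length(focus)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(p = p, overlap = k, expected = n * K / N)
}
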