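#' Correlation-distance hierarchical clustering of samples
#'
#' Clusters samples with distance \code{1 - Pearson(sample profiles)}
#' and average linkage, and cuts the dendrogram at \code{k} clusters.
#'
#' @param expr numeric matrix (genes x samples), typically log2 RPM.
#' @param k number of clusters for the reported cut (default 2).
#' @return list with \code{hclust} (the merge tree), \code{dist}
#'   (the distance matrix) and \code{membership} (named integer vector,
#'   cluster per sample).
#' @export
hierarchical_cluster <- function(expr, k = 2L) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("at least 3 samples are required")
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant profile (undefined correlation) in sample(s): ",
         paste(colnames(expr)[sds == 0] %||% which(sds == 0), collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(expr))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, dist = d, membership = stats::cutree(hc, k = k))
}

# Pairwise co-membership matrix (logical, upper triangle as vector).
co_membership <- function(membership) {
  outer(membership, membership, "==")[upper.tri(diag(length(membership)))]
}

#' Cluster stability under noise perturbation (R and D indices)
#'
#' Quantifies how reproducible a k-cluster cut is when Gaussian noise is
#' added to the data and the samples are re-clustered.  The noise
#' variance is the median, over genes, of the per-gene across-sample
#' variance.  For each of \code{n_iter} iterations, i.i.d.
#' \eqn{N(0, \sigma^2)} noise is added to every cell, the perturbed
#' matrix is re-clustered (1 - correlation distance, average linkage)
#' and cut at \code{k}.  The R (robustness) index is the mean, over
#' iterations, of the proportion of sample pairs co-clustered in the
#' original cut that remain co-clustered in the perturbed cut; the D
#' (discrepancy) index is the mean count of sample pairs whose
#' co-membership status differs between the two cuts.  R = 1 and D = 0
#' indicate a cut that the perturbation never disturbs.
#'
#' @param expr numeric matrix, genes x samples, on the log scale.
#' @param k number of clusters (default 2).
#' @param n_iter perturbation iterations (default 100).
#' @param seed integer seed for the noise draws.
#' @param noise_var optional override of the noise variance.
#' @return list with \code{R}, \code{D}, \code{n_iter},
#'   \code{noise_var} and \code{membership} (the unperturbed cut).
#' @export
cluster_robustness <- function(expr, k = 2L, n_iter = 100L, seed = 1L,
                               noise_var = NULL) {
  expr <- as.matrix(expr)
  if (k > ncol(expr)) stop("k exceeds the number of samples")
  base <- hierarchical_cluster(expr, k = k)
  orig <- base$membership
  co0 <- co_membership(orig)
  n_co0 <- sum(co0)
  if (is.null(noise_var))
    noise_var <- stats::median(apply(expr, 1L, stats::var))

  res <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      pert <- expr +
        matrix(stats::rnorm(length(expr), sd = sqrt(noise_var)),
               nrow = nrow(expr))
      mem <- hierarchical_cluster(pert, k = k)$membership
      coi <- co_membership(mem)
      r <- if (n_co0 > 0) sum(co0 & coi) / n_co0 else 1
      c(R = r, D = sum(co0 != coi))
    }, numeric(2))
  })
  list(R = mean(res["R", ]), D = mean(res["D", ]),
       n_iter = n_iter, noise_var = noise_var, membership = orig)
}
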