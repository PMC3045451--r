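#' Log2 reads-per-million normalization with a +1 pseudocount
#'
#' Converts raw gene-level counts to \code{log2(((count + 1) / total) *
#' 1e6)}.  The denominator is, by default, the per-sample sum of raw
#' counts over the annotated genes; an externally supplied total (for
#' example total mapped reads) can be given instead.  A pseudocount of 1
#' is added to every gene in every sample before scaling so that zero
#' counts remain finite after the log; with a library of one million
#' reads a zero count maps to exactly log2 RPM = 0.
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param totals optional numeric vector of per-sample totals to use as
#'   denominators; defaults to \code{colSums(counts)}.
#' @return numeric matrix of log2 RPM values with the same dimnames,
#'   with the totals used attached as \code{attr(, "totals")}.
#' @export
normalize_rpm <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative and complete")
  if (is.null(totals)) totals <- colSums(counts)
  if (length(totals) != ncol(counts))
    stop("one total per sample is required")
  bad <- which(totals <= 0)
  if (length(bad))
    stop("sample(s) with non-positive total counts: ",
         paste(colnames(counts)[bad] %||% bad, collapse = ", "))
  rpm <- sweep(counts + 1, 2L, totals, "/") * 1e6
  out <- log2(rpm)
  attr(out, "totals") <- totals
  out
}

#' Abundance filters for count matrices
#'
#' Applies the staged filters used before differential testing: (1)
#' genes with zero counts in every sample are removed; (2) a gene is
#' retained only if, in at least one group, the mean raw count exceeds
#' \code{min_mean} AND every sample of that same group has at least
#' \code{min_each} raw counts.
#'
#' @param counts raw count matrix, genes x samples.
#' @param groups group label per sample (two levels).
#' @param min_mean group-mean raw count a qualifying group must exceed
#'   (default 50, roughly 1 RPM at these depths).
#' @param min_each minimum raw count required in every sample of the
#'   qualifying group (default 5).
#' @return list with \code{kept} (retained gene ids), \code{counts}
#'   (the retained submatrix) and \code{audit}, a named vector
#'   recording input size and genes dropped at each stage.
#' @export
filter_genes <- function(counts, groups, min_mean = 50, min_each = 5) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("empty count matrix")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  lev <- check_two_groups(groups, min_per_group = 1L)
  groups <- as.character(groups)

  nonzero <- rowSums(counts) > 0
  n_zero <- sum(!nonzero)
  cz <- counts[nonzero, , drop = FALSE]

  qualifies <- rep(FALSE, nrow(cz))
  for (g in lev) {
    sel <- groups == g
    m <- rowMeans(cz[, sel, drop = FALSE])
    lo <- apply(cz[, sel, drop = FALSE], 1L, min)
    qualifies <- qualifies | (m > min_mean & lo >= min_each)
  }
  kept <- rownames(cz)[qualifies]
  list(kept = kept,
       counts = cz[qualifies, , drop = FALSE],
       audit = c(input = nrow(counts),
                 zero_in_all = n_zero,
                 failed_abundance = sum(!qualifies),
                 retained = length(kept)))
}

# Newton inversion of the trigamma function, used for empirical-Bayes
# moment matching of the variance prior.
trigamma_inverse <- function(x) {
  out <- x
  pos <- is.finite(x) & x > 0
  out[!pos] <- Inf
  y <- 0.5 + 1 / x[pos]          # starting value
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[pos]) / psigamma(y, 2L)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-8) break
  }
  out[pos] <- y
  out
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits the two-group contrast per gene and shrinks each gene's residual
#' variance toward a prior estimated by moment matching on the log
#' residual variances: with residual df \eqn{d}, the prior df \eqn{d_0}
#' and prior variance \eqn{s_0^2} are obtained by matching the mean and
#' variance of \eqn{\log s^2} to the scaled-F model (trigamma
#' inversion).  The moderated variance is
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)} and the moderated
#' statistic \eqn{\tilde t = \Delta \bar y / (\tilde s \sqrt{1/n_1 +
#' 1/n_2})} is referred to a t distribution on \eqn{d + d_0} degrees of
#' freedom (normal when \eqn{d_0 = \infty}).
#'
#' @param expr numeric matrix (typically log2 RPM), genes x samples.
#' @param groups two-level label per sample.  The reported fold change
#'   is \code{mean(group1) - mean(group2)} where group1 is
#'   \code{levels[1]} (or the first label encountered).
#' @param levels optional explicit ordering of the two group labels.
#' @return data.frame with one row per gene: group means, \code{log2fc},
#'   \code{s2} (residual variance), \code{s2_post}, \code{t}, \code{p},
#'   plus hyperparameters \code{d0} and \code{s02} as attributes.
#' @export
moderated_t_test <- function(expr, groups, levels = NULL) {
  expr <- as.matrix(expr)
  lev <- check_two_groups(groups)
  if (!is.null(levels)) {
    if (!setequal(levels, lev)) stop("'levels' must name the two groups")
    lev <- levels
  }
  groups <- as.character(groups)
  i1 <- groups == lev[1]; i2 <- groups == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  d <- n1 + n2 - 2

  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  ss1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d

  hp <- fit_variance_prior(s2, d)
  d0 <- hp$d0; s02 <- hp$s02
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  tstat[m1 == m2] <- 0          # exact ties: 0/0 guards
  # total df capped at the pooled residual df; at d0 = Inf this is
  # effectively the normal reference
  df_total <- min(d + d0, nrow(expr) * d)
  p <- if (is.finite(df_total)) 2 * stats::pt(-abs(tstat), df = df_total)
       else 2 * stats::pnorm(-abs(tstat))
  p[tstat == 0] <- 1

  out <- data.frame(gene = rownames(expr) %||% seq_len(nrow(expr)),
                    mean1 = m1, mean2 = m2, log2fc = m1 - m2,
                    s2 = s2, s2_post = s2_post, t = tstat, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_residual") <- d
  attr(out, "groups") <- lev
  out
}

# Moment matching of log s^2 against the scaled-F model.  Returns prior
# df d0 and prior variance s02; d0 = Inf when the log-variances are
# underdispersed relative to chi-square sampling alone.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2)]
  med <- stats::median(s2)
  if (med == 0) {
    warning("all (or most) residual variances are zero; falling back to d0 = Inf")
    return(list(d0 = Inf, s02 = 0))
  }
  if (any(s2 == 0)) {
    warning("zero residual variances offset away from zero")
    s2 <- pmax(s2, 1e-5 * med)
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- if (length(e) > 1) stats::var(e) - trigamma(d / 2) else 0
  if (is.na(evar) || evar <= 0) {
    # log-variances no more dispersed than chi-square sampling alone:
    # the prior absorbs everything and the pooled variance is the prior
    d0 <- Inf
    s02 <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls \eqn{\pi_0} on the grid
#' \eqn{\lambda = 0.05, 0.10, \ldots, 0.95} with a natural cubic
#' smoother evaluated at the largest \eqn{\lambda}, then converts sorted
#' p-values to q-values by the step-down rule
#' \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)} / j}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda grid for the \eqn{\pi_0} estimate.
#' @return numeric vector of q-values in the input order, with the
#'   \eqn{\pi_0} estimate attached as \code{attr(, "pi0")}.
#' @export
estimate_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  # the lambda-grid estimate needs a reasonable number of tests; with
  # very few, take the conservative pi0 = 1
  if (m < 20L || length(unique(p)) == 1L) {
    pi0 <- 1
  } else {
    pi0_hat <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_hat, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    if (pi0 > 1) pi0 <- 1
    if (pi0 <= 0) {
      warning("pi0 estimate non-positive; clamping")
      pi0 <- .Machine$double.eps
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)[ro]
  attr(q, "pi0") <- pi0
  q
}

#' Select differentially expressed genes
#'
#' Applies the joint cut: nominal p below \code{p_cut} and linear-scale
#' fold change above \code{fc_cut} (i.e. \code{|log2fc| > log2(fc_cut)}).
#'
#' @param de data.frame from \code{\link{moderated_t_test}} (columns
#'   \code{gene}, \code{log2fc}, \code{p}).
#' @param p_cut nominal p-value cut (default 0.05).
#' @param fc_cut linear fold-change cut (default 1.5).
#' @return character vector of selected gene ids.
#' @export
select_de <- function(de, p_cut = 0.05, fc_cut = 1.5) {
  stopifnot(all(c("gene", "log2fc", "p") %in% names(de)))
  de$gene[de$p < p_cut & abs(de$log2fc) > log2(fc_cut)]
}

#' P-value histogram against the uniform expectation
#'
#' Bins p-values into equal-width bins on [0, 1] and reports, alongside
#' the observed counts, the count per bin expected if all genes were
#' null (total / bins).
#'
#' @param p numeric vector of p-values.
#' @param bins number of bins (default 20).
#' @return list with \code{counts} (named by bin), \code{breaks} and
#'   \code{expected} (scalar uniform expectation per bin).
#' @export
report_pvalue_histogram <- function(p, bins = 20L) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = bins + 1L)
  cut_idx <- pmin(findInterval(p, breaks, rightmost.closed = TRUE), bins)
  counts <- tabulate(cut_idx, nbins = bins)
  names(counts) <- sprintf("(%.2f,%.2f]", breaks[-length(breaks)], breaks[-1])
  list(counts = counts, breaks = breaks, expected = length(p) / bins)
}
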