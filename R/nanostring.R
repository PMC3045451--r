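# Count-based validation panel: positive-control normalization,
# negative-control background subtraction, detection limits, and
# cross-platform concordance.

#' Normalize a count-based validation panel
#'
#' Each sample's counts are scaled by factor (grand mean of per-sample
#' positive-control sums) / (that sample's positive-control sum), so
#' that the positive-control totals agree across samples.  The
#' background is the mean of the (scaled) negative controls in each
#' sample: endogenous counts are floored at the background and the
#' background is then subtracted, so sub-background genes land exactly
#' at 0.  A gene is flagged below the detection limit when its scaled
#' count is under mean + 2 SD of the negatives.
#'
#' @param run list with matrices \code{endogenous}, \code{pos} and
#'   \code{neg} (features x samples, shared sample columns).
#' @return list: \code{corrected} (background-corrected counts),
#'   \code{detected} (logical matrix), \code{factors},
#'   \code{background}, \code{detection_limit} (per sample).
#' @export
normalize_panel <- function(run) {
  stopifnot(all(c("endogenous", "pos", "neg") %in% names(run)))
  if (!nrow(run$pos) || !nrow(run$neg)) stop("control counts are required")
  if (any(run$endogenous < 0) || any(run$pos < 0) || any(run$neg < 0))
    stop("counts must be non-negative")
  pos_sums <- colSums(run$pos)
  if (any(pos_sums == 0))
    stop("zero positive-control sum in sample(s): ",
         paste(colnames(run$pos)[pos_sums == 0], collapse = ", "))
  factors <- mean(pos_sums) / pos_sums
  scaled <- sweep(run$endogenous, 2L, factors, "*")
  neg_scaled <- sweep(run$neg, 2L, factors, "*")
  background <- colMeans(neg_scaled)
  neg_sd <- apply(neg_scaled, 2L, stats::sd)
  limit <- background + 2 * neg_sd
  corrected <- sweep(pmax(scaled, rep(background, each = nrow(scaled))),
                     2L, background, "-")
  detected <- sweep(scaled, 2L, limit, ">=")
  list(corrected = corrected, detected = detected, factors = factors,
       background = background, detection_limit = limit)
}

#' Cross-platform concordance of panel and sequencing expression
#'
#' Log2(x + 1)-transforms both platforms, reports the per-sample
#' Pearson correlation over shared genes, the correlation of
#' two-group log2 fold changes for a supplied DE gene list, and a
#' per-gene two-sample t-test on the panel values.
#'
#' @param panel background-corrected panel counts (genes x samples,
#'   linear scale).
#' @param expr sequencing expression on the linear scale (e.g. RPM),
#'   same sample columns.
#' @param de_genes character vector of differentially expressed genes
#'   to compare fold changes on (default: all shared genes).
#' @param groups two-level label per sample.
#' @param levels optional explicit group ordering.
#' @return list: \code{sample_r} (named per-sample Pearson r),
#'   \code{fc_r} (fold-change correlation), \code{fc_table},
#'   \code{t_table} (panel t-tests: gene, log2fc, t, p).
#' @export
compare_platforms <- function(panel, expr, de_genes = NULL, groups = NULL,
                              levels = NULL) {
  shared <- intersect(rownames(panel), rownames(expr))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  lp <- log2(panel[shared, , drop = FALSE] + 1)
  le <- log2(expr[shared, , drop = FALSE] + 1)
  samples <- intersect(colnames(lp), colnames(le))
  sample_r <- vapply(samples, function(s) stats::cor(lp[, s], le[, s]),
                     numeric(1))

  fc_r <- NA_real_; fc_table <- NULL; t_table <- NULL
  if (!is.null(groups)) {
    lev <- check_two_groups(groups)
    if (!is.null(levels)) lev <- levels
    groups <- as.character(groups)
    g1 <- samples[groups[match(samples, colnames(lp))] == lev[1]]
    g2 <- setdiff(samples, g1)
    fc <- function(m) rowMeans(m[, g1, drop = FALSE]) -
      rowMeans(m[, g2, drop = FALSE])
    genes <- if (is.null(de_genes)) shared else intersect(de_genes, shared)
    if (length(genes) >= 3L) {
      fc_table <- data.frame(gene = genes, panel_fc = fc(lp)[genes],
                             expr_fc = fc(le)[genes],
                             stringsAsFactors = FALSE)
      fc_r <- stats::cor(fc_table$panel_fc, fc_table$expr_fc)
    }
    t_table <- do.call(rbind, lapply(shared, function(g) {
      tt <- tryCatch(stats::t.test(lp[g, g1], lp[g, g2], var.equal = TRUE),
                     error = function(e) NULL)
      data.frame(gene = g, log2fc = fc(lp)[g],
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(sample_r = sample_r, fc_r = fc_r, fc_table = fc_table,
       t_table = t_table)
}
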