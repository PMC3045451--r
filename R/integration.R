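# Cross-layer integration: join expression, methylation and copy
# number per gene; quantify the inverse methylation/expression
# relationship and the copy-number/expression coupling; emit the
# signature gene sets.

#' Join the three layers into per-gene-island records
#'
#' Builds one record per (gene, associated island) pair carrying the
#' gene's expression statistics, the island's differential-methylation
#' statistics, the island-to-TSS distance and membership flags.  A
#' record is flagged \code{inverse} when both layers are significant at
#' their cut-offs and the methylation difference has the opposite sign
#' to the expression fold change.
#'
#' @param de moderated-t table from \code{\link{moderated_t_test}}
#'   (with a \code{q} column added if available).
#' @param dm differential-methylation table from
#'   \code{\link{differential_methylation}}.
#' @param assoc island-gene association table from
#'   \code{\link{map_islands_to_genes}}.
#' @param de_genes character vector of genes passing the expression
#'   selection (see \code{\link{select_de}}).
#' @param dm_p_cut island significance cut (default 0.05).
#' @return data.frame of records, one row per gene-island pair.
#' @export
join_layers <- function(de, dm, assoc, de_genes = select_de(de),
                        dm_p_cut = 0.05) {
  rec <- merge(assoc, de[, intersect(c("gene", "log2fc", "p", "q"),
                                     names(de))], by = "gene")
  rec <- merge(rec, dm[, c("island", "mean_diff", "p")],
               by = "island", suffixes = c("", "_dm"))
  names(rec)[names(rec) == "p_dm"] <- "dm_p"
  rec$de_sig <- rec$gene %in% de_genes
  rec$dm_sig <- rec$dm_p < dm_p_cut
  rec$inverse <- rec$de_sig & rec$dm_sig &
    sign(rec$mean_diff) != 0 & sign(rec$log2fc) != 0 &
    sign(rec$mean_diff) != sign(rec$log2fc)
  rec[order(rec$gene, rec$island), ]
}

#' Pearson correlation between expression fold change and methylation
#' difference
#'
#' @param records data.frame with \code{log2fc} and \code{mean_diff}
#'   columns (one row per gene or gene-island pair).
#' @return list: \code{r}, \code{ci} (95\% interval via the Fisher z
#'   transform), \code{p} (two-sided t-test of r = 0), \code{n}.
#' @export
correlate_methylation_expression <- function(records) {
  x <- records$log2fc; y <- records$mean_diff
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete records are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the axes")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), ci = unname(ct$conf.int),
       p = ct$p.value, n = length(x))
}

#' Flag genes whose methylation is not inversely related to expression
#'
#' The default rule flags a record as an outlier when the methylation
#' difference has the SAME sign as the expression fold change (the
#' relationship is not inverse); the remaining records form the
#' inverse-correlated set.  Records with a zero methylation difference
#' are ambiguous and are retained.  The alternative
#' \code{method = "residual"} flags records whose studentized residual
#' from the least-squares line exceeds \code{resid_cut}.
#'
#' @param records data.frame with \code{log2fc} and \code{mean_diff};
#'   a \code{gene} column is used for ids when present.
#' @param method "sign" (default) or "residual".
#' @param resid_cut studentized-residual threshold for the residual
#'   rule (default 3).
#' @return list: \code{outliers}, \code{retained}, \code{ambiguous}
#'   (row ids), partitioning the input.
#' @export
flag_outliers <- function(records, method = c("sign", "residual"),
                          resid_cut = 3) {
  method <- match.arg(method)
  ids <- records$gene %||% rownames(records) %||%
    as.character(seq_len(nrow(records)))
  if (method == "sign") {
    same <- sign(records$mean_diff) == sign(records$log2fc) &
      records$mean_diff != 0 & records$log2fc != 0
    amb <- records$mean_diff == 0
    list(outliers = ids[same], retained = ids[!same], ambiguous = ids[amb])
  } else {
    fit <- stats::lm(mean_diff ~ log2fc, data = records)
    rs <- stats::rstudent(fit)
    out <- abs(rs) > resid_cut
    list(outliers = ids[out], retained = ids[!out], ambiguous = character(0))
  }
}

#' Distance-to-TSS structure of the inverse-correlated islands
#'
#' @param records data.frame with \code{distance} and \code{log2fc}.
#' @param bin_width histogram bin width in bp (default 250).
#' @param max_dist histogram range upper end (default 5000).
#' @return list: \code{median_distance}, \code{histogram} (counts per
#'   bin), \code{breaks}, \code{spearman_rho} between distance and
#'   |log2fc| (NA when degenerate).
#' @export
distance_analysis <- function(records, bin_width = 250, max_dist = 5000) {
  d <- records$distance
  breaks <- seq(0, max_dist, by = bin_width)
  counts <- tabulate(pmin(findInterval(d, breaks, rightmost.closed = TRUE),
                          length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  names(counts) <- sprintf("[%d,%d)", breaks[-length(breaks)], breaks[-1])
  rho <- if (length(unique(d)) > 1L && length(unique(abs(records$log2fc))) > 1L)
    suppressWarnings(stats::cor(d, abs(records$log2fc), method = "spearman"))
  else NA_real_
  list(median_distance = stats::median(d), histogram = counts,
       breaks = breaks, spearman_rho = rho)
}

#' Correlate expression fold change with group copy-number difference
#'
#' For every differentially expressed gene mapped to a recurrent CNA
#' region, the group copy-number difference is the arithmetic mean of
#' the gene's per-sample segment log2 ratios over group-1 samples minus
#' the mean over group-2 samples; the function returns the Pearson
#' correlation between these differences and the expression log2 fold
#' changes.
#'
#' @param de moderated-t table (columns \code{gene}, \code{log2fc}).
#' @param cna_values matrix genes x samples of per-sample segment log2
#'   ratios (\code{values} from \code{\link{assign_genes_to_cna}}).
#' @param groups two-level label per sample (columns of
#'   \code{cna_values}); difference is \code{levels[1] - levels[2]}.
#' @param levels optional explicit group ordering.
#' @return list: \code{r}, \code{n}, and the per-gene table.
#' @export
correlate_cna_expression <- function(de, cna_values, groups, levels = NULL) {
  lev <- unique(as.character(groups))
  if (!is.null(levels)) lev <- levels
  shared <- intersect(de$gene, rownames(cna_values))
  if (length(shared) < 3L)
    stop("fewer than 3 genes shared between the DE table and CNA regions")
  g1 <- cna_values[shared, groups == lev[1], drop = FALSE]
  g2 <- cna_values[shared, groups == lev[2], drop = FALSE]
  cn_diff <- rowMeans(g1) - rowMeans(g2)
  fc <- de$log2fc[match(shared, de$gene)]
  r <- stats::cor(fc, cn_diff)
  list(r = r, n = length(shared),
       table = data.frame(gene = shared, log2fc = fc, cn_diff = cn_diff,
                          stringsAsFactors = FALSE))
}

#' Build the methylation/expression and CNA/expression signatures
#'
#' The methylation signature contains genes that are differentially
#' expressed, linked to a significantly differentially methylated
#' island within the TSS window, and inverse (opposite signs),
#' partitioned by direction: up in group 1 with hypermethylation in
#' group 2, and the converse.  The CNA signature contains
#' differentially expressed genes lying in regions aberrant in EVERY
#' sample of one group and neutral in EVERY sample of the other.
#'
#' @param records joined records from \code{\link{join_layers}}.
#' @param cna_values per-sample gene copy values
#'   (\code{\link{assign_genes_to_cna}}); may be NULL to skip the CNA
#'   signature.
#' @param groups two-level label per sample (columns of
#'   \code{cna_values}).
#' @param de optional moderated-t table used to annotate the CNA
#'   signature table with fold changes and p-values.
#' @param levels optional explicit group ordering.
#' @return list with \code{methylation} (list: \code{up_in_1},
#'   \code{up_in_2}, \code{all}, and the Table-1-style two-column
#'   \code{table}), and \code{cna} (list: \code{genes} and a
#'   Table-2-style \code{table} with per-sample log2 ratios).
#' @export
build_signatures <- function(records, cna_values = NULL, groups = NULL,
                             de = NULL, levels = NULL) {
  inv <- records[records$inverse, , drop = FALSE]
  up1 <- sort(unique(inv$gene[inv$log2fc > 0]))
  up2 <- sort(unique(inv$gene[inv$log2fc < 0]))
  n <- max(length(up1), length(up2))
  tab1 <- data.frame(
    up_in_group1 = c(up1, rep("", n - length(up1))),
    up_in_group2 = c(up2, rep("", n - length(up2))),
    stringsAsFactors = FALSE)
  meth <- list(up_in_1 = up1, up_in_2 = up2,
               all = sort(unique(inv$gene)), table = tab1,
               n_islands = length(unique(inv$island)))

  cna <- NULL
  if (!is.null(cna_values) && nrow(cna_values)) {
    lev <- unique(as.character(groups))
    if (!is.null(levels)) lev <- levels
    a1 <- cna_values[, groups == lev[1], drop = FALSE] != 0
    a2 <- cna_values[, groups == lev[2], drop = FALSE] != 0
    consistent <- (rowSums(a1) == ncol(a1) & rowSums(a2) == 0) |
      (rowSums(a2) == ncol(a2) & rowSums(a1) == 0)
    genes <- rownames(cna_values)[consistent]
    if (!is.null(de)) genes <- intersect(genes, de$gene[de$p < 0.05])
    tab2 <- data.frame(gene = genes, stringsAsFactors = FALSE)
    if (!is.null(de)) {
      m <- match(genes, de$gene)
      tab2$log2fc <- de$log2fc[m]
      tab2$p <- de$p[m]
    }
    tab2 <- cbind(tab2, as.data.frame(cna_values[genes, , drop = FALSE]))
    cna <- list(genes = genes, table = tab2)
  }
  list(methylation = meth, cna = cna)
}
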