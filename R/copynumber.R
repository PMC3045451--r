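# Read-depth copy number: windowed tag counts, normalized log2 ratios,
# recursive t-test segmentation, one-copy-threshold classification and
# recurrent-region construction across samples.

#' Count tags in fixed windows
#'
#' Tiles each chromosome with non-overlapping windows of
#' \code{window_size} bp (the last window is truncated at the
#' chromosome end) and counts tag start positions per window.  Windows
#' are half-open, so a tag exactly on a boundary belongs to the
#' right-hand window.
#'
#' @param tags data.frame(chrom, pos), 0-based start positions.
#' @param chrom_lengths named vector of chromosome lengths, or a
#'   \code{synthetic_genome}.
#' @param window_size window width in bp.
#' @return data.frame(chrom, start, end, count).
#' @export
count_windows <- function(tags, chrom_lengths, window_size = 1e4) {
  if (inherits(chrom_lengths, "synthetic_genome"))
    chrom_lengths <- vapply(chrom_lengths$chromosomes, nchar, numeric(1))
  stopifnot_scalar_pos(window_size, "window_size")
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    if (window_size > len)
      warning(sprintf("window larger than %s; using a single window", chrom))
    starts <- seq(0, max(len - 1, 0), by = window_size)
    ends <- pmin(starts + window_size, len)
    p <- tags$pos[tags$chrom == chrom]
    idx <- findInterval(p, starts)      # half-open: boundary -> right window
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               count = tabulate(idx, nbins = length(starts)),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Windowed tumor-vs-reference log2 ratio track
#'
#' Computes per-window \code{log2(tumor + 0.5) - log2(ref + 0.5)}, then
#' normalizes at the individual-chromosome level by subtracting each
#' chromosome's median raw ratio (assuming most of a chromosome carries
#' no copy change), and finally subtracts the global median so the
#' tumor and reference medians align.
#'
#' @param tumor,ref window-count data.frames from
#'   \code{\link{count_windows}} on the same grid.
#' @return data.frame of class \code{log_ratio_track}: chrom, start,
#'   end, tumor, ref, log2ratio; the per-chromosome offsets are kept in
#'   \code{attr(, "chrom_offsets")}.
#' @export
compute_log2_ratios <- function(tumor, ref) {
  if (nrow(tumor) != nrow(ref) || any(tumor$start != ref$start) ||
      any(tumor$chrom != ref$chrom))
    stop("tumor and reference tracks must share the same window grid")
  zero_chrom <- tapply(ref$count, ref$chrom, function(x) all(x == 0))
  if (any(zero_chrom))
    stop("reference has zero coverage on chromosome(s): ",
         paste(names(zero_chrom)[zero_chrom], collapse = ", "))
  raw <- log2(tumor$count + 0.5) - log2(ref$count + 0.5)
  offs <- tapply(raw, tumor$chrom, stats::median)
  lr <- raw - offs[tumor$chrom]
  lr <- lr - stats::median(lr)
  out <- data.frame(chrom = tumor$chrom, start = tumor$start,
                    end = tumor$end, tumor = tumor$count,
                    ref = ref$count, log2ratio = as.numeric(lr),
                    stringsAsFactors = FALSE)
  attr(out, "chrom_offsets") <- offs
  class(out) <- c("log_ratio_track", class(out))
  out
}

# Best candidate sub-segment [i, j] of x: pooled two-sample t-test of
# the windows inside [i, j] against all remaining windows of the
# interval (two breakpoints scanned jointly, so an interior event is
# compared against its full flanking background).  Both the candidate
# and each non-empty flank must keep min_points windows.  Vectorized
# over j with cumulative sums.  Returns list(i, j, p, diff, sd).
best_split <- function(x, min_points) {
  n <- length(x)
  if (n < 2L * min_points) return(NULL)
  cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    if (i > 1L && i < min_points + 1L) next   # left flank too small
    j_min <- i + min_points - 1L
    js <- j_min:n
    js <- js[js == n | js <= n - min_points]  # right flank too small
    if (!length(js)) next
    n1 <- js - i + 1L; n2 <- n - n1
    ok <- n2 > 0L
    js <- js[ok]; n1 <- n1[ok]; n2 <- n2[ok]
    if (!length(js)) next
    s1 <- cs[js + 1L] - cs[i]; q1 <- css[js + 1L] - css[i]
    m1 <- s1 / n1; m2 <- (cs[n + 1L] - s1) / n2
    ss1 <- q1 - n1 * m1^2
    ss2 <- (css[n + 1L] - q1) - n2 * m2^2
    sp2 <- (ss1 + ss2) / (n - 2)
    sp2[sp2 <= 0] <- .Machine$double.eps
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    k <- which.min(p)
    if (is.null(best) || p[k] < best$p)
      best <- list(i = i, j = js[k], p = p[k], diff = m1[k] - m2[k],
                   sd = sqrt(sp2[k]))
  }
  best
}

#' Segment a log2-ratio track by recursive t-test splitting
#'
#' Recursively partitions each chromosome: at every step the candidate
#' sub-segment whose windows differ most from the remaining windows
#' (pooled two-sample t-test over all two-breakpoint candidates) is
#' split out, provided p < \code{p_split}, every resulting piece keeps
#' at least \code{min_points} windows, and the mean difference is at
#' least \code{min_sn} pooled standard deviations.  Scanning both
#' breakpoints jointly lets an interior aberration be tested against
#' its full flanking background, which a single-breakpoint scan dilutes
#' past the acceptance threshold.  A merge pass then re-joins adjacent
#' segments whose difference no longer meets the same criteria, making
#' the output independent of the split order.
#'
#' @param track a \code{log_ratio_track}.
#' @param p_split split acceptance p-value (default 1e-4).
#' @param min_points minimum windows per segment (default 10).
#' @param min_sn minimum mean difference in pooled-SD units
#'   (default 0.3).
#' @return data.frame: chrom, start, end, first, last (window indices
#'   within chromosome), n_windows, mean.
#' @export
segment_genome <- function(track, p_split = 1e-4, min_points = 10L,
                           min_sn = 0.3) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    tr <- track[track$chrom == chrom, , drop = FALSE]
    x <- tr$log2ratio
    segs <- list()
    recurse <- function(lo, hi) {
      bs <- best_split(x[lo:hi], min_points)
      if (!is.null(bs) && bs$p < p_split &&
          abs(bs$diff) >= min_sn * bs$sd) {
        i <- lo + bs$i - 1L; j <- lo + bs$j - 1L
        if (i > lo) recurse(lo, i - 1L)
        recurse(i, j)
        if (j < hi) recurse(j + 1L, hi)
      } else {
        segs[[length(segs) + 1L]] <<- c(lo, hi)
      }
    }
    recurse(1L, length(x))
    segs <- do.call(rbind, segs)
    segs <- segs[order(segs[, 1L]), , drop = FALSE]

    # merge pass: re-join adjacent segments with non-significant breaks
    repeat {
      if (nrow(segs) < 2L) break
      worst <- NULL; worst_p <- -1
      for (i in seq_len(nrow(segs) - 1L)) {
        a <- x[segs[i, 1L]:segs[i, 2L]]
        b <- x[segs[i + 1L, 1L]:segs[i + 1L, 2L]]
        sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
          (length(a) + length(b) - 2)
        sp2 <- max(sp2, .Machine$double.eps)
        tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
        p <- 2 * stats::pt(-abs(tt), df = length(a) + length(b) - 2)
        ok <- p < p_split && abs(mean(a) - mean(b)) >= min_sn * sqrt(sp2)
        if (!ok && p > worst_p) { worst <- i; worst_p <- p }
      }
      if (is.null(worst)) break
      segs[worst, 2L] <- segs[worst + 1L, 2L]
      segs <- segs[-(worst + 1L), , drop = FALSE]
    }

    # boundary refinement: re-scan each breakpoint between adjacent
    # segments for the position maximizing their separation (the
    # greedy joint scan can misplace a boundary by a few windows)
    if (nrow(segs) > 1L) {
      for (pass in 1:5) {
        moved <- FALSE
        for (i in seq_len(nrow(segs) - 1L)) {
          lo <- segs[i, 1L]; hi <- segs[i + 1L, 2L]
          ks <- (lo + min_points):(hi - min_points + 1L)
          if (!length(ks)) next
          tt <- vapply(ks, function(k) {
            a <- x[lo:(k - 1L)]; b <- x[k:hi]
            sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
              (length(a) + length(b) - 2)
            abs(mean(a) - mean(b)) / sqrt(max(sp2, .Machine$double.eps) *
                                            (1 / length(a) + 1 / length(b)))
          }, numeric(1))
          k_best <- ks[which.max(tt)]
          if (k_best != segs[i + 1L, 1L]) {
            segs[i, 2L] <- k_best - 1L
            segs[i + 1L, 1L] <- k_best
            moved <- TRUE
          }
        }
        if (!moved) break
      }
    }

    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = tr$start[segs[, 1L]],
      end = tr$end[segs[, 2L]],
      first = segs[, 1L], last = segs[, 2L],
      n_windows = segs[, 2L] - segs[, 1L] + 1L,
      mean = vapply(seq_len(nrow(segs)), function(i)
        mean(x[segs[i, 1L]:segs[i, 2L]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify segments as amplified, deleted or neutral
#'
#' A segment is called amplified when its window ratios are
#' significantly above zero (one-sided t-test, p < \code{p_call}) and
#' are statistically consistent with at least a one-copy gain: the
#' one-sided test against the amplification threshold \code{t_amp}
#' (log2(3/2) = 0.59) does not reject "mean >= t_amp" at \code{p_call}.
#' Deletions mirror this against \code{t_del} (log2(1/2) = -1).
#' Segments significantly changed but inconsistent with a full
#' one-copy event -- or not significantly changed at all -- are
#' neutral.
#'
#' @param segments output of \code{\link{segment_genome}}.
#' @param track the \code{log_ratio_track} the segments partition.
#' @param t_del,t_amp one-copy deletion/amplification thresholds on the
#'   log2 scale (defaults -1 and 0.59).
#' @param p_call one-sided test level (default 1e-4).
#' @return \code{segments} with added columns \code{p_change} (one-sided
#'   p vs 0 in the direction of the mean), \code{p_threshold} (one-sided
#'   p of the consistency test against the relevant threshold) and
#'   \code{class} ("amplified", "deleted" or "neutral").
#' @export
classify_segments <- function(segments, track, t_del = -1, t_amp = 0.59,
                              p_call = 1e-4) {
  segments$p_change <- NA_real_
  segments$p_threshold <- NA_real_
  segments$class <- "neutral"
  for (i in seq_len(nrow(segments))) {
    tr <- track[track$chrom == segments$chrom[i], , drop = FALSE]
    x <- tr$log2ratio[segments$first[i]:segments$last[i]]
    n <- length(x)
    if (n < 2L) next
    se <- stats::sd(x) / sqrt(n)
    if (se == 0) se <- .Machine$double.eps
    m <- mean(x); df <- n - 1L
    if (m > 0) {
      p0 <- stats::pt(m / se, df, lower.tail = FALSE)
      pthr <- stats::pt((m - t_amp) / se, df)    # reject => below one-copy gain
      segments$p_change[i] <- p0
      segments$p_threshold[i] <- pthr
      if (p0 < p_call && pthr >= p_call) segments$class[i] <- "amplified"
    } else {
      p0 <- stats::pt(m / se, df)
      pthr <- stats::pt((m - t_del) / se, df, lower.tail = FALSE)
      segments$p_change[i] <- p0
      segments$p_threshold[i] <- pthr
      if (p0 < p_call && pthr >= p_call) segments$class[i] <- "deleted"
    }
  }
  segments
}

#' Merge adjacent aberrations and build recurrent regions
#'
#' Within each sample, adjacent segments of the same class are merged.
#' Across samples, recurrent regions are the maximal intervals over
#' which the same set of at least \code{min_samples} samples carries a
#' same-direction aberration (computed by an interval sweep over all
#' aberration breakpoints).
#'
#' @param seglists named list (per sample) of classified segment
#'   data.frames from \code{\link{classify_segments}}.
#' @param min_samples minimum supporting samples (default 2).
#' @return object of class \code{cna_catalog}: list with
#'   \code{per_sample} (merged segment lists) and \code{regions}
#'   (data.frame: chrom, start, end, class, n_support, samples).
#' @export
merge_and_overlap <- function(seglists, min_samples = 2L) {
  merged <- lapply(seglists, function(segs) {
    segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
    keep <- list()
    for (chrom in unique(segs$chrom)) {
      s <- segs[segs$chrom == chrom, , drop = FALSE]
      # merge runs of genomically adjacent segments of the same class
      brk <- c(TRUE, s$class[-1] != s$class[-nrow(s)] |
                 s$start[-1] != s$end[-nrow(s)])
      grp <- cumsum(brk)
      for (j in unique(grp)) {
        rows <- which(grp == j)
        w <- s$n_windows[rows]
        keep[[length(keep) + 1L]] <- data.frame(
          chrom = chrom, start = s$start[rows[1L]],
          end = s$end[rows[length(rows)]],
          n_windows = sum(w),
          mean = sum(s$mean[rows] * w) / sum(w),
          class = s$class[rows[1L]], stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, keep)
    rownames(res) <- NULL
    res
  })

  # interval sweep per chromosome and direction
  regions <- list()
  all_ab <- do.call(rbind, lapply(names(merged), function(s) {
    m <- merged[[s]]
    m <- m[m$class != "neutral", , drop = FALSE]
    if (nrow(m)) cbind(m, sample = s) else NULL
  }))
  if (!is.null(all_ab) && nrow(all_ab)) {
    for (chrom in unique(all_ab$chrom)) {
      for (cls in c("amplified", "deleted")) {
        iv <- all_ab[all_ab$chrom == chrom & all_ab$class == cls, ,
                     drop = FALSE]
        if (!nrow(iv)) next
        bp <- sort(unique(c(iv$start, iv$end)))
        atoms <- data.frame(start = bp[-length(bp)], end = bp[-1L])
        sup <- lapply(seq_len(nrow(atoms)), function(a) {
          sort(unique(iv$sample[iv$start <= atoms$start[a] &
                                  iv$end >= atoms$end[a]]))
        })
        qual <- vapply(sup, length, integer(1)) >= min_samples
        # merge adjacent atoms with identical support
        i <- 1L
        while (i <= nrow(atoms)) {
          if (!qual[i]) { i <- i + 1L; next }
          j <- i
          while (j + 1L <= nrow(atoms) && qual[j + 1L] &&
                 atoms$end[j] == atoms$start[j + 1L] &&
                 identical(sup[[j]], sup[[j + 1L]])) j <- j + 1L
          regions[[length(regions) + 1L]] <- data.frame(
            chrom = chrom, start = atoms$start[i], end = atoms$end[j],
            class = cls, n_support = length(sup[[i]]),
            samples = paste(sup[[i]], collapse = ","),
            stringsAsFactors = FALSE)
          i <- j + 1L
        }
      }
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               class = character(0), n_support = integer(0),
               samples = character(0), stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(per_sample = merged, regions = regions,
                 min_samples = min_samples),
            class = "cna_catalog")
}

#' Assign genes to recurrent CNA regions
#'
#' A gene is assigned to a recurrent region when its interval overlaps
#' it (genes straddling a region boundary are flagged partial).  The
#' gene's copy value in a sample is the log2 ratio of that sample's
#' containing merged segment when that segment is aberrant, and 0 when
#' it is neutral.
#'
#' @param catalog a \code{cna_catalog}.
#' @param genes data.frame: id, chrom, start, end.
#' @return list with \code{table} (data.frame: gene, region fields,
#'   partial) and \code{values} (matrix genes x samples of per-sample
#'   log2 ratios, 0 for neutral).
#' @export
assign_genes_to_cna <- function(catalog, genes) {
  rownames(genes) <- genes$id
  regions <- catalog$regions
  samples <- names(catalog$per_sample)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[r] &
                 genes$start < regions$end[r] &
                 genes$end > regions$start[r], , drop = FALSE]
    if (!nrow(g)) next
    partial <- !(g$start >= regions$start[r] & g$end <= regions$end[r])
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g$id, chrom = regions$chrom[r], region_start = regions$start[r],
      region_end = regions$end[r], class = regions$class[r],
      n_support = regions$n_support[r], partial = partial,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), chrom = character(0),
               region_start = integer(0), region_end = integer(0),
               class = character(0), n_support = integer(0),
               partial = logical(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  gene_ids <- unique(tab$gene)
  vals <- matrix(0, nrow = length(gene_ids), ncol = length(samples),
                 dimnames = list(gene_ids, samples))
  for (s in samples) {
    m <- catalog$per_sample[[s]]
    ab <- m[m$class != "neutral", , drop = FALSE]
    for (k in seq_len(nrow(ab))) {
      gsel <- gene_ids[genes[gene_ids, "chrom"] == ab$chrom[k] &
                         genes[gene_ids, "start"] < ab$end[k] &
                         genes[gene_ids, "end"] > ab$start[k]]
      vals[gsel, s] <- ab$mean[k]
    }
  }
  list(table = tab, values = vals)
}

#' Expected tag spacing at a given sequencing depth
#'
#' @param genome_size genome length in bp.
#' @param n_tags aligned tag count.
#' @return expected bp between consecutive tags (genome_size / n_tags).
#' @export
tag_spacing <- function(genome_size, n_tags) {
  stopifnot_scalar_pos(genome_size, "genome_size")
  stopifnot_scalar_pos(n_tags, "n_tags")
  genome_size / n_tags
}
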