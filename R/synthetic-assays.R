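# Planted truth and simulators for the three assays.

#' Default two-group study design
#'
#' Four ER+ and three ER- tumor lines plus one diploid reference line,
#' mirroring the cell-line panel structure the analysis assumes.
#'
#' @return named character vector sample -> group ("ERpos"/"ERneg");
#'   the reference sample is attached as \code{attr(, "reference")}.
#' @export
default_design <- function() {
  d <- c(s1 = "ERpos", s2 = "ERpos", s3 = "ERpos", s4 = "ERpos",
         s5 = "ERneg", s6 = "ERneg", s7 = "ERneg")
  attr(d, "reference") <- "ref"
  d
}

#' Plant ground truth for all three assay layers
#'
#' Draws per-gene expression effects, per-island methylation levels and
#' per-sample copy-number segments with known inter-layer coupling:
#'
#' \itemize{
#'   \item a fraction \code{de_frac} of genes receives a signed log2
#'     group shift with magnitude in \code{effect_range};
#'   \item for a fraction \code{inverse_frac} of the DE genes that have
#'     an island within 5 kb of their TSS, the island's methylation is
#'     shifted in the group OPPOSITE to the expression shift
#'     (hypermethylated where the gene is silenced), between
#'     \code{meth_low} and \code{meth_high};
#'   \item one genomic region is amplified (ratio \code{amp_ratio}) in
#'     every group-1 sample and one deleted (ratio \code{del_ratio}) in
#'     every group-2 sample; genes inside gain a dosage expression
#'     shift of \code{dosage * log2(ratio)}; each sample also gets
#'     \code{n_private_cna} private aberrations.
#' }
#'
#' @param genome a \code{synthetic_genome}.
#' @param design named group vector (see \code{\link{default_design}}).
#' @param seed integer seed.
#' @param de_frac fraction of genes differentially expressed
#'   (default 0.15, the study-scale DE rate).
#' @param effect_range magnitude range of planted log2 fold changes.
#' @param inverse_frac fraction of island-linked DE genes with
#'   inverse methylation coupling.
#' @param meth_low,meth_high methylation probabilities for the
#'   unmethylated and methylated island states (difference >= 40
#'   percentage points so coupling is detectable).
#' @param background_meth methylation probability of CpGs outside
#'   islands (genomic background is mostly methylated).
#' @param dispersion negative-binomial dispersion of the counts.
#' @param base_mean_log,base_sd_log log-normal parameters of baseline
#'   expression means.
#' @param amp_ratio,del_ratio,cna_span,dosage,n_private_cna copy-number
#'   plant parameters.
#' @return object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(genome, design = default_design(), seed = 1L,
                            de_frac = 0.15, effect_range = c(1, 4),
                            inverse_frac = 0.9,
                            meth_low = 0.10, meth_high = 0.85,
                            background_meth = 0.75,
                            dispersion = 0.05,
                            base_mean_log = log(200), base_sd_log = 1.2,
                            amp_ratio = 2, del_ratio = 0.5,
                            cna_span = 0.1, dosage = 1,
                            n_private_cna = 2L) {
  if (dispersion <= 0) stop("dispersion must be positive")
  lev <- unique(as.character(design))
  stopifnot(length(lev) == 2L)
  with_seed(seed, {
    genes <- genome$genes
    n_g <- nrow(genes)
    samples <- names(design)

    base_expr <- stats::rlnorm(n_g, base_mean_log, base_sd_log)
    names(base_expr) <- genes$id
    de_effects <- stats::setNames(numeric(n_g), genes$id)
    n_de <- round(de_frac * n_g)
    de_idx <- sample(n_g, n_de)
    de_effects[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, effect_range[1], effect_range[2])

    # island methylation: baseline unmethylated; inverse-coupled islands
    # methylated in the group where the linked gene is silenced
    assoc <- map_islands_to_genes(genome$islands, genes,
                                  window = genome$config$tss_window %||% 5000L)
    isl <- genome$islands$id
    meth <- matrix(meth_low, nrow = length(isl), ncol = length(samples),
                   dimnames = list(isl, samples))
    inverse_genes <- character(0)
    linked <- assoc[assoc$gene %in% genes$id[de_idx], ]
    if (nrow(linked)) {
      pick <- unique(linked$gene)
      pick <- resample(pick, round(inverse_frac * length(pick)))
      for (g in pick) {
        is_ids <- linked$island[linked$gene == g]
        silenced <- if (de_effects[g] > 0) lev[2] else lev[1]
        meth[is_ids, design == silenced] <- meth_high
      }
      inverse_genes <- pick
    }

    # copy number: one consistent aberration per group + private ones
    cl <- vapply(genome$chromosomes, nchar, numeric(1))
    pick_region <- function() {
      chrom <- resample(names(cl), 1L)
      w <- round(cna_span * cl[chrom])
      start <- resample(seq(0L, as.integer(cl[chrom] - w)), 1L)
      data.frame(chrom = chrom, start = start, end = start + w,
                 stringsAsFactors = FALSE)
    }
    amp_region <- pick_region()
    del_region <- pick_region()
    # keep the two group-consistent regions disjoint
    while (del_region$chrom == amp_region$chrom &&
           del_region$start < amp_region$end &&
           amp_region$start < del_region$end)
      del_region <- pick_region()

    cn_segments <- stats::setNames(vector("list", length(samples)), samples)
    for (s in samples) {
      segs <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), copy_ratio = numeric(0),
                         stringsAsFactors = FALSE)
      if (design[[s]] == lev[1])
        segs <- rbind(segs, cbind(amp_region, copy_ratio = amp_ratio))
      else
        segs <- rbind(segs, cbind(del_region, copy_ratio = del_ratio))
      for (i in seq_len(n_private_cna)) {
        r <- pick_region()
        ov <- any(r$chrom == segs$chrom & r$start < segs$end &
                    segs$start < r$end)
        if (!ov)
          segs <- rbind(segs, cbind(r, copy_ratio = resample(
            c(amp_ratio, del_ratio), 1L)))
      }
      cn_segments[[s]] <- segs[order(segs$chrom, segs$start), ]
    }

    # dosage coupling: amplification in group 1 raises the group1-minus-
    # group2 contrast; deletion in group 2 raises it too
    in_region <- function(r) genes$chrom == r$chrom &
      genes$start < r$end & genes$end > r$start
    de_effects[in_region(amp_region)] <-
      de_effects[in_region(amp_region)] + dosage * log2(amp_ratio)
    de_effects[in_region(del_region)] <-
      de_effects[in_region(del_region)] - dosage * log2(del_ratio)

    lib <- stats::setNames(stats::runif(length(samples), 0.8, 1.2) * 1e6,
                           samples)

    structure(list(de_effects = de_effects, base_expr = base_expr,
                   island_meth = meth, background_meth = background_meth,
                   cn_segments = cn_segments, library_sizes = lib,
                   dispersion = dispersion,
                   inverse_genes = inverse_genes,
                   amp_region = amp_region, del_region = del_region,
                   group_levels = lev, design = design, seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic truth: %d genes (%d DE), %d islands, %d samples\n",
              length(x$de_effects), sum(x$de_effects != 0),
              nrow(x$island_meth), length(x$design)))
  invisible(x)
}

#' Simulate gene-level mRNA-seq counts
#'
#' Draws negative-binomial counts per gene and sample with mean
#' \eqn{\mu_g \cdot 2^{\pm e_g / 2} \cdot f_s}, where \eqn{e_g} is the
#' planted log2 group shift (split symmetrically between the groups)
#' and \eqn{f_s} the sample's library-size factor.
#'
#' @param genome a \code{synthetic_genome}.
#' @param truth a \code{synthetic_truth}.
#' @param design named group vector; defaults to the truth's design.
#' @param seed integer seed.
#' @return integer count matrix genes x samples with the group labels
#'   attached as \code{attr(, "groups")}.
#' @export
simulate_mrnaseq <- function(genome, truth, design = truth$design, seed = 1L) {
  if (truth$dispersion <= 0) stop("dispersion must be positive")
  with_seed(seed, {
    samples <- names(design)
    lev <- truth$group_levels
    eff <- truth$de_effects
    libf <- truth$library_sizes[samples] / mean(truth$library_sizes)
    counts <- sapply(samples, function(s) {
      sign <- if (design[[s]] == lev[1]) +1 else -1
      mu <- truth$base_expr * 2^(sign * eff / 2) * libf[[s]]
      stats::rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion)
    })
    rownames(counts) <- names(truth$de_effects)
    storage.mode(counts) <- "integer"
    attr(counts, "groups") <- stats::setNames(as.character(design), samples)
    counts
  })
}

#' Simulate reduced-representation bisulfite reads for one sample
#'
#' Reads are drawn only from size-selected MspI fragments (the in-silico
#' digest of the genome).  Each fragment yields reads anchored at its
#' two MspI ends, of length \code{min(read_len, fragment length)}.  A
#' CpG cytosine is retained as C with probability equal to the planted
#' methylation level of its island (or the genomic background level
#' outside islands); every other cytosine is converted to T with
#' probability \code{conversion}.  Reads from the reverse strand are
#' emitted reverse-complemented, as a sequencer would.
#'
#' @param genome a \code{synthetic_genome}.
#' @param truth a \code{synthetic_truth} (per-island methylation).
#' @param sample sample id (column of \code{truth$island_meth}).
#' @param config list: \code{coverage} (target per-strand-pair coverage,
#'   default 30), \code{read_len} (default 50), \code{size_windows}
#'   (insert-size selection, passed to \code{\link{digest_reference}}),
#'   \code{conversion} (bisulfite conversion efficiency, default 1.0),
#'   \code{error_rate} (flat substitution rate, default 0).
#' @param seed integer seed.
#' @param fastq optional path; when given, reads are written as FASTQ.
#' @return character vector of reads (names = read ids, with the source
#'   fragment recorded in \code{attr(, "origin")}).
#' @export
simulate_rrbs_reads <- function(genome, truth, sample,
                                config = list(), seed = 1L, fastq = NULL) {
  cfg <- utils::modifyList(list(coverage = 30, read_len = 50L,
                                size_windows = NULL, conversion = 1.0,
                                error_rate = 0), config)
  frags <- digest_reference(genome, size_windows = cfg$size_windows,
                            read_len = cfg$read_len)
  tpl <- frags$templates
  if (nrow(tpl) == 0L)
    stop("empty library: no MspI fragments pass size selection")
  if (!sample %in% colnames(truth$island_meth))
    stop("unknown sample: ", sample)

  # methylation level per CpG position, per chromosome
  isl <- genome$islands
  meth_of <- function(chrom, pos) {
    lv <- rep(truth$background_meth, length(pos))
    ii <- isl[isl$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(ii)))
      lv[pos >= ii$start[k] & pos < ii$end[k]] <-
        truth$island_meth[ii$id[k], sample]
    lv
  }

  with_seed(seed, {
    per_tpl <- vector("list", nrow(tpl))
    for (ti in seq_len(nrow(tpl))) {
      n_reads <- stats::rpois(1L, cfg$coverage / 2)
      if (n_reads == 0L) next
      chars <- strsplit(tpl$seq[ti], "")[[1]]
      chrom <- tpl$chrom[ti]
      chrom_seq <- genome$chromosomes[[chrom]]
      L <- length(chars)
      gpos <- tpl$start[ti] + seq_len(L) - 1L   # 0-based genomic positions
      nxt <- substring(chrom_seq, gpos + 2L, gpos + 2L)
      prv <- substring(chrom_seq, gpos, gpos)

      if (tpl$strand[ti] == "+") {
        conv_idx <- which(chars == "C")
        cpg <- conv_idx[nxt[conv_idx] == "G"]
        cpg_cpos <- gpos[cpg]             # the C of the CpG
        to <- "T"
      } else {
        conv_idx <- which(chars == "G")
        cpg <- conv_idx[prv[conv_idx] == "C"]
        cpg_cpos <- gpos[cpg] - 1L        # paired plus-strand C
        to <- "A"
      }
      noncpg <- setdiff(conv_idx, cpg)
      mlv <- meth_of(chrom, cpg_cpos)

      rds <- vapply(seq_len(n_reads), function(r) {
        b <- chars
        if (length(cpg))
          b[cpg][stats::runif(length(cpg)) >= mlv] <- to
        if (length(noncpg))
          b[noncpg][stats::runif(length(noncpg)) < cfg$conversion] <- to
        if (cfg$error_rate > 0) {
          hit <- which(stats::runif(L) < cfg$error_rate)
          if (length(hit))
            b[hit] <- resample(c("A", "C", "G", "T"), length(hit),
                               replace = TRUE)
        }
        paste(b, collapse = "")
      }, character(1))
      if (tpl$strand[ti] == "-") rds <- revcomp(rds)
      per_tpl[[ti]] <- rds
    }
    reads <- unlist(per_tpl)
    origin <- rep(tpl$template_id, times = lengths(per_tpl))
    names(reads) <- sprintf("%s_read_%06d", sample, seq_along(reads))
    attr(reads, "origin") <- origin
    if (!is.null(fastq)) write_fastq(reads, fastq)
    reads
  })
}

#' Simulate DNA-seq tag positions for one sample
#'
#' Tag start positions are sampled with density proportional to the
#' local planted copy ratio (1 outside any planted segment), then
#' uniformly within each constant-ratio interval.
#'
#' @param genome a \code{synthetic_genome}.
#' @param truth a \code{synthetic_truth}; the sample's
#'   \code{cn_segments} define the local ratios.  A sample absent from
#'   the truth (e.g. the diploid reference) gets ratio 1 everywhere.
#' @param sample sample id.
#' @param depth total number of tags.
#' @param seed integer seed.
#' @return data.frame(chrom, pos) with positions sorted within
#'   chromosome (0-based).
#' @export
simulate_dnaseq <- function(genome, truth, sample, depth = 1e5, seed = 1L) {
  stopifnot_scalar_pos(depth, "depth")
  segs <- truth$cn_segments[[sample]]
  with_seed(seed, {
    # partition each chromosome into constant-ratio intervals
    parts <- list()
    for (chrom in names(genome$chromosomes)) {
      len <- nchar(genome$chromosomes[[chrom]])
      ss <- if (!is.null(segs)) segs[segs$chrom == chrom, , drop = FALSE]
            else NULL
      bp <- sort(unique(c(0L, len, if (!is.null(ss)) c(ss$start, ss$end))))
      for (i in seq_len(length(bp) - 1L)) {
        ratio <- 1
        if (!is.null(ss) && nrow(ss)) {
          hit <- ss$start <= bp[i] & ss$end >= bp[i + 1L]
          if (any(hit)) ratio <- ss$copy_ratio[which(hit)[1L]]
        }
        parts[[length(parts) + 1L]] <-
          list(chrom = chrom, start = bp[i], end = bp[i + 1L], ratio = ratio)
      }
    }
    w <- vapply(parts, function(p) (p$end - p$start) * p$ratio, numeric(1))
    if (any(w < 0)) stop("copy_ratio must be positive")
    n_per <- stats::rmultinom(1L, size = depth, prob = w / sum(w))[, 1L]
    out <- do.call(rbind, lapply(seq_along(parts), function(i) {
      if (n_per[i] == 0L) return(NULL)
      p <- parts[[i]]
      data.frame(chrom = p$chrom,
                 pos = p$start +
                   sort(resample(seq_len(p$end - p$start), n_per[i],
                                 replace = TRUE)) - 1L,
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
  })
}
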