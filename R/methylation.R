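# RRBS methylation calling: in-silico MspI digestion, 3-letter
# alignment against fragment-anchored templates, C/(C+T) site calls,
# island summaries and differential methylation.

default_size_windows <- function() list(c(30L, 55L), c(55L, 105L))

#' In-silico MspI digestion of a genome
#'
#' Cuts every chromosome at C^CGG (after the first C of each CCGG
#' occurrence) and collects the internal fragments between successive
#' cut sites, so every fragment is bounded by MspI sites.  Fragments
#' are size-selected against the configured insert windows; for each
#' retained fragment two read templates of at most \code{read_len}
#' nucleotides are anchored at the fragment's MspI ends, one per
#' strand.  Reverse-strand templates are stored as plus-strand
#' sequence; their converted form replaces G by A (the 3-letter image
#' of C-to-T conversion on the minus strand).
#'
#' @param genome a \code{synthetic_genome}, a named character vector of
#'   chromosome sequences, or a path to a FASTA file.
#' @param size_windows list of insert-size intervals (bp, inclusive)
#'   retained by the gel cut; default 30-55 and 55-105 bp.
#' @param read_len template (read) length cap, default 50.
#' @return object of class \code{mspi_reference}: list with
#'   \code{fragments} (all internal fragments, with \code{retained}
#'   flag) and \code{templates} (per retained fragment and strand:
#'   template_id, chrom, start, end, strand, seq, conv, key).
#'   Coordinates are 0-based half-open.
#' @export
digest_reference <- function(genome, size_windows = NULL, read_len = 50L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  chroms <- if (inherits(genome, "synthetic_genome")) genome$chromosomes
            else genome
  if (is.null(size_windows)) size_windows <- default_size_windows()

  frag_list <- list()
  for (chrom in names(chroms)) {
    seq <- chroms[[chrom]]
    hits <- gregexpr("CCGG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    cuts <- as.integer(hits)          # 1-based CCGG starts; cut after C
    # 0-based cut coordinate = (start - 1) + 1 = start
    bounds <- cuts
    if (length(bounds) < 2L) next
    frag_list[[chrom]] <- data.frame(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      stringsAsFactors = FALSE)
  }
  if (!length(frag_list)) {
    warning("no CCGG site found: empty MspI reference")
    frags <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), length = integer(0),
                        retained = logical(0))
    return(structure(list(fragments = frags,
                          templates = empty_templates()),
                     class = "mspi_reference"))
  }
  frags <- do.call(rbind, frag_list)
  frags$length <- frags$end - frags$start
  frags$retained <- Reduce(`|`, lapply(size_windows, function(w)
    frags$length >= w[1] & frags$length <= w[2]))
  frags$frag_id <- sprintf("frag_%05d", seq_len(nrow(frags)))
  rownames(frags) <- NULL

  keep <- frags[frags$retained, , drop = FALSE]
  tpl <- if (nrow(keep)) build_templates(keep, chroms, read_len)
         else empty_templates()
  structure(list(fragments = frags, templates = tpl,
                 size_windows = size_windows, read_len = read_len),
            class = "mspi_reference")
}

empty_templates <- function() {
  data.frame(template_id = character(0), frag_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), seq = character(0),
             conv = character(0), key = character(0),
             stringsAsFactors = FALSE)
}

build_templates <- function(keep, chroms, read_len) {
  rows <- vector("list", 2L * nrow(keep))
  for (i in seq_len(nrow(keep))) {
    chrom <- keep$chrom[i]
    L <- min(read_len, keep$length[i])
    fs <- keep$start[i]; fe <- keep$end[i]
    # forward template: fragment 5' end on the plus strand
    ws <- fs; we <- fs + L
    seq_f <- substr(chroms[[chrom]], ws + 1L, we)
    # reverse template: fragment 5' end on the minus strand
    rs <- fe - L; re <- fe
    seq_r <- substr(chroms[[chrom]], rs + 1L, re)
    rows[[2L * i - 1L]] <- data.frame(
      template_id = paste0(keep$frag_id[i], "_f"),
      frag_id = keep$frag_id[i], chrom = chrom, start = ws, end = we,
      strand = "+", seq = seq_f,
      conv = gsub("C", "T", seq_f, fixed = TRUE),
      stringsAsFactors = FALSE)
    rows[[2L * i]] <- data.frame(
      template_id = paste0(keep$frag_id[i], "_r"),
      frag_id = keep$frag_id[i], chrom = chrom, start = rs, end = re,
      strand = "-", seq = seq_r,
      conv = gsub("G", "A", seq_r, fixed = TRUE),
      stringsAsFactors = FALSE)
  }
  tpl <- do.call(rbind, rows)
  # alignment key in read space: for reverse templates the sequenced
  # read is the reverse complement, so revcomp(G->A image) = C->T image
  # of the minus-strand read
  tpl$key <- tpl$conv
  rev <- tpl$strand == "-"
  if (any(rev)) tpl$key[rev] <- revcomp(tpl$conv[rev])
  rownames(tpl) <- NULL
  tpl
}

#' Build the converted-reference lookup index
#'
#' Indexes the 3-letter (bisulfite-converted) form of every template
#' for exact and near-exact lookup.  Templates whose converted
#' sequences collide (identical after conversion) are flagged as
#' multi-mapping targets: reads matching them cannot be placed
#' uniquely.
#'
#' @param frags an \code{mspi_reference} from
#'   \code{\link{digest_reference}}.
#' @return object of class \code{converted_index}.
#' @export
build_converted_reference <- function(frags) {
  tpl <- frags$templates
  amb <- duplicated(tpl$key) | duplicated(tpl$key, fromLast = TRUE)
  tpl$ambiguous <- amb
  exact <- split(seq_len(nrow(tpl)), tpl$key)
  # seed blocks for <=2-mismatch lookup (any intact 16-mer block finds
  # the candidate)
  seed_maps <- lapply(1:3, function(b) {
    lo <- (b - 1L) * 16L + 1L
    ok <- which(nchar(tpl$key) >= lo + 3L)   # need at least a 4-mer
    sds <- substr(tpl$key[ok], lo, lo + 15L)
    split(ok, sds)
  })
  structure(list(templates = tpl, exact = exact, seed_maps = seed_maps,
                 reference = frags),
            class = "converted_index")
}

#' Align bisulfite reads against the converted fragment reference
#'
#' Each read is converted to 3-letter space (C replaced by T) and
#' matched against the converted templates, allowing at most
#' \code{max_mismatch} mismatches.  Reads compatible with more than one
#' fragment -- or matching a template whose converted sequence is not
#' unique -- are discarded as multi-mapping; reads longer than their
#' template are trimmed with a warning.  The placement keeps the
#' original (4-letter) read bases for methylation calling.
#'
#' @param reads named character vector of reads, or a FASTQ path.
#' @param index a \code{converted_index}.
#' @param max_mismatch maximum mismatches in converted space (default 2).
#' @return list with \code{placements} (data.frame: read_id,
#'   template_id, mismatches, read_seq) and \code{audit} (named counts:
#'   input, aligned, multimapped, unaligned, trimmed).
#' @export
align_bisulfite_reads <- function(reads, index, max_mismatch = 2L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  tpl <- index$templates
  n <- length(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_len(n))
  conv <- gsub("C", "T", reads, fixed = TRUE)

  n_trimmed <- 0L
  res_tpl <- character(n); res_mm <- integer(n)
  status <- character(n)
  for (i in seq_len(n)) {
    rc <- conv[[i]]
    cand <- index$exact[[rc]]
    if (is.null(cand)) {
      cand <- integer(0)
      for (b in 1:3) {
        lo <- (b - 1L) * 16L + 1L
        if (nchar(rc) < lo + 3L) break
        sd <- substr(rc, lo, lo + 15L)
        cand <- c(cand, index$seed_maps[[b]][[sd]])
      }
      cand <- unique(cand)
    }
    hits <- integer(0); mms <- integer(0); trimmed <- FALSE
    for (j in cand) {
      key <- tpl$key[j]
      rr <- rc
      if (nchar(rr) > nchar(key)) { rr <- substr(rr, 1L, nchar(key)); trimmed <- TRUE }
      if (nchar(rr) < nchar(key)) next     # reads are full templates here
      mm <- hamming(rr, key)
      if (mm <= max_mismatch) { hits <- c(hits, j); mms <- c(mms, mm) }
    }
    if (length(hits) == 0L) { status[i] <- "unaligned"; next }
    # distinct fragments (not just the two strands) make a read ambiguous
    if (length(unique(tpl$frag_id[hits])) > 1L || any(tpl$ambiguous[hits])) {
      status[i] <- "multimapped"; next
    }
    best <- hits[which.min(mms)]
    status[i] <- "aligned"
    res_tpl[i] <- tpl$template_id[best]
    res_mm[i] <- min(mms)
    if (trimmed) n_trimmed <- n_trimmed + 1L
  }
  if (n_trimmed > 0L)
    warning(sprintf("%d read(s) longer than their template were trimmed",
                    n_trimmed))
  ok <- status == "aligned"
  list(placements = data.frame(read_id = names(reads)[ok],
                               template_id = res_tpl[ok],
                               mismatches = res_mm[ok],
                               read_seq = unname(reads[ok]),
                               stringsAsFactors = FALSE),
       audit = c(input = n, aligned = sum(ok),
                 multimapped = sum(status == "multimapped"),
                 unaligned = sum(status == "unaligned"),
                 trimmed = n_trimmed))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Call per-CpG methylation from aligned reads
#'
#' At each genomic CpG cytosine covered by a placement, the original
#' read base is compared to the original fragment base: C counts as
#' methylated and T as unmethylated on forward-strand fragments (G and
#' A respectively on reverse-strand fragments, whose reads are stored
#' as sequenced and re-oriented here).  Any other base is ignored and
#' audited.  The methylation ratio is C/(C+T).
#'
#' @param placements result of \code{\link{align_bisulfite_reads}} (or
#'   its \code{placements} component).
#' @param frags the \code{mspi_reference} (or \code{converted_index})
#'   the reads were aligned to.
#' @param genome the genome the reference was digested from (needed to
#'   locate CpG context at template edges): a \code{synthetic_genome}
#'   or named character vector.
#' @return data.frame of class \code{cpg_site_calls}: chrom, pos
#'   (0-based plus-strand position of the cytosine's C; for
#'   minus-strand cytosines the position of the paired plus-strand G),
#'   strand, count_C, count_T, coverage, ratio; audit of non-C/T bases
#'   in \code{attr(, "other_base_audit")}.
#' @export
call_methylation <- function(placements, frags, genome) {
  if (is.list(placements) && !is.data.frame(placements) &&
      !is.null(placements$placements))
    placements <- placements$placements
  if (inherits(frags, "converted_index")) frags <- frags$reference
  chroms <- if (inherits(genome, "synthetic_genome")) genome$chromosomes
            else genome
  tpl <- frags$templates
  rownames(tpl) <- tpl$template_id

  other <- 0L
  acc <- list()
  for (tid in unique(placements$template_id)) {
    t <- tpl[tid, ]
    reads <- placements$read_seq[placements$template_id == tid]
    L <- t$end - t$start
    gpos <- t$start + seq_len(L) - 1L
    chrom_seq <- chroms[[t$chrom]]
    bases <- substring(chrom_seq, gpos + 1L, gpos + 1L)
    nxt <- substring(chrom_seq, gpos + 2L, gpos + 2L)
    prv <- substring(chrom_seq, gpos, gpos)
    if (t$strand == "+") {
      off <- which(bases == "C" & nxt == "G")
      meth_base <- "C"; unmeth_base <- "T"
      oriented <- reads
    } else {
      off <- which(bases == "G" & prv == "C")
      meth_base <- "G"; unmeth_base <- "A"
      oriented <- revcomp(reads)
    }
    if (!length(off)) next
    for (o in off) {
      b <- substr(oriented, o, o)
      nC <- sum(b == meth_base); nT <- sum(b == unmeth_base)
      other <- other + sum(b != meth_base & b != unmeth_base & b != "")
      if (nC + nT == 0L) next
      key <- paste(t$chrom, gpos[o], t$strand, sep = ":")
      prev <- acc[[key]] %||% c(0L, 0L)
      acc[[key]] <- prev + c(nC, nT)
    }
  }
  if (!length(acc)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count_C = integer(0),
                      count_T = integer(0), coverage = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(names(acc), ":", fixed = TRUE)
    m <- do.call(rbind, acc)
    out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      strand = vapply(parts, `[`, "", 3L),
                      count_C = m[, 1L], count_T = m[, 2L],
                      stringsAsFactors = FALSE)
    out$coverage <- out$count_C + out$count_T
    out$ratio <- out$count_C / out$coverage
    out <- out[order(out$chrom, out$pos, out$strand), ]
    rownames(out) <- NULL
  }
  attr(out, "other_base_audit") <- other
  class(out) <- c("cpg_site_calls", class(out))
  out
}

#' Summarize CpG site calls into an island-by-sample percent matrix
#'
#' An island's percent methylation in a sample is 100 times the
#' unweighted mean ratio over its CpG sites with coverage at least
#' \code{min_cov}.  Islands with no qualifying site in one or more
#' samples are dropped from the cross-sample matrix (every retained
#' island is assayed in every sample).  With \code{strict = TRUE} an
#' island is retained only if every covered site in it reaches
#' \code{min_cov} in every sample.
#'
#' @param sites named list (per sample) of \code{cpg_site_calls}, or a
#'   single \code{cpg_site_calls} for a one-sample summary.
#' @param islands data.frame with columns id, chrom, start, end.
#' @param min_cov site coverage threshold (default 10).
#' @param strict require every covered site to qualify (default FALSE).
#' @return list with \code{percent} (matrix islands x samples),
#'   \code{n_sites} and \code{mean_cov} (same shape) and \code{audit}
#'   (islands in, retained, retained fraction).
#' @export
summarize_islands <- function(sites, islands, min_cov = 10L,
                              strict = FALSE) {
  if (inherits(sites, "cpg_site_calls")) sites <- list(sample = sites)
  samples <- names(sites)
  n_isl <- nrow(islands)
  pct <- nsit <- mcov <- matrix(NA_real_, n_isl, length(samples),
                                dimnames = list(islands$id, samples))
  strict_fail <- matrix(FALSE, n_isl, length(samples),
                        dimnames = list(islands$id, samples))
  for (s in samples) {
    sc <- sites[[s]]
    for (i in seq_len(n_isl)) {
      sel <- sc$chrom == islands$chrom[i] & sc$pos >= islands$start[i] &
        sc$pos < islands$end[i]
      sub <- sc[sel, , drop = FALSE]
      strict_fail[i, s] <- any(sub$coverage > 0 & sub$coverage < min_cov)
      q <- sub[sub$coverage >= min_cov, , drop = FALSE]
      if (nrow(q)) {
        pct[i, s] <- 100 * mean(q$ratio)
        nsit[i, s] <- nrow(q)
        mcov[i, s] <- mean(q$coverage)
      }
    }
  }
  keep <- rowSums(is.na(pct)) == 0L
  if (strict) keep <- keep & rowSums(strict_fail) == 0L
  list(percent = pct[keep, , drop = FALSE],
       n_sites = nsit[keep, , drop = FALSE],
       mean_cov = mcov[keep, , drop = FALSE],
       audit = c(islands_in = n_isl, retained = sum(keep),
                 retained_fraction = if (n_isl) sum(keep) / n_isl else NA))
}

#' Differential methylation of CpG islands
#'
#' Applies the same empirical-Bayes moderated t machinery used for
#' expression to the island percent-methylation matrix and reports the
#' group mean difference in percentage points.
#'
#' @param percent matrix islands x samples of percent methylation
#'   (0-100), e.g. the \code{percent} element of
#'   \code{\link{summarize_islands}}.
#' @param groups two-level label per sample.
#' @param levels optional explicit group ordering (difference is
#'   \code{levels[1] - levels[2]}).
#' @param p_cut significance cut recorded in the \code{significant}
#'   column (default 0.05).
#' @return data.frame: island, mean_diff, t, p, q, significant.
#' @export
differential_methylation <- function(percent, groups, levels = NULL,
                                     p_cut = 0.05) {
  de <- moderated_t_test(percent, groups, levels = levels)
  out <- data.frame(island = de$gene, mean_diff = de$log2fc,
                    t = de$t, p = de$p, q = estimate_qvalues(de$p),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < p_cut
  attr(out, "d0") <- attr(de, "d0")
  attr(out, "s02") <- attr(de, "s02")
  out
}

#' Associate CpG islands with genes by TSS proximity
#'
#' An island is associated with every gene whose transcription start
#' site (the 5' end of its longest transcript) lies within
#' \code{window} bp of the island start.  Distances are reported
#' unsigned (|island start - TSS|); the signed offset (island start
#' minus TSS) is kept for reporting.  One island may map to several
#' genes and vice versa.
#'
#' @param islands data.frame: id, chrom, start (0-based).
#' @param genes data.frame: id, chrom, tss, strand.
#' @param window association window in bp (default 5000).
#' @return data.frame: island, gene, distance, signed_distance.
#' @export
map_islands_to_genes <- function(islands, genes, window = 5000L) {
  out <- list()
  for (i in seq_len(nrow(islands))) {
    g <- genes[genes$chrom == islands$chrom[i], , drop = FALSE]
    d <- islands$start[i] - g$tss
    hit <- abs(d) <= window
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        island = islands$id[i], gene = g$id[hit],
        distance = abs(d[hit]), signed_distance = d[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(island = character(0), gene = character(0),
                      distance = integer(0), signed_distance = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
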