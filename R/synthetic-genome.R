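# Synthetic toy genome with CpG islands bounded by MspI sites.

#' Default parameters for the toy genome
#'
#' @return named list of generator parameters: chromosome lengths,
#'   numbers of genes and islands, the fraction of islands placed within
#'   5 kb of a gene TSS, per-island MspI fragment counts and lengths,
#'   and the CpG spacing inside islands.
#' @export
genome_config <- function(chr_lengths = c(chr1 = 1e6),
                          n_genes = 50L,
                          n_islands = 30L,
                          islands_near_tss_frac = 0.8,
                          fragments_per_island = c(3L, 6L),
                          fragment_length = c(36L, 100L),
                          cpg_spacing = 8L,
                          tss_window = 5000L) {
  list(chr_lengths = chr_lengths, n_genes = as.integer(n_genes),
       n_islands = as.integer(n_islands),
       islands_near_tss_frac = islands_near_tss_frac,
       fragments_per_island = as.integer(fragments_per_island),
       fragment_length = as.integer(fragment_length),
       cpg_spacing = as.integer(cpg_spacing),
       tss_window = as.integer(tss_window))
}

# Random inner sequence for one MspI fragment: CpG-dense, sanitized so
# it introduces no internal CCGG cut site.
random_island_inner <- function(len, cpg_spacing) {
  if (len <= 0) return("")
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  at <- seq(1L, len - 1L, by = cpg_spacing)
  for (p in at) { base[p] <- "C"; base[p + 1L] <- "G" }
  s <- paste(base, collapse = "")
  while (grepl("CCGG", s, fixed = TRUE))
    s <- sub("CCGG", "CAGG", s, fixed = TRUE)
  s
}

random_background <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a toy genome with annotated genes and CpG islands
#'
#' Builds random chromosome sequence into which CpG islands are
#' spliced.  Each island is a run of MspI fragments: CCGG cut sites are
#' planted at the island ends and between fragments, and the sequence
#' between sites is CpG-dense, so every island is bounded by (and
#' overlaps) MspI restriction sites and carries many CG dinucleotides.
#' A configurable fraction of islands is placed within
#' \code{tss_window} (5 kb) of a gene's transcription start site, with
#' island-to-TSS offsets drawn from an exponential law with a few
#' hundred bp median, emulating promoter-proximal islands.
#'
#' @param config list from \code{\link{genome_config}}.
#' @param seed integer seed; the result is a pure function of
#'   \code{(config, seed)}.
#' @param dir optional directory; when given, the genome FASTA and
#'   gene/island BED annotations are written there.
#' @return object of class \code{synthetic_genome}: list with
#'   \code{chromosomes} (named character vector of sequences),
#'   \code{genes} (data.frame: id, chrom, tss, strand, length, start,
#'   end; 0-based half-open), \code{islands} (data.frame: id, chrom,
#'   start, end) and \code{cpg_positions} (list of 0-based plus-strand
#'   C positions per island).
#' @export
generate_genome <- function(config = genome_config(), seed = 1L, dir = NULL) {
  with_seed(seed, {
    cl <- config$chr_lengths
    if (is.null(names(cl))) names(cl) <- paste0("chr", seq_along(cl))
    n_isl <- config$n_islands
    n_gen <- config$n_genes

    # build island blocks first so required span is known
    isl_chrom <- sort(sample(rep_len(seq_along(cl), n_isl)))
    blocks <- vapply(seq_len(n_isl), function(i) {
      nf <- resample(seq(config$fragments_per_island[1],
                         config$fragments_per_island[2]), 1L)
      lens <- resample(seq(config$fragment_length[1],
                           config$fragment_length[2]), nf, replace = TRUE)
      inner <- vapply(lens - 4L, random_island_inner,
                      character(1), cpg_spacing = config$cpg_spacing)
      paste0("CCGG", paste0(inner, "CCGG", collapse = ""))
    }, character(1))

    gap <- 200L
    chroms <- character(length(cl)); names(chroms) <- names(cl)
    islands <- data.frame(id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
    for (ci in seq_along(cl)) {
      idx <- which(isl_chrom == ci)
      need <- sum(nchar(blocks[idx])) + (length(idx) + 1L) * gap
      if (need > cl[ci])
        stop(sprintf(
          "island density incompatible with chromosome length: %s needs %d bp of %d",
          names(cl)[ci], need, cl[ci]))
      # random non-overlapping placement: distribute the slack
      slack <- cl[ci] - sum(nchar(blocks[idx])) - (length(idx) + 1L) * gap
      cuts <- if (length(idx)) sort(sample.int(slack + 1L, length(idx) + 1L,
                                               replace = TRUE) - 1L)
              else integer(0)
      pieces <- character(0); pos <- 0L
      if (length(idx)) {
        extra <- diff(c(0L, cuts))[seq_along(idx)]
        for (k in seq_along(idx)) {
          pre <- gap + extra[k]
          pieces <- c(pieces, random_background(pre))
          pos <- pos + pre
          islands <- rbind(islands, data.frame(
            id = sprintf("cgi_%03d", idx[k]), chrom = names(cl)[ci],
            start = pos, end = pos + nchar(blocks[idx[k]]),
            stringsAsFactors = FALSE))
          pieces <- c(pieces, blocks[idx[k]])
          pos <- pos + nchar(blocks[idx[k]])
        }
      }
      pieces <- c(pieces, random_background(cl[ci] - pos))
      chroms[ci] <- paste(pieces, collapse = "")
    }

    # genes: a fraction anchored near island starts, the rest random
    n_near <- min(round(config$islands_near_tss_frac * n_isl), n_gen, n_isl)
    near_isl <- if (n_near > 0) sample(seq_len(n_isl), n_near) else integer(0)
    genes <- vector("list", n_gen)
    for (g in seq_len(n_gen)) {
      chrom <- NULL
      if (g <= n_near) {
        isl <- islands[near_isl[g], ]
        off <- min(round(stats::rexp(1, rate = 1 / 400)),
                   config$tss_window - 1L)
        tss <- isl$start + as.integer(off)
        chrom <- isl$chrom
      } else {
        chrom <- names(cl)[sample(seq_along(cl), 1L)]
        tss <- sample.int(cl[chrom] - 1L, 1L)
      }
      strand <- sample(c("+", "-"), 1L)
      len <- resample(1000:10000, 1L)
      start <- if (strand == "+") tss else max(0L, tss - len)
      end <- if (strand == "+") min(cl[chrom], tss + len) else tss
      genes[[g]] <- data.frame(id = sprintf("gene_%03d", g), chrom = chrom,
                               tss = as.integer(tss), strand = strand,
                               length = as.integer(len),
                               start = as.integer(start), end = as.integer(end),
                               stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- genes$id
    islands <- islands[order(islands$chrom, islands$start), ]
    rownames(islands) <- islands$id

    cpg <- lapply(seq_len(nrow(islands)), function(i) {
      s <- substr(chroms[islands$chrom[i]], islands$start[i] + 1L,
                  islands$end[i])
      islands$start[i] + gregexpr("CG", s, fixed = TRUE)[[1]] - 1L
    })
    names(cpg) <- islands$id

    out <- structure(list(chromosomes = chroms, genes = genes,
                          islands = islands, cpg_positions = cpg,
                          config = config, seed = seed),
                     class = "synthetic_genome")
    if (!is.null(dir)) write_genome(out, dir)
    out
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d chromosome(s), %s bp total\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  cat(sprintf("  %d genes, %d CpG islands (%d CpG sites)\n",
              nrow(x$genes), nrow(x$islands),
              sum(lengths(x$cpg_positions))))
  invisible(x)
}

#' Write a synthetic genome and its annotations to disk
#'
#' Emits \code{genome.fa} plus BED (0-based half-open) annotations
#' \code{genes.bed} and \code{islands.bed}.
#'
#' @param genome a \code{synthetic_genome}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  g <- genome$genes
  write_tsv(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                       name = g$id, score = 0L, strand = g$strand),
            file.path(dir, "genes.bed"))
  i <- genome$islands
  write_tsv(data.frame(chrom = i$chrom, start = i$start, end = i$end,
                       name = i$id),
            file.path(dir, "islands.bed"))
  invisible(dir)
}
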