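# MspI digestion, 3-letter alignment, site calling, island summaries,
# differential methylation, island-gene mapping.

test_that("MspI digestion cuts after the first C of CCGG", {
  g <- c(chrA = "TTCCGGAAAACCGGTT")
  fr <- digest_reference(g, size_windows = list(c(1L, 1000L)))
  expect_equal(nrow(fr$fragments), 1L)
  expect_equal(fr$fragments$start, 3L)
  expect_equal(fr$fragments$end, 11L)
  expect_equal(fr$fragments$length, 8L)

  expect_warning(fr0 <- digest_reference(c(chrA = "AAAATTTTGGGG")),
                 "no CCGG")
  expect_equal(nrow(fr0$fragments), 0L)

  # a 500 bp fragment is excluded by a 40-220 insert window
  long <- paste0("CCGG", paste(rep("A", 496), collapse = ""), "CCGG")
  frL <- digest_reference(c(chrA = long),
                          size_windows = list(c(40L, 220L)))
  expect_equal(sum(frL$fragments$retained), 0L)
})

test_that("template conversion follows the strand rules and flags collisions", {
  # one internal fragment: CGGACGTC + C (from next CCGG) = CGGACGTCC
  g <- c(chrA = "ACCGGACGTCCGGT")
  fr <- digest_reference(g, size_windows = list(c(1L, 100L)))
  tpl <- fr$templates
  fwd <- tpl[tpl$strand == "+", ]
  rev <- tpl[tpl$strand == "-", ]
  expect_equal(fwd$seq, "CGGACGTC")
  expect_equal(fwd$conv, gsub("C", "T", fwd$seq))     # C -> T
  expect_equal(rev$conv, gsub("G", "A", rev$seq))     # G -> A (plus strand)

  # two fragments identical after conversion are ambiguous targets
  g2 <- c(chrA = paste0("ACCGGATATACCGGTTTTTTTTTTCCGGACATACCGGT"))
  fr2 <- digest_reference(g2, size_windows = list(c(5L, 12L)))
  idx2 <- build_converted_reference(fr2)
  amb <- idx2$templates
  same_key <- amb$key[duplicated(amb$key)]
  expect_gt(length(same_key), 0)
  expect_true(all(amb$ambiguous[amb$key %in% same_key]))
})

test_that("alignment places exact reads, drops ambiguous ones, audits all", {
  g <- tiny_genome(seed = 6, len = 2e4, n_islands = 3L, n_genes = 4L)
  fr <- digest_reference(g)
  idx <- build_converted_reference(fr)
  tpl <- idx$templates[!idx$templates$ambiguous, ]
  tpl <- tpl[tpl$strand == "+", ]

  reads <- c(r1 = gsub("C", "T", tpl$seq[1]),      # fully converted read
             r2 = gsub("C", "T", tpl$seq[2]))
  # three mismatches exceed the limit
  bad <- strsplit(reads[[1]], "")[[1]]
  flip <- function(b) c(A = "G", C = "A", G = "T", T = "A")[[b]]
  for (i in c(2L, 5L, 8L)) bad[i] <- flip(bad[i])
  reads <- c(reads, r3 = paste(bad, collapse = ""))

  res <- align_bisulfite_reads(reads, idx)
  expect_setequal(res$placements$read_id, c("r1", "r2"))
  expect_equal(res$placements$template_id[res$placements$read_id == "r1"],
               tpl$template_id[1])
  a <- res$audit
  expect_equal(unname(a["input"]),
               unname(a["aligned"] + a["multimapped"] + a["unaligned"]))
  expect_equal(unname(a["unaligned"]), 1)
})

test_that("site calls count C/(C+T) on the correct strand", {
  # one fragment, forward template CGGACGTC: CpG C at offset 3 (0-based
  # genomic position 5); reverse template has the paired G at offset 4
  g <- c(chrA = "ACCGGACGTCCGGT")
  fr <- digest_reference(g, size_windows = list(c(1L, 100L)))
  idx <- build_converted_reference(fr)

  meth <- "CGGACGTC"                     # methylated CpG kept as C
  unmeth <- "CGGATGTC"                   # converted CpG reads T
  reads <- stats::setNames(
    c(rep(gsub("C", "T", meth), 0) , rep(meth, 7), rep(unmeth, 3)),
    paste0("r", 1:10))
  res <- align_bisulfite_reads(reads, idx)
  calls <- call_methylation(res, fr, g)
  fwd_site <- calls[calls$strand == "+", ]
  # two plus-strand CpGs: the MspI-site CpG at position 2 (always C in
  # these reads) and the internal CpG at position 6 (7 C, 3 T)
  expect_equal(nrow(fwd_site), 2L)
  expect_equal(fwd_site$pos, c(2L, 6L))
  expect_equal(fwd_site$count_C, c(10L, 7L))
  expect_equal(fwd_site$count_T, c(0L, 3L))
  expect_equal(fwd_site$coverage, c(10L, 10L))
  expect_equal(fwd_site$ratio[2], 0.7)

  # reverse-strand fragment: reads are reverse-complemented; G/A at the
  # paired position carry the minus-strand methylation state
  rev_tpl <- fr$templates[fr$templates$strand == "-", ]
  meth_r <- revcomp_chr(rev_tpl$seq)               # G kept (methylated)
  unmeth_r <- revcomp_chr(gsub("G", "A", rev_tpl$seq))
  reads_r <- stats::setNames(c(rep(meth_r, 5), rep(unmeth_r, 5)),
                             paste0("q", 1:10))
  res_r <- align_bisulfite_reads(reads_r, idx)
  calls_r <- call_methylation(res_r, fr, g)
  rev_site <- calls_r[calls_r$strand == "-", ]
  expect_equal(rev_site$ratio, c(0.5, 0.5))
})

test_that("island summaries apply the 10x site filter", {
  islands <- data.frame(id = c("i1", "i2"), chrom = "chrA",
                        start = c(0L, 100L), end = c(50L, 150L))
  # island i1 sites: 80% at 10x, 40% at 15x, 80% at 5x (below filter)
  s1 <- data.frame(chrom = "chrA", pos = c(5L, 10L, 20L, 110L),
                   strand = "+",
                   count_C = c(8L, 6L, 4L, 12L),
                   count_T = c(2L, 9L, 1L, 0L))
  s1$coverage <- s1$count_C + s1$count_T
  s1$ratio <- s1$count_C / s1$coverage
  class(s1) <- c("cpg_site_calls", class(s1))
  s2 <- s1
  s2$coverage[4] <- 5L                   # island i2 has no 10x site in s2
  s2$count_C[4] <- 5L; s2$count_T[4] <- 0L

  sm <- summarize_islands(list(a = s1, b = s2), islands, min_cov = 10)
  # i1 in sample a: the 5x site is excluded -> mean(0.8, 0.4) = 60%
  expect_equal(sm$percent["i1", "a"], 60, tolerance = 1e-10)
  expect_equal(sm$n_sites["i1", "a"], 2)
  expect_false("i2" %in% rownames(sm$percent))
  expect_equal(unname(sm$audit["retained"]), 1)

  # fully methylated island reads 100
  s3 <- s1; s3$count_C <- s1$coverage; s3$count_T <- 0L
  s3$ratio <- 1
  sm3 <- summarize_islands(list(a = s3), islands[islands$id == "i1", ],
                           min_cov = 10)
  expect_equal(unname(sm3$percent["i1", "a"]), 100)
})

test_that("differential methylation separates planted islands and is antisymmetric", {
  groups <- two_group_labels()
  pct <- rbind(sep = c(90, 90, 90, 90, 10, 10, 10),
               null = c(50, 50, 50, 50, 50, 50, 50),
               noisy = c(60, 55, 58, 62, 45, 50, 48))
  pct <- pct + matrix(rnorm(21, sd = 0.5), 3)
  colnames(pct) <- names(groups)
  dm <- differential_methylation(pct, groups)
  expect_equal(dm$mean_diff[1], 80, tolerance = 1)
  expect_lt(dm$p[1], 0.001)
  expect_gt(dm$p[2], 0.05)

  # reversing the contrast orientation negates every mean difference
  dm3 <- differential_methylation(pct, groups,
                                  levels = c("ERneg", "ERpos"))
  expect_equal(dm3$mean_diff, -dm$mean_diff, tolerance = 1e-10)
  expect_equal(dm3$p, dm$p, tolerance = 1e-10)
})

test_that("island-gene association uses the 5 kb window with unsigned distance", {
  genes <- data.frame(id = c("gA", "gB", "gC"), chrom = "chr1",
                      tss = c(1300L, 9000L, 4000L), strand = "+")
  islands <- data.frame(id = c("i1", "i2"), chrom = "chr1",
                        start = c(1000L, 15000L), end = c(1400L, 15400L))
  assoc <- map_islands_to_genes(islands, genes, window = 5000)
  expect_setequal(assoc$gene[assoc$island == "i1"], c("gA", "gC"))
  expect_equal(assoc$distance[assoc$gene == "gA"], 300)
  expect_equal(assoc$signed_distance[assoc$gene == "gA"], -300)
  expect_false("i2" %in% assoc$island | "gB" %in% assoc$gene)
})

test_that("end-to-end: called island means recover the planted truth at 50x", {
  g <- tiny_genome(seed = 10, len = 5e4, n_islands = 8L, n_genes = 10L)
  tr <- synthetic_truth(g, seed = 3)
  set.seed(1)
  tr$island_meth[, "s1"] <- runif(nrow(tr$island_meth), 0.05, 0.95)
  rd <- simulate_rrbs_reads(g, tr, "s1", config = list(coverage = 50),
                            seed = 11)
  fr <- digest_reference(g)
  idx <- build_converted_reference(fr)
  aln <- align_bisulfite_reads(rd, idx)
  # read conservation
  expect_equal(unname(aln$audit["input"]), length(rd))
  calls <- call_methylation(aln, fr, g)
  sm <- summarize_islands(list(s1 = calls), g$islands)
  planted <- 100 * tr$island_meth[rownames(sm$percent), "s1"]
  expect_lte(mean(abs(sm$percent[, "s1"] - planted)), 5)

  # complete conversion implies no non-CpG C calls in forward reads:
  # every called site's position is a genomic CpG
  chrom <- g$chromosomes[["chr1"]]
  fwd <- calls[calls$strand == "+", ]
  expect_true(all(substring(chrom, fwd$pos + 1, fwd$pos + 2) == "CG"))
})
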