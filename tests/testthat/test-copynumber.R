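# Window counts, normalized log2 ratios, segmentation, classification,
# recurrent regions, gene assignment.

test_that("window counting conserves tags and uses half-open windows", {
  set.seed(2)
  tags <- data.frame(chrom = "chr1", pos = sample(0:99999, 1000,
                                                  replace = TRUE))
  wc <- count_windows(tags, c(chr1 = 1e5), 1e4)
  expect_equal(nrow(wc), 10L)
  expect_equal(sum(wc$count), 1000L)

  # a tag exactly on a boundary lands in the right-hand window
  wb <- count_windows(data.frame(chrom = "chr1", pos = 10000L),
                      c(chr1 = 1e5), 1e4)
  expect_equal(wb$count[2], 1L)
  expect_equal(wb$count[1], 0L)

  w0 <- count_windows(data.frame(chrom = character(0), pos = integer(0)),
                      c(chr1 = 1e5), 1e4)
  expect_true(all(w0$count == 0L))
})

test_that("log2 ratios are zero-centred and reveal a planted 2x region", {
  set.seed(4)
  n <- 100L
  ref <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e4,
                    end = (1:n) * 1e4, count = rpois(n, 200))
  tum <- ref
  tum$count <- rpois(n, 200)
  expect_equal(compute_log2_ratios(ref, ref)$log2ratio, rep(0, n))

  tum2 <- ref
  tum2$count <- rpois(n, ifelse(seq_len(n) %in% 41:60, 400, 200))
  tr <- compute_log2_ratios(tum2, ref)
  expect_lt(abs(mean(tr$log2ratio[41:60]) - 1), 0.15)
  expect_lt(abs(stats::median(tr$log2ratio[-(41:60)])), 0.1)

  bad <- ref; bad$count <- 0L
  expect_error(compute_log2_ratios(tum, bad), "zero coverage")
})

test_that("segmentation recovers planted steps and resists noise", {
  # flat noise: a single segment on most seeds
  ones <- vapply(1:20, function(s) {
    nrow(segment_genome(toy_track(n = 100, sd = 0.2, seed = s)))
  }, numeric(1))
  expect_gte(mean(ones == 1), 0.95)

  # planted +1 step over windows 41..70: breakpoints within +-2
  segs <- segment_genome(toy_track(n = 100, step_at = 41:70, step = 1,
                                   sd = 0.2, seed = 3))
  expect_equal(nrow(segs), 3L)
  expect_lte(abs(segs$first[2] - 41), 2)
  expect_lte(abs(segs$last[2] - 70), 2)
  # segments partition the chromosome exactly
  expect_equal(segs$first[1], 1L)
  expect_equal(segs$last[3], 100L)
  expect_true(all(segs$first[-1] == segs$last[-3] + 1L))

  # a step below the signal-to-noise floor is not split
  segs2 <- segment_genome(toy_track(n = 100, step_at = 41:70, step = 0.05,
                                    sd = 0.2, seed = 3))
  expect_equal(nrow(segs2), 1L)
})

test_that("classification respects the one-copy thresholds", {
  mk <- function(mean, n = 40L, sd = 0.2, seed = 1) {
    set.seed(seed)
    tr <- toy_track(n = n, sd = sd, seed = seed)
    tr$log2ratio <- tr$log2ratio - mean(tr$log2ratio) + mean
    segs <- data.frame(chrom = "chr1", start = 0, end = n * 1e4,
                       first = 1L, last = n, n_windows = n,
                       mean = mean(tr$log2ratio))
    classify_segments(segs, tr)
  }
  expect_equal(mk(1.06)$class, "amplified")
  expect_equal(mk(-2.17)$class, "deleted")
  expect_equal(mk(0.3)$class, "neutral")
  expect_equal(mk(0)$class, "neutral")
})

test_that("recurrent regions match a brute-force interval oracle", {
  seg <- function(sample, start, end, class)
    data.frame(chrom = "chr1", start = start, end = end, class = class,
               sample = sample, stringsAsFactors = FALSE)

  # identical deletion in three samples
  mk_seglist <- function(iv, lim = 100L) {
    # wrap intervals into per-sample classified segment tables with
    # neutral filler so each sample partitions [0, lim)
    lapply(split(iv, iv$sample), function(s) {
      data.frame(chrom = "chr1", start = s$start, end = s$end,
                 n_windows = (s$end - s$start), mean = ifelse(
                   s$class == "deleted", -1.5, 1.5),
                 class = s$class, stringsAsFactors = FALSE)
    })
  }
  iv1 <- rbind(seg("a", 10, 40, "deleted"), seg("b", 10, 40, "deleted"),
               seg("c", 10, 40, "deleted"))
  cat1 <- merge_and_overlap(mk_seglist(iv1), min_samples = 2)
  expect_equal(nrow(cat1$regions), 1L)
  expect_equal(cat1$regions$n_support, 3L)
  expect_equal(cat1$regions$start, 10)
  expect_equal(cat1$regions$end, 40)

  # an aberration private to one sample is excluded
  iv2 <- seg("a", 10, 40, "deleted")
  cat2 <- merge_and_overlap(mk_seglist(iv2), min_samples = 2)
  expect_equal(nrow(cat2$regions), 0L)

  # partially overlapping amplifications: the supported interval is the
  # intersection
  iv3 <- rbind(seg("a", 10, 50, "amplified"), seg("b", 30, 80, "amplified"))
  cat3 <- merge_and_overlap(mk_seglist(iv3), min_samples = 2)
  expect_equal(cat3$regions$start, 30)
  expect_equal(cat3$regions$end, 50)

  # randomized cases against the brute-force oracle
  set.seed(14)
  for (rep in 1:5) {
    iv <- do.call(rbind, lapply(letters[1:4], function(s) {
      k <- sample(1:3, 1)
      st <- sort(sample(0:90, k))
      en <- pmin(st + sample(5:30, k, replace = TRUE), 100L)
      ok <- en > st
      if (sum(ok) == 0) return(NULL)
      data.frame(chrom = "chr1", start = st[ok], end = en[ok],
                 class = sample(c("amplified", "deleted"), sum(ok),
                                replace = TRUE),
                 sample = s, stringsAsFactors = FALSE)
    }))
    # drop intra-sample overlaps to keep segments disjoint
    iv <- do.call(rbind, lapply(split(iv, iv$sample), function(s) {
      s <- s[order(s$start), ]
      keep <- rep(TRUE, nrow(s))
      for (i in seq_len(nrow(s))[-1])
        if (s$start[i] < max(s$end[seq_len(i - 1)])) keep[i] <- FALSE
      s[keep, ]
    }))
    got <- merge_and_overlap(mk_seglist(iv), min_samples = 2)$regions
    want <- brute_recurrent(iv, 2L, 100L)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$class, want$start), ]
      got <- got[order(got$class, got$start), ]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$class, want$class)
      expect_equal(got$samples, want$samples)
    }
  }
})

test_that("gene assignment takes the containing segment's ratio, 0 when neutral", {
  seglists <- list(
    t1 = data.frame(chrom = "chr1", start = c(0, 100, 200),
                    end = c(100, 200, 300), n_windows = 10,
                    mean = c(0.01, -2.166, 0.02),
                    class = c("neutral", "deleted", "neutral")),
    t2 = data.frame(chrom = "chr1", start = c(0, 100, 200),
                    end = c(100, 200, 300), n_windows = 10,
                    mean = c(0.0, -1.8, 0.0),
                    class = c("neutral", "deleted", "neutral")))
  cat <- merge_and_overlap(seglists, min_samples = 2)
  genes <- data.frame(id = c("inside", "outside", "straddle"),
                      chrom = "chr1",
                      start = c(120L, 210L, 90L), end = c(180L, 290L, 130L))
  asg <- assign_genes_to_cna(cat, genes)
  expect_equal(asg$values["inside", "t1"], -2.166)
  expect_equal(asg$values["inside", "t2"], -1.8)
  expect_false("outside" %in% rownames(asg$values))
  expect_true("straddle" %in% asg$table$gene)
  expect_true(asg$table$partial[asg$table$gene == "straddle"])
})

test_that("group-level CNA summary is antisymmetric under group swap", {
  vals <- matrix(c(-1.2, -1.2, 0, 0, 0, 0, 0,
                   0, 0, 0, 0, 2.0, 2.0, 1.0,
                   0.7, 0.7, 0.7, 0.7, 0, 0, 0), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:7)))
  groups <- two_group_labels()
  de <- data.frame(gene = c("gA", "gB", "gC"), log2fc = c(-2, 3, 1))
  r1 <- correlate_cna_expression(de, vals, groups)
  r2 <- correlate_cna_expression(de, vals, groups,
                                 levels = c("ERneg", "ERpos"))
  expect_equal(r1$table$cn_diff, -r2$table$cn_diff[
    match(r1$table$gene, r2$table$gene)])
})
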