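# RPM normalization, abundance filters, moderated t, q-values.

test_that("log2 RPM normalization matches direct arithmetic", {
  cm <- matrix(c(0, 999, 10), ncol = 1,
               dimnames = list(c("a", "b", "c"), "s1"))
  lg <- normalize_rpm(cm, totals = 1e6)
  expect_equal(lg["a", 1], 0)                     # 1 RPM at a zero count
  expect_equal(lg["b", 1], log2(1000), tolerance = 1e-12)

  # doubling counts and totals moves values by at most the pseudocount
  # bound |log2((2c+1)/(2c+2)) - log2((c+1)/(c+1))| -> 0 for large c
  c0 <- c(0, 1, 10, 100, 10000)
  m1 <- normalize_rpm(matrix(c0, ncol = 1), totals = 1e6)
  m2 <- normalize_rpm(matrix(2 * c0, ncol = 1), totals = 2e6)
  bound <- abs(log2((2 * c0 + 1) / (2 * (c0 + 1))))
  expect_true(all(abs(m2 - m1) <= bound + 1e-12))
  expect_lt(abs(m2[5] - m1[5]), 1e-4)

  bad <- matrix(0L, 2, 2, dimnames = list(NULL, c("ok", "empty")))
  bad[, 1] <- 5L
  expect_error(normalize_rpm(bad), "empty")
})

test_that("abundance filters apply the group-mean and per-sample rules", {
  groups <- two_group_labels()
  cm <- rbind(keep  = c(60, 60, 60, 60, 0, 0, 0),
              drop1 = c(100, 100, 3, 100, 0, 0, 0),
              zero  = c(0, 0, 0, 0, 0, 0, 0),
              low   = c(10, 10, 10, 10, 10, 10, 10))
  colnames(cm) <- names(groups)
  f <- filter_genes(cm, groups)
  expect_identical(f$kept, "keep")
  expect_equal(unname(f$audit["zero_in_all"]), 1)
  expect_equal(unname(f$audit["input"]),
               unname(f$audit["zero_in_all"] + f$audit["failed_abundance"] +
                        f$audit["retained"]))

  # sample order within the matrix does not change the outcome
  perm <- c(3, 1, 4, 2, 7, 5, 6)
  f2 <- filter_genes(cm[, perm], groups[perm])
  expect_identical(sort(f2$kept), sort(f$kept))
})

test_that("moderated t matches the empirical-Bayes oracle (limma)", {
  skip_if_not_installed("limma")
  groups <- two_group_labels()
  against_limma <- function(m) {
    ours <- moderated_t_test(m, groups)
    design <- stats::model.matrix(
      ~ 0 + factor(groups, levels = c("ERpos", "ERneg")))
    colnames(design) <- c("ERpos", "ERneg")
    fit <- limma::lmFit(m, design)
    fit <- limma::contrasts.fit(fit, limma::makeContrasts(ERpos - ERneg,
                                                          levels = design))
    fit <- limma::eBayes(fit)
    expect_equal(attr(ours, "d0"), fit$df.prior, tolerance = 1e-6)
    expect_equal(attr(ours, "s02"), fit$s2.prior, tolerance = 1e-6)
    expect_equal(ours$t, unname(fit$t[, 1]), tolerance = 1e-8)
    expect_equal(ours$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
    expect_equal(ours$log2fc, unname(fit$coefficients[, 1]),
                 tolerance = 1e-10)
    attr(ours, "d0")
  }
  # wide variance spread: finite prior df (trigamma inversion path)
  set.seed(42)
  m1 <- matrix(rnorm(20 * 7, sd = rep(runif(20, 0.2, 5), 7)), nrow = 20,
               dimnames = list(paste0("g", 1:20), names(groups)))
  m1[1:5, 1:4] <- m1[1:5, 1:4] + 3
  expect_true(is.finite(against_limma(m1)))
  # tight spread: log-variances underdispersed, the d0 = Inf fallback
  m2 <- matrix(rep(rnorm(7), each = 20) + rnorm(140, sd = 0.05) +
                 seq_len(20) / 10, nrow = 20,
               dimnames = list(paste0("g", 1:20), names(groups)))
  expect_true(is.infinite(against_limma(m2)))
})

test_that("moderated t is exact under symmetry and stable under shared variance", {
  groups <- two_group_labels()
  m <- matrix(rnorm(10 * 7), nrow = 10,
              dimnames = list(paste0("g", 1:10), names(groups)))
  m[1, ] <- rep(c(2, 5), length.out = 7)
  m[1, groups == "ERpos"] <- c(1, 2, 3, 4)
  m[1, groups == "ERneg"] <- c(2, 3, 5) - mean(c(2, 3, 5)) + mean(1:4)
  de <- moderated_t_test(m, groups)
  expect_equal(de$t[1], 0)
  expect_equal(de$p[1], 1)

  # identical residual variance in every gene: the prior absorbs all
  # weight (d0 = Inf), posterior variances are constant, and the
  # moderated t is a common rescaling of the ordinary t
  n1 <- 16L; n2 <- 16L
  glab <- c(rep("A", n1), rep("B", n2))
  base <- rnorm(n1 + n2)
  # same within-group variance in every gene, different group shifts
  m2 <- t(sapply(1:12, function(i)
    base + c(rep(i / 4, n1), rep(0, n2))))
  de2 <- moderated_t_test(m2, glab)
  expect_true(is.infinite(attr(de2, "d0")))
  expect_lt(diff(range(de2$s2_post)), 1e-12)
  # with identical residual variances the prior equals the common
  # variance and the moderated t reduces to the ordinary t exactly
  tt <- apply(m2, 1, function(x)
    stats::t.test(x[glab == "A"], x[glab == "B"], var.equal = TRUE)$statistic)
  expect_equal(de2$t, unname(tt), tolerance = 1e-10)

  expect_warning(
    moderated_t_test(matrix(1, 4, 7,
                            dimnames = list(letters[1:4], names(groups))),
                     groups),
    "zero")
})

test_that("moderation beats the ordinary t at small n under planted effects", {
  set.seed(11)
  groups <- two_group_labels()
  n <- 2000
  # moderately expressed genes, where n = 4 vs 3 leaves the per-gene
  # variance estimate noisy and moderation has room to help
  mu <- rlnorm(n, log(15), 1)
  eff <- rep(0, n); eff[1:200] <- 2 * sample(c(-1, 1), 200, replace = TRUE)
  cm <- sapply(seq_along(groups), function(j) {
    s <- if (groups[j] == "ERpos") +1 else -1
    rnbinom(n, mu = mu * 2^(s * eff / 2), size = 1 / 0.05)
  })
  rownames(cm) <- paste0("g", 1:n)
  lg <- normalize_rpm(cm)
  de <- moderated_t_test(lg, groups)
  pt_ord <- apply(lg, 1, function(x)
    stats::t.test(x[groups == "ERpos"], x[groups == "ERneg"],
                  var.equal = TRUE)$p.value)
  pow_mod <- mean(de$p[1:200] < 0.05)
  pow_ord <- mean(pt_ord[1:200] < 0.05)
  expect_gt(pow_mod, pow_ord)
})

test_that("Storey q-values behave at the boundaries and under spiked signal", {
  expect_equal(unclass(estimate_qvalues(rep(1, 100))), rep(1, 100),
               ignore_attr = TRUE)
  expect_error(estimate_qvalues(numeric(0)), "empty")

  set.seed(7)
  p <- c(rep(0.0001, 50), runif(950))
  q <- estimate_qvalues(p)
  expect_true(all(q[1:50] < 0.05))
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))        # step-down monotonicity
  expect_lte(min(q), min(stats::p.adjust(p, "bonferroni")))
})

test_that("DE selection applies the joint p and fold-change cut", {
  de <- data.frame(gene = c("a", "b", "c"),
                   log2fc = c(0.4, -0.7, 3),
                   p = c(0.01, 0.04, 0.06))
  expect_identical(select_de(de), "b")
})

test_that("p-value histogram reports the uniform expectation", {
  set.seed(3)
  h <- report_pvalue_histogram(runif(10000))
  expect_equal(h$expected, 500)
  expect_true(all(abs(h$counts - 500) < 5 * sqrt(500)))
  expect_equal(report_pvalue_histogram(runif(20))$expected, 1)
})
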