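make_cm <- function(counts, conds, assay = "Med1", sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  sm <- data.frame(assay = assay, condition = conds,
                   replicate = stats::ave(seq_along(conds), conds,
                                          FUN = seq_along),
                   stringsAsFactors = FALSE)
  count_matrix(counts, sm, size_factors = sf)
}

test_that("window quantification is half-open around feature centers", {
  feats <- data.frame(chrom = "chr1", center = 1000L, id = "p1")
  mk <- function(pos) fix_track(pos, assay = "Med1", condition = "WT")
  expect_identical(quantify(feats, list(mk(1000L)))$counts[1, 1], 1L)
  # tag exactly at center + w is excluded; center - w included
  expect_identical(quantify(feats, list(mk(1250L)))$counts[1, 1], 0L)
  expect_identical(quantify(feats, list(mk(1249L)))$counts[1, 1], 1L)
  expect_identical(quantify(feats, list(mk(750L)))$counts[1, 1], 1L)
  expect_identical(quantify(feats, list(mk(749L)))$counts[1, 1], 0L)
  # H3K27ac uses the +/-1500 window
  h3 <- fix_track(2400L, assay = "H3K27ac", condition = "WT")
  expect_identical(quantify(feats, list(h3))$counts[1, 1], 1L)
  bad <- fix_track(10L, assay = "unknown_assay")
  expect_error(quantify(feats, list(bad)), "unknown assay")
})

test_that("quantification equals a brute-force membership count and is
           additive over sample merges", {
  set.seed(31)
  pos1 <- sort(sample.int(50000L, 400L, replace = TRUE)) - 1L
  pos2 <- sort(sample.int(50000L, 300L, replace = TRUE)) - 1L
  feats <- data.frame(chrom = "chr1",
                      center = as.integer(seq(2000, 48000, by = 5000)))
  feats$id <- paste0("p", seq_len(nrow(feats)))
  t1 <- fix_track(pos1, assay = "Med1", condition = "WT", replicate = 1L)
  t2 <- fix_track(pos2, assay = "Med1", condition = "WT", replicate = 2L)
  cm <- quantify(feats, list(t1, t2))
  brute <- vapply(feats$center, function(ctr)
    sum(pos1 >= ctr - 250 & pos1 < ctr + 250), 0L)
  expect_identical(unname(cm$counts[, 1]), brute)
  merged <- fix_track(sort(c(pos1, pos2)), assay = "Med1",
                      condition = "WT")
  cmm <- quantify(feats, list(merged))
  expect_identical(unname(cmm$counts[, 1]),
                   unname(cm$counts[, 1] + cm$counts[, 2]))
})

test_that("size factors behave on identical, scaled and degenerate input", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), ncol = 2)
  expect_equal(size_factors(m, "median_of_ratios"), c(1, 1))
  expect_equal(size_factors(m, "total_count"), c(1, 1))

  m2 <- cbind(m[, 1], m[, 1] * 2)
  tc <- size_factors(m2, "total_count")
  expect_equal(tc[2] / tc[1], 2)
  mr <- size_factors(m2, "median_of_ratios")
  expect_equal(mr[2] / mr[1], 2)

  set.seed(9)
  m3 <- matrix(rpois(300, 40), ncol = 3)
  for (meth in c("median_of_ratios", "total_count"))
    expect_equal(exp(mean(log(size_factors(m3, meth)))), 1,
                 tolerance = 1e-12)

  m4 <- matrix(c(0, 5, 3, 0), ncol = 2)  # no feature positive everywhere
  expect_warning(f <- size_factors(m4, "median_of_ratios"), "total_count")
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("NB Wald test returns exact nulls and symmetric contrasts", {
  cm <- make_cm(cbind(c(5, 50, 0), c(7, 46, 0), c(5, 52, 0), c(7, 44, 0)),
                c("A", "A", "B", "B"), sf = rep(1, 4))
  r <- nb_wald(cm, c("A", "B"))
  expect_identical(r$id, rownames(cm$counts))
  # identical group means -> L2FC 0, p 1
  expect_equal(r$log2FoldChange[1:2], c(0, 0))
  expect_equal(r$pvalue[1:2], c(1, 1))
  # all-zero feature
  expect_equal(r$baseMean[3], 0)
  expect_equal(r$log2FoldChange[3], 0)
  expect_equal(r$pvalue[3], 1)
  expect_true(all(r$padj >= r$pvalue - 1e-15))

  set.seed(21)
  cm2 <- make_cm(matrix(rnbinom(400, mu = 60, size = 50), ncol = 4),
                 c("A", "A", "B", "B"), sf = rep(1, 4))
  fwd <- nb_wald(cm2, c("A", "B"))
  rev <- nb_wald(cm2, c("B", "A"))
  expect_equal(rev$log2FoldChange, -fwd$log2FoldChange, tolerance = 1e-12)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-12)
})

test_that("NB Wald reduces to the Poisson Wald test as dispersion -> 0", {
  cm <- make_cm(cbind(c(30, 80), c(34, 76), c(61, 158), c(55, 166)),
                c("A", "A", "B", "B"), sf = rep(1, 4))
  r <- nb_wald(cm, c("A", "B"), dispersion = 1e-12, min_mu = 0.5)
  ma <- rowMeans(cm$counts[, 1:2]); mb <- rowMeans(cm$counts[, 3:4])
  l2fc <- log2((mb + 0.5) / (ma + 0.5))
  se <- sqrt((1 / log(2))^2 * (1 / (2 * ma) + 1 / (2 * mb)))
  p <- 2 * pnorm(-abs(l2fc / se))
  expect_equal(r$log2FoldChange, unname(l2fc), tolerance = 1e-9)
  expect_equal(r$pvalue, unname(p), tolerance = 1e-6)
})

test_that("NB Wald recovers a planted four-fold change and is calibrated
           under the null", {
  set.seed(88)
  n <- 2000
  # null: n = 3 per group, dispersion 0.02
  cnt <- matrix(rnbinom(n * 6, mu = 100, size = 1 / 0.02), n, 6)
  r0 <- nb_wald(make_cm(cnt, rep(c("A", "B"), each = 3), sf = rep(1, 6)),
                c("A", "B"))
  t1 <- mean(r0$pvalue < 0.05)
  expect_gt(t1, 0.03)
  expect_lt(t1, 0.07)

  # power and effect recovery: fold 4, n = 2
  cnt2 <- cbind(matrix(rnbinom(n * 2, mu = 50, size = 1 / 0.02), n, 2),
                matrix(rnbinom(n * 2, mu = 200, size = 1 / 0.02), n, 2))
  r1 <- nb_wald(make_cm(cnt2, rep(c("A", "B"), each = 2), sf = rep(1, 4)),
                c("A", "B"))
  expect_gt(mean(r1$padj < 0.05), 0.9)
  med <- median(r1$log2FoldChange[1:500])
  expect_gt(med, 1.8)
  expect_lt(med, 2.2)
})

test_that("NB Wald agrees in direction and magnitude with an established
           NB GLM implementation on strong effects", {
  skip_if_not_installed("DESeq2")
  set.seed(123)
  n <- 300
  mu <- cbind(matrix(80, n, 3), matrix(80 * rep(c(1, 4), each = n / 2),
                                       n, 3))
  cnt <- matrix(rnbinom(n * 6, mu = mu, size = 1 / 0.02), n, 6)
  rownames(cnt) <- paste0("f", 1:n)
  cm <- make_cm(cnt, rep(c("A", "B"), each = 3))
  r <- nb_wald(cm, c("A", "B"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(condition = factor(rep(c("A", "B"), each = 3))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dr <- as.data.frame(DESeq2::results(dds, contrast = c("condition",
                                                          "B", "A")))
  })
  changed <- (n / 2 + 1):n
  expect_gt(cor(r$log2FoldChange, dr$log2FoldChange), 0.95)
  expect_lt(median(abs(r$log2FoldChange[changed] -
                         dr$log2FoldChange[changed])), 0.2)
  expect_gt(mean(r$padj[changed] < 0.05 & dr$padj[changed] < 0.05), 0.9)
})

test_that("BH step-up matches hand-computed adjustments exactly", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # hand step-up on an unsorted vector: padj_(k) = min_{j>=k} m p_(j) / j
  p <- c(0.30, 0.001, 0.04, 0.70, 0.012)
  o <- order(p)
  m <- length(p)
  stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
  want <- pmin(stepup[match(seq_len(m), o)], 1)
  expect_equal(bh_adjust(p), want)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("BH adjustment preserves the p-value ordering", {
  set.seed(4)
  for (i in 1:10) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})
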