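test_that("DE gene calls partition tested genes with the printed marginals", {
  n <- 2000L
  ids <- sprintf("g%04d", seq_len(n))
  status <- c(rep("induced", 277), rep("repressed", 122),
              rep("unaffected", n - 399))
  l2fc <- ifelse(status == "induced", 2,
                 ifelse(status == "repressed", -2, 0))
  d <- fix_diff(ids, padj = ifelse(status == "unaffected", 0.6, 0.01),
                l2fc = l2fc)
  res <- define_de_genes(d)
  expect_identical(res$counts$induced, 277L)
  expect_identical(res$counts$repressed, 122L)
  expect_identical(res$counts$total, 399L)
  expect_identical(res$counts$induced + res$counts$repressed +
                     res$counts$unaffected, n)
})

test_that("DE gene thresholds are strict on fold and padj", {
  ids <- c("a", "b", "c", "d")
  # a: exactly 1.5-fold -> unaffected; b: huge fold, padj 0.06 ->
  # unaffected; c: just above 1.5; d: repressed
  d <- fix_diff(ids, padj = c(0.01, 0.06, 0.01, 0.01),
                l2fc = c(log2(1.5), log2(10), log2(1.51), -1))
  res <- define_de_genes(d)
  expect_identical(as.character(res$status$de_status),
                   c("unaffected", "unaffected", "induced", "repressed"))
})

test_that("gene sensitivity classes reproduce the mutant overlap counts", {
  n_ind <- 277L
  ids <- sprintf("g%03d", seq_len(n_ind))
  less_e <- c(rep(TRUE, 98), rep(FALSE, n_ind - 98))
  less_r <- c(rep(TRUE, 81), rep(FALSE, 98 - 81), rep(TRUE, 140 - 81),
              rep(FALSE, n_ind - 98 - 59))
  de <- fix_diff(ids, padj = ifelse(less_e, 0.01, 0.5),
                 l2fc = ifelse(less_e, -1, 0))
  dr <- fix_diff(ids, padj = ifelse(less_r, 0.01, 0.5),
                 l2fc = ifelse(less_r, -1, 0))
  res <- classify_gene_sensitivity(de, dr, ids)
  expect_identical(res$counts$less_E379K, 98L)
  expect_identical(res$counts$less_R212Q, 140L)
  expect_identical(as.integer(res$counts$dual), 81L)
  expect_identical(as.integer(res$counts$E379K_only), 17L)
  expect_identical(as.integer(res$counts$R212Q_only), 59L)
  # dual + only counts recover each mutant's less-induced total
  expect_identical(as.integer(res$counts$dual) +
                     as.integer(res$counts$E379K_only), 98L)
  expect_identical(as.integer(res$counts$dual) +
                     as.integer(res$counts$R212Q_only), 140L)
})

test_that("gene sensitivity boundaries: insensitive needs small change in
           both mutants", {
  ids <- c("a", "b", "c", "d")
  # a: both L2FC 0 -> insensitive; b: -13% significant -> not less-induced,
  # and |change| < 25% in both -> insensitive; c: -30% but padj 0.2 ->
  # none (change too large for insensitive); d: less-induced by E379K
  de <- fix_diff(ids, padj = c(0.9, 0.04, 0.2, 0.01),
                 l2fc = c(0, log2(0.87), log2(0.70), -1))
  dr <- fix_diff(ids, padj = rep(0.9, 4), l2fc = c(0, 0, 0, 0))
  res <- classify_gene_sensitivity(de, dr, ids)
  expect_identical(as.character(res$classes$sensitivity),
                   c("insensitive", "insensitive", "none", "E379K_only"))
})

test_that("vicinity enrichment is ~1 for randomly placed enhancers and
           deterministic per seed", {
  set.seed(55)
  genes <- data.frame(id = sprintf("g%03d", 1:400),
                      chrom = sample(c("chr1", "chr2"), 400, TRUE),
                      tss = sample.int(2e6, 400),
                      group = c(rep("sens", 100), rep("unaffected", 300)),
                      stringsAsFactors = FALSE)
  enh <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                    center = sample.int(2e6, 300), group = "dual",
                    stringsAsFactors = FALSE)
  # sparse geometry (window small relative to the genome) so the linear
  # baseline scaling is unbiased
  r1 <- vicinity_enrichment(enh, genes, window = 5e3, n_random = 200,
                            reps = 10, seed = 3)
  r2 <- vicinity_enrichment(enh, genes, window = 5e3, n_random = 200,
                            reps = 10, seed = 3)
  expect_identical(r1, r2)
  expect_gt(r1$ratio, 0.6)
  expect_lt(r1$ratio, 1.6)
})

test_that("planted proximity yields the exactly computable enrichment", {
  # 30 enhancers all within 10 kb of the 10 'sens' TSSs on chr1; pool
  # genes live on chr2, so every baseline draw counts 0 except scaling
  genes <- data.frame(id = sprintf("g%03d", 1:210),
                      chrom = c(rep("chr1", 10), rep("chr2", 200)),
                      tss = c(seq(1e5, 1e6, length.out = 10),
                              seq(1e5, 1.9e6, length.out = 200)),
                      group = c(rep("sens", 10), rep("unaffected", 200)),
                      stringsAsFactors = FALSE)
  enh <- data.frame(chrom = "chr1",
                    center = rep(seq(1e5, 1e6, length.out = 10), 3) + 500,
                    group = "dual", stringsAsFactors = FALSE)
  r <- vicinity_enrichment(enh, genes, window = 1e4, n_random = 200,
                           reps = 5, seed = 1)
  expect_identical(r$observed, 30L)
  expect_identical(r$baseline, 0)
  expect_true(r$baseline_zero)
  expect_identical(r$ratio, Inf)

  # move half the pool onto chr1 so the baseline is positive and the
  # ratio is checkable against direct counting
  genes2 <- genes
  genes2$chrom[11:110] <- "chr1"
  genes2$tss[11:110] <- seq(1.2e6, 1.9e6, length.out = 100)
  r2 <- vicinity_enrichment(enh, genes2, window = 1e4, n_random = 100,
                            reps = 3, seed = 2)
  expect_identical(r2$observed, 30L)
  expect_gte(r2$ratio, 0)
})

test_that("duplicating the enhancer set leaves the enrichment ratio fixed", {
  set.seed(77)
  genes <- data.frame(id = sprintf("g%03d", 1:300),
                      chrom = "chr1", tss = sample.int(1e6, 300),
                      group = c(rep("sens", 50), rep("unaffected", 250)),
                      stringsAsFactors = FALSE)
  enh <- data.frame(chrom = "chr1", center = sample.int(1e6, 80),
                    group = "dual", stringsAsFactors = FALSE)
  r1 <- vicinity_enrichment(enh, genes, window = 2e4, n_random = 200,
                            reps = 10, seed = 9)
  r2 <- vicinity_enrichment(rbind(enh, enh), genes, window = 2e4,
                            n_random = 200, reps = 10, seed = 9)
  expect_equal(r2$observed, 2L * r1$observed)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)
})

test_that("a pool smaller than the requested draw errors", {
  genes <- data.frame(id = c("a", "b"), chrom = "chr1", tss = c(1, 2),
                      group = c("sens", "unaffected"))
  enh <- data.frame(chrom = "chr1", center = 5L, group = "dual")
  expect_error(vicinity_enrichment(enh, genes, n_random = 200), "pool")
})
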