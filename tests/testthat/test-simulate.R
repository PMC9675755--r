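# Small configurations keep these fast; the full default configuration is
# exercised once in the acceptance suite.

small_cfg <- function(...) {
  sim_config(n_chrom = 2L, chrom_size = 3e5, enhancers_per_group = 8L,
             n_nontarget = 30L, genes_per_group = 4L, n_null_genes = 40L,
             ...)
}

test_that("genome generation is deterministic with the requested shape and
           composition", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg, seed = 1)
  g2 <- generate_genome(cfg, seed = 1)
  expect_identical(g1$seq, g2$seq)
  expect_identical(unname(g1$lengths), rep(300000L, 2))
  g3 <- generate_genome(cfg, seed = 2)
  expect_false(identical(g1$seq, g3$seq))
  # GC of a uniform-composition genome: binomial CI around 0.5
  gc <- sum(vapply(strsplit(g1$seq, ""), function(x)
    sum(x %in% c("G", "C")), 0L)) / sum(g1$lengths)
  expect_lt(abs(gc - 0.5), 4 * sqrt(0.25 / sum(g1$lengths)) + 0.002)
})

test_that("planting with zero mismatches writes the exact consensus
           everywhere", {
  cfg <- small_cfg(seg_mismatches = list(
    dual = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 0L),
    E379K_only = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 0L),
    R212Q_only = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 0L),
    insensitive = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 0L),
    nontarget = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 0L)))
  p <- ppre_pwm()
  g <- generate_genome(cfg, seed = 3)
  pl <- plant_enhancers(g, p, cfg, seed = 4)
  cons <- pwm_consensus(p)
  expect_true(all(pl$truth$enhancers$motif == cons))
  # and the genome carries it (on the planted strand)
  e <- pl$truth$enhancers[1, ]
  s <- substr(pl$genome$seq[[e$chrom]], e$motif_start + 1,
              e$motif_start + nchar(cons))
  if (e$motif_strand == "-")
    s <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  expect_identical(s, cons)
})

test_that("planted segment strengths separate the groups as designed", {
  cfg <- small_cfg()
  p <- ppre_pwm()
  pl <- plant_enhancers(generate_genome(cfg, seed = 5), p, cfg, seed = 6)
  enh <- pl$truth$enhancers
  # recompute segment scores from the truth strings, independently
  lo <- pwm_logodds(p)
  ext5_rescore <- vapply(enh$motif, function(m) {
    b <- match(strsplit(m, "")[[1]], c("A", "C", "G", "T"))
    sum(lo[cbind(b[1:4], 1:4)])
  }, 0, USE.NAMES = FALSE)
  expect_equal(ext5_rescore, enh$seg_ext5, tolerance = 1e-12)
  strong <- enh$group %in% c("dual", "R212Q_only")
  weak <- enh$group %in% c("insensitive", "E379K_only")
  expect_gt(mean(ext5_rescore[strong]), mean(ext5_rescore[weak]))
  # truth reproducibility
  pl2 <- plant_enhancers(generate_genome(cfg, seed = 5), p, cfg, seed = 6)
  expect_identical(pl2$truth$enhancers, enh)
  # invariants: rates positive, accessibility consistent with groups
  rate_cols <- grep("^rate_", names(enh), value = TRUE)
  expect_true(all(as.matrix(enh[rate_cols]) > 0))
  expect_true(all(enh$accessibility[strong] == "inaccessible"))
  expect_true(all(enh$accessibility[enh$group == "nontarget"] ==
                    "accessible"))
})

test_that("a genome too small for the requested enhancers errors", {
  cfg <- sim_config(n_chrom = 1L, chrom_size = 5e4,
                    enhancers_per_group = 10L, n_nontarget = 20L)
  expect_error(plant_enhancers(generate_genome(cfg, 1), ppre_pwm(), cfg, 1),
               "too small")
})

test_that("ChIP windows concentrate at the planted mean as dispersion
           vanishes", {
  cfg <- small_cfg(dispersion = 1e-10)
  pl <- plant_enhancers(generate_genome(cfg, 7), ppre_pwm(), cfg, seed = 8)
  truth <- pl$truth
  counts <- replicate(40, {
    tr <- simulate_chip_tags(truth, "Med1", "control", 1,
                             seed = sample.int(1e6, 1))
    e <- truth$enhancers[1, ]
    pos <- tr$tags[[e$chrom]]$pos
    sum(pos >= e$center - 250 & pos < e$center + 250)
  })
  mu <- truth$enhancers$rate_Med1.control[1]
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 40) + 0.5)
  expect_lt(var(counts), 3 * mu)  # Poisson-limit variance, not NB
})

test_that("planted binding fold is recovered within Monte-Carlo error and
           the factor control track is flat", {
  cfg <- small_cfg()
  pl <- plant_enhancers(generate_genome(cfg, 9), ppre_pwm(), cfg, seed = 10)
  truth <- pl$truth
  enh <- truth$enhancers
  reps <- 60
  obs <- replicate(reps, {
    tr <- simulate_chip_tags(truth, "PPARg", "WT", 1,
                             seed = sample.int(1e6, 1))
    e <- enh[3, ]
    pos <- tr$tags[[e$chrom]]$pos
    sum(pos >= e$center - 250 & pos < e$center + 250)
  })
  mu <- enh$rate_PPARg.WT[3]
  sd_nb <- sqrt(mu + cfg$dispersion * mu^2)
  expect_lt(abs(mean(obs) - mu), 2 * sd_nb / sqrt(reps) + 1)

  ctrl <- simulate_chip_tags(truth, "PPARg", "control", 1, seed = 11)
  win <- vapply(seq_len(nrow(enh)), function(i) {
    pos <- ctrl$tags[[enh$chrom[i]]]$pos
    sum(pos >= enh$center[i] - 250 & pos < enh$center[i] + 250)
  }, 0L)
  bg_exp <- cfg$bg_density * 500
  # no enhancer-centered excess: mean window count is background-level
  expect_lt(mean(win), bg_exp + 4 * sqrt(bg_exp / nrow(enh)))
})

test_that("ATAC fragment mixture behaves under the nucleosome-free filter", {
  cfg <- small_cfg()
  pl <- plant_enhancers(generate_genome(cfg, 12), ppre_pwm(), cfg,
                        seed = 13)
  truth <- pl$truth
  fr1 <- simulate_atac(truth, "control", 1, seed = 14)
  fr2 <- simulate_atac(truth, "control", 1, seed = 14)
  expect_identical(fr1, fr2)
  nf <- fr1[fr1$length <= 120, ]
  # sub-nucleosomal component ~N(70, 20): the filtered set is dominated by
  # it; the mono-nucleosomal tail below 120 bp is ~0.1% of its mass
  expect_gt(mean(nf$length < 120), 0.99)
  expect_lt(mean(nf$length), cfg$frag_sub_mean + 10)

  # accessible enhancers emit more nucleosome-free fragments than
  # inaccessible ones in the control condition
  sl <- stats::setNames(rep(cfg$chrom_size, cfg$n_chrom),
                        paste0("chr", seq_len(cfg$n_chrom)))
  tr <- atac_nf_track(fr1, sl, 120, "control", 1)
  enh <- truth$enhancers
  win <- vapply(seq_len(nrow(enh)), function(i) {
    pos <- tr$tags[[enh$chrom[i]]]$pos
    sum(pos >= enh$center[i] - 250 & pos < enh$center[i] + 250)
  }, 0L)
  acc <- enh$accessibility == "accessible"
  expect_gt(mean(win[acc]), mean(win[!acc]))
})

test_that("expression counts follow the construction arithmetic of linked
           genes", {
  cfg <- small_cfg()
  pl <- plant_enhancers(generate_genome(cfg, 15), ppre_pwm(), cfg,
                        seed = 16)
  truth <- pl$truth
  genes <- truth$genes
  dual <- genes$group == "dual"
  # mutant/WT expected fold equals the penalty for linked genes
  expect_equal(unique(genes$expr_E379K[dual] / genes$expr_WT[dual]),
               cfg$penalties$dual[["E379K"]])
  expect_equal(unique(genes$expr_WT[dual] / genes$expr_control[dual]),
               cfg$expr_fold)
  em <- simulate_expression(truth, seed = 17)
  em2 <- simulate_expression(truth, seed = 17)
  expect_identical(em$counts, em2$counts)
  # empirical means track the planted rates
  wt_cols <- em$samples$condition == "WT"
  expect_equal(mean(em$counts[dual, wt_cols]),
               mean(genes$expr_WT[dual]),
               tolerance = 0.15)
})

test_that("with all penalties at 1 no excess mutation sensitivity is
           called (null calibration)", {
  cfg <- small_cfg(
    penalties = list(dual = c(E379K = 1, R212Q = 1),
                     E379K_only = c(E379K = 1, R212Q = 1),
                     R212Q_only = c(E379K = 1, R212Q = 1),
                     insensitive = c(E379K = 1, R212Q = 1),
                     nontarget = c(E379K = 1, R212Q = 1)))
  pl <- plant_enhancers(generate_genome(cfg, 18), ppre_pwm(), cfg,
                        seed = 19)
  truth <- pl$truth
  enh <- truth$enhancers
  feats <- data.frame(chrom = enh$chrom, center = enh$center, id = enh$id)
  tracks <- list()
  for (cond in c("WT", "E379K", "R212Q")) for (r in 1:2)
    tracks[[paste(cond, r)]] <-
      simulate_chip_tags(truth, "PPARg", cond, r,
                         seed = 1000 + 10 * r + nchar(cond))
  cm <- quantify(feats, tracks)
  res_e <- nb_wald(cm, c("WT", "E379K"), assay = "PPARg")
  res_r <- nb_wald(cm, c("WT", "R212Q"), assay = "PPARg")
  sens <- classify_sensitivity(res_e, res_r, enh$id)
  frac <- mean(sens$groups$group %in% c("dual", "E379K_only", "R212Q_only"))
  n <- nrow(enh)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("full datasets are byte-identical under a fixed seed", {
  cfg <- small_cfg()
  s1 <- simulate_dataset(cfg, seed = 42)
  s2 <- simulate_dataset(cfg, seed = 42)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$truth$enhancers, s2$truth$enhancers)
  expect_identical(lapply(s1$chip, `[[`, "tags"),
                   lapply(s2$chip, `[[`, "tags"))
  expect_identical(s1$atac_fragments, s2$atac_fragments)
  expect_identical(s1$expression$counts, s2$expression$counts)
})
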