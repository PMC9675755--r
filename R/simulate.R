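# Synthetic-data generator: a toy genome with planted response elements,
# condition-specific ChIP/ATAC tag tracks and linked gene expression, plus
# a TruthTable recording every planted parameter so the downstream
# pipeline can be validated against a known answer.
#
# Causal structure emulated: four planted sensitivity groups of target
# enhancers plus a majority class of constitutive non-target binding
# sites (bound by the factor but with no activation gain and no mutant
# effect, mirroring the genome-wide predominance of non-activated sites).
# R212Q-only and dual groups carry strong 5' extension and PPARg
# half-sites and sit in inaccessible chromatin; E379K-only and
# insensitive groups carry weaker motifs and are accessible at baseline.
# Mutant binding is the WT rate times a per-(group x mutant) penalty;
# activation marks, chromatin remodeling and linked gene induction follow
# binding through the same penalties.

SIM_CONDITIONS <- c("control", "WT", "E379K", "R212Q")
SIM_GROUPS <- c("dual", "E379K_only", "R212Q_only", "insensitive")
SIM_PLANT_GROUPS <- c(SIM_GROUPS, "nontarget")

#' Simulation configuration
#'
#' All knobs of the synthetic generator with the default study conditions:
#' two replicates per condition, negative-binomial counts with dispersion
#' 0.02 (Var = mu + d mu^2), and strong planted effects (binding fold >= 4
#' over background, mutant penalties 0.3).
#'
#' @param n_chrom,chrom_size toy genome shape (default 4 x 1.5 Mb).
#' @param enhancers_per_group planted enhancers per sensitivity group
#'   (default 100; groups: dual, E379K_only, R212Q_only, insensitive).
#' @param n_nontarget constitutive non-target binding sites (bound, never
#'   activated, insensitive to the mutations); default 1500, so the
#'   non-activated class is the large majority, as genome-wide — which is
#'   also what makes median-of-ratios normalization valid.
#' @param replicates replicates per condition (default 2).
#' @param dispersion NB dispersion (default 0.02).
#' @param bg_density uniform background tag density per bp per library
#'   (default 0.005).
#' @param chip_mean per-replicate expected WT factor-ChIP tags in the
#'   500-bp peak window at a consensus-strength motif (default 100, i.e.
#'   planted binding 15-20x over local background; the 4-fold calling
#'   threshold is a floor, not the typical site strength).
#' @param penalties per-group multiplicative binding reduction for each
#'   mutant, in (0, 1]; defaults reproduce the planted interaction.
#' @param seg_mismatches per-group consensus mismatch counts in the
#'   (5' extension, PPARg half-site, RXR half-site) segments.
#' @param basal_med1,basal_h3k27ac per-group basal mark window means.
#' @param activation_fold WT-induced gain of both marks at targets.
#' @param atac_accessible_mean,atac_inaccessible_mean basal nucleosome-free
#'   ATAC window means for the two accessibility classes.
#' @param remodel_fold WT-induced accessibility gain at inaccessible
#'   (remodel-planted) enhancers.
#' @param frag_sub_mean,frag_sub_sd,frag_mono_mean,frag_mono_sd ATAC
#'   fragment-length mixture components (sub- and mono-nucleosomal, bp).
#' @param mono_ratio_accessible,mono_ratio_inaccessible mono-nucleosomal
#'   fragment rate relative to the nucleosome-free rate.
#' @param genes_per_group enhancer-linked (induced) genes per group.
#' @param n_null_genes unaffected genes forming the resampling pool.
#' @param expr_mean,expr_fold baseline gene count mean and WT induction
#'   fold of linked genes.
#' @param link_dist maximum planted TSS-to-enhancer distance (bp).
#' @param margin enhancer-free margin at chromosome ends (bp).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4L, chrom_size = 2e6,
                       enhancers_per_group = 100L, n_nontarget = 1500L,
                       replicates = 2L,
                       dispersion = 0.02, bg_density = 0.005,
                       chip_mean = 100,
                       penalties = list(
                         dual = c(E379K = 0.3, R212Q = 0.3),
                         E379K_only = c(E379K = 0.3, R212Q = 1),
                         R212Q_only = c(E379K = 1, R212Q = 0.3),
                         insensitive = c(E379K = 1, R212Q = 1),
                         nontarget = c(E379K = 1, R212Q = 1)),
                       seg_mismatches = list(
                         dual = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 1L),
                         E379K_only = c(ext5 = 2L, ppar_hs = 2L, rxr_hs = 1L),
                         R212Q_only = c(ext5 = 0L, ppar_hs = 0L, rxr_hs = 1L),
                         insensitive = c(ext5 = 2L, ppar_hs = 2L, rxr_hs = 1L),
                         nontarget = c(ext5 = 2L, ppar_hs = 3L, rxr_hs = 2L)),
                       basal_med1 = c(dual = 12, E379K_only = 25,
                                      R212Q_only = 12, insensitive = 40,
                                      nontarget = 30),
                       basal_h3k27ac = c(dual = 15, E379K_only = 30,
                                         R212Q_only = 15, insensitive = 45,
                                         nontarget = 45),
                       activation_fold = 4,
                       atac_accessible_mean = 40, atac_inaccessible_mean = 4,
                       remodel_fold = 5,
                       frag_sub_mean = 70, frag_sub_sd = 20,
                       frag_mono_mean = 180, frag_mono_sd = 20,
                       mono_ratio_accessible = 0.25,
                       mono_ratio_inaccessible = 2,
                       genes_per_group = 50L, n_null_genes = 500L,
                       expr_mean = 100, expr_fold = 4,
                       link_dist = 5000L, margin = 10000L) {
  cfg <- as.list(environment())
  stopifnot(n_chrom >= 1, chrom_size >= 1e4, enhancers_per_group >= 1,
            n_nontarget >= 0, replicates >= 1, dispersion > 0,
            bg_density > 0, chip_mean > 0, activation_fold > 0,
            expr_fold > 0)
  for (g in SIM_PLANT_GROUPS) {
    p <- cfg$penalties[[g]]
    if (is.null(p) || any(p <= 0) || any(p > 1))
      stop_arg("penalties for ", g, " must lie in (0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# accessibility class is a deterministic function of the planted group;
# constitutive non-target sites sit in open chromatin
group_accessibility <- function(group) {
  ifelse(group %in% c("dual", "R212Q_only"), "inaccessible", "accessible")
}

#' Generate a random toy genome
#'
#' I.i.d. uniform A/C/G/T background; deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return a [genome] with chromosomes `chr1..chrN`.
#' @export
generate_genome <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  codes <- utf8ToInt("ACGT")
  seqs <- with_seed(seed, {
    vapply(seq_len(config$n_chrom), function(i) {
      intToUtf8(codes[sample.int(4L, config$chrom_size, replace = TRUE)])
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(config$n_chrom))
  genome(seqs)
}

# degrade one segment of the consensus: replace `k` random positions (within
# the segment's 1-based motif range) with the worst-scoring column base
degrade_segment <- function(bases, probs, range, k) {
  if (k <= 0) return(bases)
  idx <- sample(range, min(k, length(range)))
  for (i in idx) bases[i] <- DNA_BASES[which.min(probs[, i])]
  bases
}

segment_match_frac <- function(bases, consensus, range) {
  mean(bases[range] == consensus[range])
}

#' Plant response-element enhancers into a genome
#'
#' Enhancers are laid out on an evenly spaced grid (with jitter) per
#' chromosome and assigned to the four sensitivity groups at random. Each
#' enhancer receives a motif instance: the PWM consensus degraded by the
#' per-group, per-segment mismatch counts (mismatches use the
#' worst-scoring column base), written into the genome on a random strand
#' at the enhancer center. Expected tag rates follow the generative rules:
#' WT binding scales with the planted motif score, mutant binding is WT
#' times the group penalty, marks/ATAC/remodeling follow binding.
#'
#' @param g a [genome] from [generate_genome()].
#' @param p the [pwm] whose consensus is planted.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `genome` (motifs written in) and `truth`, a list of
#'   class `truth_table`: `enhancers` (interval, group, accessibility,
#'   segment match fractions and scores, per-assay/condition expected
#'   window rates) and `genes` (TSS, linked enhancer, group, per-condition
#'   expected expression).
#' @export
plant_enhancers <- function(g, p, config, seed = 1L) {
  stopifnot(inherits(g, "genome"), inherits(p, "pwm"),
            inherits(config, "sim_config"))
  n_total <- 4L * config$enhancers_per_group + config$n_nontarget
  per_chrom <- diff(round(seq(0, n_total, length.out = config$n_chrom + 1L)))
  lo <- pwm_logodds(p)
  L <- pwm_width(p)
  consensus <- strsplit(pwm_consensus(p), "")[[1L]]
  seg_ranges <- list(ext5 = 1:4, ppar_hs = 5:10,
                     rxr_hs = 12:min(17L, L))
  with_seed(seed, {
    rows <- list()
    k <- 0L
    for (ci in seq_len(config$n_chrom)) {
      ch <- names(g$seq)[ci]
      n_e <- per_chrom[ci]
      if (n_e == 0L) next
      span <- config$chrom_size - 2 * config$margin
      spacing <- span / n_e
      if (spacing < 3000 + 500)
        stop_arg("genome too small to place ", n_e,
                 " enhancers with 3 kb padding on ", ch)
      jitter <- round(stats::runif(n_e, -spacing / 8, spacing / 8))
      centers <- as.integer(round(config$margin + (seq_len(n_e) - 0.5) *
                                    spacing + jitter))
      for (ctr in centers) {
        k <- k + 1L
        rows[[k]] <- data.frame(chrom = ch, center = ctr,
                                stringsAsFactors = FALSE)
      }
    }
    enh <- do.call(rbind, rows)
    enh$group <- sample(c(rep(SIM_GROUPS, each = config$enhancers_per_group),
                          rep("nontarget", config$n_nontarget)))
    enh$id <- sprintf("enh_%04d", seq_len(nrow(enh)))
    enh$start <- enh$center - 250L
    enh$end <- enh$center + 250L
    enh$accessibility <- group_accessibility(enh$group)
    # motif instance per enhancer
    enh$motif <- NA_character_
    enh$motif_strand <- sample(c("+", "-"), nrow(enh), replace = TRUE)
    enh$score <- NA_real_
    for (seg in names(seg_ranges)) enh[[paste0("frac_", seg)]] <- NA_real_
    for (seg in names(seg_ranges)) enh[[paste0("seg_", seg)]] <- NA_real_
    for (i in seq_len(nrow(enh))) {
      mm <- config$seg_mismatches[[enh$group[i]]]
      bases <- consensus
      for (seg in names(seg_ranges))
        bases <- degrade_segment(bases, p$probs, seg_ranges[[seg]],
                                 mm[[seg]])
      enh$motif[i] <- paste0(bases, collapse = "")
      per_pos <- lo[cbind(match(bases, DNA_BASES), seq_len(L))]
      enh$score[i] <- sum(per_pos)
      for (seg in names(seg_ranges)) {
        rng <- seg_ranges[[seg]]
        enh[[paste0("frac_", seg)]][i] <-
          segment_match_frac(bases, consensus, rng)
        enh[[paste0("seg_", seg)]][i] <- sum(per_pos[rng])
      }
    }
    # write motifs into the genome at the enhancer centers
    seqs <- g$seq
    enh$motif_start <- NA_integer_
    for (i in seq_len(nrow(enh))) {
      s <- enh$center[i] - L %/% 2L
      ins <- enh$motif[i]
      if (enh$motif_strand[i] == "-") ins <- revcomp(ins)
      substr(seqs[[enh$chrom[i]]], s + 1L, s + L) <- ins
      enh$motif_start[i] <- s
    }
    g2 <- genome(seqs)

    # expected per-replicate window rates (background included)
    score_max <- sum(apply(lo, 2, max))
    score_frac <- pmin(1, pmax(0, enh$score / score_max))
    bg250 <- config$bg_density * 500
    bg1500 <- config$bg_density * 3000
    pen <- function(mut) vapply(enh$group, function(gp)
      config$penalties[[gp]][[mut]], 1.0)
    wt_bind <- config$chip_mean * (0.5 + 0.5 * score_frac)
    rate <- list()
    rate[["PPARg.control"]] <- rep(0, nrow(enh))
    rate[["PPARg.WT"]] <- wt_bind
    rate[["PPARg.E379K"]] <- wt_bind * pen("E379K")
    rate[["PPARg.R212Q"]] <- wt_bind * pen("R212Q")
    is_target <- enh$group != "nontarget"
    for (mk in c("Med1", "H3K27ac")) {
      basal <- (if (mk == "Med1") config$basal_med1 else
                  config$basal_h3k27ac)[enh$group]
      wt <- ifelse(is_target, basal * config$activation_fold, basal)
      rate[[paste0(mk, ".control")]] <- unname(basal)
      rate[[paste0(mk, ".WT")]] <- unname(wt)
      rate[[paste0(mk, ".E379K")]] <- unname(basal + (wt - basal) * pen("E379K"))
      rate[[paste0(mk, ".R212Q")]] <- unname(basal + (wt - basal) * pen("R212Q"))
    }
    acc <- enh$accessibility == "accessible"
    basal_atac <- ifelse(acc, config$atac_accessible_mean,
                         config$atac_inaccessible_mean)
    wt_atac <- ifelse(acc, basal_atac, basal_atac * config$remodel_fold)
    rate[["ATAC.control"]] <- basal_atac
    rate[["ATAC.WT"]] <- wt_atac
    rate[["ATAC.E379K"]] <- basal_atac + (wt_atac - basal_atac) * pen("E379K")
    rate[["ATAC.R212Q"]] <- basal_atac + (wt_atac - basal_atac) * pen("R212Q")
    for (nm in names(rate)) {
      bg <- if (startsWith(nm, "H3K27ac")) bg1500 else bg250
      enh[[paste0("rate_", nm)]] <- rate[[nm]] + bg
    }
    enh$remodel_planted <- !acc

    # genes: linked (induced) genes near a subset of each group's
    # enhancers, plus an unaffected pool at random positions
    genes <- list()
    gi <- 0L
    for (gp in SIM_GROUPS) {
      eg <- enh[enh$group == gp, , drop = FALSE]
      sel <- eg[seq_len(min(config$genes_per_group, nrow(eg))), ,
                drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        gi <- gi + 1L
        off <- sample(c(-1L, 1L)) [1L] *
          sample(seq(1000L, config$link_dist), 1L)
        genes[[gi]] <- data.frame(
          id = sprintf("gene_%03d", gi), chrom = sel$chrom[i],
          tss = sel$center[i] + off, linked_enhancer = sel$id[i],
          group = gp, de_status = "induced", stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(config$n_null_genes)) {
      gi <- gi + 1L
      genes[[gi]] <- data.frame(
        id = sprintf("gene_%03d", gi),
        chrom = paste0("chr", sample.int(config$n_chrom, 1L)),
        tss = sample.int(config$chrom_size - 1L, 1L),
        linked_enhancer = NA_character_, group = "none",
        de_status = "unaffected", stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    base <- config$expr_mean
    ind <- genes$de_status == "induced"
    genes$expr_control <- rep(base, nrow(genes))
    genes$expr_WT <- ifelse(ind, base * config$expr_fold, base)
    gpen <- function(mut) ifelse(ind, vapply(genes$group, function(gp)
      if (gp == "none") 1 else config$penalties[[gp]][[mut]], 1.0), 1)
    # mutant expression of a linked gene: WT level times the penalty,
    # so the expected mutant/WT fold equals the penalty itself
    genes$expr_E379K <- ifelse(ind, genes$expr_WT * gpen("E379K"),
                               genes$expr_control)
    genes$expr_R212Q <- ifelse(ind, genes$expr_WT * gpen("R212Q"),
                               genes$expr_control)

    truth <- structure(list(enhancers = enh, genes = genes, pwm = p,
                            config = config),
                       class = "truth_table")
    list(genome = g2, truth = truth)
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: %d enhancers (%s), %d genes\n",
              nrow(x$enhancers),
              paste(sprintf("%s=%d", names(table(x$enhancers$group)),
                            table(x$enhancers$group)), collapse = ", "),
              nrow(x$genes)))
  invisible(x)
}

# symmetric triangular offsets on (-w, w)
rtri <- function(n, w) round((stats::runif(n) + stats::runif(n) - 1) * w)

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

sim_seqlengths <- function(truth) {
  cfg <- truth$config
  stats::setNames(rep(as.integer(cfg$chrom_size), cfg$n_chrom),
                  paste0("chr", seq_len(cfg$n_chrom)))
}

#' Simulate a ChIP-seq tag track
#'
#' Per-enhancer tag counts are negative-binomial around the planted
#' expected rate (background subtracted), placed with a triangular spread
#' around the enhancer center whose width matches the assay's counting
#' window (+/-250 bp for factor/Med1-like, +/-1500 bp for H3K27ac-like),
#' plus uniform background tags genome-wide. The control condition of the
#' factor assay is background-only.
#'
#' @param truth a `truth_table` from [plant_enhancers()].
#' @param assay one of `"PPARg"`, `"H3K27ac"`, `"Med1"`.
#' @param condition one of `"control"`, `"WT"`, `"E379K"`, `"R212Q"`.
#' @param replicate replicate index (labels the track).
#' @param seed RNG seed.
#' @return a [tag_track].
#' @export
simulate_chip_tags <- function(truth, assay, condition, replicate = 1L,
                               seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  if (!assay %in% c("PPARg", "H3K27ac", "Med1"))
    stop_arg("unknown assay: ", assay)
  if (!condition %in% SIM_CONDITIONS) stop_arg("unknown condition: ", condition)
  cfg <- truth$config
  enh <- truth$enhancers
  w <- if (assay == "H3K27ac") 1500L else 250L
  bg_window <- cfg$bg_density * 2 * w
  mu <- pmax(enh[[paste0("rate_", assay, ".", condition)]] - bg_window, 0)
  sl <- sim_seqlengths(truth)
  with_seed(seed, {
    counts <- nb_draw(nrow(enh), mu, cfg$dispersion)
    pos_chrom <- rep(enh$chrom, counts)
    pos <- rep(enh$center, counts) + rtri(sum(counts), w)
    n_bg <- stats::rpois(1L, cfg$bg_density * cfg$chrom_size * cfg$n_chrom)
    # paste0 coerces zero-length to "", so guard the empty draw
    bg_chrom <- if (n_bg > 0)
      paste0("chr", sample.int(cfg$n_chrom, n_bg, replace = TRUE))
    else character()
    bg_pos <- sample.int(cfg$chrom_size, n_bg, replace = TRUE) - 1L
    df <- data.frame(chrom = c(pos_chrom, bg_chrom),
                     pos = pmin(pmax(c(pos, bg_pos), 0L),
                                cfg$chrom_size - 1L),
                     strand = sample(c("+", "-"),
                                     length(pos) + n_bg, replace = TRUE),
                     stringsAsFactors = FALSE)
    tag_track(df, sl, assay, condition, replicate)
  })
}

#' Simulate ATAC-seq fragments
#'
#' Fragment lengths come from a two-component normal mixture
#' (sub-nucleosomal around `frag_sub_mean` bp, mono-nucleosomal around
#' `frag_mono_mean` bp). Nucleosome-free fragment counts per enhancer are
#' NB around the planted rate; mono-nucleosomal counts scale with the
#' accessibility-dependent `mono_ratio`. Background fragments (half
#' sub-nucleosomal) are uniform genome-wide.
#'
#' @param truth a `truth_table`.
#' @param condition simulation condition.
#' @param replicate replicate index.
#' @param seed RNG seed.
#' @return data.frame of fragments: `chrom`, `start`, `end`, `length`.
#' @export
simulate_atac <- function(truth, condition, replicate = 1L, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  if (!condition %in% SIM_CONDITIONS) stop_arg("unknown condition: ", condition)
  cfg <- truth$config
  enh <- truth$enhancers
  w <- 250L
  bg_window <- cfg$bg_density * 2 * w
  mu_nf <- pmax(enh[[paste0("rate_ATAC.", condition)]] - bg_window, 0)
  mono_ratio <- ifelse(enh$accessibility == "accessible",
                       cfg$mono_ratio_accessible, cfg$mono_ratio_inaccessible)
  with_seed(seed, {
    n_nf <- nb_draw(nrow(enh), mu_nf, cfg$dispersion)
    n_mono <- nb_draw(nrow(enh), mu_nf * mono_ratio + 1, cfg$dispersion)
    len_nf <- pmax(20L, round(stats::rnorm(sum(n_nf), cfg$frag_sub_mean,
                                           cfg$frag_sub_sd)))
    len_mono <- pmax(20L, round(stats::rnorm(sum(n_mono), cfg$frag_mono_mean,
                                             cfg$frag_mono_sd)))
    ctr <- c(rep(enh$center, n_nf) + rtri(sum(n_nf), w),
             rep(enh$center, n_mono) + rtri(sum(n_mono), w))
    chrom <- c(rep(enh$chrom, n_nf), rep(enh$chrom, n_mono))
    len <- c(len_nf, len_mono)
    n_bg <- stats::rpois(1L, cfg$bg_density * cfg$chrom_size * cfg$n_chrom)
    bg_sub <- stats::runif(n_bg) < 0.5
    bg_len <- ifelse(bg_sub,
                     pmax(20L, round(stats::rnorm(n_bg, cfg$frag_sub_mean,
                                                  cfg$frag_sub_sd))),
                     pmax(20L, round(stats::rnorm(n_bg, cfg$frag_mono_mean,
                                                  cfg$frag_mono_sd))))
    if (n_bg > 0)
      chrom <- c(chrom, paste0("chr", sample.int(cfg$n_chrom, n_bg,
                                                 replace = TRUE)))
    ctr <- c(ctr, sample.int(cfg$chrom_size, n_bg, replace = TRUE) - 1L)
    len <- c(len, bg_len)
    start <- pmax(0L, as.integer(round(ctr - len / 2)))
    end <- pmin(as.integer(cfg$chrom_size), start + as.integer(len))
    data.frame(chrom = chrom, start = start, end = end,
               length = as.integer(len), stringsAsFactors = FALSE)[
                 order(chrom, start), , drop = FALSE]
  })
}

#' Nucleosome-free tag track from ATAC fragments
#'
#' Keeps fragments of length `<= max_len` (nucleosome-free selection) and
#' collapses each to its midpoint.
#'
#' @param fragments data.frame from [simulate_atac()] (or any `chrom`,
#'   `start`, `end`, `length` table).
#' @param seqlengths named chromosome lengths.
#' @param max_len nucleosome-free length cutoff (bp); default 120.
#' @param condition,replicate sample label.
#' @return a [tag_track] with assay `"ATAC"`.
#' @export
atac_nf_track <- function(fragments, seqlengths, max_len = 120L,
                          condition = NA_character_, replicate = NA_integer_) {
  keep <- fragments$length <= max_len
  f <- fragments[keep, , drop = FALSE]
  mid <- (f$start + f$end) %/% 2L
  tag_track(data.frame(chrom = f$chrom, pos = mid, strand = "+",
                       stringsAsFactors = FALSE),
            seqlengths, "ATAC", condition, replicate)
}

#' Simulate gene-level expression counts
#'
#' NB counts around the planted per-condition expression rates; genes
#' linked to planted-sensitive enhancers are induced by the configured WT
#' fold and reduced in mutants by the linked enhancer's penalty.
#'
#' @param truth a `truth_table`.
#' @param conditions conditions to simulate (default all four).
#' @param seed RNG seed.
#' @return a [count_matrix] (assay `"RNA"`, genes x condition/replicates).
#' @export
simulate_expression <- function(truth, conditions = SIM_CONDITIONS,
                                seed = 1L) {
  stopifnot(inherits(truth, "truth_table"),
            all(conditions %in% SIM_CONDITIONS))
  cfg <- truth$config
  genes <- truth$genes
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         condition = conditions, stringsAsFactors = FALSE)
  samples <- data.frame(assay = "RNA", condition = samples$condition,
                        replicate = samples$replicate,
                        stringsAsFactors = FALSE)
  counts <- with_seed(seed, {
    m <- matrix(0L, nrow(genes), nrow(samples),
                dimnames = list(genes$id, NULL))
    for (j in seq_len(nrow(samples))) {
      mu <- genes[[paste0("expr_", samples$condition[j])]]
      m[, j] <- nb_draw(nrow(genes), mu, cfg$dispersion)
    }
    m
  })
  count_matrix(counts, samples)
}

#' Simulate a complete dataset
#'
#' Genome, planted enhancers, all ChIP and ATAC tracks for every
#' condition/replicate, and gene expression counts. Per-track seeds are
#' derived deterministically from `seed` and the sample label, so adding a
#' track never perturbs another's randomness.
#'
#' @param config a [sim_config()].
#' @param p the [pwm] to plant; default [ppre_pwm()].
#' @param seed global RNG seed.
#' @return list: `genome`, `truth`, `chip` (named list of [tag_track]s,
#'   `assay.condition.rep`), `atac_fragments` (named list of fragment
#'   tables, `condition.rep`), `atac_nf` (nucleosome-free [tag_track]s),
#'   `expression` ([count_matrix]), `seqlengths`.
#' @export
simulate_dataset <- function(config = sim_config(), p = ppre_pwm(),
                             seed = 1L) {
  g0 <- generate_genome(config, derive_seed(seed, "genome"))
  planted <- plant_enhancers(g0, p, config, derive_seed(seed, "plant"))
  truth <- planted$truth
  sl <- sim_seqlengths(truth)
  chip <- list()
  for (assay in c("PPARg", "H3K27ac", "Med1")) {
    for (cond in SIM_CONDITIONS) {
      for (r in seq_len(config$replicates)) {
        key <- paste(assay, cond, r, sep = ".")
        chip[[key]] <- simulate_chip_tags(truth, assay, cond, r,
                                          derive_seed(seed, key))
      }
    }
  }
  atac_fragments <- list()
  atac_nf <- list()
  for (cond in SIM_CONDITIONS) {
    for (r in seq_len(config$replicates)) {
      key <- paste(cond, r, sep = ".")
      fr <- simulate_atac(truth, cond, r, derive_seed(seed,
                                                      paste0("ATAC.", key)))
      atac_fragments[[key]] <- fr
      atac_nf[[key]] <- atac_nf_track(fr, sl, 120L, cond, r)
    }
  }
  expression <- simulate_expression(truth, SIM_CONDITIONS,
                                    derive_seed(seed, "expression"))
  list(genome = planted$genome, truth = truth, chip = chip,
       atac_fragments = atac_fragments, atac_nf = atac_nf,
       expression = expression, seqlengths = sl)
}

#' A synthetic 17-column PPRE-like position weight matrix
#'
#' DR1 consensus `AACT AGGTCA A AGGTCA`: 5' extension (bases 1-4), PPARg
#' half-site (5-10), single-base spacer (11) and RXR half-site (12-17).
#' This is a synthetic stand-in with the canonical consensus and moderate
#' degeneracy, not a database matrix.
#'
#' @param strength consensus base count per column (other bases get 2).
#' @param pseudocount passed to [pwm()].
#' @return a [pwm] named `"PPRE_synthetic"`.
#' @export
ppre_pwm <- function(strength = 10, pseudocount = 0.125) {
  consensus <- strsplit("AACTAGGTCAAAGGTCA", "")[[1L]]
  counts <- matrix(2, nrow = 4L, ncol = length(consensus),
                   dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(consensus)) counts[consensus[i], i] <- strength
  pwm(counts, name = "PPRE_synthetic", pseudocount = pseudocount)
}
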