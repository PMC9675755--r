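# Gene-level target definitions, mutation-sensitive gene classes, and the
# resampling-normalized enhancer-vicinity enrichment.

#' Call differentially expressed genes (WT vs control)
#'
#' Induced: `padj < padj_max` and fold change `> fold_min`
#' (`L2FC > log2(fold_min)`, strict); repressed symmetric. Everything else
#' is unaffected; the three statuses partition all tested genes.
#'
#' @param diff [nb_wald()] result on gene counts, WT vs control.
#' @param padj_max adjusted-p threshold; default 0.05.
#' @param fold_min minimum fold change (strict `>`); default 1.5.
#' @return list with `status` (data.frame `id`, `de_status`) and `counts`
#'   (`induced`, `repressed`, `total`, `unaffected`).
#' @export
define_de_genes <- function(diff, padj_max = 0.05, fold_min = 1.5) {
  sig <- diff$padj < padj_max
  sig[is.na(sig)] <- FALSE
  induced <- sig & diff$log2FoldChange > log2(fold_min)
  repressed <- sig & diff$log2FoldChange < -log2(fold_min)
  st <- ifelse(induced, "induced", ifelse(repressed, "repressed", "unaffected"))
  list(status = data.frame(id = diff$id,
                           de_status = factor(st, levels = c("induced",
                                                             "repressed",
                                                             "unaffected")),
                           stringsAsFactors = FALSE),
       counts = list(induced = sum(induced), repressed = sum(repressed),
                     total = sum(induced) + sum(repressed),
                     unaffected = sum(st == "unaffected")))
}

#' Classify induced genes by mutation sensitivity
#'
#' A gene is *less induced* by a mutant iff `padj < padj_max` and
#' `L2FC <= -log2(less_fold)` (mutant vs WT). Classes: `dual` (less induced
#' by both), `E379K_only`, `R212Q_only`, `insensitive` (absolute change
#' below `insens_frac` for both mutants, i.e. `|L2FC| < log2(1 +
#' insens_frac)`), `none` (the rest).
#'
#' @param diff_e379k,diff_r212q [nb_wald()] results, mutant vs WT, indexed
#'   by gene id.
#' @param induced_ids ids of WT-induced genes.
#' @param padj_max threshold; default 0.05.
#' @param less_fold minimum fold reduction; default 1.25.
#' @param insens_frac maximum fractional change for "insensitive";
#'   default 0.25.
#' @return list with `classes` (data.frame `id`, `less_E379K`,
#'   `less_R212Q`, `sensitivity`) and `counts`.
#' @export
classify_gene_sensitivity <- function(diff_e379k, diff_r212q, induced_ids,
                                      padj_max = 0.05, less_fold = 1.25,
                                      insens_frac = 0.25) {
  grab <- function(d) {
    less <- d$padj < padj_max & d$log2FoldChange <= -log2(less_fold)
    less[is.na(less)] <- FALSE
    list(less = stats::setNames(less, d$id),
         l2fc = stats::setNames(d$log2FoldChange, d$id))
  }
  e <- grab(diff_e379k)
  r <- grab(diff_r212q)
  le <- e$less[induced_ids]
  lr <- r$less[induced_ids]
  small <- abs(e$l2fc[induced_ids]) < log2(1 + insens_frac) &
    abs(r$l2fc[induced_ids]) < log2(1 + insens_frac)
  cls <- ifelse(le & lr, "dual",
         ifelse(le, "E379K_only",
         ifelse(lr, "R212Q_only",
         ifelse(small, "insensitive", "none"))))
  cls[is.na(cls)] <- "none"
  classes <- data.frame(id = induced_ids, less_E379K = unname(le),
                        less_R212Q = unname(lr),
                        sensitivity = factor(cls, levels = c("dual",
                                                             "E379K_only",
                                                             "R212Q_only",
                                                             "insensitive",
                                                             "none")),
                        stringsAsFactors = FALSE, row.names = NULL)
  counts <- as.list(table(classes$sensitivity))
  counts$less_E379K <- sum(le, na.rm = TRUE)
  counts$less_R212Q <- sum(lr, na.rm = TRUE)
  list(classes = classes, counts = counts)
}

# number of enhancer centers within `window` bp of any TSS in the set
count_near <- function(enh_chrom, enh_center, tss_chrom, tss_pos, window) {
  n <- 0L
  for (ch in unique(enh_chrom)) {
    ec <- enh_center[enh_chrom == ch]
    tp <- sort(tss_pos[tss_chrom == ch])
    if (length(ec) == 0L || length(tp) == 0L) next
    # enhancer is near iff some TSS lies in [center - window, center + window]
    lo <- findInterval(ec - window - 1L, tp)
    hi <- findInterval(ec + window, tp)
    n <- n + sum(hi > lo)
  }
  n
}

#' Resampling-normalized enhancer enrichment near gene groups
#'
#' For each enhancer group and gene group, counts enhancers whose center
#' lies within `window` bp of at least one TSS of the gene group; the
#' baseline is the mean of the same count over `reps` random draws of
#' `n_random` genes from the non-regulated pool, scaled linearly to the
#' gene group's size. The ratio observed/baseline is the enrichment.
#'
#' @param enhancers data.frame with `chrom`, `center` and a `group` column.
#' @param genes data.frame with `id`, `chrom`, `tss` and a `group` column;
#'   pool genes are those with `group == pool_group`.
#' @param window vicinity distance to the TSS (bp); default 1e5.
#' @param n_random genes per random draw; default 200.
#' @param reps number of draws; default 10.
#' @param seed RNG seed (draws are deterministic per seed).
#' @param pool_group label of the non-regulated gene pool; default
#'   `"unaffected"`.
#' @return data.frame: `enhancer_group`, `gene_group`, `n_genes`,
#'   `observed`, `baseline`, `ratio` (`Inf` with `baseline_zero = TRUE`
#'   when the baseline is 0).
#' @export
vicinity_enrichment <- function(enhancers, genes, window = 1e5,
                                n_random = 200L, reps = 10L, seed = 1L,
                                pool_group = "unaffected") {
  stopifnot(all(c("chrom", "center", "group") %in% names(enhancers)),
            all(c("chrom", "tss", "group") %in% names(genes)))
  pool <- genes[genes$group == pool_group, , drop = FALSE]
  if (nrow(pool) < n_random)
    stop_arg("non-regulated gene pool (", nrow(pool),
             ") smaller than n_random (", n_random, ")")
  gene_groups <- setdiff(unique(as.character(genes$group)), pool_group)
  enh_groups <- unique(as.character(enhancers$group))
  # one shared set of random draws so every cell uses the same baseline draws
  draws <- with_seed(seed, lapply(seq_len(reps), function(i)
    sample.int(nrow(pool), n_random)))
  out <- list()
  for (eg in enh_groups) {
    e <- enhancers[enhancers$group == eg, , drop = FALSE]
    base_mean <- mean(vapply(draws, function(ix)
      count_near(e$chrom, e$center, pool$chrom[ix], pool$tss[ix], window),
      0))
    for (gg in gene_groups) {
      gs <- genes[genes$group == gg, , drop = FALSE]
      obs <- count_near(e$chrom, e$center, gs$chrom, gs$tss, window)
      baseline <- base_mean * nrow(gs) / n_random
      out[[length(out) + 1L]] <- data.frame(
        enhancer_group = eg, gene_group = gg, n_genes = nrow(gs),
        observed = obs, baseline = baseline,
        ratio = if (baseline > 0) obs / baseline else Inf,
        baseline_zero = baseline == 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
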