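# Enhancer taxonomy: target-enhancer definition (gain of H3K27ac and/or
# Med1), mutation-sensitivity groups from mutant-vs-WT differential
# binding, accessibility classes from nucleosome-free ATAC signal,
# remodeling calls, and ROC evaluation of predictors.

check_same_ids <- function(a, b) {
  if (!identical(a$id, b$id))
    stop_arg("differential result sets are not indexed by the same features")
}

#' Define target enhancers by activation gain
#'
#' A binding site gains a mark iff `padj < fdr` and `L2FC > 0`; a target
#' enhancer gains H3K27ac and/or Med1 upon expression of the wild-type
#' factor.
#'
#' @param diff_h3k27ac,diff_med1 [nb_wald()] results on the same peaks
#'   (WT vs control).
#' @param fdr FDR threshold on `padj` (strict `<`); default 0.1.
#' @return list with `flags` (data.frame: `id`, `gain_h3k27ac`,
#'   `gain_med1`, `is_target`) and `counts`
#'   (`n_h3k27ac`, `n_med1`, `n_both`, `n_union`); the union satisfies
#'   `n_union = n_h3k27ac + n_med1 - n_both`.
#' @export
define_target_enhancers <- function(diff_h3k27ac, diff_med1, fdr = 0.1) {
  check_same_ids(diff_h3k27ac, diff_med1)
  gain_h <- diff_h3k27ac$padj < fdr & diff_h3k27ac$log2FoldChange > 0
  gain_m <- diff_med1$padj < fdr & diff_med1$log2FoldChange > 0
  gain_h[is.na(gain_h)] <- FALSE
  gain_m[is.na(gain_m)] <- FALSE
  flags <- data.frame(id = diff_h3k27ac$id, gain_h3k27ac = gain_h,
                      gain_med1 = gain_m, is_target = gain_h | gain_m,
                      stringsAsFactors = FALSE)
  counts <- list(n_h3k27ac = sum(gain_h), n_med1 = sum(gain_m),
                 n_both = sum(gain_h & gain_m),
                 n_union = sum(gain_h | gain_m))
  list(flags = flags, counts = counts)
}

SENSITIVITY_GROUPS <- c("dual", "E379K_only", "R212Q_only", "insensitive",
                        "gained", "other")

#' Classify target enhancers by mutation sensitivity
#'
#' An enhancer is *lost* by a mutant iff `padj < padj_max` and its binding
#' decreases by at least `change_frac` (ratio <= 1 - change_frac, i.e.
#' `L2FC <= log2(0.75)` at the default); *gained* is symmetric
#' (ratio >= 1 + change_frac). Groups partition the targets: `dual` (lost
#' by both), `E379K_only` / `R212Q_only` (lost by exactly one), `gained`
#' (gained by either, lost by none), `insensitive` (the rest), `other`
#' (missing from either result set, logged).
#'
#' @param diff_e379k,diff_r212q [nb_wald()] results, mutant vs WT, indexed
#'   by enhancer id.
#' @param target_ids ids of target enhancers to classify.
#' @param padj_max adjusted-p threshold; default 0.05.
#' @param change_frac minimum fractional intensity change; default 0.25.
#' @return list with `groups` (data.frame `id`, `lost_E379K`,
#'   `lost_R212Q`, `group`) and `counts` (named integer vector over the
#'   groups plus `lost_E379K`, `lost_R212Q`).
#' @export
classify_sensitivity <- function(diff_e379k, diff_r212q, target_ids,
                                 padj_max = 0.05, change_frac = 0.25) {
  lost <- function(d) {
    x <- d$padj < padj_max & d$log2FoldChange <= log2(1 - change_frac)
    x[is.na(x)] <- FALSE
    stats::setNames(x, d$id)
  }
  gained <- function(d) {
    x <- d$padj < padj_max & d$log2FoldChange >= log2(1 + change_frac)
    x[is.na(x)] <- FALSE
    stats::setNames(x, d$id)
  }
  le <- lost(diff_e379k); lr <- lost(diff_r212q)
  ge <- gained(diff_e379k); gr <- gained(diff_r212q)
  present <- target_ids %in% diff_e379k$id & target_ids %in% diff_r212q$id
  if (any(!present))
    log_msg("warning", sum(!present),
            " target enhancer(s) missing from a result set; classified 'other'")
  group <- rep("other", length(target_ids))
  lost_e <- lost_r <- rep(NA, length(target_ids))
  idx <- which(present)
  e <- le[target_ids[idx]]; r <- lr[target_ids[idx]]
  g <- ge[target_ids[idx]] | gr[target_ids[idx]]
  grp <- ifelse(e & r, "dual",
         ifelse(e, "E379K_only",
         ifelse(r, "R212Q_only",
         ifelse(g, "gained", "insensitive"))))
  group[idx] <- grp
  lost_e[idx] <- e
  lost_r[idx] <- r
  groups <- data.frame(id = target_ids, lost_E379K = lost_e,
                       lost_R212Q = lost_r,
                       group = factor(group, levels = SENSITIVITY_GROUPS),
                       stringsAsFactors = FALSE)
  counts <- table(groups$group)
  list(groups = groups,
       counts = c(as.list(counts),
                  lost_E379K = sum(lost_e, na.rm = TRUE),
                  lost_R212Q = sum(lost_r, na.rm = TRUE)))
}

#' Classify enhancer accessibility from basal ATAC signal
#'
#' Accessible iff the mean normalized nucleosome-free ATAC count in the
#' untreated condition exceeds `threshold` (strict `>`); a count exactly at
#' the threshold — which the two strict inequalities of the source
#' definition leave unassigned — is pinned to `inaccessible`.
#'
#' @param atac_norm numeric vector (or matrix of replicates, averaged) of
#'   normalized basal ATAC counts, named by enhancer id.
#' @param threshold normalized tag-count split; default 15.
#' @return data.frame `id`, `atac_basal`, `accessibility` (factor
#'   accessible/inaccessible).
#' @export
classify_accessibility <- function(atac_norm, threshold = 15) {
  if (is.matrix(atac_norm)) atac_norm <- rowMeans(atac_norm)
  if (is.null(names(atac_norm))) stop_arg("atac_norm must be named by id")
  acc <- ifelse(atac_norm > threshold, "accessible", "inaccessible")
  data.frame(id = names(atac_norm), atac_basal = unname(atac_norm),
             accessibility = factor(acc, levels = c("accessible",
                                                    "inaccessible")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag enhancers remodeled by the wild-type factor
#'
#' Gained accessibility: `padj < padj_max` and `L2FC > 0` in the WT vs
#' control ATAC differential.
#'
#' @param diff_atac [nb_wald()] result, WT vs control ATAC.
#' @param padj_max threshold; default 0.05.
#' @return list with `flags` (data.frame `id`, `remodeled`) and `n`.
#' @export
define_remodeled <- function(diff_atac, padj_max = 0.05) {
  rem <- diff_atac$padj < padj_max & diff_atac$log2FoldChange > 0
  rem[is.na(rem)] <- FALSE
  list(flags = data.frame(id = diff_atac$id, remodeled = rem,
                          stringsAsFactors = FALSE),
       n = sum(rem))
}

#' ROC AUC by the rank (Mann-Whitney) formula
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(score_pos == score_neg)`,
#' computed from midranks, so ties contribute 1/2. To evaluate "low score
#' predicts positive", negate the scores and state so in the output.
#'
#' @param scores numeric predictor values.
#' @param labels logical (or 0/1) vector; `TRUE` = positive class.
#' @param higher_predicts_positive if `FALSE`, scores are negated first.
#' @return list with `auc`, `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(scores, labels, higher_predicts_positive = TRUE) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop_arg("AUC undefined: need at least one positive and one negative")
  if (!higher_predicts_positive) scores <- -scores
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, n_pos = n1, n_neg = n0,
       direction = if (higher_predicts_positive) "higher score predicts positive"
                   else "lower score predicts positive")
}
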