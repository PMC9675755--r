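# Window quantification and a self-contained negative-binomial Wald test
# with Benjamini-Hochberg correction. The NB test is deliberately simple
# (no fold-change shrinkage, no outlier filtering, no independent
# filtering): per-feature method-of-moments dispersion, delta-method
# standard error on the log2 ratio of normalized group means, normal Wald
# p-values. At the large planted effect sizes the synthetic data uses,
# results are robust to these simplifications.

# per-assay half-windows (bp) around the peak center used for counting
ASSAY_HALF_WINDOW <- c(PPARg = 250L, H3K27ac = 1500L, Med1 = 250L, ATAC = 250L)

#' Construct a count matrix
#'
#' @param counts integer feature x sample matrix (rownames = feature ids).
#' @param samples data.frame with columns `assay`, `condition`, `replicate`.
#' @param features optional interval data.frame parallel to rows.
#' @param size_factors optional positive per-sample factors.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, features = NULL,
                         size_factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(samples),
            all(c("assay", "condition", "replicate") %in% names(samples)),
            nrow(samples) == ncol(counts))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_arg("counts must be non-negative integers")
  if (!is.null(features)) stopifnot(nrow(features) == nrow(counts))
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts))
    if (any(size_factors <= 0)) stop_arg("size factors must be positive")
  }
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(samples$assay, samples$condition,
                              samples$replicate, sep = "_")
  structure(list(counts = counts, samples = samples, features = features,
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = ", ")))
  invisible(x)
}

#' Count tags in fixed windows around feature centers
#'
#' `counts[i, j]` is the number of tags of sample `j` whose position falls
#' in `[center_i - w, center_i + w)` (half-open: a tag exactly at
#' `center + w` is not counted). The half-window `w` follows the assay of
#' each track: +/-1500 bp for H3K27ac, +/-250 bp for PPARg, Med1 and ATAC.
#' Counts are raw; no depth normalization is applied at this stage.
#'
#' @param features data.frame with `chrom` and `center` columns (peaks) —
#'   or `start`/`end`, whose midpoint is used.
#' @param tracks list of [tag_track]s; each must carry a labeled assay
#'   found in `half_window`.
#' @param half_window named half-window sizes per assay.
#' @return a [count_matrix].
#' @export
quantify <- function(features, tracks, half_window = ASSAY_HALF_WINDOW) {
  stopifnot(is.data.frame(features))
  if (is.null(features$center)) {
    if (!all(c("start", "end") %in% names(features)))
      stop_arg("features need a center (or start/end) column")
    features$center <- (features$start + features$end) %/% 2L
  }
  ids <- if (!is.null(features$id)) features$id
  else sprintf("%s:%d", features$chrom, features$center)
  samples <- do.call(rbind, lapply(tracks, function(t) {
    as.data.frame(t$label, stringsAsFactors = FALSE)
  }))
  counts <- matrix(0L, nrow = nrow(features), ncol = length(tracks),
                   dimnames = list(ids, NULL))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    assay <- tr$label$assay
    if (is.na(assay) || !assay %in% names(half_window))
      stop_arg("unknown assay for track ", j, ": ", assay)
    w <- half_window[[assay]]
    for (ch in unique(features$chrom)) {
      sel <- features$chrom == ch
      pos <- track_positions(tr, ch)
      ctr <- features$center[sel]
      counts[sel, j] <- count_in(pos, ctr - w, ctr + w)
    }
  }
  count_matrix(counts, samples, features = features)
}

#' Estimate per-sample size factors
#'
#' `total_count`: factor_j = N_j / geometric mean of the N's (library-size
#' scaling). `median_of_ratios`: DESeq-style median over features of
#' counts[i,j] / per-feature geometric mean, computed on features positive
#' in every sample, then rescaled to geometric mean 1. If no feature is
#' positive in all samples, falls back to `total_count` with a warning.
#'
#' @param cm a [count_matrix] or a counts matrix.
#' @param method `"median_of_ratios"` or `"total_count"`.
#' @return numeric vector of positive per-sample factors (geometric mean 1).
#' @export
size_factors <- function(cm, method = c("median_of_ratios", "total_count")) {
  method <- match.arg(method)
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  totals <- colSums(counts)
  if (method == "total_count") {
    if (any(totals <= 0)) stop_arg("sample with zero total count")
    return(totals / geomean(totals))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature positive in all samples; falling back to total_count")
    return(size_factors(counts, "total_count"))
  }
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  f <- apply(exp(sweep(lg, 1, ref, "-")), 2, stats::median)
  f / geomean(f)
}

#' Negative-binomial Wald test between two conditions
#'
#' Counts are normalized by size factors; the dispersion `d`
#' (Var = mu + d mu^2) is estimated per feature by method of moments on the
#' normalized counts pooled across both conditions after centering per
#' condition, floored at 1e-8. By default (`dispersion = "pooled"`) a
#' single dispersion `sum(s2 - mu) / sum(mu^2)` is shared across all
#' features — a crude form of the information sharing NB count tests rely
#' on, which keeps the Wald test calibrated at 2-3 replicates where
#' individual method-of-moments estimates are extremely noisy. The effect
#' is
#' `L2FC = log2((mean_B + min_mu) / (mean_A + min_mu))`, with delta-method
#' standard error `se^2 = (1/ln 2)^2 * sum_g (1/n_g) (1/mu_g + d)` where
#' `mu_g` is the group mean floored at `min_mu`. `z = L2FC / se`,
#' `p = 2 Phi(-|z|)`, adjusted by Benjamini-Hochberg.
#'
#' @param cm a [count_matrix].
#' @param contrast length-2 character: conditions (A, B); the fold change
#'   is B over A.
#' @param assay restrict to one assay (required if the matrix mixes assays).
#' @param min_mu pseudo-mean stabilizing L2FC and SE at low counts;
#'   default 0.5.
#' @param dispersion `"pooled"` (default), `"per_feature"`, or a fixed
#'   numeric value (required for single-replicate designs).
#' @param sf_method size-factor method when the matrix carries none.
#' @return data.frame with `id`, `baseMean`, `log2FoldChange`, `se`,
#'   `pvalue`, `padj`. All-zero features get L2FC 0, p 1.
#' @export
nb_wald <- function(cm, contrast, assay = NULL, min_mu = 0.5,
                    dispersion = "pooled",
                    sf_method = c("median_of_ratios", "total_count")) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2L)
  if (is.character(dispersion))
    dispersion <- match.arg(dispersion, c("pooled", "per_feature"))
  sf_method <- match.arg(sf_method)
  sel <- rep(TRUE, ncol(cm$counts))
  if (!is.null(assay)) sel <- cm$samples$assay == assay
  else if (length(unique(cm$samples$assay)) > 1L)
    stop_arg("matrix mixes assays; pass `assay`")
  ja <- which(sel & cm$samples$condition == contrast[[1L]])
  jb <- which(sel & cm$samples$condition == contrast[[2L]])
  if (length(ja) < 1L || length(jb) < 1L)
    stop_arg("contrast conditions not found: ",
             paste(contrast, collapse = " vs "))
  if ((length(ja) < 2L || length(jb) < 2L) && !is.numeric(dispersion))
    stop_arg("single-replicate design requires a fixed numeric `dispersion`")
  cols <- c(ja, jb)
  sf <- cm$size_factors
  if (is.null(sf)) {
    sf <- rep(NA_real_, ncol(cm$counts))
    sf[cols] <- size_factors(cm$counts[, cols, drop = FALSE], sf_method)
  }
  q <- sweep(cm$counts[, cols, drop = FALSE], 2, sf[cols], "/")
  na <- length(ja)
  nb <- length(jb)
  qa <- q[, seq_len(na), drop = FALSE]
  qb <- q[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(qa)
  mb <- rowMeans(qb)
  baseMean <- rowMeans(q)
  if (is.numeric(dispersion)) {
    if (dispersion < 0) stop_arg("dispersion must be non-negative")
    d <- rep(dispersion, nrow(q))
  } else {
    rss <- rowSums((qa - ma)^2) + rowSums((qb - mb)^2)
    s2 <- rss / (na + nb - 2L)
    mu <- (ma + mb) / 2
    d <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    d <- pmax(d, 1e-8)
    if (dispersion == "pooled") {
      # unbiased under the NB model: E[s2_i] = mu_i + d mu_i^2, so
      # d0 = sum(s2 - mu) / sum(mu^2) aggregated over features
      ok <- mu > 0
      d0 <- sum(s2[ok] - mu[ok]) / sum(mu[ok]^2)
      d <- rep(max(d0, 1e-8), nrow(q))
    }
  }
  l2fc <- log2((mb + min_mu) / (ma + min_mu))
  mua <- pmax(ma, min_mu)
  mub <- pmax(mb, min_mu)
  se <- sqrt((1 / log(2))^2 * ((1 / mua + d) / na + (1 / mub + d) / nb))
  z <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  zero <- ma == 0 & mb == 0
  l2fc[zero] <- 0
  p[zero] <- 1
  data.frame(id = rownames(q), baseMean = baseMean, log2FoldChange = l2fc,
             se = se, pvalue = p, padj = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(k) = min_{j >= k} (m / j) p_(j)`, clipped at 1, returned in the
#' input order (delegates to [stats::p.adjust()] after validation).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop_arg("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
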