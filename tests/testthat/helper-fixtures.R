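# Shared fixtures, built in code.

# tag track from a bare position vector on a single chromosome
fix_track <- function(pos, len = 50000L, chrom = "chr1", assay = "PPARg",
                      condition = "WT", replicate = 1L, strand = "+") {
  tag_track(data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                       stringsAsFactors = FALSE),
            stats::setNames(as.integer(len), chrom),
            assay, condition, replicate)
}

# uniform grid background (one tag per `by` bp), optionally excluding a window
fix_grid <- function(len, by = 100L, exclude = NULL) {
  p <- seq(by %/% 2L, len - 1L, by = by)
  if (!is.null(exclude)) p <- p[p < exclude[1L] | p >= exclude[2L]]
  p
}

# a small sharp PWM: near-deterministic consensus, for scanning tests
fix_pwm <- function(consensus = "AACTAGGTCAAAGGTCA", strength = 20) {
  b <- strsplit(consensus, "")[[1L]]
  counts <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"),
                                                    NULL))
  for (i in seq_along(b)) counts[b[i], i] <- strength
  pwm(counts, name = "fix", pseudocount = 0.05)
}

# differential-result data.frame shaped like nb_wald() output
fix_diff <- function(id, padj, l2fc, p = padj) {
  data.frame(id = id, baseMean = 100, log2FoldChange = l2fc, se = 0.1,
             pvalue = p, padj = padj, stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force scorer: best PWM placement over both strands
oracle_scan <- function(window, p) {
  lo <- log(sweep(p$probs, 1, p$background, "/"))
  L <- ncol(lo)
  revcomp_chr <- function(x) chartr("ACGTN", "TGCAN",
                                    paste(rev(strsplit(x, "")[[1L]]),
                                          collapse = ""))
  best <- NULL
  n <- nchar(window)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") window else revcomp_chr(window)
    for (o in seq_len(n - L + 1L)) {
      sub <- match(strsplit(substr(s, o, o + L - 1L), "")[[1L]],
                   rownames(lo))
      if (anyNA(sub)) next
      sc <- sum(lo[cbind(sub, seq_len(L))])
      off <- if (strand == "+") o - 1L else n - L - (o - 1L)
      cand <- list(offset = off, strand = strand, score = sc)
      if (is.null(best) || sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 &&
           (off < best$offset ||
            (off == best$offset && strand == "+" && best$strand == "-"))))
        best <- cand
    }
  }
  best
}

# independent brute-force peak caller: every window position at 1-bp steps,
# repeated greedy max (leftmost tie), then the retention filters
oracle_peaks <- function(target_pos, ctrl_pos, len, n_target, n_ctrl,
                         local_size = 20000, fold_min = 4, p_max = 1e-4,
                         width = 500) {
  n_s <- len - width + 1L
  w <- vapply(seq_len(n_s) - 1L, function(s)
    sum(target_pos >= s & target_pos < s + width), 0L)
  picked <- integer()
  avail <- rep(TRUE, n_s)
  repeat {
    cand <- which(avail & w > 0)
    if (length(cand) == 0L) break
    s <- cand[which.max(w[cand])]      # which.max returns first (leftmost)
    picked <- c(picked, s)
    avail[max(1L, s - width + 1L):min(n_s, s + width - 1L)] <- FALSE
  }
  floor_exp <- width * n_target / len
  out <- lapply(sort(picked), function(s1) {
    s <- s1 - 1L
    tags <- w[s1]
    center <- s + width %/% 2
    lo <- max(0, center - local_size / 2)
    hi <- min(len, center + local_size / 2)
    local <- sum(target_pos >= lo & target_pos < hi) - tags
    exp_local <- max(local * width / (local_size - width), floor_exp)
    ctrl <- sum(ctrl_pos >= s & ctrl_pos < s + width)
    exp_ctrl <- max(ctrl * n_target / n_ctrl, floor_exp)
    data.frame(start = s, center = center, tags = tags,
               fold_local = tags / exp_local,
               p_local = stats::ppois(tags - 1, exp_local,
                                      lower.tail = FALSE),
               fold_control = tags / exp_ctrl,
               p_control = stats::ppois(tags - 1, exp_ctrl,
                                        lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out[out$fold_local >= fold_min & out$p_local < p_max &
        out$fold_control >= fold_min, , drop = FALSE]
}
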