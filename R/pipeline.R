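# End-to-end orchestration: simulate -> tag directories -> peaks ->
# quantify -> differential tests -> enhancer taxonomy -> motif -> gene
# classes -> vicinity enrichment, with a manifest of summary counts and a
# recovery evaluation against the generator's truth table.

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full analysis on a simulated dataset
#'
#' Executes every stage of the pipeline on data drawn from `config`:
#' tag-directory construction (`tbp = 1`) and pooling of the factor ChIP
#' replicates, peak calling against the pooled control, finalization
#' (500 bp, blacklist, 35-tag floor), window quantification, NB Wald tests
#' (marks WT vs control, factor mutant vs WT, ATAC WT vs control, genes),
#' enhancer and gene classification, motif dissection and vicinity
#' enrichment. Per-stage seeds are derived from `seed`, so the run is
#' deterministic end to end.
#'
#' @param config a [sim_config()], a list of its arguments, or a path to a
#'   YAML file of them.
#' @param seed global seed.
#' @param out_dir optional directory; when given, result tables and a
#'   `manifest.json` are written there. If a manifest with the same config
#'   hash and seed already exists and all referenced files are present,
#'   the stored manifest is returned unchanged (`resumed = TRUE`).
#' @param blacklist optional interval data.frame of artifact regions.
#' @param vicinity_window TSS vicinity distance (bp) for the enrichment
#'   stage; the default 1e4 matches the toy genome's planted link
#'   distances.
#' @return a list of class `run_manifest`: `seed`, `config_hash`,
#'   per-stage summary `counts`, `results` (all stage tables) and, when
#'   `out_dir` is given, the written `paths`.
#' @export
run_all <- function(config = sim_config(), seed = 1L, out_dir = NULL,
                    blacklist = NULL, vicinity_window = 1e4) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  hash <- config_hash(list(config, blacklist, vicinity_window))
  if (!is.null(out_dir)) {
    mf <- file.path(out_dir, "manifest.json")
    if (file.exists(mf)) {
      old <- jsonlite::read_json(mf, simplifyVector = TRUE)
      if (identical(old$config_hash, hash) &&
          identical(as.integer(old$seed), as.integer(seed)) &&
          all(file.exists(file.path(out_dir, unlist(old$paths))))) {
        log_msg("info", "resuming from existing manifest in ", out_dir)
        old$resumed <- TRUE
        class(old) <- "run_manifest"
        return(old)
      }
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- stage("simulate", simulate_dataset(config, seed = seed))
  truth <- sim$truth

  # tag directories: tbp = 1; factor ChIP replicates pooled for calling
  chip <- stage("tagdir", lapply(sim$chip, make_tag_directory, tbp = 1L))
  pooled_wt <- pool_tracks(chip[grep("^PPARg\\.WT\\.", names(chip))],
                           "PPARg", "WT")
  pooled_ctrl <- pool_tracks(chip[grep("^PPARg\\.control\\.", names(chip))],
                             "PPARg", "control")

  raw_peaks <- stage("peaks", call_peaks(pooled_wt, pooled_ctrl))
  peaks <- stage("peaks", finalize_peaks(raw_peaks, blacklist = blacklist))

  tracks <- c(chip, sim$atac_nf)
  # ATAC tracks from simulate_dataset are labeled by condition/replicate
  assays <- c("PPARg", "H3K27ac", "Med1", "ATAC")
  assay_tracks <- lapply(assays, function(a)
    Filter(function(t) identical(t$label$assay, a), tracks))
  names(assay_tracks) <- assays
  cmats <- stage("quantify", lapply(assay_tracks, function(tr)
    quantify(peaks, tr)))
  # tag-directory library sizes, for "normalized count" displays
  libsizes <- lapply(assay_tracks, function(tr) vapply(tr, function(t) t$n, 0))

  diffs <- stage("diff", list(
    h3k27ac = nb_wald(cmats$H3K27ac, c("control", "WT"), assay = "H3K27ac"),
    med1 = nb_wald(cmats$Med1, c("control", "WT"), assay = "Med1"),
    pparg_e379k = nb_wald(cmats$PPARg, c("WT", "E379K"), assay = "PPARg"),
    pparg_r212q = nb_wald(cmats$PPARg, c("WT", "R212Q"), assay = "PPARg"),
    atac = nb_wald(cmats$ATAC, c("control", "WT"), assay = "ATAC")))

  targets <- stage("classify",
                   define_target_enhancers(diffs$h3k27ac, diffs$med1))
  target_ids <- targets$flags$id[targets$flags$is_target]
  sens <- stage("classify",
                classify_sensitivity(diffs$pparg_e379k, diffs$pparg_r212q,
                                     target_ids))
  # normalized basal ATAC: total-count factors rescaled to mean library size
  atac_ctrl_cols <- which(cmats$ATAC$samples$condition == "control")
  libs <- libsizes$ATAC[atac_ctrl_cols]
  norm_atac <- sweep(cmats$ATAC$counts[, atac_ctrl_cols, drop = FALSE], 2,
                     libs / mean(libs), "/")
  access <- stage("classify", classify_accessibility(rowMeans(norm_atac)))
  remodeled <- stage("classify", define_remodeled(diffs$atac))

  motifs <- stage("motif",
                  scan_peaks_motif(peaks, sim$genome, truth$pwm))

  # gene-level analysis
  expr_diffs <- stage("expression", list(
    wt = nb_wald(sim$expression, c("control", "WT"), assay = "RNA"),
    e379k = nb_wald(sim$expression, c("WT", "E379K"), assay = "RNA"),
    r212q = nb_wald(sim$expression, c("WT", "R212Q"), assay = "RNA")))
  de <- stage("expression", define_de_genes(expr_diffs$wt))
  induced_ids <- de$status$id[de$status$de_status == "induced"]
  gene_sens <- stage("expression",
                     classify_gene_sensitivity(expr_diffs$e379k,
                                               expr_diffs$r212q, induced_ids))

  # enhancer annotation table
  ann <- peaks
  ann <- merge(ann, targets$flags, by = "id", sort = FALSE)
  ann <- merge(ann, sens$groups, by = "id", all.x = TRUE, sort = FALSE)
  ann <- merge(ann, access, by = "id", sort = FALSE)
  ann <- merge(ann, remodeled$flags, by = "id", sort = FALSE)
  ann <- merge(ann, motifs[, c("id", "strand", "score", "ext5", "ppar_hs",
                               "rxr_hs", "called")],
               by = "id", all.x = TRUE, sort = FALSE)
  basal_norm <- function(assay) {
    cols <- which(cmats[[assay]]$samples$condition == "control")
    f <- libsizes[[assay]][cols] / mean(libsizes[[assay]])
    rowMeans(sweep(cmats[[assay]]$counts[, cols, drop = FALSE], 2, f, "/"))
  }
  basal_med1 <- basal_norm("Med1")
  basal_h3 <- basal_norm("H3K27ac")
  ann$basal_med1 <- basal_med1[ann$id]
  ann$basal_h3k27ac <- basal_h3[ann$id]
  ann <- sort_intervals(ann)

  # vicinity enrichment: called sensitive-enhancer groups near called
  # sensitive-gene groups, baseline from unaffected genes
  enh_groups <- ann[ann$is_target & !is.na(ann$group), ,
                    drop = FALSE][, c("chrom", "center", "group")]
  genes_tbl <- data.frame(id = truth$genes$id, chrom = truth$genes$chrom,
                          tss = truth$genes$tss, stringsAsFactors = FALSE)
  gmap <- stats::setNames(as.character(gene_sens$classes$sensitivity),
                          gene_sens$classes$id)
  genes_tbl$group <- "unaffected"
  genes_tbl$group[match(induced_ids, genes_tbl$id)] <-
    ifelse(is.na(gmap[induced_ids]), "none", gmap[induced_ids])
  enrich <- stage("enrich",
                  vicinity_enrichment(enh_groups, genes_tbl,
                                      window = vicinity_window,
                                      seed = derive_seed(seed, "enrich")))

  # recovery against truth: planted enhancer matched to a peak center
  # within 250 bp; accuracy over all planted enhancers
  truth_enh <- truth$enhancers
  assigned <- rep(NA_character_, nrow(truth_enh))
  grp_by_id <- stats::setNames(as.character(sens$groups$group),
                               sens$groups$id)
  for (i in seq_len(nrow(truth_enh))) {
    cand <- which(ann$chrom == truth_enh$chrom[i] &
                    abs(ann$center - truth_enh$center[i]) <= 250)
    if (length(cand)) {
      id <- ann$id[cand[which.min(abs(ann$center[cand] -
                                        truth_enh$center[i]))]]
      assigned[i] <- grp_by_id[id]
    }
  }
  planted_target <- truth_enh$group %in% SIM_GROUPS
  recovery_accuracy <- mean((!is.na(assigned) &
                               assigned == truth_enh$group)[planted_target])
  nontarget_fpr <- if (any(!planted_target))
    mean((assigned %in% SIM_GROUPS)[!planted_target], na.rm = FALSE)
  else NA_real_

  called_sensitive <- ann$group %in% c("dual", "E379K_only", "R212Q_only")
  roc_med1 <- tryCatch(
    roc_auc(ann$basal_med1[ann$is_target & !is.na(ann$group)],
            called_sensitive[ann$is_target & !is.na(ann$group)],
            higher_predicts_positive = FALSE),
    error = function(e) list(auc = NA_real_))
  roc_h3 <- tryCatch(
    roc_auc(ann$basal_h3k27ac[ann$is_target & !is.na(ann$group)],
            called_sensitive[ann$is_target & !is.na(ann$group)],
            higher_predicts_positive = FALSE),
    error = function(e) list(auc = NA_real_))

  counts <- list(
    peaks_called = nrow(peaks),
    n_h3k27ac = targets$counts$n_h3k27ac, n_med1 = targets$counts$n_med1,
    n_both = targets$counts$n_both, n_union = targets$counts$n_union,
    groups = lapply(sens$counts[SENSITIVITY_GROUPS], as.integer),
    lost_E379K = sens$counts$lost_E379K, lost_R212Q = sens$counts$lost_R212Q,
    n_accessible = sum(access$accessibility == "accessible"),
    n_remodeled = remodeled$n,
    de_genes = de$counts,
    gene_groups = lapply(gene_sens$counts[c("dual", "E379K_only",
                                            "R212Q_only", "insensitive",
                                            "none")], as.integer),
    recovery_accuracy = recovery_accuracy,
    nontarget_misclassified = nontarget_fpr,
    auc_basal_med1 = roc_med1$auc, auc_basal_h3k27ac = roc_h3$auc)

  manifest <- list(seed = as.integer(seed), config_hash = hash,
                   counts = counts, resumed = FALSE,
                   results = list(peaks = peaks, annotation = ann,
                                  diffs = diffs, enrichment = enrich,
                                  de_genes = de$status,
                                  gene_classes = gene_sens$classes,
                                  truth = truth_enh))
  class(manifest) <- "run_manifest"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(annotation = "enhancer_annotation.tsv",
                  peaks = "peaks.bed",
                  enrichment = "enrichment.tsv",
                  gene_classes = "gene_classes.tsv",
                  truth = "truth_enhancers.tsv")
    write_table_tsv(ann, file.path(out_dir, paths$annotation))
    pk <- peaks[, c("chrom", "start", "end", "id", "tags")]
    pk$strand <- "."
    names(pk)[4:5] <- c("name", "score")
    write_bed(pk, file.path(out_dir, paths$peaks))
    write_table_tsv(enrich, file.path(out_dir, paths$enrichment))
    write_table_tsv(gene_sens$classes, file.path(out_dir, paths$gene_classes))
    write_table_tsv(truth_enh, file.path(out_dir, paths$truth))
    manifest$paths <- paths
    slim <- manifest
    slim$results <- NULL
    jsonlite::write_json(slim, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (seed ", x$seed, ")\n", sep = "")
  cat("  peaks: ", x$counts$peaks_called,
      "; targets: ", x$counts$n_union,
      " (H3K27ac ", x$counts$n_h3k27ac, ", Med1 ", x$counts$n_med1,
      ", both ", x$counts$n_both, ")\n", sep = "")
  g <- unlist(x$counts$groups)
  cat("  groups: ", paste(names(g), g, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  recovery accuracy: ", round(x$counts$recovery_accuracy, 3),
      "; basal-Med1 AUC: ", round(x$counts$auc_basal_med1, 3), "\n", sep = "")
  invisible(x)
}

#' Validate internal consistency of a run manifest
#'
#' Checks inclusion-exclusion of the mark union, that sensitivity groups
#' partition the targets, that gene statuses partition tested genes, and
#' (for written manifests) that every referenced file exists.
#'
#' @param manifest a `run_manifest` from [run_all()].
#' @param out_dir directory holding the written files, if any.
#' @return character vector of violations (empty when consistent).
#' @export
validate_manifest <- function(manifest, out_dir = NULL) {
  v <- character()
  cc <- manifest$counts
  if (cc$n_union + cc$n_both != cc$n_h3k27ac + cc$n_med1)
    v <- c(v, sprintf("inclusion-exclusion violated: %d + %d != %d + %d",
                      cc$n_union, cc$n_both, cc$n_h3k27ac, cc$n_med1))
  gsum <- sum(unlist(cc$groups))
  if (gsum != cc$n_union)
    v <- c(v, sprintf("sensitivity groups sum to %d, expected %d (union)",
                      gsum, cc$n_union))
  de <- cc$de_genes
  if (de$total != de$induced + de$repressed)
    v <- c(v, "DE gene total != induced + repressed")
  if (!is.null(manifest$paths)) {
    if (is.null(out_dir))
      v <- c(v, "manifest references files but out_dir not given")
    else {
      missing <- !file.exists(file.path(out_dir, unlist(manifest$paths)))
      if (any(missing))
        v <- c(v, paste("missing file:",
                        unlist(manifest$paths)[missing]))
    }
  }
  v
}
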