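#' Run the full analysis pipeline on a cell table
#'
#' Orchestrates the stages in their fixed order -- preprocess, strain-level
#' phenotypes, QTL scan, QTL clustering, correlation partitioning, pleiotropy
#' classification, network clustering, allele splits for pleiotropic clusters
#' -- writing each stage's table to `out_dir` and an md5 manifest of every
#' output. All randomness derives from `seed` via [substream_seed()], so a
#' rerun with the same inputs and seed reproduces identical manifests.
#'
#' @param cells cell table (or path to one).
#' @param genotypes strains x markers matrix (or path); NULL skips the
#'   mapping, classification, and allele-split stages.
#' @param map marker map (or path); required with `genotypes`.
#' @param out_dir output directory.
#' @param control_strains two parental labels for plate correction, or NULL.
#' @param stages character subset of
#'   `c("preprocess", "scan", "partition", "network", "split")`; omitted
#'   stages (and stages whose inputs are missing) are skipped.
#' @param n_perm,scan_alpha permutation settings for the scan.
#' @param partition_alpha family-wise level of the r_B vs r_W test.
#' @param rW_threshold classification threshold on |r_W|.
#' @param network_perms permutations for the wcc null.
#' @param seed master seed.
#' @return invisible list of stage results; side effect: TSV outputs and
#'   `manifest.tsv` in `out_dir`.
#' @export
run_pipeline <- function(cells, genotypes = NULL, map = NULL, out_dir,
                         control_strains = NULL,
                         stages = c("preprocess", "scan", "partition",
                                    "network", "split"),
                         n_perm = 1000, scan_alpha = 0.05,
                         partition_alpha = 0.01, rW_threshold = 0.2,
                         network_perms = 100, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(cells)) cells <- read_cell_table(cells)
  if (is.character(genotypes)) genotypes <- read_genotype_table(genotypes)
  if (is.character(map)) map <- read_marker_map(map)
  res <- list()
  emit <- function(obj, file) {
    write.table(obj, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  tab <- cells
  if ("preprocess" %in% stages) {
    pp <- preprocess_cells(tab, control_strains = control_strains)
    tab <- pp$table
    res$preprocess <- pp$report
    emit(pp$report$h2, "heritability.tsv")
    write_cell_table(tab, file.path(out_dir, "cells_preprocessed.tsv"))
  }

  if ("scan" %in% stages && !is.null(genotypes)) {
    if (is.null(map)) stop("scan stage needs a marker map")
    pheno <- strain_phenotypes(tab, strains = rownames(genotypes))
    hits <- scan_all(pheno, genotypes, map, n_perm = n_perm,
                     alpha = scan_alpha, seed = substream_seed(seed, 11L))
    clusters <- cluster_qtl(hits)
    res$hits <- hits; res$clusters <- clusters
    emit(hits, "qtl_hits.tsv"); emit(clusters, "qtl_clusters.tsv")
  }

  if ("partition" %in% stages) {
    part <- partition_all(tab, alpha = partition_alpha)
    res$partitions <- part
    emit(part, "partitions.tsv")
    if (!is.null(res$clusters) && nrow(res$clusters)) {
      calls <- classify_pairs(part, res$clusters, rW_threshold)
      res$calls <- calls
      res$enrichment <- enrichment_summary(calls, rW_threshold)
      emit(calls, "pleiotropy_calls.tsv")
    }
  }

  if ("network" %in% stages && !is.null(res$partitions)) {
    res$network <- list()
    for (ty in unique(res$partitions$cell_type)) {
      w <- rw_network(res$partitions, ty)
      if (nrow(w) < 3) next
      res$network[[ty]] <- network_permutation_null(
        w, n_perm = network_perms, seed = substream_seed(seed, 21L))
      emit(data.frame(trait = rownames(w),
                      wcc = as.numeric(res$network[[ty]]$observed)),
           paste0("wcc_", ty, ".tsv"))
    }
  }

  if ("split" %in% stages && !is.null(res$clusters) &&
      !is.null(res$partitions) && nrow(res$clusters)) {
    splits <- list()
    pleio <- res$clusters[res$clusters$degree >= 2, , drop = FALSE]
    for (i in seq_len(nrow(pleio))) {
      mk <- select_split_marker(pleio[i, ], res$hits, map)
      sp <- tryCatch(
        split_and_repartition(tab, genotypes, mk, alpha = partition_alpha),
        error = function(e) { message("split skipped: ", conditionMessage(e)); NULL })
      if (is.null(sp)) next
      sp$cluster_id <- pleio$cluster_id[i]
      splits[[length(splits) + 1]] <- sp
    }
    if (length(splits)) {
      res$splits <- do.call(rbind, splits)
      emit(res$splits, "allele_splits.tsv")
    }
  }

  files <- setdiff(list.files(out_dir), "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = as.vector(tools::md5sum(file.path(out_dir, files))))
  emit(manifest, "manifest.tsv")
  res$manifest <- manifest
  invisible(res)
}
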