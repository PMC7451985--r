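#' Read and validate a cell-level trait table
#'
#' TSV with a header row; required columns `strain`, `replicate`, `cell_type`
#' (values among unbudded/small/large); every non-metadata column is a trait
#' and must be numeric (NA for traits outside a cell's type).
#'
#' @param path file path.
#' @return validated data.frame (a `cell_id` is added when absent).
#' @export
read_cell_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (col in c("strain", "replicate", "cell_type")) {
    if (!col %in% names(tab)) stop("missing required column: ", col)
  }
  bad <- setdiff(unique(tab$cell_type), .cell_types)
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  for (tr in trait_cols(tab)) {
    if (!is.numeric(tab[[tr]])) {
      row <- which(is.na(suppressWarnings(as.numeric(tab[[tr]]))) &
                     !is.na(tab[[tr]]))[1]
      stop("non-numeric trait value in column '", tr, "' at data row ", row)
    }
  }
  if (!"cell_id" %in% names(tab))
    tab$cell_id <- sprintf("c%07d", seq_len(nrow(tab)))
  tab
}

#' Write a cell table (TSV, header, NA for missing)
#' @param table cell table.
#' @param path output path.
#' @export
write_cell_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a strain x marker genotype table
#'
#' TSV: first column `strain`, remaining columns biallelic codes. Accepts
#' -1/+1 directly or any two labels (mapped to -1/+1 in sorted order).
#'
#' @param path file path.
#' @return numeric matrix with strain rownames.
#' @export
read_genotype_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (names(tab)[1] != "strain") stop("first column must be 'strain'")
  g <- as.matrix(tab[, -1, drop = FALSE])
  vals <- sort(unique(as.vector(g)))
  if (!all(vals %in% c(-1, 1))) {
    if (length(vals) != 2) stop("genotypes must be biallelic")
    g <- matrix(ifelse(g == vals[1], -1, 1), nrow(g), ncol(g),
                dimnames = dimnames(g))
  }
  storage.mode(g) <- "double"
  rownames(g) <- tab$strain
  g
}

#' Write a genotype table
#' @param genotypes strains x markers matrix.
#' @param path output path.
#' @export
write_genotype_table <- function(genotypes, path) {
  df <- data.frame(strain = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker map (TSV: marker, chromosome, position_cM)
#' @param path file path.
#' @return validated map data.frame.
#' @export
read_marker_map <- function(path) {
  map <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .validate_map(map)
  map
}

#' @rdname read_marker_map
#' @param map map data.frame.
#' @export
write_marker_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load simulation ground truth losslessly
#'
#' `sim_truth` objects (configs, matrices, truth tables) are serialized to
#' structured JSON text so that round-tripping through disk preserves every
#' value bit-for-bit.
#'
#' @param truth a `sim_truth` object.
#' @param path file path (conventionally `.json`).
#' @return `write_sim_truth`: the path; `read_sim_truth`: the object.
#' @export
write_sim_truth <- function(truth, path) {
  writeLines(jsonlite::serializeJSON(truth, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Generate a bundled demonstration fixture
#'
#' Deterministic miniature datasets for examples and tests:
#' \describe{
#'   \item{cross-demo}{60 strains x 30 markers (3 chromosomes), 200 cells per
#'     strain, 12 traits in one cell type, one QTL of each mechanism.}
#'   \item{ma-demo}{24 lines, 300 cells each, 6 traits, 2 altered lines.}
#'   \item{dose-demo}{20 strains, 3 doses with growing correlation shifts.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory (created if needed); NULL returns the objects
#'   without writing.
#' @param seed fixture seed (default 20).
#' @return list of generated objects (and written `paths` when `dir` given).
#' @export
make_fixture <- function(name = c("cross-demo", "ma-demo", "dose-demo"),
                         dir = NULL, seed = 20L) {
  name <- match.arg(name)
  tr12 <- sprintf("t%03d_unbudded", 1:12)
  base <- function(n_tr, rho_block) {
    C <- diag(n_tr)
    C[1, 2] <- C[2, 1] <- rho_block
    C
  }
  if (name == "cross-demo") {
    cfg <- sim_config(
      n_strains = 60, n_markers = 30, n_chromosomes = 3, chrom_length_cM = 150,
      n_traits_per_celltype = c(12, 0, 0), cells_per_strain = 200,
      base_within_corr = base(12, 0.4),
      qtl_spec = list(
        qtl_effect(5, "vertical", traits = tr12[3:5], beta = 0.6, loading = 0.6),
        qtl_effect(15, "direct_horizontal", traits = tr12[6:7], beta = 0.8),
        qtl_effect(25, "corr_modifying", pair = tr12[8:9], rho0 = 0.1, delta = 0.6)),
      cellcycle_spec = data.frame(trait = tr12,
                                  shape = rep(c("monotone", "bump", "none"), 4),
                                  amplitude = 0.6),
      strain_var = 0.08, seed = seed)
    sim <- simulate_cells(cfg)
    out <- list(config = cfg, cells = sim$cells, truth = sim$truth)
  } else if (name == "ma-demo") {
    cfg <- sim_config(n_strains = 2, n_markers = 2, n_chromosomes = 1,
                      chrom_length_cM = 100,
                      n_traits_per_celltype = c(6, 0, 0),
                      base_within_corr = base(6, 0.1),
                      cells_per_strain = 10, seed = seed)
    pr <- list(c("t001_unbudded", "t002_unbudded"))
    sim <- simulate_ma_panel(cfg, n_lines = 24, n_altered = 2, pairs = pr,
                             delta = 0.6, cells_per_line = 300)
    out <- list(config = cfg, cells = sim$cells, truth = sim$truth)
  } else {
    cfg <- sim_config(n_strains = 20, n_markers = 6, n_chromosomes = 1,
                      chrom_length_cM = 100,
                      n_traits_per_celltype = c(4, 0, 0),
                      base_within_corr = base(4, 0.2),
                      cells_per_strain = 150, seed = seed)
    sim <- simulate_dose_series(cfg, doses = c(8.5, 25, 100),
                                shifts = c(0.05, 0.15, 0.3),
                                pairs = list(c("t001_unbudded", "t002_unbudded")))
    out <- list(config = cfg, cells = sim$cells, truth = sim$truth)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(cells = file.path(dir, paste0(name, "-cells.tsv")),
               truth = file.path(dir, paste0(name, "-truth.json")))
    write_cell_table(out$cells, paths["cells"])
    write_sim_truth(out$truth, paths["truth"])
    if (!is.null(out$truth$genotypes)) {
      paths["genotypes"] <- file.path(dir, paste0(name, "-geno.tsv"))
      paths["map"] <- file.path(dir, paste0(name, "-map.tsv"))
      write_genotype_table(out$truth$genotypes, paths["genotypes"])
      write_marker_map(out$truth$map, paths["map"])
    }
    out$paths <- paths
  }
  out
}
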