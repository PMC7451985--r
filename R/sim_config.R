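#' Simulation configuration
#'
#' Bundles the generative assumptions for the synthetic mapping panel:
#' genome/map geometry, trait counts per cell type, hierarchical variance
#' components, a within-strain (cell-level) correlation structure, QTL effects,
#' cell-cycle trajectories, and plate effects. Defaults emulate the study
#' conditions of the yeast cross the package models: 374 homozygous recombinant
#' strains genotyped at 225 markers over 16 chromosomes (~4,076 cM map), three
#' replicate plates, on average 800 clonal cells per strain, and 167
#' morphological traits split 28/47/92 among unbudded, small-budded and
#' large-budded cells, with broad-sense heritability kept under ~15% because
#' cell-cycle progression dominates within-strain variation.
#'
#' @param n_strains number of recombinant strains.
#' @param n_markers total marker count (spread evenly over chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM numeric vector of map lengths (cM), recycled to
#'   `n_chromosomes`.
#' @param n_traits_per_celltype integer vector of three trait counts, named or
#'   ordered as unbudded/small/large. A count of zero drops that cell type.
#' @param cells_per_strain clonal cells sampled per strain (pooled over
#'   replicates).
#' @param n_replicates number of replicate plates.
#' @param qtl_spec list of [qtl_effect()] objects.
#' @param base_within_corr within-strain (cell-noise) trait correlation: either
#'   NULL (identity), a single matrix (applied to the one nonempty cell type)
#'   or a list of matrices, one per nonempty cell type.
#' @param strain_var variance of the strain (genetic background) random effect,
#'   scalar or per-trait.
#' @param cell_var variance of cell-level noise, scalar or per-trait.
#' @param strain_corr correlation of strain random effects across traits
#'   (same shapes accepted as `base_within_corr`); default identity.
#' @param cellcycle_spec data.frame with columns `trait`, `shape`
#'   (`"none"`, `"monotone"`, `"bump"`) and `amplitude`, or NULL for the
#'   default: alternating monotone/bump trajectories of amplitude 1 on every
#'   trait, mimicking asynchronous exponential-phase sampling where cell-cycle
#'   position drives most within-strain variation.
#' @param plate_effect_sd SD of the additive per-(replicate x trait) plate
#'   effect.
#' @param trait_baseline baseline trait mean (keeps raw values positive, as
#'   morphometric features are).
#' @param include_parents if TRUE, [simulate_cells()] also emits cells for the
#'   two parental genotypes (all-wine and all-oak alleles) on every plate,
#'   labelled `parent_wine`/`parent_oak`, for use as plate-correction controls.
#' @param parent_cells_per_plate cells per parent per plate when
#'   `include_parents` is TRUE.
#' @param seed master seed for all randomness derived from this config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 374,
                       n_markers = 225,
                       n_chromosomes = 16,
                       chrom_length_cM = 4076 / 16,
                       n_traits_per_celltype = c(unbudded = 28, small = 47, large = 92),
                       cells_per_strain = 800,
                       n_replicates = 3,
                       qtl_spec = list(),
                       base_within_corr = NULL,
                       strain_var = 0.08,
                       cell_var = 1,
                       strain_corr = NULL,
                       cellcycle_spec = NULL,
                       plate_effect_sd = 0.1,
                       trait_baseline = 10,
                       include_parents = FALSE,
                       parent_cells_per_plate = 50,
                       seed = 1L) {
  stopifnot(n_strains >= 1, n_markers >= 1, n_chromosomes >= 1,
            cells_per_strain >= 1, n_replicates >= 1)
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  if (any(chrom_length_cM < 0)) stop("chromosome lengths must be nonnegative")
  nt <- rep_len(as.integer(n_traits_per_celltype), 3L)
  names(nt) <- .cell_types
  n_traits <- sum(nt)
  if (n_traits < 1) stop("need at least one trait")
  trait_type <- rep(.cell_types, times = nt)
  traits <- sprintf("t%03d_%s", seq_len(n_traits), trait_type)

  expand_var <- function(v, what) {
    v <- rep_len(v, n_traits)
    if (any(v < 0)) stop(what, " must be nonnegative")
    setNames(v, traits)
  }
  strain_var <- expand_var(strain_var, "strain_var")
  cell_var <- expand_var(cell_var, "cell_var")

  if (is.null(cellcycle_spec)) {
    cellcycle_spec <- data.frame(
      trait = traits,
      shape = rep_len(c("monotone", "bump"), n_traits),
      amplitude = 1,
      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("trait", "shape", "amplitude") %in% names(cellcycle_spec)))
    miss <- setdiff(traits, cellcycle_spec$trait)
    if (length(miss))
      cellcycle_spec <- rbind(cellcycle_spec,
                              data.frame(trait = miss, shape = "none", amplitude = 0))
    cellcycle_spec <- cellcycle_spec[match(traits, cellcycle_spec$trait), ]
  }
  if (!all(cellcycle_spec$shape %in% c("none", "monotone", "bump")))
    stop("unknown trajectory shape")
  if (any(!is.finite(cellcycle_spec$amplitude)))
    stop("trait trajectories must be bounded")

  cfg <- structure(list(
    n_strains = as.integer(n_strains),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = chrom_length_cM,
    n_traits_per_celltype = nt,
    traits = traits,
    trait_type = setNames(trait_type, traits),
    cells_per_strain = as.integer(cells_per_strain),
    n_replicates = as.integer(n_replicates),
    qtl_spec = qtl_spec,
    base_within_corr = .expand_corr(base_within_corr, nt, traits, trait_type),
    strain_var = strain_var,
    cell_var = cell_var,
    strain_corr = .expand_corr(strain_corr, nt, traits, trait_type),
    cellcycle_spec = cellcycle_spec,
    plate_effect_sd = plate_effect_sd,
    trait_baseline = trait_baseline,
    include_parents = isTRUE(include_parents),
    parent_cells_per_plate = as.integer(parent_cells_per_plate),
    seed = as.integer(seed)), class = "sim_config")
  for (q in qtl_spec) .validate_qtl(q, cfg)
  cfg
}

# Normalize a correlation spec to one matrix per nonempty cell type.
.expand_corr <- function(corr, nt, traits, trait_type) {
  types <- names(nt)[nt > 0]
  out <- lapply(types, function(ty) {
    tr <- traits[trait_type == ty]
    m <- diag(length(tr))
    dimnames(m) <- list(tr, tr)
    m
  })
  names(out) <- types
  if (is.null(corr)) return(out)
  if (is.matrix(corr)) {
    if (length(types) != 1)
      stop("a single correlation matrix needs a single nonempty cell type")
    corr <- setNames(list(corr), types)
  }
  for (ty in names(corr)) {
    m <- corr[[ty]]
    tr <- traits[trait_type == ty]
    if (!all(dim(m) == length(tr)))
      stop("correlation matrix for cell type '", ty, "' has wrong dimension")
    if (max(abs(m - t(m))) > 1e-8) stop("correlation matrix must be symmetric")
    dimnames(m) <- list(tr, tr)
    .check_psd(m, paste0("within-strain correlation (", ty, ")"))
    out[[ty]] <- m
  }
  out
}

.check_psd <- function(m, what) {
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop(what, " is not positive semi-definite")
  invisible(TRUE)
}

#' Declare a QTL effect for the simulator
#'
#' Three mechanisms mirror the ways a locus can couple traits:
#' \describe{
#'   \item{vertical}{the QTL shifts a shared latent factor with loadings
#'     `loading` on `traits`; the same factor fluctuates cell-to-cell, so the
#'     target traits are correlated within strains *and* jointly shifted by
#'     the allele -- pleiotropy via an inherent trait relationship.}
#'   \item{direct_horizontal}{the QTL shifts each target trait mean by
#'     `beta` (trait units per allele substitution, alleles coded -1/+1)
#'     with no within-strain coupling -- the locus itself induces the
#'     between-strain correlation.}
#'   \item{corr_modifying}{the allele changes the within-strain correlation of
#'     a trait `pair` from `rho0` (reference allele) to `rho0 + delta`
#'     (alternate allele) without changing trait marginals; with
#'     `strain_coupling = TRUE` (default) the strain-effect correlation of the
#'     pair is modified identically, so genetic variation hitting one trait
#'     propagates to the other only in the strengthened-allele background.}
#' }
#'
#' @param marker marker index (column of the genotype table).
#' @param mechanism one of `"vertical"`, `"direct_horizontal"`,
#'   `"corr_modifying"`.
#' @param traits target trait names (vertical / direct_horizontal).
#' @param beta effect size: scalar latent-factor shift (vertical) or per-trait
#'   mean shift (direct_horizontal), per allele substitution.
#' @param loading latent-factor loadings in (0,1), recycled over `traits`
#'   (vertical only).
#' @param pair length-2 trait names (corr_modifying only); must share a cell
#'   type.
#' @param rho0,delta within-strain correlation of `pair` for the -1 allele and
#'   its change for the +1 allele; both `rho0` and `rho0 + delta` must lie in
#'   (-1, 1).
#' @param strain_coupling also apply the per-allele correlation to the strain
#'   random effects of `pair` (corr_modifying only).
#' @return an object of class `qtl_effect`.
#' @export
qtl_effect <- function(marker, mechanism,
                       traits = NULL, beta = NULL, loading = 0.6,
                       pair = NULL, rho0 = NULL, delta = NULL,
                       strain_coupling = TRUE) {
  mechanism <- match.arg(mechanism,
                         c("vertical", "direct_horizontal", "corr_modifying"))
  if (mechanism == "corr_modifying") {
    stopifnot(length(pair) == 2, is.numeric(rho0), is.numeric(delta))
    if (abs(rho0) >= 1 || abs(rho0 + delta) >= 1)
      stop("rho0 and rho0 + delta must lie in (-1, 1)")
  } else {
    stopifnot(length(traits) >= 1, is.numeric(beta))
    if (mechanism == "vertical") {
      loading <- rep_len(loading, length(traits))
      if (any(loading <= 0 | loading >= 1))
        stop("vertical loadings must lie in (0, 1)")
    } else {
      beta <- rep_len(beta, length(traits))
    }
  }
  structure(list(marker = as.integer(marker), mechanism = mechanism,
                 traits = traits, beta = beta, loading = loading,
                 pair = pair, rho0 = rho0, delta = delta,
                 strain_coupling = isTRUE(strain_coupling)),
            class = "qtl_effect")
}

.validate_qtl <- function(q, cfg) {
  if (q$marker < 1 || q$marker > cfg$n_markers)
    stop("qtl marker index out of range")
  tg <- if (q$mechanism == "corr_modifying") q$pair else q$traits
  if (!all(tg %in% cfg$traits))
    stop("qtl targets unknown trait(s): ", paste(setdiff(tg, cfg$traits), collapse = ", "))
  if (length(unique(cfg$trait_type[tg])) != 1)
    stop("qtl targets must share one cell type (traits of different cell ",
         "types are never measured in the same cell)")
  invisible(TRUE)
}

# Deterministic cell-cycle trajectory value at pseudotime u in [0,1].
# The monotone cubic keeps a strictly positive slope (>= amplitude) so the
# trait-space curve never folds; the bump is a single Gaussian peak.
.traj_value <- function(shape, amplitude, u) {
  switch(shape,
         none = rep(0, length(u)),
         monotone = amplitude * ((2 * u - 1)^3 + (2 * u - 1)) / 2,
         bump = amplitude * exp(-(u - 0.5)^2 / (2 * 0.15^2)),
         stop("unknown trajectory shape"))
}

# Moments of trajectory functions under U(0,1) pseudotime, used to record the
# expected pooled within-strain correlation in SimTruth.
.traj_moments <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    u <- seq(0, 1, length.out = 20001)
    f <- cbind(none = rep(0, length(u)),
               monotone = ((2 * u - 1)^3 + (2 * u - 1)) / 2,
               bump = exp(-(u - 0.5)^2 / (2 * 0.15^2)))
    f <- sweep(f, 2, colMeans(f))
    cache <<- crossprod(f) / length(u)  # covariance of unit-amplitude shapes
    cache
  }
})
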