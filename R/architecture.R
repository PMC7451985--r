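#' Example mapping panel with all three pleiotropy mechanisms
#'
#' Builds (and optionally simulates) a validation panel in the regime the
#' package targets: recombinant strains phenotyped for 36 traits of one cell
#' type with default cell-cycle trajectories, carrying five QTL of each
#' mechanism on separate chromosomes:
#' \itemize{
#'   \item 5 vertical QTL, each acting on a trait triple through a shared
#'     latent factor (loading 0.65, factor shift 0.4 per allele
#'     substitution): target pairs correlate within clones (r_W ~ 0.35 after
#'     trajectory dilution) and the locus shifts all three traits through the
#'     factor -- multi-trait targets also keep the locus's per-trait peaks
#'     chained into a single cluster under the 5-cM rule;
#'   \item 5 direct-horizontal QTL (beta 0.45 on each trait of an otherwise
#'     weakly correlated pair, base within-strain correlation 0.1): r_B is
#'     driven far above r_W;
#'   \item 5 correlation-modifying QTL (within-strain correlation 0.05 for one
#'     allele vs 0.75 for the other, with matching strain-effect coupling,
#'     plus a mean shift of 0.25 on both traits -- the mean effect is what
#'     makes such loci detectable in a scan; the correlation effect is what
#'     sets their mode apart).
#' }
#' Truth labels for every target pair are attached for recovery scoring. The
#' expected classification is `vertical-consistent` for vertical pairs and
#' `horizontal-candidate` for direct-horizontal pairs; under the allele
#' split, direct-horizontal loci drop r_B in both allele subsets,
#' correlation-modifying loci in exactly one (the weak-coupling background).
#'
#' @param n_strains,cells_per_strain panel size (defaults 100 x 500, the
#'   scaled validation regime).
#' @param seed master seed.
#' @param simulate if TRUE (default) also run [simulate_cells()].
#' @return list with `config`, `pair_truth` (data.frame `pair_id`, `trait_x`,
#'   `trait_y`, `mechanism`, `marker`), and (when simulated) `cells`, `truth`.
#' @export
make_architecture_sim <- function(n_strains = 100, cells_per_strain = 500,
                                  seed = 1L, simulate = TRUE) {
  tr <- sprintf("t%03d_unbudded", 1:36)
  base <- diag(36); dimnames(base) <- list(tr, tr)
  qtl <- list(); truth_rows <- list()
  # one QTL per chromosome, at the middle marker (10 markers/chromosome)
  mk_mid <- function(chr) (chr - 1) * 10 + 5
  for (i in 1:5) {   # vertical: trait triples (t1..t3) .. (t13..t15)
    trio <- tr[(3 * i - 2):(3 * i)]
    qtl[[length(qtl) + 1]] <- qtl_effect(mk_mid(i), "vertical", traits = trio,
                                         beta = 0.4, loading = 0.65)
    pairs <- combn(trio, 2)
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(trait_x = pairs[1, ], trait_y = pairs[2, ],
                 mechanism = "vertical", marker = mk_mid(i))
  }
  for (i in 1:5) {   # direct horizontal: pairs (t16,t17) .. (t24,t25)
    pair <- tr[c(2 * i + 14, 2 * i + 15)]
    base[pair[1], pair[2]] <- base[pair[2], pair[1]] <- 0.1
    qtl[[length(qtl) + 1]] <- qtl_effect(mk_mid(i + 5), "direct_horizontal",
                                         traits = pair, beta = 0.45)
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(trait_x = pair[1], trait_y = pair[2],
                 mechanism = "direct_horizontal", marker = mk_mid(i + 5))
  }
  for (i in 1:5) {   # correlation-modifying: pairs (t26,t27) .. (t34,t35)
    pair <- tr[c(2 * i + 24, 2 * i + 25)]
    # such loci are detectable as QTL because they also shift the trait
    # means; the correlation effect is what distinguishes their mode
    qtl[[length(qtl) + 1]] <- qtl_effect(mk_mid(i + 10), "corr_modifying",
                                         pair = pair, rho0 = 0.05, delta = 0.7)
    qtl[[length(qtl) + 1]] <- qtl_effect(mk_mid(i + 10), "direct_horizontal",
                                         traits = pair, beta = 0.25)
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(trait_x = pair[1], trait_y = pair[2],
                 mechanism = "corr_modifying", marker = mk_mid(i + 10))
  }
  config <- sim_config(
    n_strains = n_strains, n_markers = 150, n_chromosomes = 15,
    chrom_length_cM = 100, n_traits_per_celltype = c(36, 0, 0),
    cells_per_strain = cells_per_strain, base_within_corr = base,
    qtl_spec = qtl, strain_var = 0.08, seed = seed)
  pair_truth <- do.call(rbind, truth_rows)
  pair_truth$pair_id <- paste(pair_truth$trait_x, pair_truth$trait_y, sep = "|")
  out <- list(config = config, pair_truth = pair_truth)
  if (simulate) {
    sim <- simulate_cells(config)
    out$cells <- sim$cells
    out$truth <- sim$truth
  }
  out
}

#' Example panel where a correlation discrepancy is pure cell-cycle mixing
#'
#' Ten traits of one cell type with strong cell-cycle trajectories and low
#' residual noise (so pseudotime is recoverable). The focal pair (traits 1 and
#' 2, monotone vs bump trajectory, so their trajectory covariance is zero) has
#' within-strain noise correlation 0.6 and strain-effect correlation 0.9: the
#' pooled r_W is heavily diluted by the asynchronous cell cycle (~0.06) while
#' r_B stays high (~0.85), a discrepancy that conditioning on cell-cycle
#' position should largely resolve. A second pair (traits 3 and 4, no
#' trajectories) carries a correlation-modifying QTL (with the mean effect
#' that makes such loci mappable) instead; its discrepancy is genetic and
#' should *not* resolve under binning but should resolve under the allele
#' split.
#'
#' @param n_strains,cells_per_strain panel size (defaults 20 x 400).
#' @param seed master seed.
#' @return list with `config`, `cells`, `truth`, `focal_pair`, `cm_pair`.
#' @export
make_mixing_sim <- function(n_strains = 20, cells_per_strain = 400, seed = 1L) {
  tr <- sprintf("t%03d_unbudded", 1:10)
  base <- diag(10); dimnames(base) <- list(tr, tr)
  base[1, 2] <- base[2, 1] <- 0.6
  scorr <- diag(10); dimnames(scorr) <- list(tr, tr)
  scorr[1, 2] <- scorr[2, 1] <- 0.9
  config <- sim_config(
    n_strains = n_strains, n_markers = 20, n_chromosomes = 2,
    chrom_length_cM = 100, n_traits_per_celltype = c(10, 0, 0),
    cells_per_strain = cells_per_strain,
    base_within_corr = base, strain_corr = scorr,
    strain_var = 0.1, cell_var = 0.15, plate_effect_sd = 0.02,
    qtl_spec = list(qtl_effect(15, "corr_modifying", pair = tr[3:4],
                               rho0 = 0.05, delta = 0.7),
                    qtl_effect(15, "direct_horizontal", traits = tr[3:4],
                               beta = 0.4)),
    cellcycle_spec = data.frame(trait = tr,
                                shape = rep(c("monotone", "bump"), 5),
                                amplitude = c(3, 3, 0, 0, rep(3, 6))),
    seed = seed)
  sim <- simulate_cells(config)
  list(config = config, cells = sim$cells, truth = sim$truth,
       focal_pair = paste(tr[1], tr[2], sep = "|"),
       cm_pair = paste(tr[3], tr[4], sep = "|"))
}
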