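# Shared small simulations, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# tiny flat config helper: one cell type, no trajectories/plates by default
flat_config <- function(n_traits = 2, n_strains = 20, cells = 200,
                        rho = 0, strain_var = 0.1, cell_var = 1,
                        qtl = list(), seed = 1, n_markers = 6,
                        traj_amplitude = 0, plate_sd = 0, ...) {
  tr <- sprintf("t%03d_unbudded", seq_len(n_traits))
  C <- diag(n_traits)
  if (n_traits >= 2) C[1, 2] <- C[2, 1] <- rho
  sim_config(n_strains = n_strains, n_markers = n_markers, n_chromosomes = 1,
             chrom_length_cM = 100,
             n_traits_per_celltype = c(n_traits, 0, 0),
             cells_per_strain = cells, base_within_corr = C,
             strain_var = strain_var, cell_var = cell_var,
             cellcycle_spec = data.frame(trait = tr,
                                         shape = rep_len(c("monotone", "bump"), n_traits),
                                         amplitude = traj_amplitude),
             plate_effect_sd = plate_sd, qtl_spec = qtl, seed = seed, ...)
}

cross_demo <- function() cached("cross_demo", make_fixture("cross-demo"))
ma_demo <- function() cached("ma_demo", make_fixture("ma-demo"))
dose_demo <- function() cached("dose_demo", make_fixture("dose-demo"))

# a small hierarchical table with known structure for partition tests
toy_hier <- function(seed = 4, J = 15, n = 40, rho_w = 0.4, rho_b = 0.7) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(J)), each = n)
  sb <- matrix(rnorm(2 * J), J)
  sb[, 2] <- rho_b * sb[, 1] + sqrt(1 - rho_b^2) * sb[, 2]
  e1 <- rnorm(J * n); e2 <- rho_w * e1 + sqrt(1 - rho_w^2) * rnorm(J * n)
  data.frame(strain = g, x = sb[rep(seq_len(J), each = n), 1] + e1,
             y = sb[rep(seq_len(J), each = n), 2] + e2)
}

# brute-force weighted clustering oracle: explicit triangle enumeration
wcc_bruteforce <- function(w) {
  if (max(w) == 0) return(rep(0, nrow(w)))
  w <- w / max(w)
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    num <- 0; den <- 0
    for (j in others) for (k in setdiff(others, j)) {
      num <- num + w[i, j] * w[j, k] * w[k, i]
      den <- den + w[i, j] * w[i, k]
    }
    if (den <= 1e-14) 0 else num / den
  })
}
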