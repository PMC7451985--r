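test_that("zero variances and no QTL give exactly the baseline", {
  cfg <- flat_config(n_traits = 3, n_strains = 3, cells = 10,
                     strain_var = 0, cell_var = 0, seed = 6)
  sim <- simulate_cells(cfg)
  vals <- as.matrix(sim$cells[, trait_cols(sim$cells)])
  expect_true(all(vals == cfg$trait_baseline))
})

test_that("pooled within-strain correlation converges to the configured value", {
  cfg <- flat_config(n_traits = 2, n_strains = 100, cells = 1000, rho = 0.5,
                     seed = 12)
  sim <- simulate_cells(cfg)   # 100,000 pooled cells
  tb <- sim$cells
  w1 <- tb$t001_unbudded - ave(tb$t001_unbudded, tb$strain)
  w2 <- tb$t002_unbudded - ave(tb$t002_unbudded, tb$strain)
  expect_lt(abs(cor(w1, w2) - 0.5), 0.02)
})

test_that("a mean-shifting QTL reproduces its moment prediction", {
  q <- qtl_effect(3, "direct_horizontal", traits = "t001_unbudded", beta = 1)
  cfg <- flat_config(n_traits = 1, n_strains = 400, cells = 400,
                     strain_var = 0, qtl = list(q), seed = 13)
  sim <- simulate_cells(cfg)
  sm <- tapply(sim$cells$t001_unbudded, sim$cells$strain, mean)
  g <- sim$truth$genotypes[names(sm), 3]
  # allele-group mean difference ~ 2 beta; between-strain variance ~ beta^2
  expect_lt(abs(mean(sm[g == 1]) - mean(sm[g == -1]) - 2), 0.05)
  expect_lt(abs(var(sm) - 1), 0.15)
})

test_that("correlation-modifying QTL change r_W per allele without touching marginals", {
  q <- qtl_effect(2, "corr_modifying", pair = sprintf("t%03d_unbudded", 1:2),
                  rho0 = 0.1, delta = 0.6)
  cfg <- flat_config(n_traits = 2, n_strains = 120, cells = 400,
                     qtl = list(q), strain_var = 0.05, seed = 14)
  sim <- simulate_cells(cfg)
  tb <- sim$cells
  g <- sim$truth$genotypes[, 2]
  rw <- sapply(c(-1, 1), function(a) {
    s <- tb$strain %in% rownames(sim$truth$genotypes)[g == a]
    w1 <- tb$t001_unbudded[s] - ave(tb$t001_unbudded[s], tb$strain[s])
    w2 <- tb$t002_unbudded[s] - ave(tb$t002_unbudded[s], tb$strain[s])
    cor(w1, w2)
  })
  expect_lt(abs(rw[1] - 0.1), 0.05)
  expect_lt(abs(rw[2] - 0.7), 0.05)
  # marginal SDs identical across allele backgrounds (Gaussian copula claim)
  s1 <- tapply(tb$t001_unbudded - ave(tb$t001_unbudded, tb$strain),
               tb$strain %in% rownames(sim$truth$genotypes)[g == 1], sd)
  expect_lt(abs(s1[1] - s1[2]), 0.03)
})

test_that("identical seeds give bit-identical cell tables and truth", {
  cfg <- flat_config(n_traits = 2, n_strains = 10, cells = 50, rho = 0.3,
                     traj_amplitude = 1, plate_sd = 0.1, seed = 77)
  a <- simulate_cells(cfg); b <- simulate_cells(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
})

test_that("sim truth round-trips through file I/O losslessly", {
  sim <- simulate_cells(flat_config(n_traits = 2, n_strains = 5, cells = 20,
                                    rho = 0.2, seed = 3))
  path <- tempfile(fileext = ".json")
  write_sim_truth(sim$truth, path)
  back <- read_sim_truth(path)
  expect_identical(back$genotypes, sim$truth$genotypes)
  expect_identical(back$pseudotime, sim$truth$pseudotime)
  expect_identical(back$sigma_cells, sim$truth$sigma_cells)
})

test_that("expected pooled r_W accounts for trajectory dilution", {
  cfg <- flat_config(n_traits = 2, n_strains = 60, cells = 800, rho = 0.5,
                     traj_amplitude = 2, seed = 21)
  sim <- simulate_cells(cfg)
  tp <- sim_truth_pairs(sim$truth,
                        pairs = list(sprintf("t%03d_unbudded", 1:2)))
  tb <- sim$cells
  w1 <- tb$t001_unbudded - ave(tb$t001_unbudded, tb$strain)
  w2 <- tb$t002_unbudded - ave(tb$t002_unbudded, tb$strain)
  expect_lt(tp$r_w_expected, 0.3)     # strong dilution below the noise rho
  expect_lt(abs(cor(w1, w2) - tp$r_w_expected), 0.02)
})

test_that("degenerate configs error informatively", {
  expect_error(flat_config(rho = 1.5), "positive semi-definite")
  expect_error(
    qtl_effect(1, "corr_modifying", pair = c("a", "b"), rho0 = 0.6, delta = 0.6),
    "must lie in")
  expect_error(
    sim_config(n_traits_per_celltype = c(2, 2, 0),
               qtl_spec = list(qtl_effect(1, "direct_horizontal",
                                          traits = c("t001_unbudded", "t003_small"),
                                          beta = 1))),
    "share one cell type")
})
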