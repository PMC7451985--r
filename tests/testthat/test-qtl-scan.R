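toy_geno <- function(n = 100, m = 5, seed = 7) {
  set.seed(seed)
  g <- matrix(sample(c(-1, 1), n * m, TRUE), n, m,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("m%02d", 1:m)))
  map <- data.frame(marker = colnames(g), chromosome = 1,
                    position_cM = seq(0, 80, by = 20))
  list(g = g, map = map)
}

test_that("strain phenotype means collapse cells correctly", {
  tab <- data.frame(strain = c("a", "a", "a", "b", "b"), replicate = 1,
                    cell_type = "unbudded", tA = c(1, 2, 3, 7, 7))
  ph <- strain_phenotypes(tab)
  expect_equal(ph["a", "tA"], 2)
  expect_equal(ph["b", "tA"], 7)
})

test_that("marker LOD matches the closed form and is affine invariant", {
  tg <- toy_geno()
  set.seed(8)
  y <- 0.8 * tg$g[, 3] + rnorm(100)
  sc <- hk_scan(y, tg$g, tg$map)
  k <- which(sc$at_marker)[3]
  r2 <- cor(y, tg$g[, 3])^2
  expect_equal(sc$lod[k], -(100 / 2) * log10(1 - r2), tolerance = 1e-10)
  sc2 <- hk_scan(3.7 * y - 11, tg$g, tg$map)
  expect_equal(sc2$lod, sc$lod, tolerance = 1e-10)
  # reference point: n = 100, R^2 = 0.2 -> LOD = 4.845
  expect_equal(-(100 / 2) * log10(1 - 0.2), 4.845, tolerance = 5e-4)
})

test_that("pseudomarkers between identical flanks carry the shared genotype", {
  set.seed(9)
  g <- cbind(m1 = sample(c(-1, 1), 80, TRUE))
  g <- cbind(g, m2 = g[, 1])   # identical flanking markers
  rownames(g) <- sprintf("s%02d", 1:80)
  map <- data.frame(marker = c("m1", "m2"), chromosome = 1,
                    position_cM = c(0, 20))
  y <- g[, 1] + rnorm(80, sd = 0.5)
  sc <- hk_scan(y, g, map, step_cM = 10)
  mid <- which(sc$position_cM == 10)
  expect_equal(sc$lod[mid], sc$lod[sc$position_cM == 0], tolerance = 1e-10)
})

test_that("permutation p-values follow the plus-one rule and degenerate inputs behave", {
  tg <- toy_geno(seed = 10)
  y <- 2 * tg$g[, 2] + rnorm(100, sd = 0.3)   # enormous signal
  pt <- perm_threshold(y, tg$g, tg$map, n_perm = 100, seed = 1)
  sc <- hk_scan(y, tg$g, tg$map)
  expect_equal(pt$p_value(max(sc$lod)), 1 / 101)
  expect_error(perm_threshold(y, tg$g, tg$map, n_perm = 50), "at least 100")
  # constant phenotype: flat scan, zero threshold
  yc <- rep(1, 100)
  expect_warning(scc <- hk_scan(yc, tg$g, tg$map), "monomorphic")
  expect_true(all(scc$lod == 0))
  ptc <- suppressWarnings(perm_threshold(yc, tg$g, tg$map, n_perm = 100, seed = 1))
  expect_equal(ptc$threshold, 0)
})

test_that("BH q-values match hand computation", {
  expect_equal(fdr_across_traits(c(0.01, 0.02, 0.03, 1)),
               c(0.04, 0.04, 0.04, 1))
  expect_equal(fdr_across_traits(1), 1)
  expect_equal(fdr_across_traits(0.2), 0.2)  # single test: q = p
  expect_equal(fdr_across_traits(rep(1, 5)), rep(1, 5))
})

test_that("clustering follows the 5-cM chaining rule", {
  h <- data.frame(trait = c("a", "b"), chromosome = 1, position_cM = c(10, 16))
  expect_equal(nrow(cluster_qtl(h)), 2)            # gap 6 -> separate
  h2 <- data.frame(trait = c("a", "b", "c"), chromosome = 1,
                   position_cM = c(10, 12, 13.5))
  cl2 <- cluster_qtl(h2)                           # all gaps <= 2 -> one
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$degree, 3)
  h3 <- data.frame(trait = sprintf("t%02d", 1:30), chromosome = 2,
                   position_cM = seq(0, 29))
  expect_warning(cl3 <- cluster_qtl(h3), "spans")
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$span_cM, 29)
})

test_that("effect sizes are the allele-group contrast over the parental difference", {
  tg <- toy_geno(seed = 11)
  ph <- matrix(0.1 * tg$g[, 2], 100, 1, dimnames = list(rownames(tg$g), "tA"))
  hit <- data.frame(trait = "tA", chromosome = 1, position_cM = 20)
  pm <- matrix(c(0.5, -0.5), 2, 1, dimnames = list(NULL, "tA"))
  es <- effect_size(hit, ph, tg$g, tg$map, pm)
  expect_equal(unname(es["effect"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(es["fraction"]), 0.2, tolerance = 1e-12)  # 20% of parents
  pm0 <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(NULL, "tA"))
  expect_true(is.nan(effect_size(hit, ph, tg$g, tg$map, pm0)["fraction"]))
})

test_that("a pleiotropic QTL is recovered as one cluster with full degree", {
  tr5 <- sprintf("t%03d_unbudded", 1:5)
  q <- qtl_effect(3, "direct_horizontal", traits = tr5, beta = 0.8)
  cfg <- flat_config(n_traits = 5, n_strains = 120, cells = 150,
                     qtl = list(q), seed = 51)
  sim <- simulate_cells(cfg)
  ph <- strain_phenotypes(sim$cells)
  hits <- scan_all(ph, sim$truth$genotypes, sim$truth$map,
                   n_perm = 200, seed = 52)
  cl <- cluster_qtl(hits)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$degree, 5)
})
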