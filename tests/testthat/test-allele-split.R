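test_that("the most-represented marker is chosen, ties to the lower position", {
  map <- data.frame(marker = sprintf("m%02d", 1:12), chromosome = 15,
                    position_cM = seq(0, 55, by = 5))
  one <- data.frame(trait = "a", chromosome = 15, position_cM = 20)
  cl1 <- data.frame(chromosome = 15, start_cM = 20, end_cM = 20)
  expect_equal(select_split_marker(cl1, one, map), "m05")
  # hits nearest markers (m9, m9, m9, m8, m10, m11) -> m9
  hits <- data.frame(trait = letters[1:6], chromosome = 15,
                     position_cM = c(40, 41, 40, 35, 45, 50))
  cl <- data.frame(chromosome = 15, start_cM = 35, end_cM = 50)
  expect_equal(select_split_marker(cl, hits, map), "m09")
  tie <- data.frame(trait = c("a", "b"), chromosome = 15,
                    position_cM = c(10, 30))
  clt <- data.frame(chromosome = 15, start_cM = 10, end_cM = 30)
  expect_equal(select_split_marker(clt, tie, map), "m03")
})

test_that("splitting at a neutral marker leaves r_B within the noise band", {
  fx <- cross_demo()
  tab <- fx$cells; geno <- fx$truth$genotypes
  pair <- "t001_unbudded|t002_unbudded"     # base-correlated, no QTL
  sp <- split_and_repartition(tab, geno, "m001", pairs = pair)
  band <- split_noise_band(tab, geno, "m001", pairs = pair,
                           n_reps = 60, seed = 9)
  expect_lt(max(abs(c(sp$delta_rb_neg, sp$delta_rb_pos))), 1.5 * band)
  expect_equal(classify_mode(sp, band)$mode, "none")
})

test_that("direct and correlation-modifying QTL show their two modes", {
  fx <- cross_demo()
  tab <- fx$cells; geno <- fx$truth$genotypes
  band <- split_noise_band(tab, geno, "m015",
                           pairs = c("t006_unbudded|t007_unbudded",
                                     "t008_unbudded|t009_unbudded"),
                           n_reps = 60, seed = 10)
  dh <- split_and_repartition(tab, geno, "m015",
                              pairs = "t006_unbudded|t007_unbudded")
  expect_equal(classify_mode(dh, band)$mode, "both-drop")
  expect_gt(min(dh$delta_rb_neg, dh$delta_rb_pos), band)
})

test_that("delta thresholds map onto modes", {
  res <- data.frame(delta_rb_neg = c(0.1, 0.1, 0.01),
                    delta_rb_pos = c(0.1, -0.01, 0.01))
  expect_equal(classify_mode(res, 0.02)$mode,
               c("both-drop", "one-drop", "none"))
})

test_that("the union of the two allele subsets reproduces the full partition", {
  fx <- cross_demo()
  tab <- fx$cells; geno <- fx$truth$genotypes
  g <- geno[, "m010"]
  union_tab <- rbind(
    tab[tab$strain %in% rownames(geno)[g == -1], ],
    tab[tab$strain %in% rownames(geno)[g == 1], ])
  p_all <- partition_all(tab[tab$strain %in% rownames(geno), ])
  p_union <- partition_all(union_tab)
  expect_equal(p_union$r_w, p_all$r_w, tolerance = 1e-12)
  expect_equal(p_union$r_b, p_all$r_b, tolerance = 1e-12)
})

test_that("mean-shifting QTL leave r_W essentially unchanged under the split", {
  fx <- cross_demo()
  sp <- split_and_repartition(fx$cells, fx$truth$genotypes, "m015")
  med <- median(abs(c(sp$delta_rw_neg, sp$delta_rw_pos)), na.rm = TRUE)
  expect_lt(med, 0.02)
})

test_that("undersized allele subsets abort the split", {
  fx <- cross_demo()
  geno <- fx$truth$genotypes
  geno[, "m001"] <- c(rep(-1, 2), rep(1, nrow(geno) - 2))
  expect_error(split_and_repartition(fx$cells, geno, "m001"), "fewer than")
})
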