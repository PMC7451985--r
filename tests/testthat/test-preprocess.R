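make_raw <- function(n = 300, seed = 1) {
  set.seed(seed)
  data.frame(strain = rep(sprintf("s%02d", 1:10), each = n / 10),
             replicate = rep(1:3, length.out = n),
             cell_type = "unbudded",
             tA = rnorm(n, 10), tB = rnorm(n, 10),
             stringsAsFactors = FALSE)
}

test_that("traits over the missingness threshold are dropped, cells completed", {
  raw <- make_raw()
  raw$tA[seq_len(33)] <- NA           # 11% missing -> dropped
  out <- filter_missing(raw, 0.10)
  expect_false("tA" %in% trait_cols(out$table))
  expect_true("tB" %in% trait_cols(out$table))

  raw2 <- make_raw()
  out2 <- filter_missing(raw2, 0.10)  # nothing missing -> identity
  expect_identical(out2$table, raw2)
  expect_equal(out2$report$cells_dropped, 0)

  raw3 <- make_raw()
  raw3$tB[5] <- NA                    # retained trait, incomplete cell
  out3 <- filter_missing(raw3, 0.10)
  expect_equal(nrow(out3$table), nrow(raw3) - 1)
})

test_that("Box-Cox lambda search lands on log for lognormal data and near 1 for Gaussian", {
  set.seed(2)
  n <- 2000
  g <- rep(sprintf("s%02d", 1:10), each = n / 10)
  tab <- data.frame(strain = g, replicate = 1, cell_type = "unbudded",
                    tLog = exp(rnorm(n, sd = 0.8) + rep(rnorm(10), each = n / 10)),
                    tNorm = rnorm(n, mean = 50, sd = 2),
                    stringsAsFactors = FALSE)
  out <- boxcox_by_strain(tab)
  lam <- setNames(out$report$lambda, out$report$trait)
  expect_lt(abs(lam["tLog"]), 0.15)
  expect_lt(abs(lam["tNorm"] - 1), 0.35)
  # log branch: y = e -> exactly 1
  expect_equal(pleioscope:::.boxcox_apply(exp(1), 0), 1)
  # constant trait flagged, untouched
  tab$tConst <- 5
  rep2 <- boxcox_by_strain(tab)$report
  expect_true(rep2$skipped[rep2$trait == "tConst"])
})

test_that("plate correction removes injected plate offsets", {
  raw <- make_raw(n = 300, seed = 3)
  ctrl <- data.frame(strain = rep(c("pW", "pO"), each = 300),
                     replicate = rep(1:3, 200), cell_type = "unbudded",
                     tA = rnorm(600, 10), tB = rnorm(600, 10))
  tab <- rbind(raw, ctrl)
  # exactly identical control values on every plate -> zero offsets
  same <- tab
  same$tA[same$strain %in% c("pW", "pO")] <- rep(c(9, 11), 300)
  out0 <- plate_correct(same, c("pW", "pO"))
  expect_equal(max(abs(out0$report$offset[out0$report$trait == "tA"])), 0)
  expect_equal(out0$table$tA, same$tA)
  # +2 plate shift: the plate's cells move down by 2 * (1 - 1/3) after
  # centering the offsets across the 3 plates (control noise ~ 0.06 SE)
  shifted <- tab
  shifted$tA[shifted$replicate == 2] <- shifted$tA[shifted$replicate == 2] + 2
  out <- plate_correct(shifted, c("pW", "pO"))
  delta <- out$table$tA - shifted$tA
  expect_lt(abs(mean(delta[tab$replicate == 2]) + 2 * 2 / 3), 0.25)
  expect_lt(abs(mean(delta[tab$replicate == 1]) - 2 / 3), 0.25)
  expect_error(plate_correct(raw, c("pW", "pO")), "missing on plate")
})

test_that("plate correction drives residual control variance to zero", {
  cfg <- flat_config(n_traits = 2, n_strains = 20, cells = 100,
                     plate_sd = 0.5, seed = 41, include_parents = TRUE)
  sim <- simulate_cells(cfg)
  out <- plate_correct(sim$cells, c("parent_wine", "parent_oak"))
  ctrl <- out$table[out$table$strain %in% c("parent_wine", "parent_oak"), ]
  mp <- tapply(ctrl$t001_unbudded, list(ctrl$replicate, ctrl$strain), mean)
  raw_mp <- tapply(sim$cells$t001_unbudded[sim$cells$strain %in% c("parent_wine", "parent_oak")],
                   list(sim$cells$replicate[sim$cells$strain %in% c("parent_wine", "parent_oak")],
                        sim$cells$strain[sim$cells$strain %in% c("parent_wine", "parent_oak")]),
                   mean)
  expect_lt(max(apply(mp, 2, sd)), max(apply(raw_mp, 2, sd)))
  expect_lt(max(apply(mp, 2, sd)), 0.25)
})

test_that("the 5-SD outlier rule removes exactly the injected cell", {
  raw <- make_raw(seed = 5)
  base <- outlier_filter(raw, k = 5)
  expect_identical(base$table, raw)     # all |z| <= 5
  raw$tA[7] <- 10 + 6 * sd(raw$tA)
  out <- outlier_filter(raw, k = 5)
  expect_equal(out$report$cells_dropped, 1)
  expect_false(7 %in% as.integer(rownames(out$table)))
  expect_identical(outlier_filter(raw, k = Inf)$table, raw)
})

test_that("heritability recovers variance components and clips at the edges", {
  set.seed(6)
  J <- 200; n <- 50
  g <- rep(sprintf("s%03d", 1:J), each = n)
  y <- rep(rnorm(J, sd = 1), each = n) + rnorm(J * n, sd = 3)  # H2 = 1/10
  tab <- data.frame(strain = g, replicate = 1, cell_type = "unbudded", tA = y)
  expect_lt(abs(heritability(tab, "tA") - 0.10), 0.02)
  tab$tB <- rnorm(J * n)                       # no strain signal
  expect_lt(heritability(tab, "tB"), 0.01)
  tab$tC <- rep(rnorm(J), each = n)            # no within-strain noise
  expect_equal(heritability(tab, "tC"), 1)
  expect_error(heritability(tab[tab$strain == "s001", ], "tA"), "single strain")
})

test_that("preprocessing is idempotent with the filters disabled", {
  fx <- cross_demo()
  pp <- preprocess_cells(fx$cells)
  again <- filter_missing(pp$table, 0.10)$table
  again <- outlier_filter(again, k = Inf)$table
  expect_identical(again, pp$table)
})
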