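mixing <- function() cached("mixing", make_mixing_sim(seed = 2))
mixing_pt <- function() cached("mixing_pt", {
  mx <- mixing()
  infer_pseudotime(mx$cells, "unbudded",
                   anchor = list(trait = "t001_unbudded", extreme = "min"))
})

test_that("pseudotime recovers the true ordering on low-noise trajectories", {
  mx <- mixing()
  pt <- mixing_pt()
  truth <- mx$truth$pseudotime[names(pt)]
  expect_gte(abs(cor(pt, truth, method = "spearman")), 0.9)
  expect_true(all(pt >= 0 & pt <= 1))
})

test_that("reversing the anchor flips the ordering exactly", {
  mx <- mixing()
  pt <- mixing_pt()
  pt2 <- infer_pseudotime(mx$cells, "unbudded",
                          anchor = list(trait = "t001_unbudded", extreme = "max"))
  expect_equal(unname(pt2), unname(1 - pt), tolerance = 1e-12)
})

test_that("pure-noise input still yields a valid ranking in [0, 1]", {
  set.seed(40)
  tab <- data.frame(strain = "s01", replicate = 1, cell_type = "unbudded",
                    tA = rnorm(300), tB = rnorm(300), tC = rnorm(300))
  tab$cell_id <- sprintf("c%03d", 1:300)
  pt <- infer_pseudotime(tab, "unbudded", anchor = 1, k = 15)
  expect_equal(sort(unique(pt)), (0:299) / 299)
  expect_error(infer_pseudotime(tab[1:100, ], "unbudded", anchor = 1),
               "at least 200")
})

test_that("binning is equal-count per strain and pools rank windows", {
  set.seed(41)
  tab <- data.frame(strain = rep(c("a", "b"), c(32, 37)), replicate = 1,
                    cell_type = "unbudded", tA = rnorm(69))
  tab$cell_id <- sprintf("c%03d", 1:69)
  pt <- setNames(runif(69), tab$cell_id)
  b <- bin_cells(tab, pt, n_bins = 16)
  ca <- table(b$bin[b$strain == "a"])
  expect_true(all(ca == 2))                       # 32 cells, 16 bins
  cb <- table(b$bin[b$strain == "b"])
  expect_lte(diff(range(cb)), 1)                  # counts differ by <= 1
  # bin b contains only cells from rank-window b of each strain
  for (s in c("a", "b")) {
    sel <- b[b$strain == s, ]
    expect_true(all(tapply(sel$pseudotime, sel$bin, max) ==
                      cummax(tapply(sel$pseudotime, sel$bin, max))))
  }
  # a strain with too few cells is excluded and reported
  small <- tab; small$strain[1:60] <- "a"; small$strain[61:69] <- "tiny"
  b2 <- bin_cells(small, pt, n_bins = 16)
  expect_false("tiny" %in% b2$strain)
  expect_match(attr(b2, "excluded"), "tiny")
})

test_that("per-bin r_W is stationary when the correlation does not depend on pseudotime", {
  cfg <- flat_config(n_traits = 2, n_strains = 10, cells = 640, rho = 0.6,
                     seed = 42)
  sim <- simulate_cells(cfg)
  b <- bin_cells(sim$cells, setNames(sim$cells$pseudotime, sim$cells$cell_id),
                 n_bins = 16)
  ser <- per_bin_partition(b)
  expect_equal(nrow(ser), 16)                     # 16 rows per pair, 1 pair
  expect_lt(max(abs(ser$r_w_bin - 0.6)), 0.15)
  expect_lt(abs(mean(ser$r_w_bin) - 0.6), 0.05)
})

test_that("percent resolved follows its arithmetic, floor and cap", {
  mk <- function(rw_bins, rw = 0.15, rb = 0.40) {
    data.frame(pair_id = "p", cell_type = "unbudded", trait_x = "x",
               trait_y = "y", bin = seq_along(rw_bins), r_w_bin = rw_bins,
               r_w = rw, r_b = rb, r_b_adj = rb, significant = TRUE)
  }
  expect_equal(percent_resolved(mk(c(0.10, 0.30, 0.2)))$percent_resolved, 60)
  expect_equal(percent_resolved(mk(c(0.10, 0.12)))$percent_resolved, 0)
  expect_equal(percent_resolved(mk(c(0.10, 0.40)))$percent_resolved, 100)
  expect_equal(percent_resolved(mk(c(0.10, 0.55)))$percent_resolved, 100)
  # no discrepancy -> excluded
  expect_equal(nrow(percent_resolved(mk(c(0.5), rw = 0.5, rb = 0.4))), 0)
})

test_that("cell-cycle mixing resolves under binning; a genetic discrepancy does not", {
  mx <- mixing()
  pt <- mixing_pt()
  b <- bin_cells(mx$cells, pt, n_bins = 16)
  ser <- per_bin_partition(b, pairs = c(mx$focal_pair, mx$cm_pair))
  pr <- percent_resolved(ser)
  expect_gte(pr$percent_resolved[pr$pair_id == mx$focal_pair], 50)
  expect_lte(pr$percent_resolved[pr$pair_id == mx$cm_pair], 35)
  # the genetic pair resolves under the allele split instead
  sp <- split_and_repartition(mx$cells, mx$truth$genotypes, "m015",
                              pairs = mx$cm_pair)
  expect_gte(sp$percent_resolved, 80)
})
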