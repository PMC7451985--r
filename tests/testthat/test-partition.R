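test_that("decomposition identity and eta normalization hold on random data", {
  set.seed(10)
  for (i in 1:50) {
    J <- sample(3:10, 1); n <- sample(3:20, 1)
    g <- rep(seq_len(J), each = n)
    x <- rnorm(J * n) + rep(rnorm(J), each = n)
    y <- rnorm(J * n) + rep(rnorm(J), each = n)
    p <- partition_pair(x, y, g)
    expect_lt(abs(p$eta_bx^2 + p$eta_wx^2 - 1), 1e-10)
    expect_lt(abs(p$eta_by^2 + p$eta_wy^2 - 1), 1e-10)
    expect_lt(abs(p$r_total -
                    (p$eta_bx * p$eta_by * p$r_b + p$eta_wx * p$eta_wy * p$r_w)),
              1e-10)
  }
})

test_that("r_B equals the size-weighted correlation of group means", {
  tab <- toy_hier(seed = 11, J = 12, n = 25)
  tab <- tab[-(1:7), ]                      # unbalance the groups
  p <- partition_pair(tab$x, tab$y, tab$strain)
  wts <- as.vector(table(tab$strain))
  mx <- tapply(tab$x, tab$strain, mean); my <- tapply(tab$y, tab$strain, mean)
  wcor <- function(a, b, w) {
    am <- sum(w * a) / sum(w); bm <- sum(w * b) / sum(w)
    sum(w * (a - am) * (b - bm)) /
      sqrt(sum(w * (a - am)^2) * sum(w * (b - bm)^2))
  }
  expect_equal(p$r_b, wcor(mx, my, wts), tolerance = 1e-12)
})

test_that("degenerate groupings are rejected and two balanced groups give |r_B| = 1", {
  x <- rnorm(40); y <- rnorm(40)
  expect_error(partition_pair(x, y, rep(1, 40)), "at least 2 groups")
  g2 <- rep(1:2, each = 20)
  p <- partition_pair(x + g2, y + 2 * g2, g2)
  expect_equal(abs(p$r_b), 1)
  xw <- rep(c(1, 2), 20)  # no within-group variance
  expect_error(partition_pair(rep(g2, 1), y, g2), "zero within-group")
})

test_that("groups with identical means put all weight on r_W", {
  g <- rep(1:4, each = 10)
  x <- rep(rnorm(10), 4); y <- rep(rnorm(10), 4)
  x <- x - ave(x, g); y <- y - ave(y, g)   # every group mean exactly 0
  p <- partition_pair(x + 5, y + 5, g)
  expect_lt(p$eta_bx, 1e-8)
  expect_true(is.na(p$r_b))
  expect_equal(p$r_total, p$r_w, tolerance = 1e-10)
})

test_that("r_W ignores strain-level shifts and r_B ignores within-strain noise", {
  tab <- toy_hier(seed = 12)
  p0 <- partition_pair(tab$x, tab$y, tab$strain)
  shift <- rnorm(length(unique(tab$strain)))[as.integer(factor(tab$strain))]
  p1 <- partition_pair(tab$x + 3 * shift, tab$y, tab$strain)
  expect_equal(p1$r_w, p0$r_w, tolerance = 1e-12)
  noise <- rnorm(nrow(tab))
  noise <- noise - ave(noise, tab$strain)   # mean-zero within every strain
  p2 <- partition_pair(tab$x + noise, tab$y, tab$strain)
  expect_equal(p2$r_b, p0$r_b, tolerance = 1e-12)
})

test_that("the r-to-z comparison reproduces its reference values", {
  expect_equal(round(critical_z(0.01, 5645), 2), 4.64)
  expect_lt(abs(critical_z(0.01, 5645) - 4.63), 0.01)
  z0 <- compare_rB_rW(list(r_b = 0.4, r_w = 0.4, j = 100, n = 5000), m = 10)
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  zx <- compare_rB_rW(list(r_b = 0.5, r_w = 0.1, j = 374, n = 300000), m = 1)
  expect_equal(zx$z, 8.64, tolerance = 0.005)
  expect_warning(
    compare_rB_rW(list(r_b = 1, r_w = 0.2, j = 50, n = 1000), m = 1),
    "capped")
  expect_error(compare_rB_rW(list(r_b = 0.2, r_w = 0.1, j = 3, n = 100)),
               "J >= 4")
})

test_that("sign adjustment penalizes opposite-sign components", {
  p <- partition_pair(toy_hier(13)$x, toy_hier(13)$y, toy_hier(13)$strain)
  expect_equal(pleioscope:::.sign_adjust(-0.5, 0.2), -0.5)
  expect_equal(pleioscope:::.sign_adjust(-0.5, -0.2), 0.5)
  expect_equal(pleioscope:::.sign_adjust(0.5, 0.2), 0.5)
})

test_that("partition_all forms within-type pairs only, with the right counts", {
  set.seed(14)
  n <- 240
  tab <- data.frame(strain = rep(sprintf("s%02d", 1:6), each = 40),
                    replicate = 1,
                    cell_type = rep(c("unbudded", "small", "large"), n / 3))
  for (t in sprintf("u%d", 1:3)) tab[[t]] <- ifelse(tab$cell_type == "unbudded", rnorm(n), NA)
  for (t in sprintf("s%d", 1:4)) tab[[t]] <- ifelse(tab$cell_type == "small", rnorm(n), NA)
  tab$l1 <- ifelse(tab$cell_type == "large", rnorm(n), NA)
  part <- partition_all(tab)
  expect_equal(nrow(part), choose(3, 2) + choose(4, 2))   # large: 1 trait, 0 pairs
  expect_true(all(part$cell_type %in% c("unbudded", "small")))
  expect_equal(attr(part, "m"), nrow(part))
  # the printed pair totals: trait counts (28, 47, 92) -> 5,645 pairs
  expect_equal(choose(28, 2) + choose(47, 2) + choose(92, 2), 5645)
})

test_that("partition_all matches partition_pair record by record", {
  fx <- cross_demo()
  tab <- fx$cells
  part <- partition_all(tab)
  i <- match("t003_unbudded|t004_unbudded", part$pair_id)
  p <- partition_pair(tab$t003_unbudded, tab$t004_unbudded, tab$strain)
  expect_equal(part$r_w[i], p$r_w, tolerance = 1e-12)
  expect_equal(part$r_b[i], p$r_b, tolerance = 1e-12)
  expect_equal(part$eta_bx[i], p$eta_bx, tolerance = 1e-12)
})

test_that("pseudo-strain permutation preserves group sizes and seed determinism", {
  fx <- cross_demo()
  tab <- fx$cells
  null1 <- pseudo_strain_null(tab, seed = 5)
  null2 <- pseudo_strain_null(tab, seed = 5)
  expect_identical(null1, null2)
  # same machinery: permuting labels keeps the group-size multiset
  set.seed(5)
  perm <- tab
  for (ty in unique(perm$cell_type)) {
    idx <- which(perm$cell_type == ty)
    perm$strain[idx] <- perm$strain[idx][sample.int(length(idx))]
  }
  expect_identical(sort(as.vector(table(perm$strain, perm$cell_type))),
                   sort(as.vector(table(tab$strain, tab$cell_type))))
  # z-scores across permuted pairs behave like a standard normal
  expect_lt(abs(mean(null1$z)), 0.5)
  expect_lt(abs(sd(null1$z) - 1), 0.35)
})
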