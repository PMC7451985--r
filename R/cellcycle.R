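#' Infer cell-division pseudotime from morphological traits
#'
#' Single-branch diffusion-map ordering: traits of the chosen cell type are
#' standardized, a k-nearest-neighbor graph is built (Euclidean distance,
#' adaptive Gaussian kernel with per-cell bandwidth set to the k-th neighbor
#' distance), and the leading nontrivial eigenvector of the symmetrized
#' random-walk operator is extracted by deterministic power iteration. Cells
#' are ranked along that coordinate, oriented so the anchor cell sits at 0,
#' and ranks are rescaled to [0, 1]. If the kNN graph is disconnected, k is
#' doubled with a warning until it connects.
#'
#' @param table a cell table.
#' @param cell_type which cell type to order (>= 200 cells required).
#' @param anchor start-cell selector: either a row index into the cell-type
#'   subset / a `cell_id`, or a list `list(trait =, extreme = "min"|"max")`
#'   naming a trait whose extreme marks the start of division.
#' @param k neighbors for the graph (default 30).
#' @return numeric vector of pseudotimes in [0, 1], named by `cell_id`,
#'   aligned to the cells of `cell_type` (in table order).
#' @export
infer_pseudotime <- function(table, cell_type, anchor, k = 30) {
  idx <- which(table$cell_type == cell_type)
  if (length(idx) < 200) stop("need at least 200 cells of type ", cell_type)
  tr <- trait_cols(table)
  sub <- as.matrix(table[idx, tr, drop = FALSE])
  sub <- sub[, colSums(!is.na(sub)) > 0, drop = FALSE]
  keep <- complete.cases(sub)
  if (!all(keep)) { idx <- idx[keep]; sub <- sub[keep, , drop = FALSE] }
  X <- scale(sub)
  X[!is.finite(X)] <- 0
  n <- nrow(X)

  a_idx <- .resolve_anchor(table, idx, X, anchor)

  repeat {
    nn <- .knn(X, min(k, n - 1))
    g <- igraph::graph_from_edgelist(
      cbind(rep(seq_len(n), each = ncol(nn$idx)), as.vector(t(nn$idx))),
      directed = FALSE)
    if (igraph::components(g)$no == 1) break
    warning("kNN graph disconnected at k = ", k, "; increasing k")
    k <- min(2 * k, n - 1)
  }

  # adaptive Gaussian affinities on the kNN edges
  sigma <- nn$dist[, ncol(nn$dist)]
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  i <- rep(seq_len(n), each = ncol(nn$idx))
  j <- as.vector(t(nn$idx))
  d <- as.vector(t(nn$dist))
  aff <- exp(-d^2 / (sigma[i] * sigma[j]))
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(aff, aff) / 2,
                            dims = c(n, n))
  dg <- Matrix::rowSums(W)
  dg[dg == 0] <- 1e-12
  Dh <- 1 / sqrt(dg)
  M <- W * (Dh %o% Dh)   # symmetrized random-walk operator

  # leading eigvec is sqrt(degree); deflate it, then power-iterate
  u1 <- sqrt(dg) / sqrt(sum(dg))
  v <- seq_len(n) - (n + 1) / 2
  v <- v / sqrt(sum(v^2))
  for (it in seq_len(2000)) {
    v_new <- as.numeric(M %*% v)
    v_new <- v_new - sum(u1 * v_new) * u1
    nv <- sqrt(sum(v_new^2))
    if (nv < 1e-300) break
    v_new <- v_new / nv
    if (max(abs(v_new - v)) < 1e-10 || max(abs(v_new + v)) < 1e-10) {
      v <- v_new; break
    }
    v <- v_new
  }
  psi <- v / sqrt(dg)    # diffusion coordinate
  rk <- rank(psi, ties.method = "first")
  pt <- (rk - 1) / (n - 1)
  if (pt[a_idx] > 0.5) pt <- 1 - pt
  names(pt) <- table$cell_id[idx]
  pt
}

.resolve_anchor <- function(table, idx, X, anchor) {
  if (is.list(anchor)) {
    stopifnot(!is.null(anchor$trait))
    v <- table[[anchor$trait]][idx]
    if (identical(anchor$extreme, "max")) which.max(v) else which.min(v)
  } else if (is.character(anchor)) {
    m <- match(anchor, table$cell_id[idx])
    if (is.na(m)) stop("anchor cell_id not found in this cell type")
    m
  } else {
    stopifnot(anchor >= 1, anchor <= nrow(X))
    as.integer(anchor)
  }
}

# Brute-force kNN in blocks (self excluded).
.knn <- function(X, k) {
  n <- nrow(X)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  xs <- rowSums(X^2)
  bs <- max(1L, floor(2e7 / n))
  for (s in seq(1, n, by = bs)) {
    e <- min(s + bs - 1, n)
    D2 <- outer(xs[s:e], xs, "+") - 2 * tcrossprod(X[s:e, , drop = FALSE], X)
    D2[cbind(seq_len(e - s + 1), s:e)] <- Inf
    for (r in seq_len(e - s + 1)) {
      o <- order(D2[r, ])[seq_len(k)]
      idx[s + r - 1, ] <- o
      dst[s + r - 1, ] <- sqrt(pmax(D2[r, o], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' Assign cells to equal-count pseudotime bins per strain
#'
#' Within each strain (and cell type), cells are split into `n_bins`
#' equal-count quantile bins by pseudotime; like bins are then pooled across
#' strains so genotype representation is constant per bin. Strains with fewer
#' than `n_bins` cells of a type are excluded from that type's binning (with a
#' message in the attribute `excluded`).
#'
#' @param table a cell table.
#' @param pseudotime named vector from [infer_pseudotime()] (names =
#'   `cell_id`), or the name of a column of `table`.
#' @param n_bins number of bins (default 16; 8 gives very similar orderings).
#' @return the subset of `table` with columns `pseudotime` (overwritten where
#'   supplied) and `bin` added; attribute `excluded` lists dropped
#'   (strain, cell_type) combinations.
#' @export
bin_cells <- function(table, pseudotime, n_bins = 16) {
  if (is.character(pseudotime) && length(pseudotime) == 1) {
    pt <- setNames(table[[pseudotime]], table$cell_id)
  } else pt <- pseudotime
  keep <- table$cell_id %in% names(pt)[!is.na(pt)]
  tab <- table[keep, , drop = FALSE]
  tab$pseudotime <- as.numeric(pt[tab$cell_id])
  tab$bin <- NA_integer_
  excluded <- character(0)
  for (ty in unique(tab$cell_type)) {
    for (s in unique(tab$strain[tab$cell_type == ty])) {
      sel <- which(tab$cell_type == ty & tab$strain == s)
      if (length(sel) < n_bins) {
        excluded <- c(excluded, paste(s, ty, sep = "/"))
        next
      }
      rk <- rank(tab$pseudotime[sel], ties.method = "first")
      tab$bin[sel] <- as.integer(floor((rk - 1) * n_bins / length(sel)) + 1L)
    }
  }
  tab <- tab[!is.na(tab$bin), , drop = FALSE]
  attr(tab, "excluded") <- excluded
  attr(tab, "n_bins") <- n_bins
  tab
}

#' Correlation partitioning within each pseudotime bin
#'
#' Re-runs the within/between partitioning separately on every pseudotime bin
#' and carries the unbinned r_W and r_B alongside, giving a per-bin r_W series
#' per trait pair.
#'
#' @param binned output of [bin_cells()].
#' @param pairs optional character vector of `pair_id`s (default: all
#'   within-type pairs).
#' @param alpha passed to [partition_all()].
#' @return data.frame with one row per (pair, bin): `pair_id`, `cell_type`,
#'   `trait_x`, `trait_y`, `bin`, `r_w_bin` (NA for degenerate bins), plus the
#'   unbinned `r_w`, `r_b`, `r_b_adj`, `significant`.
#' @export
per_bin_partition <- function(binned, pairs = NULL, alpha = 0.01) {
  n_bins <- attr(binned, "n_bins")
  if (is.null(n_bins)) n_bins <- max(binned$bin)
  pooled <- partition_all(binned, alpha = alpha)
  if (!is.null(pairs)) pooled <- pooled[pooled$pair_id %in% pairs, , drop = FALSE]
  series <- list()
  for (b in seq_len(n_bins)) {
    sub <- binned[binned$bin == b, , drop = FALSE]
    pb <- tryCatch(partition_all(sub, alpha = alpha), error = function(e) NULL)
    rwb <- if (is.null(pb)) rep(NA_real_, nrow(pooled))
           else pb$r_w[match(pooled$pair_id, pb$pair_id)]
    series[[b]] <- data.frame(pooled[c("pair_id", "cell_type", "trait_x", "trait_y")],
                              bin = b, r_w_bin = rwb,
                              r_w = pooled$r_w, r_b = pooled$r_b,
                              r_b_adj = pooled$r_b_adj,
                              significant = pooled$significant,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, series)
  out <- out[order(out$pair_id, out$bin), ]
  rownames(out) <- NULL
  out
}

#' Percent of the r_B - r_W discrepancy resolved by binning
#'
#' For pairs where the (sign-adjusted) between-strain correlation exceeds the
#' within-strain correlation, scores how far the best pseudotime bin moves
#' r_W toward r_B:
#' `100 * max(0, (best bin r_W - r_W) / (r_B - r_W))`, capped at 100, all
#' correlations measured on the sign-adjusted magnitude scale (oriented by the
#' sign of r_B). Pairs without a discrepancy (r_B <= r_W) are excluded.
#'
#' @param series output of [per_bin_partition()].
#' @return data.frame per eligible pair: `pair_id`, `cell_type`, `r_w`,
#'   `r_b_adj`, `best_bin`, `best_bin_r_w`, `percent_resolved`.
#' @export
percent_resolved <- function(series) {
  out <- list()
  for (id in unique(series$pair_id)) {
    s <- series[series$pair_id == id, , drop = FALSE]
    sgn <- sign(s$r_b[1])
    if (sgn == 0) sgn <- 1
    rw <- s$r_w[1] * sgn
    rb <- abs(s$r_b[1])
    if (!(rb > rw)) next
    rwb <- s$r_w_bin * sgn
    if (all(is.na(rwb))) next
    best <- which.max(rwb)
    pct <- 100 * max(0, (rwb[best] - rw) / (rb - rw))
    out[[id]] <- data.frame(pair_id = id, cell_type = s$cell_type[1],
                            r_w = s$r_w[1], r_b_adj = s$r_b_adj[1],
                            best_bin = s$bin[best], best_bin_r_w = s$r_w_bin[best],
                            percent_resolved = min(pct, 100),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
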