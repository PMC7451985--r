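#' Classify trait pairs as vertical or horizontal pleiotropy candidates
#'
#' Joins the correlation-partition table with the QTL cluster table. A pair's
#' shared-QTL count is the number of clusters whose trait sets contain both
#' members. Categories:
#' \describe{
#'   \item{vertical-consistent}{|r_W| > `rW_threshold` and >= 1 shared QTL,
#'     without r_B significantly exceeding r_W: the correlation exists within
#'     clones, so the shared locus rides an inherent trait relationship.}
#'   \item{horizontal-candidate}{r_B significantly greater than r_W: genetic
#'     variation induces or strengthens the correlation.}
#'   \item{both}{meets both definitions.}
#'   \item{neither}{meets neither.}
#' }
#'
#' @param partitions a [partition_all()] table (with `significant` column).
#' @param clusters a [cluster_qtl()] table.
#' @param rW_threshold within-clone correlation magnitude defining the "high
#'   r_W" tail (default 0.2).
#' @return the partition table with `shared_qtl` and `category` columns.
#' @export
classify_pairs <- function(partitions, clusters, rW_threshold = 0.2) {
  memb <- lapply(seq_len(nrow(clusters)),
                 function(i) strsplit(clusters$traits[i], ",")[[1]])
  known <- unique(unlist(memb))
  bad <- setdiff(known, unique(c(partitions$trait_x, partitions$trait_y)))
  if (length(bad))
    stop("cluster trait id(s) absent from partitions: ",
         paste(head(bad, 5), collapse = ", "))
  shared <- mapply(function(x, y)
    sum(vapply(memb, function(m) x %in% m && y %in% m, logical(1))),
    partitions$trait_x, partitions$trait_y)
  vert <- partitions$r_w_adj > rW_threshold & shared >= 1
  horiz <- partitions$significant
  partitions$shared_qtl <- as.integer(shared)
  partitions$category <- ifelse(vert & horiz, "both",
                         ifelse(vert, "vertical-consistent",
                         ifelse(horiz, "horizontal-candidate", "neither")))
  partitions
}

#' Enrichment summaries linking shared QTL to within-clone correlation
#'
#' @param calls a [classify_pairs()] table.
#' @param rW_threshold tail threshold (default 0.2).
#' @return list with `frac_shared_high_rw` / `frac_shared_low_rw` (fraction of
#'   pairs above/below the r_W threshold sharing >= 1 QTL),
#'   `cor_shared_rw` (Pearson correlation of shared-QTL count with r_W
#'   magnitude; NA when the counts are constant), `frac_sig_all` and
#'   `frac_sig_shared` (fractions with r_B significantly > r_W, overall and
#'   among QTL-sharing pairs).
#' @export
enrichment_summary <- function(calls, rW_threshold = 0.2) {
  stopifnot(nrow(calls) >= 2)
  hi <- calls$r_w_adj > rW_threshold
  shared <- calls$shared_qtl >= 1
  corr <- if (sd(calls$shared_qtl) == 0 || sd(calls$r_w_adj) == 0) NA_real_
          else cor(calls$shared_qtl, calls$r_w_adj)
  list(frac_shared_high_rw = if (any(hi)) mean(shared[hi]) else NA_real_,
       frac_shared_low_rw = if (any(!hi)) mean(shared[!hi]) else NA_real_,
       cor_shared_rw = corr,
       frac_sig_all = mean(calls$significant),
       frac_sig_shared = if (any(shared)) mean(calls$significant[shared]) else NA_real_)
}

#' Weighted clustering coefficient of a complete weighted graph
#'
#' For a symmetric nonnegative weight matrix (zero diagonal), with weights
#' normalized by the maximum, node i's coefficient is
#' \deqn{wcc_i = \sum_{j \ne k} \hat w_{ij} \hat w_{jk} \hat w_{ki} /
#'       ((\sum_j \hat w_{ij})^2 - \sum_j \hat w_{ij}^2)}
#' the weighted fraction of i's neighbor pairs that are themselves connected;
#' it equals 1 when all weights are equal and lies in [0, 1]. Nodes with a
#' degenerate denominator (e.g. isolated nodes) get 0 and are flagged.
#'
#' @param weights symmetric nonnegative matrix, zero diagonal (callers pass
#'   |r_W|).
#' @return numeric vector of coefficients with attribute `degenerate`
#'   (logical).
#' @export
weighted_clustering <- function(weights) {
  w <- as.matrix(weights)
  if (any(w < 0)) stop("weights must be nonnegative (pass magnitudes)")
  stopifnot(nrow(w) == ncol(w))
  if (max(abs(w - t(w))) > 1e-10) stop("weights must be symmetric")
  diag(w) <- 0
  if (max(w) > 0) w <- w / max(w)
  s <- rowSums(w)
  s2 <- rowSums(w^2)
  num <- diag(w %*% w %*% w)   # sum over ordered (j, k), j != k
  den <- s^2 - s2
  wcc <- ifelse(den > 1e-14, num / den, 0)
  attr(wcc, "degenerate") <- den <= 1e-14
  wcc
}

#' Permutation null for the weighted clustering distribution
#'
#' Each permutation samples the observed off-diagonal weights without
#' replacement and reassigns them to random pairs of traits, preserving the
#' weight multiset exactly; clustering coefficients of the observed network
#' are compared against the permuted ones.
#'
#' @param weights symmetric nonnegative weight matrix.
#' @param n_perm number of permutations (default 100).
#' @param seed permutation seed.
#' @return list with `observed` (wcc vector) and `null` (n_perm x nodes
#'   matrix of permuted wcc values).
#' @export
network_permutation_null <- function(weights, n_perm = 100, seed = 1L) {
  w <- as.matrix(weights)
  diag(w) <- 0
  n <- nrow(w)
  iu <- upper.tri(w)
  vals <- w[iu]
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, n)
  for (b in seq_len(n_perm)) {
    wp <- matrix(0, n, n)
    wp[iu] <- vals[sample.int(length(vals))]
    wp <- wp + t(wp)
    null[b, ] <- as.numeric(weighted_clustering(wp))
  }
  list(observed = weighted_clustering(w), null = null)
}

#' Build the |r_W| weight matrix of one cell type's trait network
#'
#' @param partitions a [partition_all()] table.
#' @param cell_type which cell type's traits form the nodes.
#' @return symmetric matrix of |r_W| edge weights, zero diagonal.
#' @export
rw_network <- function(partitions, cell_type) {
  p <- partitions[partitions$cell_type == cell_type, , drop = FALSE]
  tr <- sort(unique(c(p$trait_x, p$trait_y)))
  w <- matrix(0, length(tr), length(tr), dimnames = list(tr, tr))
  ix <- cbind(match(p$trait_x, tr), match(p$trait_y, tr))
  w[ix] <- abs(p$r_w)
  w[ix[, 2:1, drop = FALSE]] <- abs(p$r_w)
  w
}
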