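#' Choose the marker that represents a QTL cluster
#'
#' For clusters spanning several markers, each member hit is assigned to its
#' nearest genotyped marker and the most-represented marker is used for the
#' allele split; ties break toward the smaller map position.
#'
#' @param cluster one row of a [cluster_qtl()] table.
#' @param hits the [scan_all()] hit table.
#' @param map marker map.
#' @return marker name (character).
#' @export
select_split_marker <- function(cluster, hits, map) {
  h <- hits[hits$chromosome == cluster$chromosome &
              hits$position_cM >= cluster$start_cM &
              hits$position_cM <= cluster$end_cM, , drop = FALSE]
  if (!nrow(h)) stop("cluster has no member hits")
  mi <- which(map$chromosome == cluster$chromosome)
  nearest <- vapply(h$position_cM, function(p)
    mi[which.min(abs(map$position_cM[mi] - p))], integer(1))
  cnt <- table(nearest)
  best <- as.integer(names(cnt)[cnt == max(cnt)])
  if (length(best) > 1)
    best <- best[which.min(map$position_cM[best])]
  map$marker[best]
}

#' Re-partition correlations within each allele subset of a marker
#'
#' Splits strains by their allele at `marker`, reruns the within/between
#' partitioning in each subset for the requested pairs, and reports the
#' sign-adjusted change in r_B (and r_W) relative to the all-strain values:
#' `delta_rb = |r_B(all)| - sign-oriented r_B(subset)`, positive when
#' eliminating the allelic variation weakens the between-strain correlation.
#'
#' @param table a cell table.
#' @param genotypes strains x markers matrix (-1/+1).
#' @param marker marker name or column index.
#' @param pairs character vector of `pair_id`s to analyze (default: all).
#' @param alpha passed to [partition_all()].
#' @param min_strains minimum strains per subset (default 4); smaller subsets
#'   abort with an error naming the marker.
#' @return data.frame per pair: all-strain and per-subset r_B / r_W,
#'   `delta_rb_neg` / `delta_rb_pos` (subset carrying the -1 / +1 allele),
#'   `delta_rw_neg` / `delta_rw_pos`, and `percent_resolved` (best subset;
#'   only for pairs with an r_B > r_W discrepancy, else NA).
#' @export
split_and_repartition <- function(table, genotypes, marker, pairs = NULL,
                                  alpha = 0.01, min_strains = 4) {
  g <- genotypes[, marker]
  subsets <- list(neg = rownames(genotypes)[g == -1],
                  pos = rownames(genotypes)[g == 1])
  if (any(lengths(subsets) < min_strains))
    stop("allele subset at marker ", marker, " has fewer than ",
         min_strains, " strains; QTL skipped")
  all_part <- partition_all(table[table$strain %in% rownames(genotypes), ,
                                  drop = FALSE], alpha = alpha)
  if (is.null(pairs)) pairs <- all_part$pair_id
  all_part <- all_part[match(pairs, all_part$pair_id), , drop = FALSE]
  sub_part <- lapply(subsets, function(ss)
    partition_all(table[table$strain %in% ss, , drop = FALSE], alpha = alpha))
  out <- data.frame(pair_id = pairs, cell_type = all_part$cell_type,
                    marker = if (is.character(marker)) marker else colnames(genotypes)[marker],
                    r_b = all_part$r_b, r_w = all_part$r_w,
                    r_b_adj = all_part$r_b_adj, r_w_adj = all_part$r_w_adj,
                    significant = all_part$significant,
                    stringsAsFactors = FALSE)
  sgn <- sign(out$r_b)
  sgn[sgn == 0] <- 1
  for (side in c("neg", "pos")) {
    sp <- sub_part[[side]][match(pairs, sub_part[[side]]$pair_id), , drop = FALSE]
    out[[paste0("r_b_", side)]] <- sp$r_b
    out[[paste0("r_w_", side)]] <- sp$r_w
    out[[paste0("delta_rb_", side)]] <- abs(out$r_b) - sp$r_b * sgn
    out[[paste0("delta_rw_", side)]] <- abs(out$r_w) - sp$r_w * sign(out$r_w)
  }
  disc <- abs(out$r_b) - out$r_w * sgn
  best <- pmax(out$delta_rb_neg, out$delta_rb_pos)
  out$percent_resolved <- ifelse(disc > 0 & out$r_b_adj > out$r_w_adj,
                                 pmin(100, 100 * pmax(0, best / disc)),
                                 NA_real_)
  out
}

#' Noise band for allele-split r_B changes
#'
#' 95th percentile of |delta r_B| over random strain bisections matching the
#' allele-subset sizes: the magnitude of r_B change expected from halving the
#' panel without removing any genetic signal.
#'
#' @param table a cell table.
#' @param genotypes genotype matrix (strain set and subset sizes).
#' @param marker marker whose allele-subset sizes are matched.
#' @param pairs `pair_id`s over which the band is pooled.
#' @param n_reps random bisections (default 200).
#' @param seed RNG seed.
#' @param alpha passed through.
#' @return numeric scalar: the 95th percentile of |delta r_B|.
#' @export
split_noise_band <- function(table, genotypes, marker, pairs = NULL,
                             n_reps = 200, seed = 1L, alpha = 0.01) {
  g <- genotypes[, marker]
  n_neg <- sum(g == -1)
  strains <- rownames(genotypes)
  all_part <- partition_all(table[table$strain %in% strains, , drop = FALSE],
                            alpha = alpha)
  if (is.null(pairs)) pairs <- all_part$pair_id
  all_part <- all_part[match(pairs, all_part$pair_id), , drop = FALSE]
  sgn <- sign(all_part$r_b); sgn[sgn == 0] <- 1
  set.seed(seed)
  deltas <- numeric(0)
  for (b in seq_len(n_reps)) {
    ss <- sample(strains, n_neg)
    sp <- partition_all(table[table$strain %in% ss, , drop = FALSE],
                        alpha = alpha)
    sp <- sp[match(pairs, sp$pair_id), , drop = FALSE]
    deltas <- c(deltas, abs(abs(all_part$r_b) - sp$r_b * sgn))
  }
  as.numeric(quantile(deltas, 0.95, na.rm = TRUE))
}

#' Classify the mode of a horizontal-pleiotropy split
#'
#' Given the per-subset r_B drops from [split_and_repartition()] and a noise
#' band, a pair is `both-drop` when eliminating allelic variation lowers r_B
#' in both subsets (the segregating locus itself couples the traits),
#' `one-drop` when only one allele background loses the correlation (the
#' allele strengthens the coupling), and `none` otherwise.
#'
#' @param result a [split_and_repartition()] table.
#' @param noise_band scalar threshold a drop must exceed (use 0 for the
#'   raw-sign convention).
#' @return `result` with a `mode` column.
#' @export
classify_mode <- function(result, noise_band) {
  dn <- result$delta_rb_neg > noise_band
  dp <- result$delta_rb_pos > noise_band
  result$mode <- ifelse(dn & dp, "both-drop",
                 ifelse(xor(dn, dp), "one-drop", "none"))
  result
}
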