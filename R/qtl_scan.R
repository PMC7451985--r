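#' Strain-level phenotype matrix
#'
#' Collapses a (preprocessed) cell table to one value per strain and trait:
#' the mean over the strain's retained cells of the trait's cell type. Strains
#' with no cells for a type get NA (complete-case handling is applied
#' trait-wise downstream).
#'
#' @param table a cell table.
#' @param strains optional strain ordering for the rows.
#' @return numeric matrix, strains x traits.
#' @export
strain_phenotypes <- function(table, strains = NULL) {
  if (is.null(strains)) strains <- sort(unique(table$strain))
  tr <- trait_cols(table)
  out <- matrix(NA_real_, length(strains), length(tr),
                dimnames = list(strains, tr))
  for (t in tr) {
    v <- tapply(table[[t]], table$strain, mean, na.rm = TRUE)
    out[names(v), t] <- v
  }
  out[is.nan(out)] <- NA
  out
}

# Expected genotype (doubled haploids coded -1/+1) at each scan position given
# the flanking observed markers, via Haldane recombination fractions. Returns
# list(positions = data.frame(chr, pos, at_marker), X = strains x positions).
.hk_design <- function(genotypes, map, step_cM = 2) {
  .validate_map(map)
  stopifnot(ncol(genotypes) == nrow(map))
  pos_list <- list(); X_list <- list()
  for (chr in unique(map$chromosome)) {
    mi <- which(map$chromosome == chr)
    mp <- map$position_cM[mi]
    g <- genotypes[, mi, drop = FALSE]
    grid <- sort(unique(c(mp, seq(min(mp), max(mp), by = step_cM))))
    Xc <- matrix(NA_real_, nrow(genotypes), length(grid))
    for (k in seq_along(grid)) {
      p <- grid[k]
      hit <- which(abs(mp - p) < 1e-9)
      if (length(hit)) { Xc[, k] <- g[, hit[1]]; next }
      il <- max(which(mp < p)); ir <- min(which(mp > p))
      rl <- haldane_r(p - mp[il]); rr <- haldane_r(mp[ir] - p)
      gl <- g[, il]; gr <- g[, ir]
      # P(no recombinant in either interval) conditional on the flank pattern
      same <- gl == gr
      pr <- ifelse(same,
                   (1 - rl) * (1 - rr) / ((1 - rl) * (1 - rr) + rl * rr),
                   (1 - rl) * rr / ((1 - rl) * rr + rl * (1 - rr)))
      Xc[, k] <- (2 * pr - 1) * gl
    }
    pos_list[[as.character(chr)]] <-
      data.frame(chromosome = chr, position_cM = grid,
                 at_marker = grid %in% mp)
    X_list[[as.character(chr)]] <- Xc
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  list(positions = positions, X = do.call(cbind, X_list))
}

#' Haley-Knott LOD scan for one phenotype
#'
#' Regresses a strain-level phenotype on the expected genotype at every marker
#' and pseudomarker (grid step `step_cM`), with expectations computed from the
#' flanking markers under the Haldane map function and a doubled-haploid
#' model. For a single regressor the LOD is
#' `(n/2) log10(RSS0 / RSS1) = -(n/2) log10(1 - R^2)`, which also makes the
#' scan invariant to affine rescaling of the phenotype.
#'
#' @param phenotype numeric vector aligned to the genotype rows.
#' @param genotypes strains x markers matrix coded -1/+1.
#' @param map marker map (`marker`, `chromosome`, `position_cM`).
#' @param step_cM pseudomarker grid step (default 2 cM).
#' @param design optional precomputed `.hk_design` (internal reuse).
#' @return data.frame `chromosome`, `position_cM`, `at_marker`, `lod`.
#' @export
hk_scan <- function(phenotype, genotypes, map, step_cM = 2, design = NULL) {
  stopifnot(length(phenotype) == nrow(genotypes))
  if (is.null(design)) design <- .hk_design(genotypes, map, step_cM)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  X <- design$X[keep, , drop = FALSE]
  n <- length(y)
  r <- suppressWarnings(as.vector(cor(y, X)))
  mono <- !is.finite(r)
  if (any(mono)) {
    warning("monomorphic region: LOD set to 0 at ", sum(mono), " position(s)")
    r[mono] <- 0
  }
  out <- design$positions
  out$lod <- -(n / 2) * log10(pmax(1 - r^2, .Machine$double.xmin))
  out
}

#' Permutation threshold and p-values for a genome scan
#'
#' Permutes the phenotype across strains `n_perm` times, records each
#' permutation's genome-wide maximum LOD, and returns the (1 - alpha) quantile
#' of that null together with a p-value for the observed maximum using the
#' plus-one rule `p = (#\{null >= obs\} + 1) / (n_perm + 1)`.
#'
#' @param phenotype,genotypes,map,step_cM as in [hk_scan()].
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed permutation seed.
#' @param design optional precomputed design (internal reuse).
#' @return list with `threshold`, `null_max` (length n_perm), and function
#'   `p_value(lod)` mapping an observed LOD to its permutation p.
#' @export
perm_threshold <- function(phenotype, genotypes, map, n_perm = 1000,
                           alpha = 0.05, seed = 1L, step_cM = 2,
                           design = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (is.null(design)) design <- .hk_design(genotypes, map, step_cM)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  X <- design$X[keep, , drop = FALSE]
  n <- length(y)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  r2 <- suppressWarnings(cor(X, P))^2
  r2[!is.finite(r2)] <- 0
  null_max <- apply(-(n / 2) * log10(pmax(1 - r2, .Machine$double.xmin)), 2, max)
  list(threshold = as.numeric(quantile(null_max, 1 - alpha, type = 7)),
       null_max = null_max,
       p_value = function(lod)
         (vapply(lod, function(l) sum(null_max >= l), numeric(1)) + 1) / (n_perm + 1))
}

#' Benjamini-Hochberg q-values across traits
#'
#' Applies BH step-up to the pooled per-trait per-chromosome maximum-LOD
#' p-values (conservative relative to Storey-type pi0 estimation).
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values, same length.
#' @export
fdr_across_traits <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Genome scan over all traits with permutation thresholds and FDR
#'
#' For each trait: Haley-Knott scan, per-trait permutation null, and the
#' per-chromosome maximum-LOD peaks. Peaks with permutation p <= `alpha` are
#' QTL hits; q-values are computed across the pooled set of per-trait
#' per-chromosome maxima. Optionally a simplified conditional second scan per
#' chromosome refits with the peak position as covariate and declares a second
#' additive QTL when a conditional peak >= 5 cM away exceeds the single-scan
#' threshold.
#'
#' @param phenotypes strains x traits matrix (see [strain_phenotypes()]).
#' @param genotypes,map,step_cM as in [hk_scan()].
#' @param n_perm,alpha permutation settings per trait.
#' @param seed master seed; trait t permutes under `substream_seed(seed, t)`.
#' @param second_scan if TRUE, run the conditional second-QTL search.
#' @param parental_means optional 2 x traits matrix (rows wine/oak) for effect
#'   sizes as a fraction of the parental difference.
#' @return data.frame of QTL hits: `trait`, `chromosome`, `position_cM`,
#'   `lod`, `p`, `q`, `threshold`, `effect_size`, `effect_fraction`,
#'   `allele_direction`, `secondary`.
#' @export
scan_all <- function(phenotypes, genotypes, map, n_perm = 1000, alpha = 0.05,
                     seed = 1L, step_cM = 2, second_scan = FALSE,
                     parental_means = NULL) {
  design <- .hk_design(genotypes, map, step_cM)
  hits <- list()
  for (t in seq_len(ncol(phenotypes))) {
    tr <- colnames(phenotypes)[t]
    y <- phenotypes[, t]
    if (sum(!is.na(y)) < 10 || sd(y, na.rm = TRUE) == 0) next
    sc <- hk_scan(y, genotypes, map, step_cM, design = design)
    pt <- perm_threshold(y, genotypes, map, n_perm, alpha,
                         seed = substream_seed(seed, t), step_cM,
                         design = design)
    for (chr in unique(sc$chromosome)) {
      sub <- sc[sc$chromosome == chr, ]
      k <- which.max(sub$lod)
      pv <- pt$p_value(sub$lod[k])
      hits[[length(hits) + 1]] <- data.frame(
        trait = tr, chromosome = chr,
        position_cM = sub$position_cM[k], lod = sub$lod[k],
        p = pv, threshold = pt$threshold, secondary = FALSE,
        stringsAsFactors = FALSE)
      if (second_scan) {
        h2 <- .conditional_second(y, sub, design, chr, k, pt$threshold)
        if (!is.null(h2)) {
          h2$trait <- tr
          hits[[length(hits) + 1]] <- h2
        }
      }
    }
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out$q <- fdr_across_traits(out$p)
  out <- out[out$p <= alpha, , drop = FALSE]
  if (nrow(out)) {
    es <- t(vapply(seq_len(nrow(out)), function(i)
      effect_size(out[i, ], phenotypes, genotypes, map, parental_means),
      numeric(3)))
    out$effect_size <- es[, 1]
    out$effect_fraction <- es[, 2]
    out$allele_direction <- es[, 3]
  }
  rownames(out) <- NULL
  out
}

# Conditional second-QTL search on one chromosome: regress out the peak
# expected genotype, rescan, and report a conditional peak >= 5 cM away that
# clears the single-scan threshold.
.conditional_second <- function(y, sub, design, chr, peak_idx, threshold) {
  cols <- which(design$positions$chromosome == chr)
  keep <- !is.na(y)
  X <- design$X[keep, cols, drop = FALSE]
  yv <- y[keep]
  xpeak <- X[, peak_idx]
  ry <- resid(lm(yv ~ xpeak))
  r <- suppressWarnings(as.vector(cor(ry, X)))
  r[!is.finite(r)] <- 0
  lod <- -(length(yv) / 2) * log10(pmax(1 - r^2, .Machine$double.xmin))
  far <- abs(sub$position_cM - sub$position_cM[peak_idx]) >= 5
  if (!any(far)) return(NULL)
  k2 <- which(far)[which.max(lod[far])]
  if (lod[k2] <= threshold) return(NULL)
  data.frame(trait = NA_character_, chromosome = chr,
             position_cM = sub$position_cM[k2], lod = lod[k2],
             p = NA_real_, threshold = threshold, secondary = TRUE,
             stringsAsFactors = FALSE)
}

#' QTL effect size at a hit
#'
#' The allele-substitution effect is the difference between allele-group
#' phenotype means at the marker nearest the peak; the effect fraction divides
#' its magnitude by the magnitude of the parental trait difference.
#'
#' @param hit one row of the [scan_all()] hit table (needs `trait`,
#'   `chromosome`, `position_cM`).
#' @param phenotypes strains x traits matrix.
#' @param genotypes,map genotype table and marker map.
#' @param parental_means optional 2 x traits matrix (rownames ignored; row 1
#'   minus row 2 is the parental difference). NA fraction when absent or when
#'   the parental difference is zero (flagged by NaN).
#' @return numeric c(effect, fraction, direction): allele-group mean
#'   difference (wine minus oak), its fraction of the parental difference, and
#'   the sign of the wine-allele effect.
#' @export
effect_size <- function(hit, phenotypes, genotypes, map, parental_means = NULL) {
  mi <- which(map$chromosome == hit$chromosome)
  m <- mi[which.min(abs(map$position_cM[mi] - hit$position_cM))]
  g <- genotypes[, m]
  y <- phenotypes[, hit$trait]
  eff <- mean(y[g == 1], na.rm = TRUE) - mean(y[g == -1], na.rm = TRUE)
  frac <- NA_real_
  if (!is.null(parental_means)) {
    pd <- unname(parental_means[1, hit$trait] - parental_means[2, hit$trait])
    frac <- if (pd == 0) NaN else abs(eff) / abs(pd)
  }
  c(effect = unname(eff), fraction = frac, direction = unname(sign(eff)))
}

#' Cluster QTL hits into loci
#'
#' Per chromosome, peak positions are sorted and chained into one cluster
#' while consecutive gaps are <= `gap_cM` (default 5 cM): peaks more than 5 cM
#' apart start separate loci, while dense runs without gaps over 2 cM are
#' never broken. A warning is emitted when a cluster spans more than
#' `span_warn_cM` (default 17 cM, the widest locus the approach is expected to
#' produce).
#'
#' @param hits the [scan_all()] hit table.
#' @param gap_cM chaining distance.
#' @param span_warn_cM sanity bound on the cluster span.
#' @return data.frame of clusters: `cluster_id`, `chromosome`, `start_cM`,
#'   `end_cM`, `span_cM`, `n_hits`, `degree` (distinct traits), `traits`
#'   (comma-separated).
#' @export
cluster_qtl <- function(hits, gap_cM = 5, span_warn_cM = 17) {
  if (!nrow(hits)) return(data.frame())
  out <- list()
  for (chr in sort(unique(hits$chromosome))) {
    h <- hits[hits$chromosome == chr, , drop = FALSE]
    h <- h[order(h$position_cM), , drop = FALSE]
    gap <- c(Inf, diff(h$position_cM))
    cl <- cumsum(gap > gap_cM)
    for (ci in unique(cl)) {
      hc <- h[cl == ci, , drop = FALSE]
      span <- diff(range(hc$position_cM))
      if (span > span_warn_cM)
        warning(sprintf("cluster on chromosome %s spans %.1f cM (> %g cM)",
                        chr, span, span_warn_cM))
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        start_cM = min(hc$position_cM), end_cM = max(hc$position_cM),
        span_cM = span, n_hits = nrow(hc),
        degree = length(unique(hc$trait)),
        traits = paste(sort(unique(hc$trait)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- cbind(cluster_id = sprintf("q%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
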