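#' Simulate a recombinant homozygous cross
#'
#' Generates genotypes for a panel of fully homozygous recombinant strains
#' (doubled-haploid model: each locus carries one of two parental alleles,
#' coded -1 for "oak" and +1 for "wine"). Along each chromosome a strain's
#' genotype is a Markov chain: the first marker allele is fair, and between
#' adjacent markers at distance d cM the allele switches with the Haldane
#' recombination fraction r = (1 - exp(-2d/100)) / 2. Chromosomes are
#' independent. Coding alleles as -1/+1 makes a QTL's `beta` the
#' half-difference of allele-group means.
#'
#' @param config a [sim_config()].
#' @param map optional marker map (data.frame with `marker`, `chromosome`,
#'   `position_cM`); by default markers are spread evenly over the configured
#'   chromosomes.
#' @return list with `genotypes` (strains x markers matrix of -1/+1, rownames
#'   `s001`...) and `map`.
#' @examples
#' cfg <- sim_config(n_strains = 20, n_markers = 12, n_chromosomes = 2,
#'                   chrom_length_cM = 100, n_traits_per_celltype = c(2, 0, 0),
#'                   seed = 1)
#' cross <- simulate_cross(cfg)
#' dim(cross$genotypes)
#' @export
simulate_cross <- function(config, map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(map)) map <- default_marker_map(config)
  .validate_map(map)
  if (nrow(map) != config$n_markers)
    stop("map has ", nrow(map), " markers; config expects ", config$n_markers)
  set.seed(substream_seed(config$seed, 101L))
  J <- config$n_strains
  geno <- matrix(NA_real_, J, nrow(map),
                 dimnames = list(sprintf("s%03d", seq_len(J)), map$marker))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$position_cM[idx]
    d <- diff(pos)
    r <- haldane_r(d)
    g <- matrix(NA_real_, J, length(idx))
    g[, 1] <- sample(c(-1, 1), J, replace = TRUE)
    if (length(idx) > 1) {
      for (k in seq_along(d)) {
        flip <- runif(J) < r[k]
        g[, k + 1] <- ifelse(flip, -g[, k], g[, k])
      }
    }
    geno[, idx] <- g
  }
  list(genotypes = geno, map = map)
}

#' Haldane map function
#'
#' Recombination fraction for a map distance in cM:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM map distance(s) in centimorgans.
#' @return recombination fraction(s) in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distances must be nonnegative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Default evenly spaced marker map for a configuration
#'
#' Markers are apportioned to chromosomes proportionally to map length and
#' placed evenly from 0 to the chromosome end.
#'
#' @param config a [sim_config()].
#' @return data.frame with `marker`, `chromosome`, `position_cM`.
#' @export
default_marker_map <- function(config) {
  nchr <- config$n_chromosomes
  len <- config$chrom_length_cM
  n <- config$n_markers
  per <- pmax(1L, floor(n * len / sum(len)))
  while (sum(per) < n) {
    i <- which.max(len / per)
    per[i] <- per[i] + 1L
  }
  while (sum(per) > n) {
    i <- which.max(ifelse(per > 1, per / len, -Inf))
    per[i] <- per[i] - 1L
  }
  chr <- rep(seq_len(nchr), per)
  pos <- unlist(lapply(seq_len(nchr), function(i) {
    if (per[i] == 1) len[i] / 2 else seq(0, len[i], length.out = per[i])
  }))
  data.frame(marker = sprintf("m%03d", seq_len(n)),
             chromosome = chr, position_cM = pos,
             stringsAsFactors = FALSE)
}

.validate_map <- function(map) {
  stopifnot(all(c("marker", "chromosome", "position_cM") %in% names(map)))
  if (any(map$position_cM < 0)) stop("marker map error: negative position")
  for (chr in unique(map$chromosome)) {
    p <- map$position_cM[map$chromosome == chr]
    if (is.unsorted(p, strictly = FALSE))
      stop("marker map error: positions not increasing on chromosome ", chr)
  }
  invisible(TRUE)
}
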