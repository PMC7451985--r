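#' Simulate clonal single-cell trait data with known architecture
#'
#' Generates a hierarchical cell-level trait table for a recombinant mapping
#' panel. Each cell's trait vector is
#' `baseline + QTL mean shifts + strain random effect + plate effect +
#' trajectory(pseudotime) + correlated cell noise`. Cell noise is drawn from a
#' Gaussian copula over a per-context correlation matrix, so
#' correlation-modifying QTL change the within-strain correlation of their
#' target pair (to `rho0` or `rho0 + delta` according to the strain's allele)
#' without changing trait marginals. Pseudotime is Uniform(0,1) per cell,
#' independent of strain; plate effects are additive per (replicate x trait).
#'
#' @param config a [sim_config()].
#' @param cross optional result of [simulate_cross()]; simulated from `config`
#'   if omitted.
#' @return list with `cells` (the cell table: `cell_id`, `strain`, `replicate`,
#'   `cell_type`, `pseudotime`, one column per trait with NA outside the
#'   trait's cell type) and `truth` (a `sim_truth` object; see
#'   [sim_truth_pairs()]).
#' @export
simulate_cells <- function(config, cross = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cross)) cross <- simulate_cross(config)
  geno <- cross$genotypes
  J <- nrow(geno)
  cm <- Filter(function(q) q$mechanism == "corr_modifying", config$qtl_spec)
  for (q in config$qtl_spec) {
    if (q$marker > ncol(geno)) stop("qtl_spec marker absent from genotype table")
  }
  ctx <- .context_keys(geno, cm)
  sig <- .sigma_tables(config, cm, unique(ctx))
  mu <- .qtl_mean_shifts(config, geno)

  tab <- .gen_table(config,
                    strain_names = rownames(geno),
                    n_cells = rep(config$cells_per_strain, J),
                    mu_strain = mu, ctx_key = ctx,
                    sigma_cells = sig$cells, strain_sigma = sig$strain,
                    seed = substream_seed(config$seed, 102L))

  if (config$include_parents) {
    pg <- rbind(parent_wine = rep(1, ncol(geno)),
                parent_oak = rep(-1, ncol(geno)))
    colnames(pg) <- colnames(geno)
    pctx <- .context_keys(pg, cm)
    psig <- .sigma_tables(config, cm, unique(pctx))
    pmu <- .qtl_mean_shifts(config, pg)
    np <- config$parent_cells_per_plate * config$n_replicates
    ptab <- .gen_table(config, rownames(pg), n_cells = rep(np, 2),
                       mu_strain = pmu, ctx_key = pctx,
                       sigma_cells = psig$cells, strain_sigma = psig$strain,
                       seed = substream_seed(config$seed, 103L))
    ptab$cell_id <- paste0("p", ptab$cell_id)
    tab <- rbind(tab, ptab)
  }

  truth <- .build_truth(config, cross, ctx, sig, tab)
  list(cells = tab, truth = truth)
}

# ---- internal generative machinery -----------------------------------------

# Per-strain context key: alleles at the correlation-modifying markers.
.context_keys <- function(geno, cm) {
  if (length(cm) == 0) return(rep("all", nrow(geno)))
  a <- sapply(cm, function(q) geno[, q$marker])
  if (is.null(dim(a))) a <- matrix(a, nrow = nrow(geno))
  apply(a, 1, paste, collapse = ",")
}

# Cell-noise and strain-effect correlation matrices per cell type and context.
.sigma_tables <- function(config, cm, keys) {
  types <- names(config$n_traits_per_celltype)[config$n_traits_per_celltype > 0]
  cells <- strain <- list()
  for (ty in types) {
    cells[[ty]] <- strain[[ty]] <- list()
    for (key in keys) {
      alleles <- if (key %in% c("all", "alt", "base")) numeric(0) else
        as.numeric(strsplit(key, ",")[[1]])
      cells[[ty]][[key]] <- .cell_sigma(config, ty, cm, alleles)
      strain[[ty]][[key]] <- .strain_sigma(config, ty, cm, alleles)
    }
  }
  list(cells = cells, strain = strain)
}

# Effective cell-noise correlation for one cell type and allele context:
# latent vertical factors + residual base correlation, then per-allele
# overrides from correlation-modifying QTL. Errors if the result is not PSD.
.cell_sigma <- function(config, ty, cm, alleles) {
  tr <- config$traits[config$trait_type == ty]
  C <- config$base_within_corr[[ty]]
  vqs <- Filter(function(q) q$mechanism == "vertical" &&
                  config$trait_type[q$traits[1]] == ty, config$qtl_spec)
  if (length(vqs)) {
    A <- matrix(0, length(tr), length(vqs), dimnames = list(tr, NULL))
    for (k in seq_along(vqs)) A[vqs[[k]]$traits, k] <- vqs[[k]]$loading
    b <- 1 - rowSums(A^2)
    if (any(b < 0)) stop("config error: vertical loadings exceed unit variance")
    b <- sqrt(b)
    C <- tcrossprod(A) + (b %o% b) * C
  }
  C <- .apply_cm(C, config, ty, cm, alleles)
  dimnames(C) <- list(tr, tr)
  .check_psd(C, paste0("config error: cell-noise correlation (", ty,
                       ", context ", paste(alleles, collapse = ","), ")"))
  C
}

.strain_sigma <- function(config, ty, cm, alleles) {
  tr <- config$traits[config$trait_type == ty]
  S <- config$strain_corr[[ty]]
  cm_sc <- Filter(function(q) q$strain_coupling, cm)
  S <- .apply_cm(S, config, ty, cm_sc, alleles[which(vapply(cm, function(q) q$strain_coupling, TRUE))])
  sv <- sqrt(config$strain_var[tr])
  S <- (sv %o% sv) * S
  dimnames(S) <- list(tr, tr)
  .check_psd(S, "config error: strain-effect covariance")
  S
}

.apply_cm <- function(C, config, ty, cm, alleles) {
  for (k in seq_along(cm)) {
    q <- cm[[k]]
    if (config$trait_type[q$pair[1]] != ty) next
    rho <- q$rho0 + (if (length(alleles) >= k && alleles[k] == 1) q$delta else 0)
    C[q$pair[1], q$pair[2]] <- C[q$pair[2], q$pair[1]] <- rho
  }
  C
}

# Strain-level mean shifts from mean-shifting QTL (alleles coded -1/+1).
.qtl_mean_shifts <- function(config, geno) {
  mu <- matrix(0, nrow(geno), length(config$traits),
               dimnames = list(rownames(geno), config$traits))
  for (q in config$qtl_spec) {
    g <- geno[, q$marker]
    if (q$mechanism == "direct_horizontal") {
      for (i in seq_along(q$traits)) mu[, q$traits[i]] <- mu[, q$traits[i]] + q$beta[i] * g
    } else if (q$mechanism == "vertical") {
      mu[, q$traits] <- mu[, q$traits] + (q$beta * g) %o% q$loading
    }
  }
  mu
}

# Draw n x p standard-normal noise with correlation C (Gaussian copula core).
.mvn_noise <- function(n, C) {
  z <- matrix(rnorm(n * ncol(C)), n, ncol(C))
  U <- chol(C, pivot = FALSE)
  z %*% U
}

# The generic cell-table generator shared by the cross, MA and dose simulators.
# All randomness is drawn in a fixed order from `seed` so identical seeds give
# bit-identical tables, and tables differing only in sigma share every other
# draw (the paired-control contract of the dose simulator).
.gen_table <- function(config, strain_names, n_cells, mu_strain, ctx_key,
                       sigma_cells, strain_sigma, seed,
                       condition = NULL, dose = NULL) {
  set.seed(seed)
  J <- length(strain_names)
  types <- names(config$n_traits_per_celltype)[config$n_traits_per_celltype > 0]
  N <- sum(n_cells)
  strain <- rep(strain_names, n_cells)
  cell_type <- sample(types, N, replace = TRUE)
  replicate <- sample.int(config$n_replicates, N, replace = TRUE)
  pseudotime <- runif(N)
  plate <- matrix(rnorm(config$n_replicates * length(config$traits),
                        sd = config$plate_effect_sd),
                  config$n_replicates, length(config$traits),
                  dimnames = list(NULL, config$traits))

  # strain random effects, drawn context-block by context-block
  strain_eff <- matrix(0, J, length(config$traits),
                       dimnames = list(strain_names, config$traits))
  for (ty in types) {
    tr <- colnames(strain_sigma[[ty]][[1]])
    for (key in sort(unique(ctx_key))) {
      rows <- which(ctx_key == key)
      S <- strain_sigma[[ty]][[key]]
      sv <- diag(S)
      if (all(sv == 0)) next
      Cs <- S / (sqrt(sv) %o% sqrt(sv))
      Cs[!is.finite(Cs)] <- 0; diag(Cs) <- 1
      e <- .mvn_noise(length(rows), Cs)
      strain_eff[rows, tr] <- e * rep(sqrt(sv), each = length(rows))
    }
  }

  vals <- matrix(NA_real_, N, length(config$traits),
                 dimnames = list(NULL, config$traits))
  strain_idx <- match(strain, strain_names)
  cell_ctx <- ctx_key[strain_idx]
  for (ty in types) {
    tr <- colnames(sigma_cells[[ty]][[1]])
    sel_ty <- which(cell_type == ty)
    for (key in sort(unique(ctx_key))) {
      sel <- sel_ty[cell_ctx[sel_ty] == key]
      if (!length(sel)) next
      noise <- .mvn_noise(length(sel), sigma_cells[[ty]][[key]])
      noise <- noise * rep(sqrt(config$cell_var[tr]), each = length(sel))
      base <- config$trait_baseline +
        mu_strain[strain_idx[sel], tr, drop = FALSE] +
        strain_eff[strain_idx[sel], tr, drop = FALSE] +
        plate[replicate[sel], tr, drop = FALSE]
      spec <- config$cellcycle_spec
      traj <- sapply(tr, function(t) {
        k <- match(t, spec$trait)
        .traj_value(spec$shape[k], spec$amplitude[k], pseudotime[sel])
      })
      if (length(sel) == 1) traj <- matrix(traj, nrow = 1)
      vals[sel, tr] <- base + traj + noise
    }
  }

  tab <- data.frame(cell_id = sprintf("c%07d", seq_len(N)),
                    strain = strain, replicate = replicate,
                    cell_type = cell_type, pseudotime = pseudotime,
                    stringsAsFactors = FALSE)
  if (!is.null(condition)) { tab$condition <- condition; tab$dose <- dose }
  cbind(tab, as.data.frame(vals))
}

# ---- ground truth -----------------------------------------------------------

.build_truth <- function(config, cross, ctx, sig, tab) {
  qtl <- do.call(rbind, lapply(config$qtl_spec, function(q) {
    data.frame(marker = colnames(cross$genotypes)[q$marker],
               marker_index = q$marker,
               mechanism = q$mechanism,
               targets = paste(if (q$mechanism == "corr_modifying") q$pair else q$traits,
                               collapse = ","),
               beta = if (is.null(q$beta)) NA_character_ else
                 paste(signif(q$beta, 6), collapse = ","),
               rho0 = if (is.null(q$rho0)) NA_real_ else q$rho0,
               delta = if (is.null(q$delta)) NA_real_ else q$delta,
               stringsAsFactors = FALSE)
  }))
  structure(list(config = config,
                 genotypes = cross$genotypes, map = cross$map,
                 qtl = qtl,
                 context_by_strain = setNames(ctx, rownames(cross$genotypes)),
                 sigma_cells = sig$cells,
                 pseudotime = setNames(tab$pseudotime, tab$cell_id)),
            class = "sim_truth")
}

#' Expected pooled within-strain correlations from simulation truth
#'
#' For every trait pair affected by a simulated QTL (and any extra pairs
#' requested), returns the within-strain noise correlation per allele context
#' together with the expected *pooled* within-strain correlation r_W, which
#' dilutes the noise correlation by the independent cell-cycle trajectory and
#' plate-effect variance:
#' \deqn{r_W = (rho * s_x s_y + cov_{traj}) / \sqrt{(s_x^2 + v_{traj,x} + v_p)
#'   (s_y^2 + v_{traj,y} + v_p)}}
#' with \eqn{v_p = (1 - 1/R)\,\sigma_{plate}^2} the within-strain share of the
#' plate variance over R replicates.
#'
#' @param truth a `sim_truth` object.
#' @param pairs optional additional pairs: 2-column matrix or list of
#'   length-2 trait-name vectors.
#' @return data.frame with `cell_type`, `trait_x`, `trait_y`, `context`,
#'   `rho_noise`, `r_w_expected`.
#' @export
sim_truth_pairs <- function(truth, pairs = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  want <- list()
  for (q in config$qtl_spec) {
    tg <- if (q$mechanism == "corr_modifying") list(q$pair) else
      if (length(q$traits) > 1) apply(combn(q$traits, 2), 2, identity, simplify = FALSE) else list()
    want <- c(want, tg)
  }
  if (!is.null(pairs)) {
    if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
    want <- c(want, pairs)
  }
  if (!length(want)) return(data.frame())
  want <- unique(lapply(want, sort))
  mom <- .traj_moments()
  spec <- config$cellcycle_spec
  R <- config$n_replicates
  vp <- (1 - 1 / R) * config$plate_effect_sd^2
  rows <- list()
  for (p in want) {
    ty <- unname(config$trait_type[p[1]])
    for (key in unique(truth$context_by_strain)) {
      C <- truth$sigma_cells[[ty]][[key]]
      kx <- match(p[1], spec$trait); ky <- match(p[2], spec$trait)
      ax <- spec$amplitude[kx]; ay <- spec$amplitude[ky]
      ctraj <- ax * ay * mom[spec$shape[kx], spec$shape[ky]]
      vx <- config$cell_var[p[1]] + ax^2 * mom[spec$shape[kx], spec$shape[kx]] + vp
      vy <- config$cell_var[p[2]] + ay^2 * mom[spec$shape[ky], spec$shape[ky]] + vp
      rho <- C[p[1], p[2]]
      num <- rho * sqrt(config$cell_var[p[1]] * config$cell_var[p[2]]) + ctraj
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ty, trait_x = p[1], trait_y = p[2], context = key,
        rho_noise = rho, r_w_expected = num / sqrt(vx * vy),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
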