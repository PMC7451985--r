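#' Simulate a mutation-accumulation line panel
#'
#' All lines share the configured within-line (cell-noise) correlation
#' structure except `n_altered` randomly chosen lines, in which a private
#' correlation-altering mutation shifts the within-line correlation of each
#' designated pair by `delta`. No genotype table is emitted: MA-line mutations
#' are private, so the panel is not amenable to mapping.
#'
#' @param config a [sim_config()] (its `qtl_spec` is ignored here).
#' @param n_lines number of MA lines (default 94, the panel size the package
#'   emulates).
#' @param n_altered number of lines carrying the correlation-altering mutation.
#' @param pairs list of length-2 trait-name vectors (or 2-column matrix) whose
#'   within-line correlation is shifted in altered lines.
#' @param delta correlation shift applied in altered lines.
#' @param cells_per_line clonal cells per line (default 1000).
#' @return list with `cells` (line labels in the `strain` column) and `truth`
#'   (fields `altered_lines`, `pairs`, `rho0`, `delta`).
#' @export
simulate_ma_panel <- function(config, n_lines = 94, n_altered = 0,
                              pairs = NULL, delta = 0,
                              cells_per_line = 1000) {
  stopifnot(inherits(config, "sim_config"))
  if (n_altered > n_lines) stop("n_altered must not exceed n_lines")
  if (n_altered > 0 && is.null(pairs))
    stop("pairs must be given when n_altered > 0")
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  for (p in pairs) {
    if (!all(p %in% config$traits)) stop("unknown trait in pairs")
    if (length(unique(config$trait_type[p])) != 1)
      stop("pair traits must share a cell type")
  }

  lines <- sprintf("l%03d", seq_len(n_lines))
  set.seed(substream_seed(config$seed, 201L))
  altered <- sort(sample.int(n_lines, n_altered))
  ctx <- ifelse(seq_len(n_lines) %in% altered, "alt", "base")

  sig <- .sigma_tables(config, list(), c("base", "alt"))
  rho0 <- numeric(0)
  for (p in pairs) {
    ty <- unname(config$trait_type[p[1]])
    r0 <- sig$cells[[ty]][["base"]][p[1], p[2]]
    r1 <- r0 + delta
    if (abs(r1) >= 1)
      stop("config error: altered correlation out of (-1, 1) for pair ",
           paste(p, collapse = "/"))
    sig$cells[[ty]][["alt"]][p[1], p[2]] <- r1
    sig$cells[[ty]][["alt"]][p[2], p[1]] <- r1
    rho0 <- c(rho0, r0)
  }
  for (ty in names(sig$cells))
    .check_psd(sig$cells[[ty]][["alt"]],
               "config error: altered cell-noise correlation")

  mu <- matrix(0, n_lines, length(config$traits),
               dimnames = list(lines, config$traits))
  tab <- .gen_table(config, lines, n_cells = rep(cells_per_line, n_lines),
                    mu_strain = mu, ctx_key = ctx,
                    sigma_cells = sig$cells, strain_sigma = sig$strain,
                    seed = substream_seed(config$seed, 202L))
  truth <- structure(list(config = config,
                          altered_lines = lines[altered],
                          pairs = pairs, rho0 = rho0, delta = delta,
                          sigma_cells = sig$cells,
                          context_by_strain = setNames(ctx, lines),
                          pseudotime = setNames(tab$pseudotime, tab$cell_id)),
                     class = "sim_truth")
  list(cells = tab, truth = truth)
}

#' Simulate a drug dose series with paired controls
#'
#' For each dose, a control table and a drug table are generated from the
#' *same* substream seed, so they share every draw (genotype assignment,
#' pseudotime, plate effects) and differ only through the dose-dependent shift
#' applied to the within-strain correlation of the designated pairs. A zero
#' shift therefore reproduces the control table exactly, and the
#' control-vs-control contrast across doses provides the replicate null.
#'
#' @param config a [sim_config()]; mean-shifting QTL in `qtl_spec` are kept,
#'   correlation-modifying ones are ignored here.
#' @param doses ordered numeric vector of dose levels.
#' @param shifts correlation shift per dose: numeric vector recycled over
#'   `doses`, or a matrix of dim (doses x pairs).
#' @param pairs list of length-2 trait-name vectors (or 2-column matrix)
#'   receiving the shift.
#' @param cross optional [simulate_cross()] result reused across conditions.
#' @return list with `cells` (columns `condition` in drug/control and `dose`)
#'   and `truth` (per-dose per-pair target correlations).
#' @export
simulate_dose_series <- function(config, doses, shifts, pairs, cross = NULL) {
  stopifnot(inherits(config, "sim_config"), length(doses) >= 1)
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  if (!is.matrix(shifts))
    shifts <- matrix(rep_len(shifts, length(doses)), length(doses), length(pairs))
  stopifnot(nrow(shifts) == length(doses), ncol(shifts) == length(pairs))
  if (is.null(cross)) cross <- simulate_cross(config)
  geno <- cross$genotypes
  cm <- Filter(function(q) q$mechanism == "corr_modifying", config$qtl_spec)
  if (length(cm)) {
    config$qtl_spec <- Filter(function(q) q$mechanism != "corr_modifying",
                              config$qtl_spec)
    warning("corr_modifying QTL ignored by the dose simulator")
  }
  ctx <- rep("all", nrow(geno))
  base_sig <- .sigma_tables(config, list(), "all")
  mu <- .qtl_mean_shifts(config, geno)

  out <- list(); targets <- list()
  for (i in seq_along(doses)) {
    dsig <- base_sig
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      ty <- unname(config$trait_type[p[1]])
      r1 <- dsig$cells[[ty]][[1]][p[1], p[2]] + shifts[i, k]
      if (abs(r1) >= 1) stop("config error: shifted correlation out of (-1, 1)")
      dsig$cells[[ty]][[1]][p[1], p[2]] <- r1
      dsig$cells[[ty]][[1]][p[2], p[1]] <- r1
      targets[[length(targets) + 1]] <- data.frame(
        dose = doses[i], trait_x = min(p), trait_y = max(p),
        rho_control = base_sig$cells[[ty]][[1]][p[1], p[2]],
        rho_drug = r1, shift = shifts[i, k], stringsAsFactors = FALSE)
    }
    for (ty in names(dsig$cells))
      .check_psd(dsig$cells[[ty]][[1]], "config error: shifted correlation matrix")
    sd_i <- substream_seed(config$seed, 300L + i)
    ctrl <- .gen_table(config, rownames(geno),
                       rep(config$cells_per_strain, nrow(geno)),
                       mu, ctx, base_sig$cells, base_sig$strain, seed = sd_i,
                       condition = "control", dose = doses[i])
    drug <- .gen_table(config, rownames(geno),
                       rep(config$cells_per_strain, nrow(geno)),
                       mu, ctx, dsig$cells, dsig$strain, seed = sd_i,
                       condition = "drug", dose = doses[i])
    ctrl$cell_id <- sprintf("d%d_%s_%s", i, "c", ctrl$cell_id)
    drug$cell_id <- sprintf("d%d_%s_%s", i, "t", drug$cell_id)
    out[[2 * i - 1]] <- ctrl; out[[2 * i]] <- drug
  }
  truth <- structure(list(config = config, doses = doses,
                          pairs = pairs,
                          targets = do.call(rbind, targets)),
                     class = "sim_truth")
  list(cells = do.call(rbind, out), truth = truth)
}
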