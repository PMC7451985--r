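#' Per-line trait-pair correlations in a mutation-accumulation panel
#'
#' Computes Pearson correlations between every within-cell-type pair of
#' traits, separately within each MA line (the `strain` column), and a
#' leave-one-out deviation score per (line, pair):
#' `(r_lp - mean of the other lines) / SD of the other lines`. A line whose
#' correlation-altering mutation shifts one pair stands out as an extreme
#' score on that pair.
#'
#' @param table a cell table with line labels in `strain`.
#' @param min_cells minimum cells per line per cell type (default 50).
#' @return list of class `ma_line_stats`: `correlations` and `scores` (lines x
#'   pairs matrices), `pairs` (data.frame `pair_id`, `cell_type`, `trait_x`,
#'   `trait_y`), `lines`.
#' @export
ma_pair_correlations <- function(table, min_cells = 50) {
  lines <- sort(unique(table$strain))
  if (length(lines) < 4)
    stop("need at least 4 lines for leave-one-out deviation scores")
  pair_info <- list(); cors <- list()
  for (ty in intersect(.cell_types, unique(table$cell_type))) {
    sub <- table[table$cell_type == ty, , drop = FALSE]
    tr <- trait_cols(sub)
    tr <- tr[colSums(!is.na(sub[tr])) > 0]
    if (length(tr) < 2) next
    cnt <- base::table(sub$strain)
    low <- names(cnt)[cnt < min_cells]
    if (length(setdiff(lines, low)) < 4)
      stop("fewer than 4 lines with >= ", min_cells, " cells of type ", ty)
    iu <- which(upper.tri(diag(length(tr))), arr.ind = TRUE)
    ids <- paste(tr[iu[, 1]], tr[iu[, 2]], sep = "|")
    pair_info[[ty]] <- data.frame(pair_id = ids, cell_type = ty,
                                  trait_x = tr[iu[, 1]], trait_y = tr[iu[, 2]],
                                  stringsAsFactors = FALSE)
    cm <- matrix(NA_real_, length(lines), length(ids),
                 dimnames = list(lines, ids))
    for (l in lines) {
      if (l %in% low) next
      X <- as.matrix(sub[sub$strain == l, tr, drop = FALSE])
      degen <- apply(X, 2, sd, na.rm = TRUE) == 0
      r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
      r[degen, ] <- NA; r[, degen] <- NA
      cm[l, ] <- r[iu]
    }
    cors[[ty]] <- cm
  }
  if (!length(cors)) stop("no cell type contributes 2 or more traits")
  correlations <- do.call(cbind, cors)
  scores <- apply(correlations, 2, .loo_z)
  dimnames(scores) <- dimnames(correlations)
  structure(list(correlations = correlations, scores = scores,
                 pairs = do.call(rbind, pair_info), lines = lines),
            class = "ma_line_stats")
}

# Leave-one-out z-score of each element against the others.
.loo_z <- function(v) {
  n_ok <- sum(!is.na(v))
  vapply(seq_along(v), function(i) {
    if (is.na(v[i]) || n_ok < 4) return(NA_real_)
    o <- v[-i]
    (v[i] - mean(o, na.rm = TRUE)) / sd(o, na.rm = TRUE)
  }, numeric(1))
}

#' Flag correlation-altering outlier lines
#'
#' A (line, pair) is flagged when its leave-one-out deviation score exceeds
#' `k` standard deviations (default 4). Per-line summaries report the maximum
#' |deviation| over pairs and the mean |deviation|.
#'
#' @param stats a [ma_pair_correlations()] result.
#' @param k SD threshold (default 4).
#' @return list with `flags` (data.frame `line`, `pair_id`, `correlation`,
#'   `score`) and `line_summary` (`line`, `max_abs_score`, `mean_abs_score`,
#'   `n_flagged`).
#' @export
flag_outliers <- function(stats, k = 4) {
  stopifnot(inherits(stats, "ma_line_stats"))
  sc <- stats$scores
  hit <- which(!is.na(sc) & abs(sc) > k, arr.ind = TRUE)
  flags <- data.frame(line = rownames(sc)[hit[, 1]],
                      pair_id = colnames(sc)[hit[, 2]],
                      correlation = stats$correlations[hit],
                      score = sc[hit],
                      stringsAsFactors = FALSE)
  summ <- data.frame(line = rownames(sc),
                     max_abs_score = apply(abs(sc), 1, max, na.rm = TRUE),
                     mean_abs_score = rowMeans(abs(sc), na.rm = TRUE),
                     stringsAsFactors = FALSE)
  summ$max_abs_score[!is.finite(summ$max_abs_score)] <- NA
  summ$n_flagged <- as.integer(table(factor(flags$line, levels = summ$line)))
  list(flags = flags, line_summary = summ)
}

#' Within-strain correlation changes across a drug dose series
#'
#' For each dose, computes the pooled within-strain correlation r_W per trait
#' pair in the drug condition and in its paired control, and reports
#' `delta = r_W(drug) - r_W(control)`. A null distribution comes from pairing
#' the controls of different doses against each other
#' (replicate-vs-replicate).
#'
#' @param table a cell table with `condition` ("drug"/"control") and `dose`
#'   columns, e.g. from [simulate_dose_series()].
#' @param pairs optional `pair_id` filter.
#' @param alpha passed to [partition_all()].
#' @return list with `deltas` (data.frame `pair_id`, `cell_type`, `dose`,
#'   `r_w_drug`, `r_w_control`, `delta`, `abs_delta`), `null` (data.frame of
#'   control-vs-control deltas, NULL with a single dose), and `by_dose`
#'   (median |delta| per dose).
#' @export
dose_delta <- function(table, pairs = NULL, alpha = 0.01) {
  stopifnot(all(c("condition", "dose") %in% names(table)))
  doses <- sort(unique(table$dose))
  rw <- function(cond, d) {
    sub <- table[table$condition == cond & table$dose == d, , drop = FALSE]
    if (!nrow(sub)) stop("unpaired condition: ", cond, " at dose ", d)
    p <- partition_all(sub, alpha = alpha)
    if (!is.null(pairs)) p <- p[p$pair_id %in% pairs, , drop = FALSE]
    p
  }
  deltas <- list()
  ctrl_tabs <- list()
  for (d in doses) {
    pc <- rw("control", d)
    pd <- rw("drug", d)
    pd <- pd[match(pc$pair_id, pd$pair_id), , drop = FALSE]
    deltas[[as.character(d)]] <- data.frame(
      pair_id = pc$pair_id, cell_type = pc$cell_type, dose = d,
      r_w_drug = pd$r_w, r_w_control = pc$r_w,
      delta = pd$r_w - pc$r_w, abs_delta = abs(pd$r_w - pc$r_w),
      stringsAsFactors = FALSE)
    ctrl_tabs[[as.character(d)]] <- pc
  }
  null <- NULL
  if (length(doses) >= 2) {
    null <- list()
    for (i in seq_along(doses)[-1]) {
      a <- ctrl_tabs[[1]]; b <- ctrl_tabs[[i]]
      b <- b[match(a$pair_id, b$pair_id), , drop = FALSE]
      null[[i - 1]] <- data.frame(pair_id = a$pair_id,
                                  dose_a = doses[1], dose_b = doses[i],
                                  delta = b$r_w - a$r_w,
                                  abs_delta = abs(b$r_w - a$r_w),
                                  stringsAsFactors = FALSE)
    }
    null <- do.call(rbind, null)
  }
  all_d <- do.call(rbind, deltas)
  rownames(all_d) <- NULL
  by_dose <- aggregate(abs_delta ~ dose, all_d, median)
  list(deltas = all_d, null = null, by_dose = by_dose)
}
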