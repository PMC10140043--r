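# Alternate aptamer-constraint analysis: enumerate every contiguous
# aptamer subregion, refold it in isolation, treat the refolded
# structure as the only part of the aptamer "locked" in the
# protein-bound state, recompute R_actual per subconstraint, and select
# the subconstraint best matching measured regulation ratios.

#' Enumerate all contiguous aptamer subconstraints
#'
#' For every 1-based pair (i, j) with i <= j, refolds the aptamer
#' subsequence i..j at MFE; unpaired flanking positions within the
#' subregion stay as unconstrained dots. Subsequences too short to pair
#' (< 5 nt) get an all-dot structure without invoking the engine.
#'
#' @param aptamer an \code{\link{aptamer_spec}} of length L.
#' @param temperature kelvin.
#' @return list of L(L+1)/2 subconstraints, each with \code{i}, \code{j}
#'   and \code{substructure}.
#' @export
enumerate_subconstraints <- function(aptamer, temperature = 310.15) {
  L <- nchar(aptamer$sequence)
  ij <- do.call(rbind, lapply(seq_len(L), function(i)
    cbind(i = i, j = i:L)))
  lens <- ij[, "j"] - ij[, "i"] + 1L
  subs <- substr(rep(aptamer$sequence, nrow(ij)), ij[, "i"], ij[, "j"])
  structures <- character(nrow(ij))
  structures[lens < 5L] <- strrep(".", lens[lens < 5L])
  todo <- which(lens >= 5L)
  if (length(todo) > 0L) {
    folds <- fold_mfe_batch(subs[todo], temperature = temperature)
    structures[todo] <- vapply(folds, `[[`, "", "structure")
  }
  lapply(seq_len(nrow(ij)), function(k) {
    structure(list(i = unname(ij[k, "i"]), j = unname(ij[k, "j"]),
                   substructure = structures[k]),
              class = "subconstraint")
  })
}

#' Rebuild a construct under an aptamer subconstraint
#'
#' Moves the aptamer sequence 5' of position i into the pre-aptamer
#' region and the sequence 3' of position j into the post-aptamer
#' region, leaving only positions i..j as the (re-folded) structural
#' constraint. The assembled mRNA sequence is unchanged; only the
#' constraint partition moves.
#'
#' @param x a \code{\link{riboswitch_construct}}.
#' @param s a subconstraint from \code{\link{enumerate_subconstraints}}.
#' @return a new \code{riboswitch_construct}.
#' @export
rebuild_construct <- function(x, s) {
  L <- nchar(x$aptamer$sequence)
  if (s$i < 1L || s$j > L || s$i > s$j) {
    stop("subconstraint (", s$i, ",", s$j, ") out of range for aptamer of length ", L)
  }
  sub_apt <- aptamer_spec(
    paste0(x$aptamer$name, "_", s$i, "_", s$j),
    substr(x$aptamer$sequence, s$i, s$j), s$substructure,
    x$aptamer$kd, ligand_name = x$aptamer$ligand_name)
  riboswitch_construct(
    x$name,
    paste0(x$pre_aptamer, substr(x$aptamer$sequence, 1L, s$i - 1L)),
    sub_apt,
    paste0(substr(x$aptamer$sequence, s$j + 1L, L), x$post_aptamer),
    x$cds, x$mode)
}

#' Scan predicted R_actual over all aptamer subconstraints
#'
#' Recomputes the R_actual prediction for every contiguous
#' subconstraint, holding all other sequences and model parameters
#' fixed; reports the grid and the max/min fold span across it.
#'
#' @param x a \code{\link{riboswitch_construct}}.
#' @param protein_conc the induction concentration, molar (typically
#'   the experiment's maximum dose).
#' @param calib \code{\link{calibration_params}}.
#' @return object of class \code{constraint_scan}: \code{grid}
#'   (data.frame i, j, r_actual), \code{baseline} (R_actual under the
#'   declared full-aptamer constraint), \code{fold_span}.
#' @export
scan_r_actual <- function(x, protein_conc, calib = calibration_params()) {
  subs <- enumerate_subconstraints(x$aptamer, temperature = calib$temperature)
  r <- vapply(subs, function(s) {
    evaluate_switch(rebuild_construct(x, s), protein_conc,
                    calib)$response$r_actual[1]
  }, 0)
  grid <- data.frame(
    i = vapply(subs, `[[`, 0L, "i"),
    j = vapply(subs, `[[`, 0L, "j"),
    r_actual = r
  )
  baseline <- evaluate_switch(x, protein_conc, calib)$response$r_actual[1]
  structure(list(grid = grid, baseline = baseline,
                 fold_span = max(r) / min(r),
                 protein_conc = protein_conc, name = x$name),
            class = "constraint_scan")
}

#' @export
print.constraint_scan <- function(x, ...) {
  cat("<constraint_scan>", x$name, "-", nrow(x$grid), "subconstraints at",
      format(x$protein_conc * 1e9), "nM\n")
  cat(sprintf("  baseline R_actual %.3g | grid span %.3g-fold (%.3g to %.3g)\n",
              x$baseline, x$fold_span, min(x$grid$r_actual),
              max(x$grid$r_actual)))
  invisible(x)
}

#' Select the aptamer subconstraint maximizing prediction accuracy
#'
#' For each candidate (i, j), accuracy is the squared Pearson
#' correlation between log predicted R_actual and log measured ratio
#' across riboswitches sharing the aptamer. Returns the argmax;
#' accuracy ties (within 1e-9) are broken toward the smallest region,
#' then the 5'-most. The fraction of riboswitches predicted within
#' 2-fold of measurement at the selected subconstraint is reported
#' alongside.
#'
#' @param scans named list of \code{constraint_scan} objects (>= 2),
#'   one per riboswitch, all over the same aptamer.
#' @param measured named numeric of measured regulation ratios (> 0),
#'   names matching \code{scans}.
#' @return list: \code{best} (i, j), \code{accuracy}, \code{within_2fold},
#'   \code{table} (per-subconstraint accuracies).
#' @export
select_constraint <- function(scans, measured) {
  if (length(scans) < 2L) {
    stop("accuracy undefined: need >= 2 riboswitches sharing the aptamer")
  }
  if (is.null(names(scans)) || !all(names(scans) %in% names(measured))) {
    stop("scans and measured must be named consistently")
  }
  measured <- measured[names(scans)]
  if (any(measured <= 0)) stop("measured ratios must be > 0")
  g0 <- scans[[1]]$grid
  pred <- vapply(scans, function(s) s$grid$r_actual, numeric(nrow(g0)))
  lm_meas <- log(measured)
  acc <- vapply(seq_len(nrow(g0)), function(k) {
    p <- log(pred[k, ])
    if (stats::sd(p) == 0 || stats::sd(lm_meas) == 0) return(NA_real_)
    stats::cor(p, lm_meas)^2
  }, 0)
  tab <- data.frame(i = g0$i, j = g0$j, accuracy = acc)
  cand <- which(!is.na(acc))
  if (length(cand) == 0L) {
    # all grids constant: fall back to the tie rule over every cell
    cand <- seq_len(nrow(g0))
    acc[cand] <- -Inf
  }
  best_acc <- max(acc[cand])
  tied <- cand[acc[cand] >= best_acc - 1e-9]
  width <- g0$j[tied] - g0$i[tied]
  tied <- tied[order(width, g0$i[tied])]
  k <- tied[1]
  within <- mean(pmax(pred[k, ] / measured, measured / pred[k, ]) <= 2)
  list(best = c(i = g0$i[k], j = g0$j[k]),
       accuracy = if (is.finite(acc[k])) acc[k] else NA_real_,
       within_2fold = within, table = tab)
}
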