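# The five-term ribosome-mRNA binding free-energy model.
#
# dG_total = dG_final - dG_initial, where
#   dG_initial = MFE of the free mRNA (aptamer constraint honored if bound)
#   dG_final   = dG_mRNA:rRNA + dG_start + dG_spacing + dG_standby
#                + MFE of the mRNA with the ribosome footprint held unpaired
# The SD placement minimizing dG_final over the allowed spacing range is
# reported. Positions are 1-based inclusive throughout.

#' An mRNA record for translation-initiation prediction
#'
#' @param name identifier.
#' @param sequence RNA (or DNA; T mapped to U) sequence, 5'->3'.
#' @param cds_start 1-based index of the first start-codon nucleotide.
#' @return object of class \code{mrna_record}.
#' @export
mrna_record <- function(name, sequence, cds_start) {
  sequence <- as_rna(sequence)
  cds_start <- as.integer(cds_start)
  n <- nchar(sequence)
  if (is.na(cds_start) || cds_start < 1L || cds_start > n - 2L) {
    stop("cds_start must lie within the sequence (leaving room for a codon)")
  }
  codon <- substr(sequence, cds_start, cds_start + 2L)
  if (!codon %in% c("AUG", "GUG", "UUG")) {
    stop("codon at cds_start is ", codon, "; expected AUG, GUG or UUG")
  }
  if (n < cds_start + 12L) {
    stop("sequence must extend >= 13 nt past cds_start so the ribosome footprint fits")
  }
  structure(list(name = as.character(name), sequence = sequence,
                 cds_start = cds_start),
            class = "mrna_record")
}

#' @export
print.mrna_record <- function(x, ...) {
  cat("<mrna_record>", x$name, "-", nchar(x$sequence), "nt, CDS at",
      x$cds_start, "\n")
  invisible(x)
}

#' Shine-Dalgarno hybridization energy within an mRNA window
#'
#' Most favorable duplex between the anti-SD (3' tail of the 16S rRNA)
#' and any subsequence of the window. Returns a no-site sentinel
#' (energy 0, flagged) when no duplex with negative free energy exists.
#'
#' @param mrna_window RNA string.
#' @param anti_sd 9-nt anti-SD sequence.
#' @param temperature kelvin.
#' @return list: \code{dg_mrna_rrna} (kcal/mol, <= 0), \code{sd_span}
#'   (1-based inclusive within the window, NULL when no site),
#'   \code{no_site}.
#' @export
sd_hybridization <- function(mrna_window, anti_sd = "ACCUCCUUA",
                             temperature = 310.15) {
  if (!nzchar(mrna_window)) stop("mrna_window must be non-empty")
  d <- duplex_fold(mrna_window, anti_sd, temperature = temperature)
  list(dg_mrna_rrna = d$energy, sd_span = d$query_span, no_site = d$no_site)
}

# Remove from a constraint any forced pair touching positions in `mask`,
# then force `mask` positions unpaired. Keeps the string balanced.
mask_constraint <- function(constraint, mask) {
  chars <- strsplit(constraint, "")[[1]]
  pt <- pair_table(constraint)
  for (i in which(pt > 0)) {
    if (i %in% mask || pt[i] %in% mask) {
      chars[i] <- "."
      chars[pt[i]] <- "."
    }
  }
  chars[mask] <- "x"
  paste(chars, collapse = "")
}

# Restrict a global constraint to a subsequence [a, b]: forced pairs
# wholly inside are kept, pairs crossing the boundary are dropped,
# 'x' marks are kept.
slice_constraint <- function(constraint, a, b) {
  chars <- strsplit(constraint, "")[[1]]
  pt <- pair_table(constraint)
  keep <- chars[a:b]
  for (i in which(pt > 0)) {
    if ((i >= a && i <= b) != (pt[i] >= a && pt[i] <= b)) {
      if (i >= a && i <= b) keep[i - a + 1L] <- "."
    }
  }
  paste(keep, collapse = "")
}

# Accessibility penalty for the standby site: unfolding free energy of
# structure formed within the window immediately 5' of the SD span,
# clamped at >= 0. Deliberately simple and isolated here so a more
# detailed standby model can replace it.
standby_penalty <- function(sequence, constraint, sd_start, calib) {
  a <- max(1L, sd_start - calib$standby_window)
  b <- sd_start - 1L
  if (b - a + 1L < 5L) return(list(dg_standby = 0, window = c(a, b)))
  sub_con <- slice_constraint(constraint, a, b)
  fs <- fold_mfe(substr(sequence, a, b), sub_con,
                 temperature = calib$temperature)
  list(dg_standby = max(0, -fs$dg_fold), window = c(a, b))
}

#' Final-state (ribosome-bound) free energy of an mRNA
#'
#' Enumerates candidate SD placements over the configured spacing range;
#' for each placement sums the mRNA:rRNA hybridization energy, the
#' start-codon/tRNA pairing energy, the spacing penalty, the standby-site
#' penalty and the folding energy of the mRNA refolded with the ribosome
#' footprint (5' end of the SD span through 13 nt past the start codon)
#' forced unpaired. Returns the placement minimizing the final-state
#' energy. When no SD placement forms any favorable duplex, a flagged
#' weakest-binding sentinel (zero hybridization at the nominal placement)
#' is returned rather than an error, so that dead design candidates can
#' still be scored.
#'
#' @param m \code{\link{mrna_record}}.
#' @param constraint optional global constraint (e.g. an aptamer locked
#'   in its protein-bound structure); forced pairs overlapping the
#'   footprint are displaced by the ribosome.
#' @param calib \code{\link{calibration_params}}.
#' @return list with \code{dg_mrna_rrna}, \code{dg_start},
#'   \code{dg_spacing}, \code{dg_standby}, \code{dg_outside},
#'   \code{dg_final}, \code{sd_span}, \code{spacing_nt},
#'   \code{final_state}, \code{no_sd}.
#' @export
ribosome_final_state <- function(m, constraint = NULL,
                                 calib = calibration_params()) {
  n <- nchar(m$sequence)
  if (is.null(constraint)) constraint <- strrep(".", n)
  validate_constraint(m$sequence, constraint)
  codon <- substr(m$sequence, m$cds_start, m$cds_start + 2L)
  dg_start <- calib$start_codon_energies[[codon]]
  foot_end <- min(n, m$cds_start + calib$footprint_past_start - 1L)
  wlen <- nchar(calib$anti_sd) + 2L

  # candidate windows, one per spacing value
  spac <- seq(calib$spacing_range[1], calib$spacing_range[2])
  ends <- m$cds_start - 1L - spac
  keep <- ends >= 1L
  spac <- spac[keep]; ends <- ends[keep]
  placements <- list()
  if (length(ends) > 0L) {
    starts <- pmax(1L, ends - wlen + 1L)
    wins <- substr(rep(m$sequence, length(ends)), starts, ends)
    dups <- duplex_fold_batch(wins, rep(calib$anti_sd, length(ends)),
                              temperature = calib$temperature)
    seen <- character(0)
    for (k in seq_along(dups)) {
      d <- dups[[k]]
      if (d$no_site) next
      span <- c(starts[k] - 1L + d$query_span[1], starts[k] - 1L + d$query_span[2])
      spacing <- m$cds_start - 1L - span[2]
      if (spacing < calib$spacing_range[1] || spacing > calib$spacing_range[2]) next
      key <- paste(span[1], span[2], d$energy)
      if (key %in% seen) next
      seen <- c(seen, key)
      placements[[length(placements) + 1L]] <-
        list(span = span, spacing = spacing, dg_mrna_rrna = d$energy)
    }
  }

  no_sd <- length(placements) == 0L
  if (no_sd) {
    # sentinel: nominal SD span at optimal spacing, zero hybridization
    b <- max(1L, m$cds_start - 1L - calib$spacing_optimum)
    a <- max(1L, b - nchar(calib$anti_sd) + 1L)
    placements <- list(list(span = c(a, b), spacing = m$cds_start - 1L - b,
                            dg_mrna_rrna = 0))
  }

  cons <- vapply(placements, function(p)
    mask_constraint(constraint, seq(p$span[1], foot_end)), "")
  folds <- fold_mfe_batch(rep(m$sequence, length(placements)), cons,
                          temperature = calib$temperature)
  best <- NULL
  for (k in seq_along(placements)) {
    p <- placements[[k]]
    sb <- standby_penalty(m$sequence, constraint, p$span[1], calib)
    e <- list(
      dg_mrna_rrna = p$dg_mrna_rrna,
      dg_start = dg_start,
      dg_spacing = unname(dg_spacing_penalty(p$spacing, calib)),
      dg_standby = sb$dg_standby,
      dg_outside = folds[[k]]$dg_fold,
      sd_span = p$span,
      spacing_nt = p$spacing,
      final_state = folds[[k]],
      no_sd = no_sd
    )
    e$dg_final <- e$dg_mrna_rrna + e$dg_start + e$dg_spacing +
      e$dg_standby + e$dg_outside
    if (is.null(best) ||
        e$dg_final < best$dg_final - 1e-9 ||
        (abs(e$dg_final - best$dg_final) <= 1e-9 &&
         (abs(e$spacing_nt - calib$spacing_optimum) <
            abs(best$spacing_nt - calib$spacing_optimum) ||
          (abs(e$spacing_nt - calib$spacing_optimum) ==
             abs(best$spacing_nt - calib$spacing_optimum) &&
           e$sd_span[1] < best$sd_span[1])))) {
      best <- e
    }
  }
  best
}

#' Total ribosome-mRNA binding free energy (dG_total)
#'
#' The difference between the final (ribosome-bound) and initial (free,
#' folded mRNA) state energies. The initial state honors the supplied
#' constraint (unconstrained for the protein-free state; aptamer locked
#' in its bound structure for the protein-bound state).
#'
#' @inheritParams ribosome_final_state
#' @return object of class \code{energy_breakdown} with the five model
#'   terms, \code{dg_initial}, \code{dg_final}, \code{dg_total}, the SD
#'   span and spacing, and the two fold states.
#' @export
total_binding_energy <- function(m, constraint = NULL,
                                 calib = calibration_params()) {
  init <- fold_mfe(m$sequence, constraint, temperature = calib$temperature)
  fin <- ribosome_final_state(m, constraint, calib)
  out <- c(fin, list(dg_initial = init$dg_fold, initial_state = init))
  out$dg_total <- out$dg_final - out$dg_initial
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> dG_total = %.2f kcal/mol (final %.2f - initial %.2f)\n",
    x$dg_total, x$dg_final, x$dg_initial))
  cat(sprintf(
    "  mRNA:rRNA %.2f | start %.2f | spacing %.2f | standby %.2f | outside-footprint %.2f\n",
    x$dg_mrna_rrna, x$dg_start, x$dg_spacing, x$dg_standby, x$dg_outside))
  cat("  SD span", paste(x$sd_span, collapse = "-"), "| spacing",
      x$spacing_nt, "nt", if (x$no_sd) "| NO SD SITE (sentinel)" else "", "\n")
  invisible(x)
}
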