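# Calibration parameters and the elementary thermodynamic relations
# (Boltzmann rate law, spacing penalty, ligand free energy, occupancy).

#' Gas constant times temperature, in kcal/mol
#' @param temperature kelvin.
#' @export
rt_kcal <- function(temperature = 310.15) 0.0019872 * temperature

#' Calibration parameters for the ribosome-binding free-energy model
#'
#' Bundles every tunable constant of the translation-initiation model.
#' \code{beta} converts free energy to rate via the Boltzmann relation
#' \code{TIR = k_tir * exp(-beta * dG_total)}. The default \code{beta}
#' of 0.45 (kcal/mol)^-1 is the in vivo apparent Boltzmann factor;
#' cell-free (TX-TL) assays show a compressed apparent beta near 0.23,
#' which can be refit from data with \code{\link{fit_beta}}. The default
#' \code{k_tir} anchors a dG_total of -7.52 kcal/mol to 36,400 au, the
#' translation initiation rate of the standard no-aptamer 5' UTR used as
#' assay control.
#'
#' Spacing and start-codon energetics are calibration data, not
#' thermodynamic constants: the spacing penalty is piecewise quadratic
#' in the deviation from \code{spacing_optimum}, with separate
#' compression and stretch coefficients (kcal/mol/nt^2).
#'
#' @param beta Boltzmann factor, (kcal/mol)^-1, > 0.
#' @param k_tir TIR proportionality constant, arbitrary units, > 0.
#' @param temperature kelvin; also the folding temperature.
#' @param anti_sd 3'-terminal nine nucleotides of the 16S rRNA, written
#'   3'->5' relative to the genome so that it aligns antiparallel to the
#'   mRNA; default the E. coli sequence ACCUCCUUA.
#' @param footprint_past_start ribosome footprint extent measured in
#'   nucleotides from (and including) the first start-codon position;
#'   default 13, i.e. the footprint ends 13 nt into the CDS.
#' @param spacing_optimum optimal SD-to-start spacing, nt.
#' @param spacing_penalty_coeffs named numeric, \code{compress} and
#'   \code{stretch} quadratic coefficients.
#' @param spacing_range integer range of spacings enumerated during the
#'   SD placement search.
#' @param standby_window nt immediately 5' of the SD span scanned for
#'   occluding hairpins.
#' @param start_codon_energies named kcal/mol per start codon (<= 0).
#' @return object of class \code{calibration_params}.
#' @export
calibration_params <- function(beta = 0.45,
                               k_tir = 36400 * exp(-0.45 * 7.52),
                               temperature = 310.15,
                               anti_sd = "ACCUCCUUA",
                               footprint_past_start = 13L,
                               spacing_optimum = 5L,
                               spacing_penalty_coeffs = c(compress = 0.15, stretch = 0.04),
                               spacing_range = c(0L, 15L),
                               standby_window = 15L,
                               start_codon_energies = c(AUG = -1.19, GUG = -0.50, UUG = -0.30)) {
  anti_sd <- as_rna(anti_sd)
  stopifnot(beta > 0, k_tir > 0, temperature > 0, nchar(anti_sd) == 9L,
            footprint_past_start >= 3L, spacing_optimum >= 0L,
            all(c("compress", "stretch") %in% names(spacing_penalty_coeffs)),
            all(spacing_penalty_coeffs >= 0),
            length(spacing_range) == 2L, spacing_range[1] <= spacing_range[2],
            standby_window >= 0L, all(start_codon_energies <= 0),
            all(c("AUG", "GUG", "UUG") %in% names(start_codon_energies)))
  structure(list(
    beta = beta, k_tir = k_tir, temperature = temperature, anti_sd = anti_sd,
    footprint_past_start = as.integer(footprint_past_start),
    spacing_optimum = as.integer(spacing_optimum),
    spacing_penalty_coeffs = spacing_penalty_coeffs,
    spacing_range = as.integer(spacing_range),
    standby_window = as.integer(standby_window),
    start_codon_energies = start_codon_energies
  ), class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("Calibration: beta =", x$beta, "(kcal/mol)^-1, k_tir =",
      format(x$k_tir, digits = 6), "au, T =", x$temperature, "K\n")
  cat("  anti-SD", x$anti_sd, "| footprint", x$footprint_past_start,
      "nt past start | spacing optimum", x$spacing_optimum,
      "nt in [", x$spacing_range[1], ",", x$spacing_range[2], "]\n")
  cat("  spacing coeffs compress/stretch:",
      paste(x$spacing_penalty_coeffs, collapse = "/"),
      "| standby window", x$standby_window, "nt\n")
  cat("  start codons:",
      paste(names(x$start_codon_energies), x$start_codon_energies,
            sep = "=", collapse = " "), "kcal/mol\n")
  invisible(x)
}

#' Read/write calibration parameters as YAML
#' @param path file path.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  y$spacing_penalty_coeffs <- unlist(y$spacing_penalty_coeffs)
  y$start_codon_energies <- unlist(y$start_codon_energies)
  do.call(calibration_params, y)
}

#' @rdname read_calibration
#' @param calib a \code{calibration_params} object.
#' @export
write_calibration <- function(calib, path) {
  obj <- unclass(calib)
  # named numeric vectors must become YAML maps, not bare sequences
  obj$spacing_penalty_coeffs <- as.list(obj$spacing_penalty_coeffs)
  obj$start_codon_energies <- as.list(obj$start_codon_energies)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Spacing penalty for non-optimal SD-to-start-codon distance
#'
#' Zero at the optimum; quadratic in the deviation with separate
#' coefficients for ribosomal compression (spacing below optimum) and
#' stretch (above).
#'
#' @param spacing nt between the 3' end of the SD-paired span and the
#'   start codon (vectorized).
#' @param calib \code{\link{calibration_params}}.
#' @return penalty in kcal/mol, >= 0.
#' @export
dg_spacing_penalty <- function(spacing, calib) {
  d <- spacing - calib$spacing_optimum
  co <- calib$spacing_penalty_coeffs
  ifelse(d < 0, co[["compress"]] * d^2, co[["stretch"]] * d^2)
}

#' Translation initiation rate from total binding free energy
#'
#' Boltzmann relation \code{rate = k_tir * exp(-beta * dg_total)}:
#' strictly positive and strictly decreasing in \code{dg_total}; rate
#' ratios depend only on free-energy differences.
#'
#' @param dg_total ribosome binding free energy, kcal/mol (vectorized).
#' @param calib \code{\link{calibration_params}}.
#' @return rate in arbitrary units.
#' @export
tir <- function(dg_total, calib = calibration_params()) {
  calib$k_tir * exp(-calib$beta * dg_total)
}

#' Maximum fold-change between two ribosome-binding free energies
#'
#' \code{exp(-beta * (dg_bound - dg_unbound))}: the ratio of bound-state
#' to unbound-state translation rates at ligand saturation. Equals
#' R_max for an ON switch and 1/R_max for an OFF switch.
#'
#' @param dg_bound,dg_unbound kcal/mol.
#' @param beta (kcal/mol)^-1.
#' @export
max_fold_change <- function(dg_bound, dg_unbound, beta = 0.45) {
  exp(-beta * (dg_bound - dg_unbound))
}

#' Protein-aptamer binding free energy from a dissociation constant
#'
#' \code{RT * ln(Kd)} with the 1 M reference state; negative for
#' sub-molar Kd.
#'
#' @param kd dissociation constant, molar, > 0 (vectorized).
#' @param temperature kelvin.
#' @return kcal/mol.
#' @export
dg_ligand_from_kd <- function(kd, temperature = 310.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive and finite")
  rt_kcal(temperature) * log(kd)
}

#' Equilibrium fraction of aptamer bound by protein
#'
#' Single-site binding with the protein in excess of mRNA:
#' \code{f = P / (P + kd_eff)}.
#'
#' @param protein_conc molar, >= 0 (vectorized; Inf allowed).
#' @param kd_eff effective dissociation constant, molar, > 0.
#' @export
fraction_bound <- function(protein_conc, kd_eff) {
  if (any(protein_conc < 0, na.rm = TRUE)) stop("protein_conc must be >= 0")
  if (any(kd_eff <= 0)) stop("kd_eff must be > 0")
  ifelse(is.infinite(protein_conc), 1, protein_conc / (protein_conc + kd_eff))
}
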