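# Four-state riboswitch evaluation: the free mRNA and the ribosome-bound
# mRNA, each with and without the protein ligand, and the three
# regulation-ratio predictions R_max, R_conc and R_actual.

#' Refolding penalty of the protein-bound conformation
#'
#' Free-energy cost of rearranging the free mRNA's MFE structure into a
#' conformation compatible with the aptamer's protein-bound structure:
#' \code{max(0, dG_initial(constrained) - dG_initial(unconstrained))}.
#' This is the structural work the protein's binding free energy must
#' pay for; it feeds the effective dissociation constant behind
#' R_actual.
#'
#' @param x a \code{\link{riboswitch_construct}}.
#' @param calib \code{\link{calibration_params}}.
#' @return kcal/mol, >= 0.
#' @export
refolding_penalty <- function(x, calib = calibration_params()) {
  m <- assemble_mrna(x)
  free <- fold_mfe(m$sequence, temperature = calib$temperature)
  locked <- fold_mfe(m$sequence, bound_constraint(x),
                     temperature = calib$temperature)
  max(0, locked$dg_fold - free$dg_fold)
}

#' Evaluate the four predominant riboswitch states
#'
#' Computes ribosome-binding free-energy breakdowns for the protein-free
#' state (unconstrained folding) and the protein-bound state (aptamer
#' locked in its bound structure in both the initial and final states),
#' converts them to translation initiation rates, and derives the three
#' regulation-ratio predictions:
#' \itemize{
#'   \item \code{r_max}: fold-change at ligand saturation,
#'     \code{TIR_bound/TIR_unbound} for ON switches and its reciprocal
#'     for OFF switches;
#'   \item \code{r_conc}: fold-change at the stated protein
#'     concentration, mixing the two rates by the equilibrium bound
#'     fraction \code{f = P/(P + Kd)};
#'   \item \code{r_actual}: as \code{r_conc} but with the effective
#'     dissociation constant \code{Kd_eff = Kd * exp(dG_refold/RT)}
#'     penalizing ligand-bound conformations the mRNA must pay refolding
#'     energy to reach.
#' }
#' Rates (not free energies) are averaged across the bound/unbound
#' ensemble, and all ratios are oriented by mode so that values >= 1
#' mean the switch works as designed.
#'
#' @param x a \code{\link{riboswitch_construct}}.
#' @param protein_conc protein concentration(s), molar (vectorized;
#'   \code{Inf} = saturation).
#' @param calib \code{\link{calibration_params}}.
#' @return object of class \code{switch_prediction}.
#' @export
evaluate_switch <- function(x, protein_conc = Inf,
                            calib = calibration_params()) {
  stopifnot(inherits(x, "riboswitch_construct"))
  if (any(protein_conc < 0, na.rm = TRUE)) stop("protein_conc must be >= 0")
  m <- assemble_mrna(x)
  unbound <- total_binding_energy(m, NULL, calib)
  bound <- total_binding_energy(m, bound_constraint(x), calib)

  rt <- rt_kcal(calib$temperature)
  dg_refold <- max(0, bound$dg_initial - unbound$dg_initial)
  kd_eff <- x$aptamer$kd * exp(dg_refold / rt)
  tir_unbound <- tir(unbound$dg_total, calib)
  tir_bound <- tir(bound$dg_total, calib)

  on_ratio <- tir_bound / tir_unbound
  r_max <- if (x$mode == "ON") on_ratio else 1 / on_ratio

  mix <- function(f) f * tir_bound + (1 - f) * tir_unbound
  ratio_at <- function(f) {
    if (x$mode == "ON") mix(f) / tir_unbound else tir_unbound / mix(f)
  }
  f_conc <- fraction_bound(protein_conc, x$aptamer$kd)
  f_actual <- fraction_bound(protein_conc, kd_eff)
  response <- data.frame(
    protein_conc = protein_conc,
    f_conc = f_conc, f_actual = f_actual,
    r_conc = ratio_at(f_conc), r_actual = ratio_at(f_actual)
  )

  structure(list(
    name = x$name, mode = x$mode,
    unbound = unbound, bound = bound,
    dg_ligand = dg_ligand_from_kd(x$aptamer$kd, calib$temperature),
    dg_refold = dg_refold, kd_eff = kd_eff,
    tir_unbound = tir_unbound, tir_bound = tir_bound,
    r_max = r_max, response = response
  ), class = "switch_prediction")
}

#' @export
print.switch_prediction <- function(x, ...) {
  cat(sprintf("<switch_prediction> %s [%s]\n", x$name, x$mode))
  cat(sprintf("  dG_total unbound %.2f | bound %.2f kcal/mol\n",
              x$unbound$dg_total, x$bound$dg_total))
  cat(sprintf("  TIR unbound %.1f | bound %.1f au | R_max %.3g\n",
              x$tir_unbound, x$tir_bound, x$r_max))
  cat(sprintf("  dG_ligand %.2f | dG_refold %.2f kcal/mol | Kd_eff %.3g nM\n",
              x$dg_ligand, x$dg_refold, x$kd_eff * 1e9))
  for (k in seq_len(nrow(x$response))) {
    cat(sprintf("  P = %.4g nM: R_conc %.3g, R_actual %.3g\n",
                x$response$protein_conc[k] * 1e9,
                x$response$r_conc[k], x$response$r_actual[k]))
  }
  invisible(x)
}

#' Serialize / reload a switch prediction at full precision
#'
#' JSON round trip reproducing all energies and ratios bit-identically.
#' @param pred a \code{switch_prediction}.
#' @param path file path.
#' @export
write_switch_prediction <- function(pred, path) {
  strip <- function(e) {
    e$final_state <- unclass(e$final_state)
    e$initial_state <- unclass(e$initial_state)
    unclass(e)
  }
  obj <- unclass(pred)
  obj$unbound <- strip(obj$unbound)
  obj$bound <- strip(obj$bound)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_switch_prediction
#' @export
read_switch_prediction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(e) {
    e$final_state <- structure(e$final_state, class = "fold_state")
    e$initial_state <- structure(e$initial_state, class = "fold_state")
    structure(e, class = "energy_breakdown")
  }
  obj$unbound <- restore(obj$unbound)
  obj$bound <- restore(obj$bound)
  obj$response <- as.data.frame(obj$response)
  structure(obj, class = "switch_prediction")
}
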