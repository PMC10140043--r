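# Readers and writers: mRNA FASTA with cds_start header keys, plate CSV
# (long format) + well-map CSV, and TSV result tables.

#' Read mRNA records from FASTA
#'
#' Headers may carry a per-record \code{cds_start=N} key
#' (\code{>name cds_start=31}); otherwise \code{cds_start} supplies a
#' common value.
#'
#' @param path FASTA file.
#' @param cds_start fallback CDS start (1-based) for records without a
#'   header key.
#' @return list of \code{\link{mrna_record}}.
#' @export
read_mrna_fasta <- function(path, cds_start = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  lapply(seq_along(set), function(k) {
    hdr <- names(set)[k]
    name <- strsplit(hdr, "\\s+")[[1]][1]
    m <- regmatches(hdr, regexec("cds_start=(\\d+)", hdr))[[1]]
    cs <- if (length(m) == 2L) as.integer(m[2]) else cds_start
    if (is.null(cs)) stop("record ", name, " has no cds_start (header key or argument)")
    mrna_record(name, as.character(set[[k]]), cs)
  })
}

#' Write mRNA records to FASTA (cds_start in the header)
#' @param records list of \code{\link{mrna_record}}.
#' @param path output file.
#' @export
write_mrna_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, function(m)
    sprintf("%s cds_start=%d", m$name, m$cds_start), "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read plate-reader kinetic data
#'
#' Plate CSV is long format with columns \code{time_min, well,
#' fluorescence}; the well map has \code{well, construct, role,
#' ligand_conc_nM, replicate}.
#'
#' @param plate_path,wellmap_path CSV files.
#' @return named list of \code{\link{kinetic_trace}} (by well).
#' @export
read_plate_csv <- function(plate_path, wellmap_path) {
  plate <- utils::read.csv(plate_path, stringsAsFactors = FALSE)
  wellmap <- utils::read.csv(wellmap_path, stringsAsFactors = FALSE)
  need <- c("time_min", "well", "fluorescence")
  if (!all(need %in% names(plate))) {
    stop("plate CSV must have columns ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(wellmap)), function(k) {
    w <- wellmap$well[k]
    d <- plate[plate$well == w, ]
    d <- d[order(d$time_min), ]
    if (nrow(d) == 0L) stop("well ", w, " in well map has no plate data")
    kinetic_trace(w, d$time_min, d$fluorescence,
                  construct = wellmap$construct[k], role = wellmap$role[k],
                  ligand_conc = wellmap$ligand_conc_nM[k] * 1e-9,
                  replicate = wellmap$replicate[k])
  })
  names(out) <- wellmap$well
  out
}

#' @rdname read_plate_csv
#' @param traces list of \code{\link{kinetic_trace}}.
#' @export
write_plate_csv <- function(traces, plate_path, wellmap_path) {
  plate <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_min = tr$times, well = tr$well,
               fluorescence = tr$fluorescence)))
  wellmap <- do.call(rbind, lapply(traces, function(tr)
    data.frame(well = tr$well, construct = tr$construct, role = tr$role,
               ligand_conc_nM = tr$ligand_conc * 1e9,
               replicate = tr$replicate)))
  utils::write.csv(plate, plate_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(wellmap, wellmap_path, row.names = FALSE, quote = FALSE)
  invisible(plate_path)
}

#' Tabulate TIR predictions for a set of mRNA records
#'
#' The \code{predict-tir} work horse: one row per record with the full
#' five-term energy decomposition and the Boltzmann-rate TIR.
#'
#' @param records list of \code{\link{mrna_record}}.
#' @param calib \code{\link{calibration_params}}.
#' @return data.frame.
#' @export
predict_tir_table <- function(records, calib = calibration_params()) {
  do.call(rbind, lapply(records, function(m) {
    e <- total_binding_energy(m, NULL, calib)
    data.frame(name = m$name, dg_mrna_rrna = e$dg_mrna_rrna,
               dg_start = e$dg_start, dg_spacing = e$dg_spacing,
               dg_standby = e$dg_standby, dg_initial = e$dg_initial,
               dg_final = e$dg_final, dg_total = e$dg_total,
               sd_start = e$sd_span[1], sd_end = e$sd_span[2],
               spacing_nt = e$spacing_nt, no_sd = e$no_sd,
               tir = tir(e$dg_total, calib))
  }))
}

#' Tabulate switch predictions for constructs at given concentrations
#'
#' @param constructs list of \code{\link{riboswitch_construct}}.
#' @param protein_conc molar concentration(s).
#' @param calib \code{\link{calibration_params}}.
#' @return data.frame, one row per construct x concentration.
#' @export
predict_switch_table <- function(constructs, protein_conc = Inf,
                                 calib = calibration_params()) {
  do.call(rbind, lapply(constructs, function(x) {
    p <- evaluate_switch(x, protein_conc, calib)
    data.frame(name = p$name, mode = p$mode,
               dg_total_unbound = p$unbound$dg_total,
               dg_total_bound = p$bound$dg_total,
               dg_ligand = p$dg_ligand, dg_refold = p$dg_refold,
               kd_eff = p$kd_eff, tir_unbound = p$tir_unbound,
               tir_bound = p$tir_bound, r_max = p$r_max,
               protein_conc = p$response$protein_conc,
               r_conc = p$response$r_conc, r_actual = p$response$r_actual)
  }))
}
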