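# Synthetic fixtures with known ground truth: plate-reader traces,
# random toy constructs, and whole simulated studies whose endpoints,
# ratios, Boltzmann factor and generating subconstraint are recoverable
# by the downstream analysis modules.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Parameters for a synthetic plate-reader trace
#'
#' Emulates mRFP1 accumulation kinetics in a cell-free reaction: a flat
#' autofluorescence baseline, a slow linear drift present even without
#' DNA, a logistic rise to a plateau once mature reporter accumulates,
#' and Gaussian reader noise.
#'
#' @param plateau expression plateau above baseline, au, >= 0.
#' @param onset_time logistic midpoint, minutes.
#' @param rise_rate logistic rate, 1/min.
#' @param baseline autofluorescence, au.
#' @param drift_slope non-specific drift, au/min.
#' @param noise_sd Gaussian noise sd, au, >= 0.
#' @param n_points number of reads, >= 30.
#' @param interval minutes between reads (default 10).
#' @param seed mandatory integer seed.
#' @export
trace_params <- function(plateau, onset_time = 480, rise_rate = 0.08,
                         baseline = 50, drift_slope = 0.05, noise_sd = 0,
                         n_points = 97L, interval = 10, seed) {
  if (missing(seed)) stop("seed is mandatory for trace generation")
  stopifnot(plateau >= 0, noise_sd >= 0, n_points >= 30L, interval > 0)
  structure(list(plateau = plateau, onset_time = onset_time,
                 rise_rate = rise_rate, baseline = baseline,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 n_points = as.integer(n_points), interval = interval,
                 seed = as.integer(seed)),
            class = "trace_params")
}

#' Generate a synthetic kinetic trace
#'
#' \code{fluorescence(t) = baseline + drift_slope * t +
#' plateau / (1 + exp(-rise_rate * (t - onset_time))) + N(0, noise_sd)};
#' seeded and reproducible.
#'
#' @param p a \code{\link{trace_params}}.
#' @param well,construct,role,ligand_conc,replicate trace metadata
#'   passed to \code{\link{kinetic_trace}}.
#' @export
generate_trace <- function(p, well = "A1", construct = NA_character_,
                           role = "riboswitch", ligand_conc = 0,
                           replicate = 1L) {
  stopifnot(inherits(p, "trace_params"))
  times <- (seq_len(p$n_points) - 1L) * p$interval
  mu <- p$baseline + p$drift_slope * times +
    p$plateau * stats::plogis(p$rise_rate * (times - p$onset_time))
  noise <- if (p$noise_sd > 0) {
    with_local_seed(p$seed, stats::rnorm(p$n_points, 0, p$noise_sd))
  } else rep(0, p$n_points)
  kinetic_trace(well, times, mu + noise, construct = construct, role = role,
                ligand_conc = ligand_conc, replicate = replicate)
}

#' Random toy riboswitch construct around an aptamer
#'
#' Samples random designed pre/post regions around the aptamer, with a
#' fixed SD cassette ahead of the CDS so every construct can initiate
#' translation; mode is oriented to the direction the construct
#' actually switches (so that the reported ratios are >= 1 by the mode
#' convention).
#'
#' @param aptamer an \code{\link{aptamer_spec}}.
#' @param seed integer seed.
#' @param pre_len,post_len designed region lengths (post is 5' of the
#'   SD cassette).
#' @param sd_cassette fixed SD + spacer placed before the CDS.
#' @param cds coding sequence.
#' @param calib \code{\link{calibration_params}} used for mode
#'   orientation.
#' @return a \code{riboswitch_construct}.
#' @export
random_construct <- function(aptamer, seed, pre_len = 8L, post_len = 8L,
                             sd_cassette = "UAAGGAGGUAAUAU",
                             cds = "AUGAGCAAAGGAGAAGAAC",
                             calib = calibration_params()) {
  with_local_seed(seed, {
    pre <- if (pre_len > 0) paste(sample(.rna_alphabet, pre_len, TRUE),
                                  collapse = "") else ""
    post <- if (post_len > 0) paste(sample(.rna_alphabet, post_len, TRUE),
                                    collapse = "") else ""
    x <- riboswitch_construct(paste0("toy_", seed), pre, aptamer,
                              paste0(post, sd_cassette), cds, "OFF")
    pred <- evaluate_switch(x, Inf, calib)
    if (pred$tir_bound > pred$tir_unbound) x$mode <- "ON"
    x
  })
}

#' Generate a complete synthetic riboswitch study
#'
#' Builds a toy aptamer and a panel of constructs around it, computes
#' the model-true predictions under a chosen "true" subconstraint and a
#' chosen true Boltzmann factor, then emits plate-reader traces whose
#' endpoints encode those truths (with optional lognormal measurement
#' noise). Every downstream quantity - corrected endpoints, regulation
#' ratios, the apparent beta, the generating subconstraint - is
#' recoverable from the generated artifacts alone.
#'
#' @param n_constructs constructs in the panel.
#' @param doses ligand doses, molar (0 is added automatically).
#' @param true_beta Boltzmann factor used to map dG_total to endpoints.
#' @param true_subconstraint integer c(i, j) locked region generating
#'   the "measured" ratios, or NULL for the full declared structure.
#' @param noise_cv lognormal coefficient of variation on endpoints.
#' @param n_replicates replicate traces per condition.
#' @param aptamer toy aptamer (default: bulged hairpin, stem 5, loop 5).
#' @param seed integer seed driving every random choice.
#' @param calib \code{\link{calibration_params}}; its beta is replaced
#'   by \code{true_beta} for truth generation.
#' @param dir optional directory; when given, writes plate.csv,
#'   wellmap.csv, constructs.tsv, aptamer.yaml and truth.json there.
#' @return list: \code{aptamer}, \code{constructs}, \code{truth}
#'   (data.frame of per-condition true endpoints and ratios),
#'   \code{dg_totals}, \code{traces}, \code{calib}, \code{seed}.
#' @export
generate_study <- function(n_constructs = 6L, doses = c(12.5e-9, 1250e-9),
                           true_beta = 0.23, true_subconstraint = NULL,
                           noise_cv = 0, n_replicates = 1L,
                           aptamer = NULL, seed = 1L,
                           calib = calibration_params(), dir = NULL) {
  if (is.null(aptamer)) {
    aptamer <- toy_aptamer("bulged_hairpin", stem_len = 5L, loop_len = 5L,
                           kd = 2e-8, temperature = calib$temperature)
  }
  true_calib <- calib
  true_calib$beta <- true_beta

  constructs <- lapply(seq_len(n_constructs), function(k) {
    random_construct(aptamer, seed = seed * 1000L + k,
                     pre_len = 4L + (k %% 5L), post_len = 5L + (k %% 7L),
                     calib = true_calib)
  })
  names(constructs) <- vapply(constructs, `[[`, "", "name")

  truth_rows <- list()
  traces <- list()
  all_doses <- sort(unique(c(0, doses)))
  scale_au <- 0.05   # au of plateau per au of model TIR
  noise_sdlog <- sqrt(log(1 + noise_cv^2))
  widx <- 0L
  with_local_seed(seed, {
    for (x in constructs) {
      xt <- if (is.null(true_subconstraint)) x else {
        subs <- enumerate_subconstraints(x$aptamer,
                                         temperature = true_calib$temperature)
        pick <- Filter(function(s) s$i == true_subconstraint[1] &&
                         s$j == true_subconstraint[2], subs)[[1]]
        rebuild_construct(x, pick)
      }
      pred <- evaluate_switch(xt, all_doses, true_calib)
      for (di in seq_along(all_doses)) {
        f <- pred$response$f_actual[di]
        rate <- f * pred$tir_bound + (1 - f) * pred$tir_unbound
        for (rep_k in seq_len(n_replicates)) {
          widx <- widx + 1L
          e_true <- rate * scale_au *
            if (noise_cv > 0) stats::rlnorm(1, -noise_sdlog^2 / 2, noise_sdlog) else 1
          tp <- trace_params(plateau = e_true, noise_sd = 0,
                             seed = seed * 100000L + widx)
          traces[[length(traces) + 1L]] <- generate_trace(
            tp, well = sprintf("W%03d", widx), construct = x$name,
            role = "riboswitch", ligand_conc = all_doses[di],
            replicate = rep_k)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            construct = x$name, ligand_conc = all_doses[di],
            replicate = rep_k, true_endpoint = e_true,
            true_rate = rate, r_actual_true = pred$response$r_actual[di],
            dg_total_unbound = pred$unbound$dg_total,
            dg_total_bound = pred$bound$dg_total, mode = x$mode)
        }
      }
    }
  })
  widx <- widx + 1L
  no_dna <- generate_trace(trace_params(plateau = 0, noise_sd = 0,
                                        seed = seed * 100000L + widx),
                           well = sprintf("W%03d", widx),
                           construct = "no_dna", role = "no_dna_control")
  traces[[length(traces) + 1L]] <- no_dna
  truth <- do.call(rbind, truth_rows)

  study <- list(aptamer = aptamer, constructs = constructs, truth = truth,
                dg_totals = vapply(constructs, function(x)
                  evaluate_switch(x, 0, true_calib)$unbound$dg_total, 0),
                traces = traces, true_beta = true_beta,
                true_subconstraint = true_subconstraint,
                scale_au = scale_au, calib = true_calib, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_plate_csv(traces, file.path(dir, "plate.csv"),
                    file.path(dir, "wellmap.csv"))
    write_constructs_tsv(constructs, file.path(dir, "constructs.tsv"))
    write_aptamer_yaml(aptamer, file.path(dir, "aptamer.yaml"))
    jsonlite::write_json(
      list(seed = seed, true_beta = true_beta,
           true_subconstraint = true_subconstraint, scale_au = scale_au,
           truth = truth),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  study
}
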