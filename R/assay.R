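# Cell-free (TX-TL) assay analysis: kinetic traces to corrected
# endpoints, regulation ratios with non-specific-control correction,
# Hill dose-response fits and apparent-Boltzmann-factor calibration.

#' A plate-reader kinetic fluorescence trace
#'
#' @param well well identifier.
#' @param times minutes, strictly increasing.
#' @param fluorescence arbitrary units, same length, no NaN.
#' @param construct construct id.
#' @param role one of \code{riboswitch}, \code{no_aptamer_control},
#'   \code{no_mrfp1_control}, \code{no_dna_control}.
#' @param ligand_conc ligand concentration, molar.
#' @param replicate replicate index.
#' @return object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(well, times, fluorescence, construct = NA_character_,
                          role = c("riboswitch", "no_aptamer_control",
                                   "no_mrfp1_control", "no_dna_control"),
                          ligand_conc = 0, replicate = 1L) {
  role <- match.arg(role)
  times <- as.numeric(times)
  fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence)) {
    stop("times and fluorescence must have equal length")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing")
  }
  if (any(!is.finite(fluorescence))) {
    stop("fluorescence contains non-finite values in well ", well)
  }
  structure(list(well = as.character(well), times = times,
                 fluorescence = fluorescence, construct = construct,
                 role = role, ligand_conc = ligand_conc,
                 replicate = as.integer(replicate)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("<kinetic_trace>", x$well, "-", x$construct, sprintf("[%s]", x$role),
      length(x$times), "points,",
      format(x$ligand_conc * 1e9), "nM ligand\n")
  invisible(x)
}

#' Corrected expression endpoint of a kinetic trace
#'
#' Endpoint = mean of the last \code{window} points; background = mean
#' of the first \code{window} points (before mature reporter
#' accumulates); the non-specific fluorescence drift is the same
#' endpoint-minus-background computed on a no-DNA reaction and is
#' subtracted:
#' \code{corrected = (endpoint - background) - drift}.
#'
#' @param trace riboswitch/control \code{\link{kinetic_trace}}.
#' @param no_dna matching no-DNA \code{\link{kinetic_trace}}.
#' @param window points per averaging window (default 15); the two
#'   windows must not overlap.
#' @return object of class \code{assay_result}.
#' @export
endpoint <- function(trace, no_dna, window = 15L) {
  for (tr in list(trace, no_dna)) {
    if (length(tr$times) < 2L * window) {
      stop("trace in well ", tr$well, " has ", length(tr$times),
           " points; endpoint analysis needs >= ", 2L * window,
           " so the two ", window, "-point windows do not overlap")
    }
  }
  win_stats <- function(tr) {
    n <- length(tr$fluorescence)
    c(bg = mean(tr$fluorescence[seq_len(window)]),
      end = mean(tr$fluorescence[seq(n - window + 1L, n)]))
  }
  s <- win_stats(trace)
  d <- win_stats(no_dna)
  drift <- unname(d["end"] - d["bg"])
  structure(list(
    well = trace$well, construct = trace$construct, role = trace$role,
    ligand_conc = trace$ligand_conc, replicate = trace$replicate,
    endpoint = unname(s["end"]), background = unname(s["bg"]),
    drift_correction = drift,
    corrected_endpoint = unname(s["end"] - s["bg"]) - drift,
    window = as.integer(window)
  ), class = "assay_result")
}

#' Aggregate replicate endpoints
#'
#' @param results list of \code{assay_result} replicates of one condition.
#' @return data.frame with n, mean, sd and the 95\% t-interval of the
#'   corrected endpoint.
#' @export
summarize_endpoints <- function(results) {
  x <- vapply(results, `[[`, 0, "corrected_endpoint")
  n <- length(x)
  s <- if (n > 1L) stats::sd(x) else NA_real_
  half <- if (n > 1L) stats::qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
  data.frame(n_replicates = n, mean = mean(x), sd = s,
             ci_lo = mean(x) - half, ci_hi = mean(x) + half)
}

as_endpoint_value <- function(x) {
  if (inherits(x, "assay_result")) x$corrected_endpoint else as.numeric(x)
}

#' Regulation (activation or repression) ratio
#'
#' ON switches: endpoint with ligand over endpoint without; OFF
#' switches: the reciprocal. Measured this way, a construct whose
#' expression moves opposite to its declared mode has ratio < 1.
#'
#' @param with_ligand,without_ligand corrected endpoints (numbers or
#'   \code{assay_result}s), must be > 0.
#' @param mode \code{"ON"} or \code{"OFF"}.
#' @return ratio >= 0.
#' @export
regulation_ratio <- function(with_ligand, without_ligand, mode = c("OFF", "ON")) {
  mode <- match.arg(toupper(mode), c("OFF", "ON"))
  a <- as_endpoint_value(with_ligand)
  b <- as_endpoint_value(without_ligand)
  if (any(c(a, b) <= 0)) {
    stop("degenerate ratio: non-positive corrected endpoint (",
         format(a), ", ", format(b), ")")
  }
  if (mode == "ON") a / b else b / a
}

#' Divide out the non-specific effect measured on a no-aptamer control
#'
#' The control's ratio must be expressed in the same mode orientation
#' as the riboswitch (an OFF-mode control that rises 2.37-fold has
#' repression ratio 1/2.37, so dividing by it multiplies the raw
#' repression up). Using \code{\link{regulation_ratio}} with the same
#' \code{mode} on the control endpoints produces exactly that
#' orientation.
#'
#' @param riboswitch_ratio,control_ratio mode-oriented ratios, > 0.
#' @return corrected ratio \code{riboswitch_ratio / control_ratio}.
#' @export
correct_nonspecific <- function(riboswitch_ratio, control_ratio) {
  if (any(riboswitch_ratio <= 0) || any(control_ratio <= 0)) {
    stop("ratios must be > 0")
  }
  riboswitch_ratio / control_ratio
}

#' Fit a Hill dose-response curve to corrected endpoints
#'
#' Least squares of \code{endpoint = baseline + amplitude * P^n /
#' (P^n + half_max^n)}; the amplitude's sign encodes activation
#' (positive) or repression (negative). Initial values: baseline from
#' the zero-dose endpoints, amplitude from the observed span, half-max
#' at the median nonzero concentration, n = 1; bounded
#' Levenberg-Marquardt optimization. Flat data yields a degenerate
#' flag, non-convergence a flagged (never silent) result.
#'
#' @param concs molar concentrations (>= 4 distinct values incl. 0).
#' @param endpoints corrected endpoints, same length.
#' @return object of class \code{dose_response_fit}.
#' @export
fit_dose_response <- function(concs, endpoints) {
  stopifnot(length(concs) == length(endpoints))
  if (length(unique(concs)) < 4L || !any(concs == 0)) {
    stop("need >= 4 distinct concentrations including 0")
  }
  y0 <- mean(endpoints[concs == 0])
  span <- mean(endpoints[concs == max(concs)]) - y0
  if (stats::sd(endpoints) == 0 ||
      abs(span) < 1e-9 * max(abs(endpoints), 1e-12)) {
    return(structure(list(baseline = y0, amplitude = 0,
                          half_max_conc = NA_real_, hill_n = NA_real_,
                          direction = NA_character_, rss = 0,
                          converged = TRUE, degenerate = TRUE),
                     class = "dose_response_fit"))
  }
  d <- data.frame(P = concs, y = endpoints)
  start <- list(b = y0, a = span, K = stats::median(concs[concs > 0]), n = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + a * ifelse(P == 0, 0, P^n / (P^n + K^n)),
                      data = d, start = start,
                      lower = c(b = -Inf, a = -Inf, K = min(concs[concs > 0]) / 100,
                                n = 0.2),
                      upper = c(b = Inf, a = Inf, K = max(concs) * 100, n = 8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(baseline = y0, amplitude = span,
                          half_max_conc = NA_real_, hill_n = NA_real_,
                          direction = if (span >= 0) "activation" else "repression",
                          rss = NA_real_, converged = FALSE, degenerate = FALSE),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(baseline = unname(cf["b"]), amplitude = unname(cf["a"]),
                 half_max_conc = unname(cf["K"]), hill_n = unname(cf["n"]),
                 direction = if (cf["a"] >= 0) "activation" else "repression",
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv, degenerate = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<dose_response_fit> degenerate (flat endpoints)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<dose_response_fit> %s: half-max at %.3g nM, Hill n %.2f, amplitude %.3g au%s\n",
    x$direction, x$half_max_conc * 1e9, x$hill_n, x$amplitude,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Predict endpoints from a dose-response fit
#' @param object a \code{dose_response_fit}.
#' @param newdata molar concentrations.
#' @param ... ignored.
#' @export
predict.dose_response_fit <- function(object, newdata, ...) {
  P <- as.numeric(newdata)
  occ <- ifelse(P == 0, 0,
                P^object$hill_n / (P^object$hill_n + object$half_max_conc^object$hill_n))
  object$baseline + object$amplitude * occ
}

#' Apparent Boltzmann factor from expression endpoints
#'
#' Ordinary least squares of \code{ln(endpoint)} on \code{-dG_total}:
#' the slope is the apparent beta of the assay, the intercept
#' \code{ln(k)}. Reports the Pearson squared correlation coefficient
#' and the two-sided p-value of the slope, plus its 95\% confidence
#' interval.
#'
#' @param dg_totals kcal/mol (>= 3 values, >= 2 distinct).
#' @param endpoints positive expression endpoints, same length.
#' @return object of class \code{beta_fit}.
#' @export
fit_beta <- function(dg_totals, endpoints) {
  stopifnot(length(dg_totals) == length(endpoints))
  if (length(dg_totals) < 3L) stop("need >= 3 (dG_total, endpoint) pairs")
  if (any(endpoints <= 0)) stop("endpoints must be > 0 to take logarithms")
  if (length(unique(dg_totals)) < 2L) {
    stop("singular design: all dG_total values identical")
  }
  x <- -dg_totals
  fit <- stats::lm(log(endpoints) ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(list(
    beta_hat = unname(stats::coef(fit)[2]),
    ln_k_hat = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    ci_95 = c(ci[1], ci[2]),
    n = length(x)
  ), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf(
    "<beta_fit> beta = %.3f (95%% CI %.3f-%.3f) (kcal/mol)^-1, R^2 = %.2f, p = %.2g, n = %d\n",
    x$beta_hat, x$ci_95[1], x$ci_95[2], x$r_squared, x$p_value, x$n))
  invisible(x)
}
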