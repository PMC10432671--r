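#' @title Cell-based binding assay quantification
#' @description EC50/IC50 estimation from dilution series of MHC
#'   stabilization (T2/RMA-S) and competition (FITC-reference) binding
#'   assays, and binder calling. Curves are fit with a four-parameter
#'   logistic in log-concentration; the EC50 is the concentration at
#'   half-maximal signal between the fitted baseline and plateau (the
#'   fitted extremes resist single-point noise better than the observed
#'   ones). When the fit does not converge, a monotone linear interpolation
#'   in log-concentration between the two points bracketing half-max is
#'   used; flat or non-bracketing curves yield no estimate.
#' @name binding-assays
NULL

four_pl <- function(conc, baseline, plateau, ec50, hill) {
  baseline + (plateau - baseline) / (1 + (ec50 / conc)^hill)
}

# Interpolate the concentration at which the curve crosses `target`,
# linearly in log10 concentration between the bracketing observed points.
interpolate_crossing <- function(conc, signal, target) {
  ord <- order(conc)
  conc <- conc[ord]
  signal <- signal[ord]
  for (i in seq_len(length(conc) - 1)) {
    lo <- signal[i]
    hi <- signal[i + 1]
    if ((lo - target) * (hi - target) <= 0 && lo != hi) {
      f <- (target - lo) / (hi - lo)
      return(10^(log10(conc[i]) + f * (log10(conc[i + 1]) - log10(conc[i]))))
    }
  }
  NA_real_
}

fit_4pl <- function(conc, signal, ascending = TRUE) {
  half_obs <- (min(signal) + max(signal)) / 2
  ec50_0 <- interpolate_crossing(conc, signal, half_obs)
  if (is.na(ec50_0)) ec50_0 <- sqrt(min(conc) * max(conc))
  start <- list(baseline = min(signal), plateau = max(signal),
                log_ec50 = log10(ec50_0), hill = 1)
  try_fit <- function(bounded) {
    args <- list(
      signal ~ baseline + (plateau - baseline) /
        (1 + 10^(hill * (log_ec50 - log10(conc)))),
      data = data.frame(conc = conc, signal = signal),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (bounded) {
      args$lower <- c(baseline = 0, plateau = 0, log_ec50 = -6, hill = 0.1)
      args$upper <- c(baseline = 1e9, plateau = 1e9, log_ec50 = 6,
                      hill = 10)
    }
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }
  fit <- try_fit(bounded = TRUE)
  if (is.null(fit)) fit <- try_fit(bounded = FALSE)
  if (is.null(fit)) return(NULL)
  p <- as.list(coef(fit))
  if (!all(vapply(p, is.finite, logical(1))) ||
      p$hill <= 0.05 || p$hill > 20 ||
      p$log_ec50 < -6 || p$log_ec50 > 6) {
    return(NULL)
  }
  list(baseline = p$baseline, plateau = p$plateau,
       ec50 = 10^p$log_ec50, hill = p$hill)
}

#' Fit an EC50 from a stabilization-assay dilution series
#'
#' @param concentrations peptide concentrations in uM (any order; zero
#'   rows, i.e. no-peptide controls, are excluded from the fit).
#' @param signals MFI readouts matching `concentrations`.
#' @param no_peptide_control MFI of the no-peptide control.
#' @param peptide_id identifier carried into the result.
#' @return a `binding_result` list: `peptide_id, assay_type, ec50_um,
#'   baseline, plateau, fit_method` (`"logistic_fit"`, `"interpolation"`
#'   or `"none"`).
#' @export
#' @examples
#' conc <- 100 / 3^(0:7)
#' mfi <- 100 + 900 / (1 + 10 / conc)
#' fit_ec50(conc, mfi, 100)$ec50_um   # ~10
fit_ec50 <- function(concentrations, signals, no_peptide_control = 0,
                     peptide_id = NA_character_) {
  keep <- concentrations > 0
  conc <- concentrations[keep]
  signal <- signals[keep]
  if (length(conc) < 4) {
    stop("insufficient data: EC50 fitting needs at least 4 positive-",
         "concentration points, got ", length(conc), call. = FALSE)
  }
  if (length(conc) != length(signal)) {
    stop("concentrations and signals differ in length", call. = FALSE)
  }
  res <- list(peptide_id = peptide_id, assay_type = "stabilization",
              ec50_um = NA_real_, baseline = min(signal),
              plateau = max(signal), fit_method = "none")
  class(res) <- "binding_result"
  scale <- max(max(signal), no_peptide_control, 1)
  if (max(signal) - min(signal) < 0.1 * scale) {
    return(res)  # flat curve: no dose response
  }
  fit <- fit_4pl(conc, signal)
  if (!is.null(fit) && fit$plateau > fit$baseline &&
      fit$ec50 > min(conc) / 100 && fit$ec50 < max(conc) * 100) {
    res$ec50_um <- fit$ec50
    res$baseline <- fit$baseline
    res$plateau <- fit$plateau
    res$fit_method <- "logistic_fit"
    return(res)
  }
  half <- (min(signal) + max(signal)) / 2
  cross <- interpolate_crossing(conc, signal, half)
  if (!is.na(cross)) {
    res$ec50_um <- cross
    res$fit_method <- "interpolation"
  }
  res
}

#' Fit an IC50 from a competition-assay dilution series
#'
#' Inhibition at concentration c is `1 - signal(c) / reference`, where
#' `reference` is the FITC-labeled reference peptide signal without
#' competitor. The IC50 is the competitor concentration at 50% inhibition,
#' from a logistic fit of the inhibition curve with interpolation
#' fallback; a curve never reaching 50% inhibition yields no IC50.
#'
#' @param concentrations competitor concentrations in uM.
#' @param signals FITC-MFI readouts matching `concentrations`.
#' @param reference_no_competitor FITC-MFI without competitor (> 0).
#' @param peptide_id identifier carried into the result.
#' @return a `binding_result` list: `peptide_id, assay_type, ic50_um,
#'   max_inhibition, fit_method`.
#' @export
fit_ic50 <- function(concentrations, signals, reference_no_competitor,
                     peptide_id = NA_character_) {
  if (is.na(reference_no_competitor) || reference_no_competitor <= 0) {
    stop("reference_no_competitor must be positive for a competition assay",
         call. = FALSE)
  }
  keep <- concentrations > 0
  conc <- concentrations[keep]
  inhibition <- 1 - signals[keep] / reference_no_competitor
  if (length(conc) < 4) {
    stop("insufficient data: IC50 fitting needs at least 4 positive-",
         "concentration points, got ", length(conc), call. = FALSE)
  }
  res <- list(peptide_id = peptide_id, assay_type = "competition",
              ic50_um = NA_real_, max_inhibition = max(inhibition),
              fit_method = "none")
  class(res) <- "binding_result"
  if (max(inhibition) - min(inhibition) < 0.05) {
    return(res)  # no dose-dependent inhibition
  }
  fit <- fit_4pl(conc, inhibition)
  if (!is.null(fit) && fit$plateau > 0.5) {
    # concentration where the fitted inhibition curve crosses 0.5
    frac <- (0.5 - fit$baseline) / (fit$plateau - fit$baseline)
    if (frac > 0 && frac < 1) {
      res$ic50_um <- fit$ec50 * (frac / (1 - frac))^(1 / fit$hill)
      res$max_inhibition <- fit$plateau
      res$fit_method <- "logistic_fit"
      return(res)
    }
  }
  cross <- interpolate_crossing(conc, inhibition, 0.5)
  if (!is.na(cross)) {
    res$ic50_um <- cross
    res$fit_method <- "interpolation"
  }
  res
}

#' Call a peptide a binder from its assay result
#'
#' A stabilization-assay peptide is a binder when its EC50 is determinate
#' within the tested concentration range and the fitted plateau reaches at
#' least `binder_plateau_fold` times the no-peptide control, so that a
#' formally determinate half-max crossing on a near-flat curve is not
#' called binding. A competition-assay peptide is a binder when its IC50
#' is determinate within range and maximal inhibition reaches 50%.
#'
#' @param result a `binding_result` from [fit_ec50()] or [fit_ic50()].
#' @param no_peptide_control MFI of the no-peptide control (stabilization).
#' @param cfg a [neovax_config()].
#' @return logical.
#' @export
call_binder <- function(result, no_peptide_control = 0,
                        cfg = neovax_config()) {
  stopifnot(inherits(result, "binding_result"))
  if (result$assay_type == "stabilization") {
    !is.na(result$ec50_um) &&
      result$ec50_um <= cfg$top_concentration &&
      result$plateau >= cfg$binder_plateau_fold * max(no_peptide_control, 1)
  } else {
    !is.na(result$ic50_um) &&
      result$ic50_um <= cfg$top_concentration &&
      result$max_inhibition >= 0.5
  }
}

#' Fit every curve of a binding-assay table and call binders
#'
#' @param curves long-format curve tibble (see [read_binding_curves()]).
#' @param cfg a [neovax_config()].
#' @return a tibble with one row per peptide: `peptide_id, assay_type,
#'   ec50_um, ic50_um, baseline, plateau, max_inhibition, fit_method,
#'   binder`.
#' @export
fit_binding_curves <- function(curves, cfg = neovax_config()) {
  out <- lapply(unique(curves$peptide_id), function(pid) {
    cur <- curves[curves$peptide_id == pid, ]
    type <- cur$assay_type[1]
    control <- if (any(cur$concentration_um == 0)) {
      mean(cur$signal[cur$concentration_um == 0])
    } else {
      0
    }
    if (type == "stabilization") {
      r <- fit_ec50(cur$concentration_um, cur$signal, control, pid)
      tibble(peptide_id = pid, assay_type = type, ec50_um = r$ec50_um,
             ic50_um = NA_real_, baseline = r$baseline,
             plateau = r$plateau, max_inhibition = NA_real_,
             fit_method = r$fit_method,
             binder = call_binder(r, control, cfg))
    } else {
      ref <- cur$reference_no_competitor[1]
      r <- fit_ic50(cur$concentration_um, cur$signal, ref, pid)
      tibble(peptide_id = pid, assay_type = type, ec50_um = NA_real_,
             ic50_um = r$ic50_um, baseline = NA_real_, plateau = NA_real_,
             max_inhibition = r$max_inhibition, fit_method = r$fit_method,
             binder = call_binder(r, 0, cfg))
    }
  })
  bind_rows(out)
}

#' Call T-cell responders
#'
#' A subject responds to a peptide when the percentage of
#' IFN-gamma-positive cells within the CD8+ population in the
#' peptide-stimulated culture is twice or higher (inclusive boundary) the
#' unstimulated background. The background enters the comparison floored
#' at `zero_floor_pct` so a 0% background cannot decide a call by
#' division.
#'
#' @param stim_pct,unstim_pct stimulated/unstimulated %IFN-gamma+ of CD8+
#'   (vectorized).
#' @param cfg a [neovax_config()].
#' @return logical vector.
#' @export
#' @examples
#' call_responder(1.2, 0.5)  # TRUE
#' call_responder(1.0, 0.5)  # TRUE  (boundary: "twice or higher")
#' call_responder(0.9, 0.5)  # FALSE
call_responder <- function(stim_pct, unstim_pct, cfg = neovax_config()) {
  stopifnot(all(stim_pct >= 0 & stim_pct <= 100),
            all(unstim_pct >= 0 & unstim_pct <= 100))
  stim_pct >= cfg$responder_fold * pmax(unstim_pct, cfg$zero_floor_pct)
}
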