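#' Trapezoidal area under a concentration-time curve
#'
#' Linear trapezoid over a profile sampled in minutes and ng/mL, reported in
#' ug.h/mL (the unit the clinical tables use).  A single point has zero
#' area.
#'
#' @param time time grid (min).
#' @param conc concentrations (ng/mL).
#' @param t_last upper integration limit (min); defaults to the last sample.
#' @return AUC(0-t_last) in ug.h/mL.
#' @export
auc_trapezoid <- function(time, conc, t_last = NULL) {
  stopifnot(length(time) == length(conc))
  if (!is.null(t_last)) {
    keep <- time <= t_last
    # interpolate the cut point so the limit is honoured exactly
    if (any(!keep) && any(keep)) {
      c_cut <- stats::approx(time, conc, xout = t_last)$y
      time <- c(time[keep], t_last)
      conc <- c(conc[keep], c_cut)
    } else {
      time <- time[keep]; conc <- conc[keep]
    }
  }
  if (length(time) < 2) return(0)
  ng_min <- sum(diff(time) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  ng_min / 1000 / 60   # ng.min/mL -> ug.h/mL
}

# Terminal slope from the last `n` positive samples (log-linear).
terminal_slope <- function(time, conc, n = 3) {
  ok <- which(conc > 0)
  if (length(ok) < n) return(NA_real_)
  i <- utils::tail(ok, n)
  fit <- stats::lm(log(conc[i]) ~ time[i])
  lz <- -unname(stats::coef(fit)[2])
  if (!is.finite(lz) || lz <= 0) NA_real_ else lz
}

#' Non-compartmental summary of a simulated profile
#'
#' Computes AUC(0-t), AUC(0-inf) (log-linear tail extrapolation from the
#' last three positive samples), Cmax, Tmax and, for intravenous dosing,
#' total clearance dose/AUC(0-inf).
#'
#' @param result a [simulate_profile()] result.
#' @param analyte which concentration column to summarise (default: the
#'   parent drug).
#' @param t_last AUC truncation time (min); defaults to the end of the
#'   profile.
#' @return an object of class `pk_summary`: a one-row data.frame with
#'   columns `analyte`, `dose_mg`, `auc0_t`, `auc0_inf` (ug.h/mL), `cmax`
#'   (ng/mL), `tmax` (min) and `cl` (L/min, `NA` for oral dosing).
#' @export
pk_summary <- function(result, analyte = NULL, t_last = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  analyte <- analyte %||% names(result$conc)[1]
  conc <- result$conc[[analyte]]
  if (is.null(conc)) stop("no analyte '", analyte, "' in result", call. = FALSE)
  time <- result$time
  auc_t <- auc_trapezoid(time, conc, t_last)
  lz <- terminal_slope(time, conc)
  c_last <- utils::tail(conc[conc > 0], 1)
  t_used <- if (is.null(t_last)) max(time) else t_last
  auc_inf <- if (is.finite(lz) && length(c_last)) {
    auc_trapezoid(time, conc) + (c_last / lz) / 1000 / 60
  } else {
    auc_trapezoid(time, conc)
  }
  auc_inf <- max(auc_inf, auc_t)
  iv <- result$system$regimen$route != "oral"
  cl <- if (iv && auc_inf > 0) {
    # dose [mg] / AUC [ug.h/mL = mg.h/L] -> L/h -> L/min
    result$dose / auc_inf / 60
  } else NA_real_
  out <- data.frame(
    analyte = analyte, dose_mg = result$dose,
    auc0_t = auc_t, t_last_min = t_used,
    auc0_inf = auc_inf,
    cmax = max(conc), tmax = time[which.max(conc)],
    cl = cl, stringsAsFactors = FALSE
  )
  class(out) <- c("pk_summary", "data.frame")
  out
}

#' Cirrhosis-to-healthy exposure ratio (AUCR)
#'
#' Dose-normalises both exposures before forming the ratio, as is done when
#' patient and healthy data come from different dose levels.
#'
#' @param auc_ci,auc_ht AUC in patients and healthy subjects (same units).
#' @param dose_ci,dose_ht corresponding doses (mg); defaults make the ratio
#'   un-normalised.
#' @return dimensionless ratio.
#' @export
aucr <- function(auc_ci, auc_ht, dose_ci = 1, dose_ht = 1) {
  (auc_ci / dose_ci) / (auc_ht / dose_ht)
}

#' Exposure ratio from clearances
#'
#' For linear intravenous kinetics the AUC ratio equals the inverse
#' clearance ratio, `CL_HT / CL_CI`.
#'
#' @param cl_ht,cl_ci total clearance in healthy subjects and patients.
#' @return dimensionless ratio.
#' @export
cl_ratio <- function(cl_ht, cl_ci) {
  cl_ht / cl_ci
}

#' Cirrhosis-to-healthy peak-concentration ratio (CmaxR)
#'
#' @param cmax_ci,cmax_ht peak concentrations.
#' @param dose_ci,dose_ht corresponding doses for normalisation.
#' @return dimensionless ratio.
#' @export
cmaxr <- function(cmax_ci, cmax_ht, dose_ci = 1, dose_ht = 1) {
  (cmax_ci / dose_ci) / (cmax_ht / dose_ht)
}

#' Two-fold and bioequivalence acceptance flags
#'
#' A prediction is conventionally accepted when the observed/predicted ratio
#' falls within 0.5- to 2-fold; the stricter bioequivalence band is
#' 0.8-1.25.
#'
#' @param pred predicted value.
#' @param obs observed value.
#' @return list with `ratio` (obs/pred), `within_2fold` and
#'   `within_bioequivalence` logicals.
#' @export
fold_check <- function(pred, obs) {
  r <- obs / pred
  list(ratio = r,
       within_2fold = is.finite(r) && r >= 0.5 && r <= 2,
       within_bioequivalence = is.finite(r) && r >= 0.8 && r <= 1.25)
}
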