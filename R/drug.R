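#' Construct a hepatic elimination pathway
#'
#' One enzymatic (or transporter) route of hepatic elimination.  A pathway is
#' either linear, described by an intrinsic clearance, or saturable,
#' described by a Michaelis-Menten pair.  Pathways that hydrolyse the parent
#' into a tracked metabolite carry the metabolite identifier; conversion is
#' 1:1 on a molar basis.
#'
#' The `enzyme` label determines how the pathway is rescaled when a healthy
#' parameter set is translated to cirrhosis: CES1 pathways follow the hepatic
#' CES1 content ratio, CYP2B6 pathways the CYP2B6 content ratio, UGT pathways
#' a fixed factor of 0.62 (the cirrhosis exposure change of the UGT-cleared
#' reference substrate metoprolol), and biliary routes the MRP2 activity
#' ratio.
#'
#' @param enzyme one of `"CES1"`, `"CYP2B6"`, `"UGT"`, `"biliary"`.
#' @param clint linear intrinsic clearance (mL/min); mutually exclusive with
#'   `vmax`/`km`.
#' @param vmax maximal rate (nmol/min/mg microsomal protein).
#' @param km Michaelis constant (umol/L); must be positive when saturable.
#' @param metabolite identifier of the metabolite produced, or `NULL` when
#'   the products are not tracked.
#' @return an object of class `elimination_pathway`.
#' @export
elimination_pathway <- function(enzyme, clint = NULL, vmax = NULL, km = NULL,
                                metabolite = NULL) {
  enzyme <- match.arg(enzyme, c("CES1", "CYP2B6", "UGT", "biliary"))
  has_lin <- !is.null(clint)
  has_sat <- !is.null(vmax) || !is.null(km)
  if (has_lin == has_sat) {
    stop("exactly one of 'clint' or ('vmax','km') must be given for pathway ",
         enzyme, call. = FALSE)
  }
  if (has_sat) {
    if (is.null(vmax) || is.null(km)) {
      stop("saturable pathway needs both 'vmax' and 'km'", call. = FALSE)
    }
    if (km <= 0) stop("'km' must be positive", call. = FALSE)
    if (vmax < 0) stop("'vmax' must be non-negative", call. = FALSE)
  } else if (clint < 0) {
    stop("'clint' must be non-negative", call. = FALSE)
  }
  structure(
    list(enzyme = enzyme,
         kind = if (has_lin) "linear" else "saturable",
         clint = clint, vmax = vmax, km = km,
         metabolite = metabolite),
    class = "elimination_pathway"
  )
}

#' Construct a drug (or metabolite) parameter record
#'
#' Holds every compound-specific ADME parameter the simulator uses, in the
#' package's internal unit system (mg, mL, min; permeability kept in cm/s
#' and converted where used).
#'
#' @param name compound identifier.
#' @param pathways list of [elimination_pathway()] objects (hepatic routes).
#' @param k_lp,k_gp,k_kp liver-, gut- and kidney-to-plasma partition
#'   coefficients (dimensionless).
#' @param v_sys systemic apparent distribution volume (L).
#' @param rb blood-to-plasma concentration ratio.
#' @param fu_b unbound fraction in blood, in (0, 1].
#' @param clint_k renal intrinsic clearance (mL/min; filtration plus
#'   secretion, before flow limitation).
#' @param cl_bile biliary intrinsic clearance (mL/min), or `NULL`.
#' @param cl_b observed total blood clearance (mL/min), kept for well-stirred
#'   back-calculation; not used by the ODE engine.
#' @param k12,k21,k13,k31 first-order exchange rate constants with up to two
#'   peripheral compartments (1/min); supply pairs together.
#' @param peff effective intestinal permeability (cm/s), or `NULL`.
#' @param ka first-order absorption rate constant (1/min), or `NULL`; when
#'   both are `NULL` the compound cannot be dosed orally.
#' @param binding_protein `"albumin"` or `"AGP"` -- selects the plasma
#'   protein whose cirrhosis concentration change drives the unbound-fraction
#'   translation.
#' @param mw molar mass (g/mol); required for Michaelis-Menten pathways,
#'   otherwise optional metadata.
#' @param logp,pka,f physicochemical / bioavailability metadata (unused by
#'   the engine).
#' @param is_metabolite logical flag.
#' @param parent identifier of the parent compound (metabolites only).
#' @param metabolite identifier of the tracked metabolite record, if any.
#' @return an object of class `drug_record`.
#' @export
drug_record <- function(name, pathways = list(),
                        k_lp, k_gp, k_kp,
                        v_sys, rb, fu_b, clint_k = 0,
                        cl_bile = NULL, cl_b = NULL,
                        k12 = NULL, k21 = NULL, k13 = NULL, k31 = NULL,
                        peff = NULL, ka = NULL,
                        binding_protein = c("albumin", "AGP"),
                        mw = NULL, logp = NULL, pka = NULL, f = NULL,
                        is_metabolite = FALSE, parent = NULL,
                        metabolite = NULL) {
  binding_protein <- match.arg(binding_protein)
  obj <- structure(
    list(name = name, pathways = pathways,
         k_lp = k_lp, k_gp = k_gp, k_kp = k_kp,
         v_sys = v_sys, rb = rb, fu_b = fu_b,
         clint_k = clint_k, cl_bile = cl_bile, cl_b = cl_b,
         k12 = k12, k21 = k21, k13 = k13, k31 = k31,
         peff = peff, ka = ka,
         binding_protein = binding_protein,
         mw = mw, logp = logp, pka = pka, f = f,
         is_metabolite = isTRUE(is_metabolite),
         parent = parent, metabolite = metabolite),
    class = "drug_record"
  )
  validate_drug(obj)
  obj
}

#' Validate a drug record
#'
#' @param drug a `drug_record`.
#' @return `drug`, invisibly, if valid.
#' @export
validate_drug <- function(drug) {
  stopifnot(inherits(drug, "drug_record"))
  fail <- function(fmt, ...) {
    stop(sprintf(paste0("drug '%s': ", fmt), drug$name, ...), call. = FALSE)
  }
  if (!is.numeric(drug$fu_b) || drug$fu_b <= 0 || drug$fu_b > 1) {
    fail("fu_b must lie in (0, 1], got %s", format(drug$fu_b))
  }
  if (drug$rb <= 0) fail("rb must be positive")
  for (f in c("k_lp", "k_gp", "k_kp")) {
    if (drug[[f]] <= 0) fail("partition coefficient %s must be positive", f)
  }
  if (drug$v_sys <= 0) fail("v_sys must be positive")
  if (drug$clint_k < 0) fail("clint_k must be non-negative")
  if (!is.null(drug$cl_bile) && drug$cl_bile < 0) fail("cl_bile must be non-negative")
  has12 <- !is.null(drug$k12) || !is.null(drug$k21)
  has13 <- !is.null(drug$k13) || !is.null(drug$k31)
  if (has12 && (is.null(drug$k12) || is.null(drug$k21))) {
    fail("k12 and k21 must be supplied together")
  }
  if (has13) {
    if (is.null(drug$k13) || is.null(drug$k31)) fail("k13 and k31 must be supplied together")
    if (!has12) fail("a second peripheral compartment (k13/k31) requires k12/k21")
  }
  for (f in c("k12", "k21", "k13", "k31")) {
    if (!is.null(drug[[f]]) && drug[[f]] < 0) fail("%s must be non-negative", f)
  }
  for (pw in drug$pathways) {
    if (!inherits(pw, "elimination_pathway")) fail("pathways must be elimination_pathway objects")
    if (pw$kind == "saturable" && is.null(drug$mw)) {
      fail("Michaelis-Menten pathway requires the molar mass 'mw'")
    }
  }
  invisible(drug)
}

#' @export
print.drug_record <- function(x, ...) {
  kind <- if (x$is_metabolite) "metabolite" else "drug"
  cat(sprintf("<drug_record: %s (%s)>\n", x$name, kind))
  cat(sprintf("  fu_b %g, Rb %g, Vsys %g L, CLint,K %g mL/min\n",
              x$fu_b, x$rb, x$v_sys, x$clint_k))
  for (pw in x$pathways) {
    if (pw$kind == "linear") {
      cat(sprintf("  pathway %s: CLint %g mL/min%s\n", pw$enzyme, pw$clint,
                  if (!is.null(pw$metabolite)) paste0(" -> ", pw$metabolite) else ""))
    } else {
      cat(sprintf("  pathway %s: Vmax %g nmol/min/mg, Km %g umol/L%s\n",
                  pw$enzyme, pw$vmax, pw$km,
                  if (!is.null(pw$metabolite)) paste0(" -> ", pw$metabolite) else ""))
    }
  }
  if (!is.null(x$cl_bile)) cat(sprintf("  biliary CL %g mL/min\n", x$cl_bile))
  if (!is.null(x$peff)) cat(sprintf("  Peff %g cm/s\n", x$peff))
  if (!is.null(x$ka)) cat(sprintf("  ka %g /min\n", x$ka))
  invisible(x)
}

#' Construct a dosing regimen
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"oral"`.
#' @param amount dose in mg as labelled (salt form), or mg/kg when
#'   `per_kg = TRUE`.
#' @param per_kg interpret `amount` as mg per kg body weight.
#' @param body_weight body weight in kg (default 70).
#' @param infusion_duration infusion length in min (0 for bolus).
#' @param salt_to_base_factor multiplicative conversion from labelled salt
#'   dose to active base; the default 1.0 uses doses exactly as labelled.
#' @return an object of class `dose_regimen`.
#' @export
dose_regimen <- function(route = c("iv_bolus", "iv_infusion", "oral"),
                         amount, per_kg = FALSE, body_weight = 70,
                         infusion_duration = 0, salt_to_base_factor = 1.0) {
  route <- match.arg(route)
  if (amount <= 0) stop("dose amount must be positive", call. = FALSE)
  if (infusion_duration < 0) stop("infusion_duration must be >= 0", call. = FALSE)
  if (route == "iv_infusion" && infusion_duration <= 0) {
    stop("iv_infusion requires a positive infusion_duration", call. = FALSE)
  }
  structure(
    list(route = route, amount = amount, per_kg = isTRUE(per_kg),
         body_weight = body_weight,
         infusion_duration = if (route == "iv_infusion") infusion_duration else 0,
         salt_to_base_factor = salt_to_base_factor),
    class = "dose_regimen"
  )
}

#' Administered dose in mg
#'
#' Resolves a regimen to the absolute dose in mg (applying per-kg scaling and
#' the salt-to-base factor).
#'
#' @param regimen a [dose_regimen()].
#' @return dose in mg.
#' @export
dose_mg <- function(regimen) {
  amt <- regimen$amount * if (regimen$per_kg) regimen$body_weight else 1
  amt * regimen$salt_to_base_factor
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen: %g mg%s, %s%s>\n",
              x$amount, if (x$per_kg) "/kg" else "", x$route,
              if (x$infusion_duration > 0)
                sprintf(" over %g min", x$infusion_duration) else ""))
  invisible(x)
}
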