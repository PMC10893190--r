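#' Scale a CES1-mediated hepatic intrinsic clearance to cirrhosis
#'
#' CES1-mediated intrinsic clearance in a cirrhotic liver is the healthy
#' value scaled by the ratio of hepatic CES1 content per gram of liver and
#' the ratio of functional liver volume:
#' \deqn{CL_{int,CI} = CL_{int,HT} \times f_{CES1} \times f_{liver}}
#'
#' @param clint_ht healthy intrinsic clearance (mL/min).
#' @param phys_ht,phys_ci healthy and patient [physiology_set()]s.
#' @return scaled intrinsic clearance (mL/min).
#' @export
scale_ces1_clint <- function(clint_ht, phys_ht, phys_ci) {
  if (phys_ht$ces1_content <= 0) {
    stop("healthy CES1 content must be positive", call. = FALSE)
  }
  clint_ht * (phys_ci$ces1_content / phys_ht$ces1_content) *
    (phys_ci$v_liver / phys_ht$v_liver)
}

#' Scale a non-CES1 hepatic clearance to cirrhosis
#'
#' Hepatic elimination through routes other than CES1 is scaled by the
#' content ratio of the responsible target (`f_other`) and the functional
#' liver volume ratio.
#'
#' @param clint_ht healthy intrinsic clearance (mL/min).
#' @param f_other target content ratio patient/healthy: the CYP2B6 content
#'   ratio, the fixed UGT factor 0.62, or the MRP2 activity ratio for
#'   biliary routes.
#' @param phys_ht,phys_ci healthy and patient physiology.
#' @return scaled clearance (mL/min).
#' @export
scale_other_clint <- function(clint_ht, f_other, phys_ht, phys_ci) {
  if (!is.numeric(f_other) || !is.finite(f_other) || f_other < 0) {
    stop("unresolvable scaling factor 'f_other'", call. = FALSE)
  }
  clint_ht * f_other * (phys_ci$v_liver / phys_ht$v_liver)
}

#' Translate an unbound fraction to an altered binding-protein level
#'
#' With the drug's binding affinity unchanged, the bound:free ratio scales
#' with the binding-protein concentration, giving
#' \deqn{f_{u,CI} = \frac{1}{1 + (1 - f_{u,HT})\,
#'   \frac{P_{CI}}{P_{HT}} / f_{u,HT}}}
#' The result lies in (0, 1] and increases as the protein level falls.
#'
#' @param fu_ht healthy unbound fraction, in (0, 1].
#' @param protein_ht,protein_ci binding-protein concentration (g/L) in
#'   healthy subjects and patients.
#' @return patient unbound fraction.
#' @export
scale_fu <- function(fu_ht, protein_ht, protein_ci) {
  if (fu_ht <= 0 || fu_ht > 1) stop("fu_ht must lie in (0, 1]", call. = FALSE)
  if (protein_ht <= 0 || protein_ci <= 0) {
    stop("binding-protein concentrations must be positive", call. = FALSE)
  }
  1 / (1 + (1 - fu_ht) * (protein_ci / protein_ht) / fu_ht)
}

#' Scale an apparent distribution volume to an altered unbound fraction
#'
#' Assumes the unbound (free) distribution volume is unaltered by disease,
#' so the apparent volume scales proportionally with the unbound fraction.
#'
#' @param v_ht healthy apparent volume (L).
#' @param fu_ht,fu_ci healthy and patient unbound fractions.
#' @return patient apparent volume (L).
#' @export
scale_volume <- function(v_ht, fu_ht, fu_ci) {
  v_ht * fu_ci / fu_ht
}

#' Scale a renal intrinsic clearance with the glomerular filtration rate
#'
#' @param clint_k_ht healthy renal intrinsic clearance (mL/min).
#' @param gfr_ht,gfr_ci healthy and patient GFR (mL/min).
#' @return patient renal intrinsic clearance (mL/min).
#' @export
scale_renal_clint <- function(clint_k_ht, gfr_ht, gfr_ci) {
  clint_k_ht * gfr_ci / gfr_ht
}

#' Scale intestinal permeability (or absorption rate) with the
#' lactulose/rhamnose ratio
#'
#' Cirrhosis loosens the intestinal barrier; the lactulose/rhamnose urinary
#' recovery ratio is the clinical permeability marker used to correct the
#' absorption parameter.  The correction applies multiplicatively to
#' whichever absorption parameter the drug carries (effective permeability
#' or a first-order absorption rate constant).
#'
#' @param x healthy absorption parameter (any units).
#' @param lr_ht,lr_ci healthy and patient lactulose/rhamnose ratios.
#' @return scaled parameter, same units as `x`.
#' @export
scale_peff <- function(x, lr_ht, lr_ci) {
  x * lr_ci / lr_ht
}

#' Well-stirred hepatic blood clearance
#'
#' @param clint intrinsic clearance (mL/min).
#' @param fu_b unbound fraction in blood.
#' @param q_l hepatic blood flow (mL/min).
#' @return hepatic blood clearance (mL/min).
#' @export
well_stirred_cl <- function(clint, fu_b, q_l) {
  q_l * fu_b * clint / (q_l + fu_b * clint)
}

#' Invert the well-stirred liver model
#'
#' Back-calculates the intrinsic clearance from an observed hepatic blood
#' clearance: the inverse of [well_stirred_cl()],
#' \deqn{CL_{int} = \frac{Q_L\, CL_b}{f_{u,b} (Q_L - CL_b)}}
#' Defined only for extraction ratios below one.
#'
#' @param cl_b hepatic blood clearance (mL/min); must be below `q_l`.
#' @param fu_b unbound fraction in blood.
#' @param q_l hepatic blood flow (mL/min).
#' @return intrinsic clearance (mL/min).
#' @export
invert_well_stirred <- function(cl_b, fu_b, q_l) {
  if (cl_b < 0) stop("cl_b must be non-negative", call. = FALSE)
  if (cl_b >= q_l) {
    stop("blood clearance >= hepatic blood flow: extraction ratio >= 1 is not representable",
         call. = FALSE)
  }
  q_l * cl_b / (fu_b * (q_l - cl_b))
}

#' Flow-limited renal blood clearance
#'
#' @param clint_k renal intrinsic clearance (mL/min).
#' @param fu_b unbound fraction in blood.
#' @param q_k kidney blood flow (mL/min).
#' @return renal blood clearance (mL/min).
#' @export
renal_cl <- function(clint_k, fu_b, q_k) {
  q_k * fu_b * clint_k / (q_k + fu_b * clint_k)
}

#' Hepatic intrinsic clearance from a total blood clearance
#'
#' For drugs whose reported total blood clearance includes a renal
#' component: computes the flow-limited renal blood clearance, subtracts it
#' from the total, and inverts the well-stirred liver model on the hepatic
#' remainder.
#'
#' @param cl_b_total total blood clearance (mL/min).
#' @param clint_k renal intrinsic clearance (mL/min).
#' @param fu_b unbound fraction in blood.
#' @param q_l,q_k hepatic and kidney blood flow (mL/min).
#' @return hepatic intrinsic clearance (mL/min).
#' @export
hepatic_split_clint <- function(cl_b_total, clint_k, fu_b, q_l, q_k) {
  cl_r <- renal_cl(clint_k, fu_b, q_k)
  cl_h <- cl_b_total - cl_r
  if (cl_h <= 0) {
    stop("renal clearance exceeds the total blood clearance: no hepatic remainder",
         call. = FALSE)
  }
  invert_well_stirred(cl_h, fu_b, q_l)
}

#' Linearised intrinsic clearance of a Michaelis-Menten pathway
#'
#' `vmax/km` (mL/min/mg microsomal protein) scaled to the whole liver via
#' the microsomal protein content per gram of liver and the liver mass
#' (1 g/mL of functional liver volume is assumed).  Used for reporting and
#' low-concentration limits; the ODE engine integrates the saturable rate
#' natively.
#'
#' @param vmax maximal rate (nmol/min/mg protein).
#' @param km Michaelis constant (umol/L).
#' @param mppgl microsomal protein per gram liver (mg/g, default 40).
#' @param liver_mass liver mass (g).
#' @return intrinsic clearance (mL/min).
#' @export
mm_to_clint <- function(vmax, km, mppgl = 40, liver_mass) {
  (vmax / km) * mppgl * liver_mass
}

#' Segmental absorption rate constant from effective permeability
#'
#' For a cylindrical intestinal lumen of radius `r`, the surface-to-volume
#' ratio is 2/r, giving `ka = 2 Peff / r` (converted from per-second to
#' per-minute).
#'
#' @param peff effective permeability (cm/s).
#' @param radius lumen radius (cm).
#' @return absorption rate constant (1/min).
#' @export
ka_from_peff <- function(peff, radius) {
  2 * peff * 60 / radius
}

#' Resolve the cirrhosis scaling factor for a hepatic pathway
#'
#' @param enzyme pathway enzyme label.
#' @param phys_ht,phys_ci healthy and patient physiology.
#' @return the content/activity ratio `f` for the pathway (liver-volume
#'   scaling excluded).
#' @keywords internal
pathway_factor <- function(enzyme, phys_ht, phys_ci) {
  same <- identical(phys_ht$population_label, phys_ci$population_label)
  switch(enzyme,
    CES1 = phys_ci$ces1_content / phys_ht$ces1_content,
    CYP2B6 = phys_ci$cyp2b6_content / phys_ht$cyp2b6_content,
    UGT = if (same) 1 else 0.62,
    biliary = phys_ci$mrp2_ratio / phys_ht$mrp2_ratio,
    stop("no scaling rule for pathway enzyme '", enzyme, "'", call. = FALSE)
  )
}

#' Translate a drug record from healthy to cirrhosis physiology
#'
#' Applies the full cirrhosis translation to one compound: hepatic pathway
#' clearances (CES1 content, CYP2B6 content, fixed UGT factor, MRP2 for
#' biliary routes, all times the functional liver volume ratio), plasma
#' protein binding (driven by albumin or alpha-1-acid glycoprotein according
#' to the compound's binding protein), apparent distribution volume, renal
#' intrinsic clearance (GFR ratio) and intestinal absorption
#' (lactulose/rhamnose ratio).  Saturable pathways scale their `vmax`.
#'
#' Translating with the healthy physiology on both sides is the identity.
#'
#' @param drug a [drug_record()] parameterised for healthy subjects.
#' @param phys_ht healthy [physiology_set()].
#' @param phys_ci patient physiology.
#' @return an object of class `translated_parameters`: a list with the
#'   scaled `drug` record, the named `scale_factors` applied, and a
#'   per-field `provenance` note.
#' @export
translate_drug <- function(drug, phys_ht, phys_ci) {
  out <- drug
  prov <- character()
  protein_ht <- if (drug$binding_protein == "AGP") phys_ht$agp else phys_ht$albumin
  protein_ci <- if (drug$binding_protein == "AGP") phys_ci$agp else phys_ci$albumin

  f_liver <- phys_ci$v_liver / phys_ht$v_liver
  f_ces1 <- phys_ci$ces1_content / phys_ht$ces1_content
  fu_ci <- scale_fu(drug$fu_b, protein_ht, protein_ci)
  fu_ratio <- fu_ci / drug$fu_b

  factors <- list(f_ces1 = f_ces1, f_liver = f_liver,
                  fu_ratio = fu_ratio,
                  gfr_ratio = phys_ci$gfr / phys_ht$gfr,
                  lr_ratio = phys_ci$lr_ratio / phys_ht$lr_ratio,
                  mrp2_ratio = phys_ci$mrp2_ratio / phys_ht$mrp2_ratio)

  out$pathways <- lapply(drug$pathways, function(pw) {
    f <- pathway_factor(pw$enzyme, phys_ht, phys_ci)
    if (pw$kind == "linear") {
      # whole-liver clearance: content ratio times liver volume ratio
      pw$clint <- pw$clint * f * f_liver
    } else {
      # per-mg Vmax carries the content ratio only; the engine rebuilds the
      # whole-liver capacity from the physiology's liver mass, which already
      # reflects the cirrhotic liver volume
      pw$vmax <- pw$vmax * f
    }
    pw
  })
  if (length(drug$pathways)) {
    prov["pathways"] <- "hepatic content ratio x liver volume ratio"
  }

  out$fu_b <- fu_ci
  prov["fu_b"] <- sprintf("protein binding (%s %g -> %g g/L)",
                          drug$binding_protein, protein_ht, protein_ci)

  out$v_sys <- scale_volume(drug$v_sys, drug$fu_b, fu_ci)
  prov["v_sys"] <- "unbound volume conserved (scaled by fu ratio)"

  if (!is.null(drug$clint_k) && drug$clint_k > 0) {
    out$clint_k <- scale_renal_clint(drug$clint_k, phys_ht$gfr, phys_ci$gfr)
    prov["clint_k"] <- "GFR ratio"
  }
  if (!is.null(drug$cl_bile)) {
    out$cl_bile <- scale_other_clint(drug$cl_bile, factors$mrp2_ratio,
                                     phys_ht, phys_ci)
    prov["cl_bile"] <- "MRP2 activity ratio x liver volume ratio"
  }
  if (!is.null(drug$peff)) {
    out$peff <- scale_peff(drug$peff, phys_ht$lr_ratio, phys_ci$lr_ratio)
    prov["peff"] <- "lactulose/rhamnose ratio"
  } else if (!is.null(drug$ka)) {
    out$ka <- scale_peff(drug$ka, phys_ht$lr_ratio, phys_ci$lr_ratio)
    prov["ka"] <- "lactulose/rhamnose ratio"
  }
  validate_drug(out)
  structure(
    list(drug = out, from = phys_ht$population_label,
         to = phys_ci$population_label,
         scale_factors = factors, provenance = prov),
    class = "translated_parameters"
  )
}

#' @export
print.translated_parameters <- function(x, ...) {
  cat(sprintf("<translated_parameters: %s, %s -> %s>\n",
              x$drug$name, x$from, x$to))
  f <- x$scale_factors
  cat(sprintf("  f_CES1 %.3g, f_liver %.3g, fu ratio %.3g, GFR ratio %.3g, L/R ratio %.3g\n",
              f$f_ces1, f$f_liver, f$fu_ratio, f$gfr_ratio, f$lr_ratio))
  invisible(x)
}

#' Two-column before/after table for a translation
#'
#' @param x a `translated_parameters` object.
#' @param original the untranslated [drug_record()].
#' @return a data.frame with columns `parameter`, `healthy`, `patient`,
#'   `rule`.
#' @export
translation_table <- function(x, original) {
  stopifnot(inherits(x, "translated_parameters"))
  rows <- list()
  add <- function(param, ht, ci, rule) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = param, healthy = ht, patient = ci, rule = rule,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(original$pathways)) {
    po <- original$pathways[[i]]; pt <- x$drug$pathways[[i]]
    if (po$kind == "linear") {
      add(sprintf("clint_%s_ml_min", po$enzyme), po$clint, pt$clint,
          x$provenance[["pathways"]])
    } else {
      add(sprintf("vmax_%s_nmol_min_mg", po$enzyme), po$vmax, pt$vmax,
          x$provenance[["pathways"]])
    }
  }
  add("fu_b", original$fu_b, x$drug$fu_b, x$provenance[["fu_b"]])
  add("v_sys_l", original$v_sys, x$drug$v_sys, x$provenance[["v_sys"]])
  if (!is.na(x$provenance["clint_k"])) {
    add("clint_k_ml_min", original$clint_k, x$drug$clint_k,
        x$provenance[["clint_k"]])
  }
  if (!is.null(original$cl_bile)) {
    add("cl_bile_ml_min", original$cl_bile, x$drug$cl_bile,
        x$provenance[["cl_bile"]])
  }
  if (!is.null(original$peff)) {
    add("peff_cm_s", original$peff, x$drug$peff, x$provenance[["peff"]])
  } else if (!is.null(original$ka)) {
    add("ka_per_min", original$ka, x$drug$ka, x$provenance[["ka"]])
  }
  do.call(rbind, rows)
}
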