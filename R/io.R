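DRUG_SCHEMA <- "ces1pbpk-drug-v1"

#' Load a drug record from a bundled fixture or file
#'
#' Compound parameter files are human-editable YAML, one per compound, with
#' units encoded in the key names (`clint_k_ml_min`, `v_sys_l`,
#' `peff_1e4_cm_s`, ...).  On load all quantities are normalised to the
#' package's internal unit system; effective permeability is stored in cm/s.
#'
#' @param source bundled compound name (e.g. `"enalapril"`) or a file path.
#' @return a [drug_record()].
#' @seealso [load_drug_pair()] to also resolve the linked metabolite record,
#'   [write_drug()] for the inverse operation.
#' @examples
#' ena <- load_drug("enalapril")
#' ena$fu_b            # 0.74
#' ena$metabolite      # "enalaprilat"
#' @export
load_drug <- function(source) {
  path <- resolve_fixture(source, subdir = "drugs", ext = ".yaml")
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, DRUG_SCHEMA)) {
    stop(sprintf("unknown drug schema '%s' in %s (expected %s)",
                 raw$schema %||% "<none>", path, DRUG_SCHEMA), call. = FALSE)
  }
  drug_from_list(normalize_units(raw))
}

#' Load a drug together with its tracked metabolite
#'
#' @param source bundled compound name or file path of the parent drug.
#' @return a list with elements `drug` and `metabolite` (the latter `NULL`
#'   when the compound has no tracked metabolite).
#' @export
load_drug_pair <- function(source) {
  drug <- load_drug(source)
  met <- NULL
  if (!is.null(drug$metabolite)) {
    met <- load_drug(drug$metabolite)
  }
  list(drug = drug, metabolite = met)
}

#' Normalise raw fixture units to the internal unit system
#'
#' Maps the unit-suffixed keys of a raw compound list onto canonical field
#' names (mg / mL / min internally; permeability in cm/s).  The operation is
#' involutive: applying it to an already-normalised list returns the list
#' unchanged.
#'
#' @param raw a named list as read from a compound YAML file.
#' @return a named list with canonical field names.
#' @export
normalize_units <- function(raw) {
  if (isTRUE(attr(raw, "normalized"))) return(raw)
  out <- list(
    schema = raw$schema,
    name = raw$name,
    is_metabolite = isTRUE(raw$is_metabolite),
    parent = raw$parent,
    metabolite = raw$metabolite,
    mw = raw$mw_g_mol,
    logp = raw$logp, pka = raw$pka, f = raw$f,
    binding_protein = raw$binding_protein %||% "albumin",
    fu_b = raw$fu_b, rb = raw$rb,
    v_sys = raw$v_sys_l,
    k_lp = raw$k_lp, k_gp = raw$k_gp, k_kp = raw$k_kp,
    cl_b = raw$cl_b_ml_min,
    clint_k = raw$clint_k_ml_min %||% 0,
    cl_bile = raw$cl_bile_ml_min,
    k12 = raw$k12_per_min, k21 = raw$k21_per_min,
    k13 = raw$k13_per_min, k31 = raw$k31_per_min,
    peff = if (!is.null(raw$peff_1e4_cm_s)) raw$peff_1e4_cm_s * 1e-4,
    ka = raw$ka_per_min,
    pathways = lapply(raw$pathways, function(pw) {
      list(enzyme = pw$enzyme,
           clint = pw$clint_ml_min,
           vmax = pw$vmax_nmol_min_mg,
           km = pw$km_umol_l,
           metabolite = pw$metabolite)
    })
  )
  attr(out, "normalized") <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drug_from_list <- function(x) {
  pathways <- lapply(x$pathways, function(pw) {
    elimination_pathway(enzyme = pw$enzyme, clint = pw$clint,
                        vmax = pw$vmax, km = pw$km,
                        metabolite = pw$metabolite)
  })
  drug_record(
    name = x$name, pathways = pathways,
    k_lp = x$k_lp, k_gp = x$k_gp, k_kp = x$k_kp,
    v_sys = x$v_sys, rb = x$rb, fu_b = x$fu_b,
    clint_k = x$clint_k, cl_bile = x$cl_bile, cl_b = x$cl_b,
    k12 = x$k12, k21 = x$k21, k13 = x$k13, k31 = x$k31,
    peff = x$peff, ka = x$ka,
    binding_protein = x$binding_protein,
    mw = x$mw, logp = x$logp, pka = x$pka, f = x$f,
    is_metabolite = x$is_metabolite, parent = x$parent,
    metabolite = x$metabolite
  )
}

#' Write a drug record to a YAML fixture file
#'
#' Inverse of [load_drug()]: a written record re-loads with every field
#' bit-identical.
#'
#' @param drug a [drug_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drug <- function(drug, path) {
  stopifnot(inherits(drug, "drug_record"))
  out <- list(schema = DRUG_SCHEMA, name = drug$name)
  if (drug$is_metabolite) out$is_metabolite <- TRUE
  out$parent <- drug$parent
  out$metabolite <- drug$metabolite
  out$mw_g_mol <- drug$mw
  out$logp <- drug$logp
  out$pka <- drug$pka
  out$f <- drug$f
  out$binding_protein <- drug$binding_protein
  out$fu_b <- drug$fu_b
  out$rb <- drug$rb
  out$v_sys_l <- drug$v_sys
  out$k_lp <- drug$k_lp
  out$k_gp <- drug$k_gp
  out$k_kp <- drug$k_kp
  out$cl_b_ml_min <- drug$cl_b
  out$clint_k_ml_min <- drug$clint_k
  out$cl_bile_ml_min <- drug$cl_bile
  out$k12_per_min <- drug$k12
  out$k21_per_min <- drug$k21
  out$k13_per_min <- drug$k13
  out$k31_per_min <- drug$k31
  # 12 significant digits: exact for tabulated permeabilities and immune to
  # the non-invertible /1e-4 rescaling in the last ulp
  if (!is.null(drug$peff)) out$peff_1e4_cm_s <- signif(drug$peff * 1e4, 12)
  out$ka_per_min <- drug$ka
  if (length(drug$pathways)) {
    out$pathways <- lapply(drug$pathways, function(pw) {
      p <- list(enzyme = pw$enzyme)
      if (!is.null(pw$clint)) p$clint_ml_min <- pw$clint
      if (!is.null(pw$vmax)) p$vmax_nmol_min_mg <- pw$vmax
      if (!is.null(pw$km)) p$km_umol_l <- pw$km
      if (!is.null(pw$metabolite)) p$metabolite <- pw$metabolite
      p
    })
  }
  out <- out[!vapply(out, is.null, logical(1))]
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' List the compounds bundled with the package
#'
#' @return character vector of bundled compound names (nine parent drugs and
#'   their tracked metabolites).
#' @export
bundled_drugs <- function() {
  dir <- system.file("extdata", "drugs", package = "ces1pbpk")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}
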