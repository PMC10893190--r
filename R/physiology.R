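#' Construct a physiology parameter set
#'
#' A `physiology_set` bundles the anatomical and physiological quantities the
#' semi-PBPK model needs for one population: organ blood flows, functional
#' organ volumes, gastrointestinal transit rate constants, gut radii,
#' glomerular filtration rate, plasma binding-protein concentrations, hepatic
#' enzyme contents, the lactulose/rhamnose intestinal permeability marker and
#' the relative biliary MRP2 transporter activity.
#'
#' Internal units are fixed to mL, mg and min throughout the package.
#'
#' @param population_label one of `"healthy"`, `"CP-A"`, `"CP-B"`, `"CP-C"`
#'   (Child-Pugh cirrhosis grades) or any other label for custom sets.
#' @param q_la,q_pv,q_k hepatic arterial, portal vein and kidney blood flow
#'   (mL/min). Total hepatic flow is `q_la + q_pv`.
#' @param q_gw gut-wall blood flows, named numeric of length 3
#'   (duodenum, jejunum, ileum), mL/min.
#' @param v_liver,v_pv,v_k functional liver, portal vein and kidney volumes
#'   (mL).
#' @param v_gw gut-wall volumes, length 3 (mL).
#' @param k_t first-order gastric emptying / intestinal transit rate
#'   constants, named numeric of length 4 (stomach, duodenum, jejunum,
#'   ileum), 1/min.
#' @param r gut lumen radii, length 3 (cm), used to convert effective
#'   permeability into segmental absorption rate constants.
#' @param gfr glomerular filtration rate (mL/min).
#' @param albumin,agp serum albumin and alpha-1-acid glycoprotein (g/L).
#' @param ces1_content hepatic carboxylesterase-1 content (mg/g liver).
#' @param cyp2b6_content hepatic CYP2B6 content (pmol/mg).
#' @param lr_ratio lactulose/rhamnose urinary recovery ratio (dimensionless).
#' @param mrp2_ratio biliary MRP2 activity relative to healthy
#'   (dimensionless).
#'
#' @return an object of class `physiology_set`.
#' @seealso [load_physiology()] for the bundled population table.
#' @export
physiology_set <- function(population_label,
                           q_la, q_pv, q_k, q_gw,
                           v_liver, v_pv, v_k, v_gw,
                           k_t, r, gfr, albumin, agp,
                           ces1_content, cyp2b6_content,
                           lr_ratio, mrp2_ratio) {
  obj <- structure(
    list(
      population_label = as.character(population_label),
      q_l = q_la + q_pv,
      q_la = q_la, q_pv = q_pv, q_k = q_k,
      q_gw = stats::setNames(as.numeric(q_gw), c("duodenum", "jejunum", "ileum")),
      v_liver = v_liver, v_pv = v_pv, v_k = v_k,
      v_gw = stats::setNames(as.numeric(v_gw), c("duodenum", "jejunum", "ileum")),
      k_t = stats::setNames(as.numeric(k_t),
                            c("stomach", "duodenum", "jejunum", "ileum")),
      r = stats::setNames(as.numeric(r), c("r1", "r2", "r3")),
      gfr = gfr, albumin = albumin, agp = agp,
      ces1_content = ces1_content, cyp2b6_content = cyp2b6_content,
      lr_ratio = lr_ratio, mrp2_ratio = mrp2_ratio
    ),
    class = "physiology_set"
  )
  validate_physiology(obj)
  obj
}

#' Validate a physiology set
#'
#' Checks strict positivity of every quantity, the hepatic flow identity
#' (total hepatic flow equals arterial plus portal flow, to 0.1%) and that
#' gut-wall flows do not exceed the portal vein flow they drain into.
#' Errors name the offending field.
#'
#' @param phys a `physiology_set`.
#' @return `phys`, invisibly, if valid.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology_set"))
  scalars <- c("q_l", "q_la", "q_pv", "q_k", "v_liver", "v_pv", "v_k",
               "gfr", "albumin", "agp", "ces1_content", "cyp2b6_content",
               "lr_ratio", "mrp2_ratio")
  for (f in scalars) {
    v <- phys[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("physiology field '%s' must be a single positive number (%s)",
                   f, phys$population_label), call. = FALSE)
    }
  }
  for (f in c("q_gw", "v_gw", "k_t", "r")) {
    v <- phys[[f]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("physiology field '%s' must be positive throughout (%s)",
                   f, phys$population_label), call. = FALSE)
    }
  }
  if (abs(phys$q_l - (phys$q_la + phys$q_pv)) > 1e-3 * phys$q_l) {
    stop(sprintf(
      "hepatic flow identity violated for '%s': q_l = %.4g but q_la + q_pv = %.4g",
      phys$population_label, phys$q_l, phys$q_la + phys$q_pv), call. = FALSE)
  }
  if (sum(phys$q_gw) > phys$q_pv) {
    stop(sprintf("sum of gut-wall flows exceeds portal vein flow (%s)",
                 phys$population_label), call. = FALSE)
  }
  invisible(phys)
}

#' @export
print.physiology_set <- function(x, ...) {
  cat(sprintf("<physiology_set: %s>\n", x$population_label))
  cat(sprintf("  hepatic flow %g mL/min (arterial %g + portal %g), kidney %g mL/min\n",
              x$q_l, x$q_la, x$q_pv, x$q_k))
  cat(sprintf("  liver %g mL, GFR %g mL/min, albumin %g g/L, AGP %g g/L\n",
              x$v_liver, x$gfr, x$albumin, x$agp))
  cat(sprintf("  CES1 %g mg/g, CYP2B6 %g pmol/mg, L/R %g, MRP2 %g\n",
              x$ces1_content, x$cyp2b6_content, x$lr_ratio, x$mrp2_ratio))
  invisible(x)
}

#' @export
as.data.frame.physiology_set <- function(x, ...) {
  flat <- unlist(x[-1])
  data.frame(population = x$population_label,
             parameter = names(flat),
             value = as.numeric(flat),
             row.names = NULL)
}

#' Load physiology sets for the four study populations
#'
#' Reads a population physiology table from a YAML file (or the bundled
#' table, `"table1"`) and returns one validated [physiology_set()] per
#' population.  The bundled table covers healthy adults and Child-Pugh A, B
#' and C cirrhosis patients.
#'
#' @param source `"table1"` for the bundled table, or a path to a YAML file
#'   with the same layout.
#' @return a named list of `physiology_set` objects
#'   (`healthy`, `CP-A`, `CP-B`, `CP-C` for the bundled table).
#' @examples
#' phys <- load_physiology()
#' phys$healthy$q_l      # 1450 mL/min
#' phys$`CP-C`$albumin   # 26.3 g/L
#' @export
load_physiology <- function(source = "table1") {
  path <- resolve_fixture(source, subdir = "", ext = ".yaml")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$populations)) {
    stop("physiology file has no 'populations' block: ", path, call. = FALSE)
  }
  out <- lapply(names(raw$populations), function(lab) {
    p <- raw$populations[[lab]]
    need <- c("q_la_ml_min", "q_pv_ml_min", "q_k_ml_min", "q_gw_ml_min",
              "v_liver_ml", "v_pv_ml", "v_k_ml", "v_gw_ml", "k_t_per_min",
              "r_cm", "gfr_ml_min", "albumin_g_l", "agp_g_l",
              "ces1_mg_g", "cyp2b6_pmol_mg", "lr_ratio", "mrp2_ratio")
    missing <- setdiff(need, names(p))
    if (length(missing)) {
      stop(sprintf("population '%s' is missing field(s): %s",
                   lab, paste(missing, collapse = ", ")), call. = FALSE)
    }
    physiology_set(
      population_label = lab,
      q_la = p$q_la_ml_min, q_pv = p$q_pv_ml_min, q_k = p$q_k_ml_min,
      q_gw = unlist(p$q_gw_ml_min),
      v_liver = p$v_liver_ml, v_pv = p$v_pv_ml, v_k = p$v_k_ml,
      v_gw = unlist(p$v_gw_ml),
      k_t = unlist(p$k_t_per_min), r = unlist(p$r_cm),
      gfr = p$gfr_ml_min, albumin = p$albumin_g_l, agp = p$agp_g_l,
      ces1_content = p$ces1_mg_g, cyp2b6_content = p$cyp2b6_pmol_mg,
      lr_ratio = p$lr_ratio, mrp2_ratio = p$mrp2_ratio
    )
  })
  names(out) <- names(raw$populations)
  out
}

# Resolve a bundled fixture name or a user path.
resolve_fixture <- function(source, subdir = "drugs", ext = ".yaml") {
  if (file.exists(source)) return(source)
  fname <- if (endsWith(source, ext)) source else paste0(source, ext)
  parts <- c("extdata", if (nzchar(subdir)) subdir, fname)
  path <- do.call(system.file, c(as.list(parts), package = "ces1pbpk"))
  if (identical(path, "") || !file.exists(path)) {
    stop(sprintf("no bundled fixture '%s' and no such file", source),
         call. = FALSE)
  }
  path
}
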