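# One-at-a-time sensitivity analysis and the healthy-to-cirrhosis
# contribution decomposition.

# Apply a fold multiplier for a named model input, returning modified
# (drug, metabolite, phys).  `GFR` acts through the renal intrinsic
# clearances of both species (the translation rule), `CLint_L` scales every
# hepatic pathway of the parent, `K_t` all four transit constants, flow
# changes keep total hepatic flow consistent.
apply_fold <- function(parameter, fold, drug, metabolite, phys) {
  if (fold <= 0) stop("fold levels must be positive", call. = FALSE)
  scale_hepatic <- function(rec, f) {
    rec$pathways <- lapply(rec$pathways, function(pw) {
      if (pw$kind == "linear") pw$clint <- pw$clint * f
      else pw$vmax <- pw$vmax * f
      pw
    })
    rec
  }
  switch(parameter,
    "Peff" = {
      if (!is.null(drug$peff)) drug$peff <- drug$peff * fold
      else if (!is.null(drug$ka)) drug$ka <- drug$ka * fold
    },
    "CLint_L" = drug <- scale_hepatic(drug, fold),
    "K_t" = phys$k_t <- phys$k_t * fold,
    "fu_b" = drug$fu_b <- min(1, drug$fu_b * fold),
    "fu_b_m" = if (!is.null(metabolite)) {
      metabolite$fu_b <- min(1, metabolite$fu_b * fold)
    },
    "Q_PV" = { phys$q_pv <- phys$q_pv * fold; phys$q_l <- phys$q_la + phys$q_pv },
    "Q_LA" = { phys$q_la <- phys$q_la * fold; phys$q_l <- phys$q_la + phys$q_pv },
    "Q_K" = phys$q_k <- phys$q_k * fold,
    "GFR" = {
      drug$clint_k <- drug$clint_k * fold
      if (!is.null(metabolite)) metabolite$clint_k <- metabolite$clint_k * fold
    },
    "K13" = if (!is.null(drug$k13)) drug$k13 <- drug$k13 * fold,
    stop("unknown sensitivity parameter '", parameter, "'", call. = FALSE)
  )
  list(drug = drug, metabolite = metabolite, phys = phys)
}

#' Default one-at-a-time fold levels
#'
#' The conventional scan levels: portal vein flow, kidney flow and transit
#' rates varied 1/2- to 2-fold; hepatic arterial flow, hepatic intrinsic
#' clearance and permeability 1/3- to 3-fold; GFR 0.5- to 1.5-fold; unbound
#' fractions 0.7- to 1.3-fold.
#'
#' @return named list of numeric fold-level vectors (each includes 1).
#' @export
default_oat_levels <- function() {
  list(
    Peff = c(1 / 3, 1, 3),
    CLint_L = c(1 / 3, 1, 3),
    K_t = c(1 / 2, 1, 2),
    fu_b = c(0.7, 1, 1.3),
    fu_b_m = c(0.7, 1, 1.3),
    Q_PV = c(1 / 2, 1, 2),
    GFR = c(0.5, 1, 1.5),
    Q_K = c(1 / 2, 1, 2),
    Q_LA = c(1 / 3, 1, 3)
  )
}

#' One-at-a-time parameter scan
#'
#' Simulates the model with each parameter varied across its fold levels
#' while all others are held at base values, and ranks parameters by their
#' influence span (the max/min ratio of the AUC across levels).
#'
#' @param drug,metabolite base records.
#' @param phys a [physiology_set()].
#' @param regimen a [dose_regimen()].
#' @param levels named list of fold-level vectors; see
#'   [default_oat_levels()].
#' @param t_end,t_last simulation horizon and AUC truncation (min).
#' @return an object of class `oat_scan`: list with `results` (long
#'   data.frame: parameter, fold, auc_parent, auc_metabolite) and `ranking`
#'   (data.frame with influence spans, sorted, per analyte).
#' @export
oat_scan <- function(drug, phys, regimen, metabolite = NULL,
                     levels = default_oat_levels(),
                     t_end = 2880, t_last = NULL) {
  if (inherits(drug, "translated_parameters")) drug <- drug$drug
  if (inherits(metabolite, "translated_parameters")) metabolite <- metabolite$drug
  if (any(vapply(levels, function(l) any(l <= 0), logical(1)))) {
    stop("fold levels must be positive", call. = FALSE)
  }
  run_auc <- function(d, m, ph) {
    sys <- build_system(d, ph, regimen, metabolite = m)
    res <- simulate_profile(sys, t_end = t_end)
    c(parent = pk_summary(res, t_last = t_last)$auc0_t,
      metabolite = if (!is.null(m))
        pk_summary(res, analyte = m$name, t_last = t_last)$auc0_t
      else NA_real_)
  }
  rows <- list()
  for (param in names(levels)) {
    for (fold in levels[[param]]) {
      mod <- apply_fold(param, fold, drug, metabolite, phys)
      auc <- run_auc(mod$drug, mod$metabolite, mod$phys)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, fold = fold,
        auc_parent = auc[["parent"]], auc_metabolite = auc[["metabolite"]],
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  span <- function(v) if (all(is.na(v))) NA_real_ else max(v) / min(v)
  ranking <- do.call(rbind, lapply(split(results, results$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               span_parent = span(d$auc_parent),
               span_metabolite = span(d$auc_metabolite),
               stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(-ranking$span_parent), ]
  rownames(ranking) <- NULL
  structure(list(results = results, ranking = ranking),
            class = "oat_scan")
}

#' @export
print.oat_scan <- function(x, ...) {
  cat("<oat_scan>\n  influence (AUC max/min across fold levels):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Parameter ranking for one analyte
#'
#' @param scan an [oat_scan()] result.
#' @param analyte `"parent"` or `"metabolite"`.
#' @return character vector of parameter names, most influential first.
#' @export
oat_ranking <- function(scan, analyte = c("parent", "metabolite")) {
  analyte <- match.arg(analyte)
  col <- paste0("span_", analyte)
  r <- scan$ranking[!is.na(scan$ranking[[col]]), ]
  r$parameter[order(-r[[col]])]
}

# The factors whose healthy-to-cirrhosis switches are examined one by one.
CONTRIBUTION_FACTORS <- c("K_t", "Q_PV", "CLint_L", "Peff", "GFR", "Q_K", "fu_b")

# Swap a single factor from its healthy to its cirrhotic value.
apply_cirrhosis_factor <- function(factor, drug, metabolite, phys_ht, phys_ci) {
  phys <- phys_ht
  scale_fu_field <- function(rec) {
    prot_ht <- if (rec$binding_protein == "AGP") phys_ht$agp else phys_ht$albumin
    prot_ci <- if (rec$binding_protein == "AGP") phys_ci$agp else phys_ci$albumin
    fu_ci <- scale_fu(rec$fu_b, prot_ht, prot_ci)
    rec$v_sys <- scale_volume(rec$v_sys, rec$fu_b, fu_ci)
    rec$fu_b <- fu_ci
    rec
  }
  switch(factor,
    "K_t" = phys$k_t <- phys_ci$k_t,
    "Q_PV" = { phys$q_pv <- phys_ci$q_pv; phys$q_l <- phys$q_la + phys$q_pv },
    "Q_K" = phys$q_k <- phys_ci$q_k,
    "Q_LA" = { phys$q_la <- phys_ci$q_la; phys$q_l <- phys$q_la + phys$q_pv },
    "CLint_L" = {
      f_liver <- phys_ci$v_liver / phys_ht$v_liver
      drug$pathways <- lapply(drug$pathways, function(pw) {
        f <- pathway_factor(pw$enzyme, phys_ht, phys_ci)
        if (pw$kind == "linear") pw$clint <- pw$clint * f * f_liver
        else pw$vmax <- pw$vmax * f
        pw
      })
    },
    "Peff" = {
      if (!is.null(drug$peff)) {
        drug$peff <- scale_peff(drug$peff, phys_ht$lr_ratio, phys_ci$lr_ratio)
      } else if (!is.null(drug$ka)) {
        drug$ka <- scale_peff(drug$ka, phys_ht$lr_ratio, phys_ci$lr_ratio)
      }
    },
    "GFR" = {
      drug$clint_k <- scale_renal_clint(drug$clint_k, phys_ht$gfr, phys_ci$gfr)
      if (!is.null(metabolite)) {
        metabolite$clint_k <- scale_renal_clint(metabolite$clint_k,
                                                phys_ht$gfr, phys_ci$gfr)
      }
    },
    "fu_b" = {
      drug <- scale_fu_field(drug)
      if (!is.null(metabolite)) metabolite <- scale_fu_field(metabolite)
    },
    stop("unknown contribution factor '", factor, "'", call. = FALSE)
  )
  list(drug = drug, metabolite = metabolite, phys = phys)
}

#' Decompose the cirrhosis effect into per-factor contributions
#'
#' Runs one simulation per disease factor -- transit rate, portal vein flow,
#' hepatic intrinsic clearance, permeability, GFR, kidney flow and plasma
#' binding -- with only that factor switched from its healthy to its
#' cirrhotic value, plus the healthy base case and the fully translated
#' ("integrated") cirrhosis case.
#'
#' @param drug,metabolite healthy-parameterised records.
#' @param phys_ht,phys_ci healthy and patient [physiology_set()]s.
#' @param regimen a [dose_regimen()].
#' @param t_end,t_last horizon and AUC truncation (min).
#' @param factors which factors to switch (default: the standard seven).
#' @return an object of class `contribution_decomposition`: list with
#'   `curves` (per-run concentration data.frames), `auc` (data.frame of
#'   per-run AUCs and their direction of change vs healthy) and `time`.
#' @export
contribution_decomposition <- function(drug, phys_ht, phys_ci, regimen,
                                       metabolite = NULL,
                                       t_end = 2880, t_last = NULL,
                                       factors = CONTRIBUTION_FACTORS) {
  if (inherits(drug, "translated_parameters")) drug <- drug$drug
  if (inherits(metabolite, "translated_parameters")) metabolite <- metabolite$drug
  run <- function(d, m, ph) {
    sys <- build_system(d, ph, regimen, metabolite = m)
    simulate_profile(sys, t_end = t_end)
  }
  runs <- list(healthy = run(drug, metabolite, phys_ht))
  for (f in factors) {
    mod <- apply_cirrhosis_factor(f, drug, metabolite, phys_ht, phys_ci)
    runs[[f]] <- run(mod$drug, mod$metabolite, mod$phys)
  }
  tr_d <- translate_drug(drug, phys_ht, phys_ci)
  tr_m <- if (!is.null(metabolite)) translate_drug(metabolite, phys_ht, phys_ci)
  runs[["integrated"]] <- run(tr_d$drug, if (!is.null(tr_m)) tr_m$drug, phys_ci)

  base_auc <- vapply(names(runs$healthy$conc), function(a)
    pk_summary(runs$healthy, analyte = a, t_last = t_last)$auc0_t, numeric(1))
  auc <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    do.call(rbind, lapply(names(r$conc), function(a) {
      v <- pk_summary(r, analyte = a, t_last = t_last)$auc0_t
      data.frame(run = nm, analyte = a, auc0_t = v,
                 change = v / base_auc[[a]],
                 direction = ifelse(abs(v / base_auc[[a]] - 1) < 1e-9, "none",
                                    ifelse(v > base_auc[[a]], "up", "down")),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(time = runs$healthy$time,
                 curves = lapply(runs, `[[`, "conc"),
                 auc = auc),
            class = "contribution_decomposition")
}

#' @export
print.contribution_decomposition <- function(x, ...) {
  cat("<contribution_decomposition>\n")
  print(x$auc, row.names = FALSE)
  invisible(x)
}
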