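# Shared fixtures: load once per test session.
PHYS <- load_physiology()
HT <- PHYS$healthy

sim_case <- function(drug_name, pop = "healthy", dose = 10, route = "oral",
                     infusion = 0, per_kg = FALSE, t_end = 2880,
                     coarse = TRUE, ...) {
  pair <- load_drug_pair(drug_name)
  d <- pair$drug; m <- pair$metabolite
  if (pop != "healthy") {
    d <- translate_drug(d, PHYS$healthy, PHYS[[pop]])$drug
    if (!is.null(m)) m <- translate_drug(m, PHYS$healthy, PHYS[[pop]])$drug
  }
  reg <- dose_regimen(route, dose, per_kg = per_kg, infusion_duration = infusion)
  sys <- build_system(d, PHYS[[pop]], reg, metabolite = m)
  times <- if (coarse) seq(0, t_end, by = min(2, t_end / 100)) else NULL
  simulate_profile(sys, t_end = t_end, times = times, ...)
}

# minimal synthetic record: no hepatic pathways, renal elimination only
renal_only_drug <- function(clint_k = 200, fu = 0.5) {
  drug_record(name = "synthetic_renal", pathways = list(),
              k_lp = 1, k_gp = 1, k_kp = 1, v_sys = 20, rb = 1,
              fu_b = fu, clint_k = clint_k)
}
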