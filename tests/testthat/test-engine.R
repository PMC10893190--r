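test_that("system layout matches the dosing route and compound structure", {
  pair <- load_drug_pair("enalapril")
  sys <- build_system(pair$drug, HT, dose_regimen("oral", 10),
                      metabolite = pair$metabolite)
  # parent: stomach + 3 lumen + 3 gut wall + PV + liver + kidney + systemic
  expect_true(all(c("a_stomach", "a_lumen_ileum", "a_liver", "a_sys",
                    "a_sys_m", "a_per2_m", "e_formed_m") %in% sys$state_names))
  expect_false("a_stomach_m" %in% sys$state_names)   # no metabolite lumen
  remi <- load_drug("remimazolam")
  sysr <- build_system(remi, HT, dose_regimen("iv_bolus", 7))
  expect_false(any(grepl("lumen|stomach", sysr$state_names)))
  expect_true(all(c("a_per2", "a_per3") %in% sysr$state_names))  # 3-compartment
  # errors: missing metabolite record, oral without absorption parameter
  expect_error(build_system(pair$drug, HT, dose_regimen("oral", 10)),
               "metabolite")
  expect_error(build_system(remi, HT, dose_regimen("oral", 10)), "Peff or ka")
})

test_that("i.v. AUC of a linear drug equals dose over closed-form clearance", {
  remi <- load_drug("remimazolam")
  res <- simulate_profile(build_system(remi, HT, dose_regimen("iv_bolus", 7)),
                          times = seq(0, 2880, 1))
  cl_oracle <- well_stirred_cl(79212.96, 0.08, 1450)  # = its blood CL, 1180
  auc_oracle <- 7 / cl_oracle * 1000 / 60             # mg/(mL/min) -> ug.h/mL
  s <- pk_summary(res)
  expect_equal(s$auc0_inf, auc_oracle, tolerance = 0.005)
  expect_equal(s$cl * 1000, cl_oracle, tolerance = 0.005)
})

test_that("zero dose yields identically zero concentrations", {
  ena <- load_drug_pair("enalapril")
  sys <- build_system(ena$drug, HT, dose_regimen("oral", 10),
                      metabolite = ena$metabolite)
  sys$y0[] <- 0
  res <- simulate_profile(sys, t_end = 100, times = seq(0, 100, 1))
  expect_true(all(res$conc$enalapril == 0))
  expect_true(all(res$conc$enalaprilat == 0))
})

test_that("compiled and reference R right-hand sides agree", {
  for (case in list(list("enalapril", "oral", 10, 0),
                    list("pethidine", "iv_infusion", 70, 2))) {
    pair <- load_drug_pair(case[[1]])
    sys <- build_system(pair$drug, HT,
                        dose_regimen(case[[2]], case[[3]],
                                     infusion_duration = case[[4]]),
                        metabolite = pair$metabolite)
    tt <- seq(0, 720, 2)
    rc <- simulate_profile(sys, t_end = 720, times = tt)
    rr <- simulate_profile(sys, t_end = 720, times = tt, engine = "R")
    for (a in names(rc$conc)) {
      expect_equal(rc$conc[[a]], rr$conc[[a]], tolerance = 1e-8, label = a)
    }
  }
})

test_that("mass balance closes to well below 0.1% and the detector catches breakage", {
  res <- sim_case("enalapril")
  expect_lt(mass_balance(res), 1e-6)
  # negative control: remove half the renal elimination record
  broken <- res
  broken$amounts[, "e_renal"] <- broken$amounts[, "e_renal"] * 0.5
  expect_gt(mass_balance(broken), 1e-3)
  # mid-infusion accounting uses administered-so-far
  flz <- load_drug("flumazenil")
  ri <- simulate_profile(build_system(flz, HT, dose_regimen("iv_infusion", 10,
                                                            infusion_duration = 60)),
                         t_end = 240, times = seq(0, 240, 1))
  expect_lt(mass_balance(ri), 1e-6)
})

test_that("metabolite formation conserves the producing pathway flux", {
  res <- sim_case("enalapril")
  a <- res$amounts[nrow(res$amounts), ]
  # single CES1 pathway produces enalaprilat with unit mass factor
  expect_equal(unname(a["e_formed_m"]), unname(a["e_hep_1"]), tolerance = 1e-10)
  # temocaprilat keeps its own biliary elimination ledger
  rt <- sim_case("temocapril", dose = 1)
  at <- rt$amounts[nrow(rt$amounts), ]
  expect_gt(unname(at["e_bile_m"]), 0)
  expect_lt(mass_balance(rt), 1e-6)
})

test_that("steady-state hepatic and renal clearances match the closed forms", {
  # hepatic: flumazenil under a long constant infusion
  flz <- load_drug("flumazenil")
  rate_dose <- 100
  res <- simulate_profile(build_system(flz, HT,
                                       dose_regimen("iv_infusion", rate_dose,
                                                    infusion_duration = 6000)),
                          t_end = 6000, times = seq(0, 6000, 10))
  c_ss <- utils::tail(res$amounts[, "a_sys"], 1) / (24.054 * 1000)  # blood mg/mL
  cl_sim <- (rate_dose / 6000) / c_ss
  cl_oracle <- well_stirred_cl(8169.9, 0.6, 1450) + renal_cl(1.67, 0.6, 1240)
  expect_equal(cl_sim, cl_oracle, tolerance = 0.01)
  # renal: synthetic compound eliminated only through the kidney
  syn <- renal_only_drug(clint_k = 400, fu = 0.5)
  rs <- simulate_profile(build_system(syn, HT,
                                      dose_regimen("iv_infusion", 50,
                                                   infusion_duration = 6000)),
                         t_end = 6000, times = seq(0, 6000, 10))
  c_ss2 <- utils::tail(rs$amounts[, "a_sys"], 1) / (20 * 1000)
  cl_sim2 <- (50 / 6000) / c_ss2
  expect_equal(cl_sim2, renal_cl(400, 0.5, 1240), tolerance = 0.01)
})

test_that("AUC is dose-linear except for pethidine, whose clearance saturates", {
  for (nm in c("enalapril", "oseltamivir", "remimazolam", "flumazenil")) {
    pair <- load_drug_pair(nm)
    route <- if (is.null(pair$drug$peff) && is.null(pair$drug$ka))
      "iv_bolus" else "oral"
    auc <- vapply(c(5, 10), function(d) {
      pk_summary(sim_case(nm, dose = d, route = route))$auc0_t
    }, numeric(1))
    expect_equal(auc[2] / auc[1], 2, tolerance = 1e-3, label = nm)
  }
  cl <- vapply(c(25, 200, 1000), function(d) {
    pk_summary(sim_case("pethidine", dose = d, route = "iv_bolus"))$cl
  }, numeric(1))
  expect_true(all(diff(cl) < 0))          # CL strictly decreasing with dose
})

test_that("oral exposure per mg never exceeds intravenous exposure per mg", {
  for (nm in c("pethidine", "flumazenil")) {
    iv <- pk_summary(sim_case(nm, dose = 50, route = "iv_bolus"))
    po <- pk_summary(sim_case(nm, dose = 50, route = "oral"))
    expect_lt(po$auc0_t, iv$auc0_t)
  }
})

test_that("every bundled parent drug simulates cleanly under its study route", {
  routes <- list(enalapril = "oral", benazepril = "oral", cilazapril = "oral",
                 perindopril = "oral", temocapril = "oral", oseltamivir = "oral",
                 flumazenil = "iv_bolus", pethidine = "iv_bolus",
                 remimazolam = "iv_bolus")
  for (nm in names(routes)) {
    res <- sim_case(nm, dose = 10, route = routes[[nm]], t_end = 1440)
    expect_lt(mass_balance(res), 1e-3, label = nm)
    expect_true(all(res$conc[[nm]] >= -1e-9), label = nm)
  }
})
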