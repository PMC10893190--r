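test_that("parameters with no route into the model have unit influence span", {
  # an intravenous drug is insensitive to absorption and transit parameters
  remi <- load_drug("remimazolam")
  scan <- oat_scan(remi, HT, dose_regimen("iv_bolus", 7),
                   levels = list(Peff = c(1 / 3, 1, 3), K_t = c(0.5, 1, 2),
                                 CLint_L = c(1 / 3, 1, 3)),
                   t_end = 720)
  spans <- stats::setNames(scan$ranking$span_parent, scan$ranking$parameter)
  expect_equal(unname(spans["Peff"]), 1, tolerance = 1e-6)
  expect_equal(unname(spans["K_t"]), 1, tolerance = 1e-6)
  # high-extraction compound: the span is flow-damped but well above unity
  expect_gt(unname(spans["CLint_L"]), 1.3)
  expect_identical(oat_ranking(scan, "parent")[1], "CLint_L")
})

test_that("fold scans reject non-positive levels and keep the base level", {
  ena <- load_drug_pair("enalapril")
  expect_error(oat_scan(ena$drug, HT, dose_regimen("oral", 10),
                        metabolite = ena$metabolite,
                        levels = list(Peff = c(-1, 1))), "positive")
})

test_that("switching no factor reproduces the healthy base case exactly", {
  pair <- load_drug_pair("enalapril")
  dec <- contribution_decomposition(pair$drug, HT, HT,
                                    dose_regimen("oral", 10),
                                    metabolite = pair$metabolite,
                                    t_end = 720, factors = "GFR")
  expect_equal(dec$auc$change, rep(1, nrow(dec$auc)), tolerance = 1e-9)
})

test_that("the integrated run equals the fully translated cirrhosis base case", {
  pair <- load_drug_pair("enalapril")
  dec <- contribution_decomposition(pair$drug, HT, PHYS$`CP-C`,
                                    dose_regimen("oral", 10),
                                    metabolite = pair$metabolite,
                                    t_end = 1440, factors = c("GFR", "CLint_L"))
  direct <- sim_case("enalapril", pop = "CP-C", t_end = 1440, coarse = FALSE)
  integrated <- dec$auc[dec$auc$run == "integrated" &
                          dec$auc$analyte == "enalapril", "auc0_t"]
  expect_equal(integrated, pk_summary(direct, t_last = 1440)$auc0_t,
               tolerance = 1e-6)
})

test_that("single-factor cirrhosis switches move exposures in the known directions", {
  pair <- load_drug_pair("enalapril")
  dec <- contribution_decomposition(pair$drug, HT, PHYS$`CP-C`,
                                    dose_regimen("oral", 10),
                                    metabolite = pair$metabolite,
                                    t_end = 1440)
  g <- function(run, analyte) {
    dec$auc[dec$auc$run == run & dec$auc$analyte == analyte, "direction"]
  }
  # lower hepatic CES1 clearance raises the parent, lower GFR raises the
  # metabolite, higher permeability raises both
  expect_identical(g("CLint_L", "enalapril"), "up")
  expect_identical(g("GFR", "enalaprilat"), "up")
  expect_identical(g("Peff", "enalapril"), "up")
  expect_identical(g("Peff", "enalaprilat"), "up")
  # faster transit and lower binding-protein levels cut parent exposure
  expect_identical(g("K_t", "enalapril"), "down")
  expect_identical(g("fu_b", "enalapril"), "down")
})
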