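test_that("the fixture set covers nine parent drugs and their six tracked metabolites", {
  all <- bundled_drugs()
  recs <- lapply(all, load_drug)
  parents <- vapply(recs, function(r) !r$is_metabolite, logical(1))
  expect_equal(sum(parents), 9L)
  expect_equal(sum(!parents), 6L)
  # every compound loads and validates; metabolite links resolve both ways
  for (r in recs) {
    expect_s3_class(r, "drug_record")
    if (!is.null(r$metabolite)) {
      m <- load_drug(r$metabolite)
      expect_identical(m$parent, r$name)
    }
  }
})

test_that("enalapril record carries the printed parameters and metabolite link", {
  ena <- load_drug("enalapril")
  expect_equal(ena$fu_b, 0.74)
  expect_equal(ena$rb, 0.74)
  expect_equal(ena$peff, 1.60e-4)   # stored in cm/s
  expect_identical(ena$metabolite, "enalaprilat")
  expect_length(ena$pathways, 1)
  expect_equal(ena$pathways[[1]]$clint, 784)
  expect_identical(ena$pathways[[1]]$metabolite, "enalaprilat")
})

test_that("pethidine carries two saturable pathways with the printed kinetics", {
  pet <- load_drug("pethidine")
  expect_length(pet$pathways, 2)
  kinds <- vapply(pet$pathways, `[[`, character(1), "kind")
  expect_true(all(kinds == "saturable"))
  expect_equal(pet$pathways[[1]]$vmax, 1.56)
  expect_equal(pet$pathways[[1]]$km, 261)
  expect_equal(pet$pathways[[2]]$vmax, 5.382)
  expect_equal(pet$pathways[[2]]$km, 356)
  expect_identical(pet$binding_protein, "AGP")
})

test_that("pathway and record invariants are enforced", {
  expect_error(elimination_pathway("CES1", vmax = 1, km = 0), "'km'")
  expect_error(elimination_pathway("CES1", clint = 10, vmax = 1, km = 5),
               "exactly one")
  expect_error(elimination_pathway("CES1"), "exactly one")
  expect_error(drug_record("x", k_lp = 1, k_gp = 1, k_kp = 1, v_sys = 10,
                           rb = 1, fu_b = 1.2), "fu_b")
  expect_error(drug_record("x", k_lp = 1, k_gp = 1, k_kp = 1, v_sys = 10,
                           rb = 1, fu_b = 0.5, k13 = 0.1, k31 = 0.1),
               "k12/k21")
})

test_that("dose regimens validate and resolve per-kg doses", {
  expect_error(dose_regimen("oral", 0), "positive")
  expect_error(dose_regimen("iv_infusion", 10), "infusion_duration")
  reg <- dose_regimen("iv_bolus", 0.1, per_kg = TRUE, body_weight = 70)
  expect_equal(dose_mg(reg), 7)
  expect_equal(dose_mg(dose_regimen("oral", 10)), 10)
})

test_that("write then re-load reproduces every field bit-identically", {
  for (nm in bundled_drugs()) {
    orig <- load_drug(nm)
    tmp <- tempfile(fileext = ".yaml")
    write_drug(orig, tmp)
    again <- load_drug(tmp)
    expect_identical(orig, again, label = nm)
  }
})

test_that("unit normalisation is involutive", {
  raw <- yaml::read_yaml(system.file("extdata", "drugs", "enalapril.yaml",
                                     package = "ces1pbpk"))
  once <- normalize_units(raw)
  twice <- normalize_units(once)
  expect_identical(once, twice)
})

test_that("unknown schema versions are rejected", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("schema: something-else", "name: x"), tmp)
  expect_error(load_drug(tmp), "unknown drug schema")
})
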