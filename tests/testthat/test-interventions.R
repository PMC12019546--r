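base_scn <- function() scenario(beef_farm_config())

test_that("applying an intervention is pure and records provenance", {
  scn <- base_scn()
  iv <- intervention("noop")
  out <- apply_intervention(scn, iv)
  expect_equal(out$provenance, "noop")
  expect_equal(scn$provenance, character())          # input untouched
  out$farm$fce_multiplier <- 99
  expect_equal(scn$farm$fce_multiplier, 1)
  # baseline has empty provenance
  expect_equal(base_scn()$provenance, character())
})

test_that("modification modes compose arithmetically and resolve paths", {
  scn <- base_scn()
  fce <- intervention("fce10", tibble::tibble(
    path = "farm.fce_multiplier", mode = "multiply", value = 1.10))
  out <- apply_intervention(scn, fce)
  expect_equal(out$farm$fce_multiplier, 1.10)
  # intake demand falls by 1/1.10 at fixed output
  clim <- constant_climate(1)
  expect_equal(simulate_farm_year(out$farm, clim)$annual$intake_mg,
               simulate_farm_year(scn$farm, clim)$annual$intake_mg / 1.10,
               tolerance = 1e-12)
  expect_equal(simulate_farm_year(out$farm, clim)$annual$meat_mg,
               simulate_farm_year(scn$farm, clim)$annual$meat_mg)
  add <- intervention("roots", tibble::tibble(
    path = "farm.pasture.root_frac_deep", mode = "add", value = 0.03))
  expect_equal(apply_intervention(scn, add)$farm$pasture$root_frac_deep,
               scn$farm$pasture$root_frac_deep + 0.03)
  vac <- intervention("vac", tibble::tibble(
    path = "inhibition", mode = "set", value = 0.30))
  expect_equal(apply_intervention(scn, vac)$inhibition, 0.30)
  bad <- intervention("bad", tibble::tibble(
    path = "farm.no_such_field", mode = "set", value = 1))
  expect_error(apply_intervention(scn, bad), "farm.no_such_field",
               class = "grazenet_path_error")
})

test_that("stacking folds left and pure multiplies commute", {
  scn <- base_scn()
  a <- intervention("a", tibble::tibble(path = "farm.fce_multiplier",
                                        mode = "multiply", value = 1.1))
  b <- intervention("b", tibble::tibble(path = "farm.production_multiplier",
                                        mode = "multiply", value = 1.05))
  ab <- stack_interventions(scn, list(a, b))
  ba <- stack_interventions(scn, list(b, a))
  expect_equal(ab$farm, ba$farm)
  expect_equal(ab$provenance, c("a", "b"))
  # stack of one is apply
  expect_equal(stack_interventions(scn, list(a))$farm,
               apply_intervention(scn, a)$farm)
})

test_that("enteric inhibitions compose by cap by default, independently on request", {
  asp <- intervention("Asp", tibble::tibble(path = "inhibition",
                                            mode = "set", value = 0.8))
  vac <- intervention("vac", tibble::tibble(path = "inhibition",
                                            mode = "set", value = 0.3))
  capped <- stack_interventions(base_scn(), list(asp, vac))
  expect_equal(capped$inhibition, 0.8)
  indep <- stack_interventions(scenario(beef_farm_config(),
                                        inhibition_mode = "independent"),
                               list(asp, vac))
  expect_equal(indep$inhibition, 1 - 0.2 * 0.7, tolerance = 1e-12)
  # never exceeds 1, in either mode
  lots <- replicate(6, intervention("i", tibble::tibble(
    path = "inhibition", mode = "set", value = 0.9)), simplify = FALSE)
  expect_lte(stack_interventions(scenario(beef_farm_config(),
                                          inhibition_mode = "independent"),
                                 lots)$inhibition, 1)
})

test_that("conflicting set modifications error unless allowed", {
  s1 <- intervention("s1", tibble::tibble(path = "farm.pasture.legume_fraction",
                                          mode = "set", value = 0.3))
  s2 <- intervention("s2", tibble::tibble(path = "farm.pasture.legume_fraction",
                                          mode = "set", value = 0.5))
  expect_error(stack_interventions(base_scn(), list(s1, s2)),
               "legume_fraction", class = "grazenet_composition_error")
  out <- stack_interventions(base_scn(), list(s1, s2), allow_conflicts = TRUE)
  expect_equal(out$farm$pasture$legume_fraction, 0.5)       # later wins
  expect_true(any(grepl("re-set", out$provenance)))
})

test_that("economic deltas, stands and adoptability accumulate", {
  iv1 <- intervention("wind", annual_income_delta = 96000, adoptability = 3)
  iv2 <- intervention("trees", capex = 150000, adoptability = 2,
                      stands = list(list(species_profile = "plantation_bluegum",
                                         area = 50, perturbation = 1)))
  out <- stack_interventions(base_scn(), list(iv1, iv2))
  expect_equal(out$econ$income_delta, 96000)
  expect_equal(out$econ$capex, 150000)
  expect_length(out$stands, 1)
  expect_equal(out$adoptability, 2)                        # most limiting
})

test_that("every parameter change is attributable to a listed intervention", {
  scn <- base_scn()
  ivs <- intervention_catalog("CN1", "beef", "2030")
  out <- stack_interventions(scn, ivs)
  expect_equal(out$provenance, purrr::map_chr(ivs, "name"))
  # diff the farm configs: only FCE differs (trees/inhibition live elsewhere)
  changed <- names(out$farm)[!purrr::map2_lgl(out$farm, scn$farm, identical)]
  expect_equal(changed, "fce_multiplier")
  expect_equal(out$inhibition, 0.8)
  expect_length(out$stands, 1)
})

test_that("the bundle catalog mirrors the published compositions", {
  cn1 <- intervention_catalog("CN1", "beef", "2030")
  expect_equal(purrr::map_chr(cn1, "name"), c("Asp", "TFCE", "Trees 50 ha"))
  expect_equal(cn1[[1]]$modifications$value, 0.80)
  expect_equal(cn1[[2]]$modifications$value, 1.20)
  expect_equal(intervention_catalog("CN1", "beef", "2050")[[2]]$modifications$value,
               1.30)
  expect_equal(intervention_catalog("CN2", "beef", "2030")[[3]]$stands[[1]]$area, 55)
  expect_equal(intervention_catalog("CN2", "beef", "2050")[[3]]$stands[[1]]$area, 110)
  cn4 <- intervention_catalog("CN4", "sheep", "2030")
  expect_equal(purrr::map_chr(cn4, "name"), c("Asp", "Lucerne", "Trees 220 ha"))
  expect_equal(cn4[[3]]$stands[[1]]$species_profile, "environmental_planting")
  cn3 <- intervention_catalog("CN3", "sheep", "2030")
  expect_equal(cn3[[3]]$stands[[1]]$area, 200)
  lhf <- intervention_catalog("LHF", "beef", "2030")
  expect_true("FCE" %in% purrr::map_chr(lhf, "name"))
  expect_error(intervention_catalog("XX", "beef", "2030"), "valid themes")
  # vaccine sets 30% inhibition within TCN
  tcn <- intervention_catalog("TCN", "beef", "2030")
  vac <- tcn[[which(purrr::map_chr(tcn, "name") == "CH4 vac")]]
  expect_equal(vac$modifications$value, 0.30)
})
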