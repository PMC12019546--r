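test_that("GWP conversion is linear and rejects unknown gases", {
  gwp <- gwp_set()
  expect_equal(to_co2e(1, "ch4", gwp), 28)
  expect_equal(to_co2e(1, "n2o", gwp), 265)
  expect_equal(to_co2e(3.5, "co2", gwp), 3.5)
  expect_equal(to_co2e(0, "ch4", gwp), 0)
  expect_equal(to_co2e(2 + 3, "n2o", gwp),
               to_co2e(2, "n2o", gwp) + to_co2e(3, "n2o", gwp))
  expect_error(to_co2e(1, "sf6", gwp), "sf6")
})

test_that("enteric methane is linear in intake and in (1 - inhibition)", {
  dmi <- tibble::tibble(species = c("cattle", "sheep"),
                        dmi_mg_yr = c(1000, 400))
  ef <- c(cattle = 0.02, sheep = 0.019)
  base <- enteric_ch4(dmi, ef)
  expect_equal(base, 1000 * 0.02 + 400 * 0.019, tolerance = 1e-12)
  expect_equal(enteric_ch4(dmi, ef, inhibition = 1), 0)
  expect_equal(enteric_ch4(dmi, ef, inhibition = 0.8), 0.2 * base,
               tolerance = 1e-12)
  dmi2 <- dmi; dmi2$dmi_mg_yr <- 2 * dmi$dmi_mg_yr
  expect_equal(enteric_ch4(dmi2, ef), 2 * base, tolerance = 1e-12)
  expect_error(enteric_ch4(dmi, ef, inhibition = 1.2),
               class = "grazenet_parameter_error")
})

test_that("manure methane scales linearly with excreted organic matter", {
  expect_equal(manure_ch4(0), 0)
  expect_equal(manure_ch4(2000, 0.0008), 2 * manure_ch4(1000, 0.0008))
  expect_equal(manure_ch4(1234, 0.0008), 1234 * 0.0008, tolerance = 1e-12)
})

test_that("N2O emissions follow the factor model with exact stoichiometry", {
  f <- inventory_factors()
  zero <- n2o_emissions(0, 0, f)
  expect_equal(zero$direct, 0); expect_equal(zero$indirect, 0)
  # 28 kg N2O-N converts to exactly 44 kg N2O
  f1 <- inventory_factors(ef_fert = 1, frac_leach = 0, frac_volat = 0)
  expect_equal(n2o_emissions(28, 0, f1)$direct, 44 / 1000, tolerance = 1e-12)
  # hand-computed fixture with all pathways active
  res <- n2o_emissions(1000, 5000, f)
  direct_n <- 1000 * f$ef_fert + 5000 * f$ef_excreta
  indirect_n <- 6000 * (f$frac_leach * f$ef_leach + f$frac_volat * f$ef_volat)
  expect_equal(res$direct, direct_n * 44 / 28 / 1000, tolerance = 1e-12)
  expect_equal(res$indirect, indirect_n * 44 / 28 / 1000, tolerance = 1e-12)
})

test_that("energy and embedded emissions are additive across sources", {
  f <- inventory_factors()
  zero <- energy_and_embedded_co2e(0, 0, 0, 0, f)
  expect_equal(zero$energy_co2 + zero$embedded_co2e, 0)
  one <- energy_and_embedded_co2e(1000, 0, 0, 0, f)
  expect_equal(one$energy_co2, f$ef_diesel, tolerance = 1e-12)
  multi <- energy_and_embedded_co2e(1000, 2000, 500, 40, f)
  oracle <- (1000 * f$ef_diesel + 2000 * f$ef_electricity) / 1000 +
    500 * f$ef_fert_embedded / 1000 + 40 * f$ef_feed_embedded
  expect_equal(multi$energy_co2 + multi$embedded_co2e, oracle,
               tolerance = 1e-12)
})

test_that("the assembled inventory nets gross against sequestration", {
  fy <- simulate_farm_year(toy_farm(), constant_climate(1))
  inv <- assemble_inventory(fy, soil_seq = 0, tree_seq = 0)
  expect_equal(inv$gross_co2e, sum(inv$items$co2e_mg), tolerance = 1e-12)
  expect_equal(inv$net_co2e, inv$gross_co2e)
  # sequestration equal to gross gives net exactly zero
  inv2 <- assemble_inventory(fy, soil_seq = inv$gross_co2e / 2,
                             tree_seq = inv$gross_co2e / 2)
  expect_equal(inv2$net_co2e, 0, tolerance = 1e-9)
  # a year of soil loss (negative removal) adds to net symmetrically
  inv3 <- assemble_inventory(fy, soil_seq = -100, tree_seq = 0)
  expect_equal(inv3$net_co2e, inv$gross_co2e + 100, tolerance = 1e-9)
  # per-item co2e respects the GWP of its gas
  gwp <- gwp_set()
  expect_equal(inv$items$co2e_mg,
               purrr::map2_dbl(inv$items$mass_mg, inv$items$gas, to_co2e,
                               gwp = gwp))
})

test_that("computing sources separately then assembling equals joint computation", {
  fy <- simulate_farm_year(toy_farm(), constant_climate(1))
  f <- inventory_factors()
  inv <- assemble_inventory(fy, factors = f)
  ann <- fy$annual
  by_hand <- to_co2e(enteric_ch4(ann$dmi, f$ef_enteric), "ch4") +
    to_co2e(manure_ch4(ann$intake_mg, f$ef_manure), "ch4") +
    to_co2e(n2o_emissions(ann$n_applied_kg, ann$n_excreted_kg, f)$direct +
              n2o_emissions(ann$n_applied_kg, ann$n_excreted_kg, f)$indirect,
            "n2o") +
    sum(unlist(energy_and_embedded_co2e(ann$diesel, ann$electricity,
                                        ann$n_applied_kg,
                                        ann$purchased_feed_mg, f)))
  expect_equal(inv$gross_co2e, by_hand, tolerance = 1e-9)
})

test_that("net emissions fall strictly as enteric inhibition rises", {
  fy <- simulate_farm_year(toy_farm(), constant_climate(1))
  nets <- vapply(seq(0, 1, by = 0.1), function(i) {
    assemble_inventory(fy, inhibition = i)$net_co2e
  }, numeric(1))
  expect_true(all(diff(nets) < 0))
})

test_that("the net position averages the post-spin-up window", {
  const <- rep(0, 26)
  np <- net_position(const)
  expect_true(np$is_net_zero); expect_false(np$is_net_negative)
  np2 <- net_position(rep(-5, 26))
  expect_true(np2$is_net_negative)
  expect_equal(np2$mean_net, -5)
  # 26-year fixture: mean over years 7..26 only
  x <- c(rep(1000, 6), 1:20)
  np3 <- net_position(x)
  expect_equal(np3$mean_net, mean(1:20))
  expect_error(net_position(rep(0, 20)), class = "grazenet_coverage_error")
  # flags are mutually exclusive
  np4 <- net_position(c(rep(0, 6), rep(10, 20)))
  expect_false(np4$is_net_zero); expect_false(np4$is_net_negative)
})

test_that("protein-mass allocation yields shares summing to one", {
  res <- emissions_intensity(100, c(meat = 10, wool = 2),
                             list(meat = 0.18, wool = 0.60))
  expect_equal(sum(res$share), 1)
  # protein masses 1.8 vs 1.2 give 0.6 / 0.4 shares
  expect_equal(res$share, c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(res$intensity[1], 0.6 * 100 / 10, tolerance = 1e-12)
  # single product takes the full share
  solo <- emissions_intensity(100, c(meat = 10, wool = 0))
  expect_equal(solo$share, 1)
  # equal protein masses split evenly
  eq <- emissions_intensity(50, c(meat = 6, wool = 6),
                            list(meat = 0.3, wool = 0.3))
  expect_equal(eq$share, c(0.5, 0.5))
  expect_error(emissions_intensity(10, c(meat = 0, wool = 0)),
               class = "grazenet_undefined_error")
})

test_that("intensity is invariant to splitting a product into sub-lots", {
  joint <- emissions_intensity(200, c(meat = 12, wool = 3))
  split <- emissions_intensity(200, c(meat = 8, meat2 = 4, wool = 3),
                               list(meat = 0.18, meat2 = 0.18, wool = 0.60))
  joint_meat <- joint$intensity[joint$product == "meat"]
  expect_equal(split$intensity[split$product == "meat"], joint_meat,
               tolerance = 1e-12)
  expect_equal(split$intensity[split$product == "meat2"], joint_meat,
               tolerance = 1e-12)
})
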