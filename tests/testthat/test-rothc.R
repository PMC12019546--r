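test_that("initial pools follow the published fractions and conserve SOC", {
  p <- soil_layer_params("top", initial_soc = 100, iom = 5)
  st <- rothc_init_pools(p)
  expect_equal(unname(st$pools["dpm"]), 1.0)
  expect_equal(unname(st$pools["bio"]), 2.2)
  expect_equal(unname(st$pools["rpm"] + st$pools["hum"]), 91.8)
  expect_equal(sum(st$pools), 100, tolerance = 1e-12)
  # SOC all inert: active pools collapse to zero
  p2 <- soil_layer_params("top", initial_soc = 10, iom = 9.999,
                          init_dpm_frac = 0, init_bio_frac = 0)
  st2 <- rothc_init_pools(p2)
  expect_lt(sum(st2$pools[c("dpm", "rpm", "bio", "hum")]), 1e-3)
  # conservation holds for arbitrary stocks
  for (soc in c(17.3, 55, 240)) {
    st3 <- rothc_init_pools(soil_layer_params("deep", initial_soc = soc))
    expect_equal(sum(st3$pools), soc, tolerance = 1e-12)
  }
})

test_that("rate modifiers match their defining formulas", {
  p <- soil_layer_params("top", clay_pct = 30)
  # temperature factor crosses 1 near 9.25 C
  m <- rothc_rate_modifiers(9.25, 100, 10, p)
  expect_equal(m$a, 47.91 / (1 + exp(106.06 / (9.25 + 18.27))), tolerance = 1e-12)
  expect_lt(abs(m$a - 1), 0.02)
  # saturated soil: b exactly 1
  expect_equal(rothc_rate_modifiers(10, 200, 10, p, tsmd = 0)$b, 1)
  # cover factor ratio exactly 0.6
  wet <- rothc_rate_modifiers(10, 100, 50, p, tsmd = -5)
  bare <- rothc_rate_modifiers(10, 100, 50, p, tsmd = -5, soil_covered = FALSE)
  expect_equal(wet$c / bare$c, 0.6)
  expect_equal(wet$b, bare$b)
  # deficit accumulates under evaporative demand and is clamped
  dry <- rothc_rate_modifiers(10, 0, 1000, p, tsmd = 0)
  max_tsmd <- -(20 + 1.3 * 30 - 0.01 * 900) * 30 / 23
  expect_equal(dry$tsmd, max_tsmd)
  expect_equal(dry$b, 0.2)
  expect_error(rothc_rate_modifiers(-18.27, 10, 10, p),
               class = "grazenet_domain_error")
})

test_that("a single step conserves carbon and respects degenerate cases", {
  p <- soil_layer_params("top", clay_pct = 25)
  mods <- rothc_rate_modifiers(12, 80, 40, p)
  # zero pools, zero inputs: nothing happens
  s0 <- list(pools = c(dpm = 0, rpm = 0, bio = 0, hum = 0, iom = 3),
             tsmd = mods$tsmd, cum_co2 = 0)
  s1 <- rothc_step(s0, 0, 0, p, mods)
  expect_equal(s1$pools, s0$pools)
  expect_equal(s1$cum_co2, 0)
  # all-zero rate constants: pools change only by inputs
  pk0 <- soil_layer_params("top", clay_pct = 25, k = c(0, 0, 0, 0))
  s2 <- rothc_step(rothc_init_pools(pk0), plant_c = 1.2, dung_c = 0.3,
                   params = pk0, modifiers = mods)
  expect_equal(sum(s2$pools) - sum(rothc_init_pools(pk0)$pools), 1.5,
               tolerance = 1e-12)
  expect_equal(s2$cum_co2, 0)
})

test_that("120 months of turnover match the independent scalar oracle", {
  p <- soil_layer_params("top", clay_pct = 35, initial_soc = 60)
  mods <- list(abc = 0.9, tsmd = -10)
  st <- rothc_init_pools(p)
  start <- st$pools
  for (m in 1:120) st <- rothc_step(st, 0.25, 0.05, p, mods)
  oracle <- rothc_oracle_run(start[c("dpm", "rpm", "bio", "hum")],
                             n_months = 120, plant = 0.25, dung = 0.05,
                             k = p$k, clay = 35, abc = 0.9)
  expect_equal(unname(st$pools[c("dpm", "rpm", "bio", "hum")]),
               unname(oracle$pools), tolerance = 1e-9)
  expect_equal(st$cum_co2, unname(oracle$co2), tolerance = 1e-9)
})

test_that("per-step carbon balance holds over randomised states", {
  withr::with_seed(123, {
    p <- soil_layer_params("top", clay_pct = 20)
    for (i in 1:200) {
      pools <- c(dpm = runif(1, 0, 5), rpm = runif(1, 0, 30),
                 bio = runif(1, 0, 5), hum = runif(1, 0, 80),
                 iom = runif(1, 0, 10))
      st <- list(pools = pools, tsmd = runif(1, -40, 0), cum_co2 = 0)
      mods <- rothc_rate_modifiers(runif(1, 0, 25), runif(1, 0, 150),
                                   runif(1, 0, 150), p, tsmd = st$tsmd)
      plant <- runif(1, 0, 2); dung <- runif(1, 0, 1)
      new <- rothc_step(st, plant, dung, p, mods)
      balance <- (sum(new$pools) - sum(pools)) - (plant + dung - new$cum_co2)
      expect_lt(abs(balance) / max(1, sum(pools)), 1e-9)
      expect_equal(new$pools[["iom"]], pools[["iom"]])
      expect_gte(new$cum_co2, 0)
    }
  })
})

test_that("the closed-form steady state matches a long simulation", {
  p <- soil_layer_params("top", clay_pct = 30)
  mods <- list(abc = 1, tsmd = 0)
  ss <- rothc_steady_state(0.3, 0.1, p, mods)
  expect_true(all(ss$convergent))
  st <- list(pools = c(dpm = 0, rpm = 0, bio = 0, hum = 0, iom = 0),
             tsmd = 0, cum_co2 = 0)
  for (m in 1:5000) st <- rothc_step(st, 0.3, 0.1, p, mods)
  for (pool in c("dpm", "rpm", "bio", "hum")) {
    expect_lt(abs(st$pools[[pool]] - ss$steady_state[ss$pool == pool]) /
                ss$steady_state[ss$pool == pool], 0.001)
  }
  # homogeneity: doubling inputs doubles every steady pool
  ss2 <- rothc_steady_state(0.6, 0.2, p, mods)
  expect_equal(ss2$steady_state, 2 * ss$steady_state, tolerance = 1e-9)
  # zero inputs: all active pools empty
  ss0 <- rothc_steady_state(0, 0, p, mods)
  expect_equal(ss0$steady_state, rep(0, 4))
})

test_that("a zero-rate pool with inflow is reported non-convergent", {
  p <- soil_layer_params("deep", clay_pct = 30)   # HUM rate is exactly 0
  ss <- rothc_steady_state(0.2, 0, p, list(abc = 1, tsmd = 0))
  expect_false(ss$convergent[ss$pool == "hum"])
  expect_true(is.na(ss$steady_state[ss$pool == "hum"]))
  expect_true(all(ss$convergent[ss$pool != "hum"]))
})

test_that("the deep layer decomposes more slowly than the top layer", {
  top <- soil_layer_params("top", clay_pct = 30, initial_soc = 50)
  deep <- soil_layer_params("deep", clay_pct = 30, initial_soc = 50,
                            depth_cm = 30)
  mods <- list(abc = 1, tsmd = 0)
  st_top <- rothc_init_pools(top); st_deep <- rothc_init_pools(deep)
  for (m in 1:24) {
    st_top <- rothc_step(st_top, 0, 0, top, mods)
    st_deep <- rothc_step(st_deep, 0, 0, deep, mods)
  }
  expect_gt(st_top$cum_co2, st_deep$cum_co2)
  expect_lt(sum(st_top$pools), sum(st_deep$pools))
})

test_that("warming lowers cumulative soil carbon accrual", {
  clim <- constant_climate(10, rain = 90, tmean = 10, pan_evap = 50)
  warm <- clim; warm$tmean <- warm$tmean + 2
  returns <- tibble::tibble(dung_c = rep(0.05, 120), litter_c = 0.1,
                            root_c_top = 0.15, root_c_deep = 0.03)
  p_top <- soil_layer_params("top", clay_pct = 30, initial_soc = 60)
  p_deep <- soil_layer_params("deep", clay_pct = 30, initial_soc = 30)
  r1 <- run_soil_carbon(clim, returns, p_top, p_deep)
  r2 <- run_soil_carbon(warm, returns, p_top, p_deep)
  expect_lt(sum(r2$annual$delta_soc), sum(r1$annual$delta_soc))
})

test_that("with no inputs SOC declines monotonically toward inert carbon", {
  clim <- constant_climate(10)
  zero <- tibble::tibble(dung_c = rep(0, 120), litter_c = 0,
                         root_c_top = 0, root_c_deep = 0)
  r <- run_soil_carbon(clim, zero)
  expect_true(all(diff(r$annual$soc) < 0))
  iom_total <- r$final$top$pools[["iom"]] + r$final$deep$pools[["iom"]]
  expect_true(all(r$annual$soc > iom_total))
})

test_that("annual SOC deltas telescope to the total change", {
  clim <- synth_historical(stanley_site(), 8, seed = 4)
  fy <- purrr::map(unique(clim$year), function(y) {
    carbon_inputs(simulate_farm_year(toy_farm(), clim[clim$year == y, ]),
                  toy_farm())
  })
  returns <- dplyr::bind_rows(fy)
  r <- run_soil_carbon(clim, returns)
  p_top <- soil_layer_params("top"); p_deep <- soil_layer_params("deep")
  soc0 <- p_top$initial_soc + p_deep$initial_soc
  expect_equal(sum(r$annual$delta_soc),
               dplyr::last(r$annual$soc) - soc0, tolerance = 1e-9)
  expect_error(run_soil_carbon(clim, returns[-1, ]),
               class = "grazenet_alignment_error")
})
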