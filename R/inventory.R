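#' 100-year global warming potentials
#'
#' Mass multipliers converting a gas to CO2 equivalents: CH4 = 28,
#' N2O = 265, CO2 = 1.
#'
#' @param ch4,n2o,co2 GWP100 values (> 0).
#' @return A named list of class `gwp_set`.
#' @export
gwp_set <- function(ch4 = 28, n2o = 265, co2 = 1) {
  if (ch4 <= 0 || n2o <= 0 || co2 <= 0) stop_param("GWP values must be > 0")
  structure(list(ch4 = ch4, n2o = n2o, co2 = co2), class = "gwp_set")
}

#' Convert a gas mass to CO2 equivalents
#'
#' @param mass Mass of gas, Mg.
#' @param gas `"ch4"`, `"n2o"`, `"co2"` or `"co2e"` (already converted).
#' @param gwp A [gwp_set()].
#' @return Mass in Mg CO2e.
#' @export
to_co2e <- function(mass, gas, gwp = gwp_set()) {
  factor <- switch(gas,
                   ch4 = gwp$ch4, n2o = gwp$n2o, co2 = gwp$co2, co2e = 1,
                   stop_param(sprintf("unknown gas label '%s'", gas)))
  mass * factor
}

#' Emission factors for the farm inventory
#'
#' Defaults are representative of temperate Australian grazing inventory
#' practice (Tier-2 style enteric factors per unit dry-matter intake;
#' national-inventory style nitrous oxide factors; a hydro-dominated grid
#' electricity factor); all are plain configuration, not asserted values.
#'
#' @param ef_enteric Named vector, kg CH4 per kg DMI by species.
#' @param ef_manure kg CH4 per kg DMI (pasture-deposited manure; low
#'   temperate-grazing factor).
#' @param ef_fert,ef_excreta Direct N2O-N emission factors, kg N2O-N per
#'   kg N applied / excreted.
#' @param frac_leach,ef_leach Fraction of N leached and its N2O-N factor.
#' @param frac_volat,ef_volat Fraction of N volatilised and its N2O-N
#'   factor.
#' @param ef_diesel kg CO2e per L diesel.
#' @param ef_electricity kg CO2e per kWh.
#' @param ef_fert_embedded kg CO2e per kg N fertiliser (manufacture and
#'   urea CO2).
#' @param ef_feed_embedded Mg CO2e per Mg DM purchased feed.
#' @return A list of class `inventory_factors`.
#' @export
inventory_factors <- function(ef_enteric = c(cattle = 0.0214, sheep = 0.0192),
                              ef_manure = 0.0008,
                              ef_fert = 0.010,
                              ef_excreta = 0.004,
                              frac_leach = 0.24, ef_leach = 0.011,
                              frac_volat = 0.20, ef_volat = 0.010,
                              ef_diesel = 2.7,
                              ef_electricity = 0.17,
                              ef_fert_embedded = 3.5,
                              ef_feed_embedded = 0.25) {
  vals <- c(ef_manure, ef_fert, ef_excreta, frac_leach, ef_leach,
            frac_volat, ef_volat, ef_diesel, ef_electricity,
            ef_fert_embedded, ef_feed_embedded, ef_enteric)
  if (any(vals < 0)) stop_param("emission factors must be >= 0")
  for (f in c(frac_leach, frac_volat)) check_fraction(f, "N loss fraction")
  structure(list(ef_enteric = ef_enteric, ef_manure = ef_manure,
                 ef_fert = ef_fert, ef_excreta = ef_excreta,
                 frac_leach = frac_leach, ef_leach = ef_leach,
                 frac_volat = frac_volat, ef_volat = ef_volat,
                 ef_diesel = ef_diesel, ef_electricity = ef_electricity,
                 ef_fert_embedded = ef_fert_embedded,
                 ef_feed_embedded = ef_feed_embedded),
            class = "inventory_factors")
}

#' Enteric methane from dry-matter intake
#'
#' `sum over classes of DMI * EF * (1 - inhibition)`: linear in intake and
#' in one minus the inhibition fraction, so an 80% inhibitor leaves
#' exactly 20% of the uninhibited emission.
#'
#' @param dmi Tibble with columns `species` and `dmi_mg_yr` (Mg DM/yr per
#'   class), e.g. the `dmi` element of a farm-year.
#' @param ef_enteric Named vector of kg CH4 per kg DMI by species.
#' @param inhibition Enteric inhibition fraction in [0, 1].
#' @return Mg CH4/yr.
#' @export
enteric_ch4 <- function(dmi, ef_enteric = c(cattle = 0.0214, sheep = 0.0192),
                        inhibition = 0) {
  check_fraction(inhibition, "inhibition")
  unknown <- setdiff(unique(dmi$species), names(ef_enteric))
  if (length(unknown) > 0) {
    stop_param(sprintf("no enteric emission factor for species: %s",
                       paste(unknown, collapse = ", ")))
  }
  if (any(ef_enteric <= 0)) stop_param("enteric emission factors must be > 0")
  sum(dmi$dmi_mg_yr * ef_enteric[dmi$species]) * (1 - inhibition)
}

#' Manure methane from excreted organic matter
#'
#' Linear factor model on intake as a proxy for volatile solids excreted
#' onto pasture.
#'
#' @param intake_mg Total intake, Mg DM/yr.
#' @param ef_manure kg CH4 per kg DMI (>= 0).
#' @return Mg CH4/yr.
#' @export
manure_ch4 <- function(intake_mg, ef_manure = 0.0008) {
  if (intake_mg < 0 || ef_manure < 0) stop_param("inputs must be >= 0")
  intake_mg * ef_manure
}

#' Direct and indirect nitrous oxide emissions
#'
#' Direct N2O-N is `n_fert * ef_fert + n_excreted * ef_excreta`; indirect
#' N2O-N routes the leached and volatilised fractions of all N streams
#' through their own factors. Both are converted from N2O-N to N2O by the
#' stoichiometric ratio 44/28.
#'
#' @param n_fert N fertiliser applied, kg N/yr.
#' @param n_excreted N excreted by stock, kg N/yr.
#' @param factors An [inventory_factors()].
#' @return Named list `direct` and `indirect`, Mg N2O/yr.
#' @export
n2o_emissions <- function(n_fert, n_excreted, factors = inventory_factors()) {
  if (n_fert < 0 || n_excreted < 0) stop_param("N inputs must be >= 0")
  n_total <- n_fert + n_excreted
  direct_n <- n_fert * factors$ef_fert + n_excreted * factors$ef_excreta
  indirect_n <- n_total * factors$frac_leach * factors$ef_leach +
    n_total * factors$frac_volat * factors$ef_volat
  list(direct = direct_n * N2O_PER_N / 1000,
       indirect = indirect_n * N2O_PER_N / 1000)
}

#' Energy and embedded CO2e
#'
#' Linear sum of use times factor for diesel, electricity, fertiliser
#' manufacture and purchased feed.
#'
#' @param diesel L/yr.
#' @param electricity kWh/yr.
#' @param fert_n kg N/yr.
#' @param feed_mg Mg DM/yr purchased feed.
#' @param factors An [inventory_factors()].
#' @return Named list `energy_co2` (diesel + electricity) and
#'   `embedded_co2e` (fertiliser + feed), Mg CO2e/yr.
#' @export
energy_and_embedded_co2e <- function(diesel, electricity, fert_n, feed_mg,
                                     factors = inventory_factors()) {
  if (any(c(diesel, electricity, fert_n, feed_mg) < 0)) {
    stop_param("use quantities must be >= 0")
  }
  list(energy_co2 = (diesel * factors$ef_diesel +
                       electricity * factors$ef_electricity) / 1000,
       embedded_co2e = (fert_n * factors$ef_fert_embedded) / 1000 +
         feed_mg * factors$ef_feed_embedded)
}

#' Assemble an annual farm emissions inventory
#'
#' Builds gas-by-source line items, converts each to CO2e with the GWP
#' set, and nets gross emissions against soil and tree sequestration
#' (stored as positive removal magnitudes and subtracted, so a year of
#' soil carbon loss enters as a negative removal and adds to net).
#'
#' @param farm_year A [simulate_farm_year()] result.
#' @param factors An [inventory_factors()].
#' @param inhibition Enteric inhibition fraction in [0, 1].
#' @param enteric_scale Extra multiplier on enteric CH4 (e.g. 0.9 for a
#'   10% rumen-modifier reduction), default 1.
#' @param soil_seq Soil sequestration, Mg CO2e/yr (positive = removal;
#'   negative = soil carbon loss).
#' @param tree_seq Tree sequestration, Mg CO2e/yr (positive = removal).
#' @param gwp A [gwp_set()].
#' @return Object of class `emissions_inventory`: list with `items`
#'   (tibble `source`, `gas`, `mass_mg`, `co2e_mg`), `gross_co2e`,
#'   `sequestration` (named soil/trees) and `net_co2e`.
#' @export
assemble_inventory <- function(farm_year,
                               factors = inventory_factors(),
                               inhibition = 0,
                               enteric_scale = 1,
                               soil_seq = 0,
                               tree_seq = 0,
                               gwp = gwp_set()) {
  ann <- farm_year$annual
  ent <- enteric_ch4(ann$dmi, factors$ef_enteric, inhibition) * enteric_scale
  man <- manure_ch4(ann$intake_mg, factors$ef_manure)
  n2o <- n2o_emissions(ann$n_applied_kg, ann$n_excreted_kg, factors)
  fert_share <- if (ann$n_applied_kg + ann$n_excreted_kg > 0) {
    ann$n_applied_kg * factors$ef_fert /
      (ann$n_applied_kg * factors$ef_fert + ann$n_excreted_kg * factors$ef_excreta)
  } else 0
  en <- energy_and_embedded_co2e(ann$diesel, ann$electricity,
                                 ann$n_applied_kg, ann$purchased_feed_mg,
                                 factors)
  items <- tibble::tibble(
    source = c("enteric_ch4", "manure_ch4", "fertiliser_n2o", "excreta_n2o",
               "indirect_n2o", "energy_co2", "embedded_co2e"),
    gas = c("ch4", "ch4", "n2o", "n2o", "n2o", "co2", "co2e"),
    mass_mg = c(ent, man,
                n2o$direct * fert_share, n2o$direct * (1 - fert_share),
                n2o$indirect, en$energy_co2, en$embedded_co2e)
  )
  items$co2e_mg <- purrr::map2_dbl(items$mass_mg, items$gas, to_co2e, gwp = gwp)
  gross <- sum(items$co2e_mg)
  structure(list(items = items,
                 gross_co2e = gross,
                 sequestration = c(soil = soil_seq, trees = tree_seq),
                 net_co2e = gross - soil_seq - tree_seq),
            class = "emissions_inventory")
}

#' Net emissions position over the analysis window
#'
#' Drops the spin-up years, averages annual net emissions over the
#' analysis window, and classifies the result: net-zero when the absolute
#' 20-year mean is within `tolerance`, net-negative below, net-positive
#' above.
#'
#' @param annual_net Numeric vector of annual net emissions, Mg CO2e/yr,
#'   in simulation order.
#' @param spin_up Years discarded for model initialisation (default 6).
#' @param window Averaging window length in years (default 20).
#' @param tolerance Net-zero tolerance on the window mean, Mg CO2e/yr.
#' @param horizon Label carried through to the result.
#' @return Object of class `net_position`: list with `horizon`,
#'   `annual_net` (window years only), `mean_net`, `is_net_zero`,
#'   `is_net_negative`.
#' @export
net_position <- function(annual_net, spin_up = 6, window = 20,
                         tolerance = 1, horizon = "historical") {
  if (length(annual_net) < spin_up + window) {
    abort_grazenet(sprintf(
      "need at least %d annual values (spin_up %d + window %d), got %d",
      spin_up + window, spin_up, window, length(annual_net)),
      "grazenet_coverage_error")
  }
  kept <- annual_net[(spin_up + 1):(spin_up + window)]
  m <- mean(kept)
  structure(list(horizon = horizon, annual_net = kept, mean_net = m,
                 tolerance = tolerance,
                 is_net_zero = abs(m) <= tolerance,
                 is_net_negative = m < -tolerance),
            class = "net_position")
}

#' Emissions intensity with protein-mass allocation
#'
#' Net emissions are allocated between meat and wool by protein mass:
#' `share_i = protein_i * mass_i / sum(protein * mass)`, and intensity is
#' the allocated emissions divided by the product mass. Shares sum to 1
#' and the intensity of a product is invariant to splitting it into
#' sub-lots.
#'
#' @param net_co2e Net emissions, Mg CO2e/yr.
#' @param products Named vector of product masses, Mg/yr (e.g.
#'   `c(meat = 10, wool = 2)`).
#' @param protein Named list/vector of protein mass fractions per product.
#' @return Tibble with `product`, `mass_mg`, `share`, `intensity`
#'   (Mg CO2e per Mg product).
#' @export
emissions_intensity <- function(net_co2e, products,
                                protein = list(meat = 0.18, wool = 0.60)) {
  products <- products[products > 0]
  if (length(products) == 0) {
    abort_grazenet("emissions intensity undefined: all product masses are zero",
                   "grazenet_undefined_error")
  }
  pfrac <- unlist(protein)[names(products)]
  if (any(is.na(pfrac))) {
    stop_param("missing protein fraction for a product")
  }
  pm <- pfrac * products
  share <- pm / sum(pm)
  tibble::tibble(product = names(products),
                 mass_mg = unname(products),
                 share = unname(share),
                 intensity = unname(share * net_co2e / products))
}
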