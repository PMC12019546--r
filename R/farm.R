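#' Define a grazing farm configuration
#'
#' The farm configuration drives the synthetic production generator that
#' stands in for a full pasture/livestock simulator. Livestock energetics
#' are deliberately reduced to (intake demand, product output, a
#' feed-conversion-efficiency multiplier): everything downstream — enteric
#' methane, excreta nitrogen, soil carbon returns, feed costs — depends only
#' on intake, head counts and product masses.
#'
#' @param farm_id Label for the farm.
#' @param grazed_area Grazed area, ha.
#' @param animal_classes Tibble with one row per stock class and columns
#'   `class`, `species` ("cattle" or "sheep"), `head`, `liveweight_kg`,
#'   `dmi_kg_day` (intake demand, kg DM per head per day), `product`
#'   ("meat", "wool" or "none"), `product_kg_head_yr` (annual saleable
#'   output per head: liveweight for meat, greasy fleece for wool),
#'   `n_excretion_kg_yr` (kg N per head per year).
#' @param fertiliser_n Nitrogen fertiliser applied, kg N/ha/yr.
#' @param diesel Diesel use, L/yr.
#' @param electricity Electricity use, kWh/yr.
#' @param purchased_feed_base Purchased feed bought regardless of seasonal
#'   deficit, Mg DM/yr.
#' @param pasture List of pasture growth parameters:
#'   `max_growth` (kg DM/ha/day at optimum), `t_breaks` (4 temperatures
#'   defining the trapezoidal temperature response: below the first and
#'   above the last growth is zero, between the middle two it is maximal),
#'   `water_sens` (water-stress sensitivity; the moisture factor is
#'   `min(1, rain / (water_sens * pan_evap))`), `co2_beta` (CO2 fertilisation
#'   slope: `f_CO2 = 1 + co2_beta * log(co2/350)`), `utilisation` (fraction
#'   of monthly growth grazable), `root_shoot` (root:shoot allocation
#'   ratio), `root_frac_top` / `root_frac_deep` (split of root carbon
#'   between the 0-30 and 30-100 cm layers, summing to <= 1),
#'   `legume_fraction` (swards fraction fixed biologically; informational),
#'   `litter_frac` (fraction of ungrazed herbage shed as litter).
#' @param protein Named list of product protein mass fractions, e.g.
#'   `list(meat = 0.18, wool = 0.60)`, used for emissions allocation.
#' @param fce_multiplier Feed conversion efficiency multiplier (>= 1 means
#'   the same product output is achieved with proportionally less intake).
#' @param production_multiplier Multiplier on product output per head at
#'   unchanged intake (e.g. a growth-promoting feed supplement).
#' @return An object of class `farm_config`.
#' @export
farm_config <- function(farm_id,
                        grazed_area,
                        animal_classes,
                        fertiliser_n = 0,
                        diesel = 0,
                        electricity = 0,
                        purchased_feed_base = 0,
                        pasture = pasture_params(),
                        protein = list(meat = 0.18, wool = 0.60),
                        fce_multiplier = 1,
                        production_multiplier = 1) {
  problems <- character()
  need <- c("class", "species", "head", "liveweight_kg", "dmi_kg_day",
            "product", "product_kg_head_yr", "n_excretion_kg_yr")
  missing <- setdiff(need, names(animal_classes))
  if (length(missing) > 0) {
    problems <- c(problems, sprintf("animal_classes missing column(s): %s",
                                    paste(missing, collapse = ", ")))
  } else {
    if (any(animal_classes$head < 0)) problems <- c(problems, "head < 0")
    if (any(animal_classes$dmi_kg_day < 0)) problems <- c(problems, "dmi_kg_day < 0")
    if (!all(animal_classes$product %in% c("meat", "wool", "none"))) {
      problems <- c(problems, "product must be one of meat/wool/none")
    }
  }
  for (nm in c("grazed_area", "fertiliser_n", "diesel", "electricity",
               "purchased_feed_base")) {
    if (get(nm) < 0) problems <- c(problems, sprintf("%s < 0", nm))
  }
  if (fce_multiplier <= 0) problems <- c(problems, "fce_multiplier <= 0")
  if (production_multiplier < 0) problems <- c(problems, "production_multiplier < 0")
  rf <- pasture$root_frac_top + pasture$root_frac_deep
  if (rf > 1 + 1e-12) problems <- c(problems, "root fractions sum > 1")
  if (pasture$legume_fraction < 0 || pasture$legume_fraction > 1) {
    problems <- c(problems, "legume_fraction outside [0, 1]")
  }
  if (length(problems) > 0) {
    abort_grazenet(paste0("invalid farm config:\n- ",
                          paste(problems, collapse = "\n- ")),
                   "grazenet_validation_error")
  }
  structure(
    list(farm_id = farm_id,
         grazed_area = grazed_area,
         animal_classes = tibble::as_tibble(animal_classes),
         fertiliser_n = fertiliser_n,
         diesel = diesel,
         electricity = electricity,
         purchased_feed_base = purchased_feed_base,
         pasture = pasture,
         protein = protein,
         fce_multiplier = fce_multiplier,
         production_multiplier = production_multiplier),
    class = "farm_config")
}

#' Pasture growth parameters
#'
#' Defaults describe a cool-temperate perennial C3 sward.
#'
#' @inheritParams farm_config
#' @param max_growth,t_breaks,water_sens,co2_beta,utilisation,root_shoot,root_frac_top,root_frac_deep,legume_fraction,litter_frac
#'   See the `pasture` argument of [farm_config()].
#' @return A list of pasture parameters.
#' @export
pasture_params <- function(max_growth = 55,
                           t_breaks = c(3, 12, 22, 32),
                           water_sens = 0.75,
                           co2_beta = 0.06,
                           utilisation = 0.6,
                           root_shoot = 0.45,
                           root_frac_top = 0.7,
                           root_frac_deep = 0.15,
                           legume_fraction = 0.2,
                           litter_frac = 0.4) {
  if (max_growth < 0 || water_sens <= 0 || co2_beta < 0 ||
      root_shoot < 0 || litter_frac < 0 || litter_frac > 1 ||
      utilisation <= 0 || utilisation > 1) {
    stop_param("negative or out-of-range pasture parameter")
  }
  if (length(t_breaks) != 4 || is.unsorted(t_breaks, strictly = TRUE)) {
    stop_param("t_breaks must be 4 strictly increasing temperatures")
  }
  list(max_growth = max_growth, t_breaks = t_breaks, water_sens = water_sens,
       co2_beta = co2_beta, utilisation = utilisation, root_shoot = root_shoot,
       root_frac_top = root_frac_top, root_frac_deep = root_frac_deep,
       legume_fraction = legume_fraction, litter_frac = litter_frac)
}

#' Monthly pasture growth
#'
#' Growth is `max_growth * f_T(tmean) * f_W(rain, pan_evap) * f_CO2(co2) *
#' days`, with a trapezoidal temperature response in [0, 1], water stress
#' `f_W = min(1, rain / (water_sens * pan_evap))`, and CO2 fertilisation
#' `f_CO2 = 1 + co2_beta * log(co2 / 350)` so that 350 ppm gives exactly 1.
#' Elevated CO2 therefore raises growth modestly — a few percent at
#' 530 ppm at the default `co2_beta` values — mirroring the modest pasture
#' response expected in temperate grazing systems.
#'
#' @param tmean Monthly mean temperature, deg C.
#' @param rain Monthly rainfall, mm.
#' @param pan_evap Monthly pan evaporation, mm.
#' @param pasture Pasture parameter list ([pasture_params()]).
#' @param co2_ppm Atmospheric CO2, ppm.
#' @param days Days in the month.
#' @return Growth, kg DM/ha/month (vectorised over the weather inputs).
#' @export
pasture_growth <- function(tmean, rain, pan_evap, pasture = pasture_params(),
                           co2_ppm = 350, days = 30) {
  tb <- pasture$t_breaks
  f_t <- ifelse(tmean <= tb[1] | tmean >= tb[4], 0,
         ifelse(tmean < tb[2], (tmean - tb[1]) / (tb[2] - tb[1]),
         ifelse(tmean <= tb[3], 1, (tb[4] - tmean) / (tb[4] - tb[3]))))
  f_w <- ifelse(pan_evap <= 0, 1,
                pmin(1, rain / (pasture$water_sens * pan_evap)))
  f_co2 <- 1 + pasture$co2_beta * log(co2_ppm / 350)
  pasture$max_growth * f_t * f_w * f_co2 * days
}

#' Simulate one farm-year of pasture and livestock production
#'
#' The monthly feed balance is closed by supplementary feed: demand is
#' `sum(head * dmi / fce_multiplier) * days`, consumed pasture is
#' `min(demand, utilisable growth)`, and supplement makes up any deficit,
#' so `consumed + supplement = demand` whenever demand is positive. Product
#' output scales with head counts and the production multiplier and, by
#' construction of the FCE multiplier, is held fixed as intake falls.
#'
#' @param config A [farm_config()].
#' @param climate_year A climate series tibble with exactly 12 rows (one
#'   year).
#' @param seed Integer seed (reserved; the generator is deterministic).
#' @return An object of class `farm_year`: a list with `monthly` (tibble of
#'   month, days, pasture growth kg DM/ha, grown/available/demand/consumed/
#'   supplement Mg DM) and `annual` (list with meat_mg, wool_mg, intake_mg,
#'   supplement_mg, n_applied_kg, n_excreted_kg, dmi tibble by class).
#' @export
simulate_farm_year <- function(config, climate_year, seed = 1L) {
  if (!inherits(config, "farm_config")) stop_param("`config` must be a farm_config")
  if (nrow(climate_year) != 12) {
    stop_alignment(sprintf("climate_year must have 12 monthly records, got %d",
                           nrow(climate_year)))
  }
  ps <- config$pasture
  days <- DAYS_IN_MONTH[climate_year$month]
  growth <- pasture_growth(climate_year$tmean, climate_year$rain,
                           climate_year$pan_evap, ps,
                           co2_ppm = climate_year$co2_ppm, days = days)
  cls <- config$animal_classes
  dmi_eff <- cls$dmi_kg_day / config$fce_multiplier
  demand_day <- sum(cls$head * dmi_eff) / 1000        # Mg DM/day
  monthly <- tibble::tibble(
    month = climate_year$month,
    days = days,
    pasture_growth = growth,                          # kg DM/ha
    grown = growth * config$grazed_area / 1000,       # Mg DM
    available = grown * ps$utilisation,
    demand = demand_day * days,
    consumed = pmin(demand, available),
    supplement = pmax(0, demand - consumed)
  )
  product_of <- function(kind) {
    sum(cls$head * cls$product_kg_head_yr * (cls$product == kind)) / 1000 *
      config$production_multiplier
  }
  annual <- list(
    meat_mg = product_of("meat"),
    wool_mg = product_of("wool"),
    intake_mg = sum(monthly$demand),
    pasture_consumed_mg = sum(monthly$consumed),
    supplement_mg = sum(monthly$supplement),
    purchased_feed_mg = sum(monthly$supplement) + config$purchased_feed_base,
    n_applied_kg = config$fertiliser_n * config$grazed_area,
    diesel = config$diesel,
    electricity = config$electricity,
    n_excreted_kg = sum(cls$head * cls$n_excretion_kg_yr),
    dmi = tibble::tibble(class = cls$class,
                         species = cls$species,
                         dmi_mg_yr = cls$head * dmi_eff * 365 / 1000,
                         dmi_kg_head_day = dmi_eff)
  )
  structure(list(farm_id = config$farm_id, monthly = monthly, annual = annual),
            class = "farm_year")
}

#' Monthly soil carbon returns from a farm-year
#'
#' Translates the production balance into the carbon inputs the soil model
#' consumes, per hectare of grazed area: dung carbon is
#' `intake * (1 - digestibility) * carbon_fraction`; litter carbon is the
#' ungrazed shoot residue (grown minus consumed, times the litter fraction)
#' times the carbon fraction; root carbon is shoot production times the
#' root:shoot ratio times the carbon fraction, split between depth layers
#' by the configured root fractions.
#'
#' @param year A [simulate_farm_year()] result.
#' @param config The [farm_config()] used to produce it.
#' @param digestibility Diet dry-matter digestibility, fraction in (0, 1).
#' @param carbon_fraction Carbon content of dry matter, fraction in (0, 1).
#' @return Tibble with one row per month: `month`, `dung_c`, `litter_c`,
#'   `root_c_top`, `root_c_deep`, all Mg C/ha/month.
#' @export
carbon_inputs <- function(year, config, digestibility = 0.7,
                          carbon_fraction = 0.4) {
  if (digestibility <= 0 || digestibility > 1) {
    stop_param("`digestibility` must be in (0, 1]")
  }
  if (carbon_fraction <= 0 || carbon_fraction >= 1) {
    stop_param("`carbon_fraction` must be in (0, 1)")
  }
  ps <- config$pasture
  if (ps$root_frac_top + ps$root_frac_deep > 1 + 1e-12) {
    stop_param("root layer fractions sum to > 1")
  }
  area <- config$grazed_area
  m <- year$monthly
  # Intake here includes supplement: dung is excreted on pasture either way.
  tibble::tibble(
    month = m$month,
    dung_c = m$demand * (1 - digestibility) * carbon_fraction / area,
    litter_c = (m$grown - m$consumed) * ps$litter_frac * carbon_fraction / area,
    root_c_top = m$grown / area * ps$root_shoot * carbon_fraction *
      ps$root_frac_top,
    root_c_deep = m$grown / area * ps$root_shoot * carbon_fraction *
      ps$root_frac_deep
  )
}

#' Beef-like fixture farm
#'
#' A self-replacing cow-and-calf enterprise on 569 ha with 367 mature cows
#' plus followers and trade stock, in a high-rainfall cool-temperate zone.
#' Calibrated to printed herd magnitudes without claiming to reproduce any
#' real farm.
#'
#' @return A [farm_config()].
#' @export
beef_farm_config <- function() {
  farm_config(
    farm_id = "beef",
    grazed_area = 569,
    animal_classes = tibble::tribble(
      ~class, ~species, ~head, ~liveweight_kg, ~dmi_kg_day, ~product,
      ~product_kg_head_yr, ~n_excretion_kg_yr,
      "cows",            "cattle", 367, 550, 10.5, "meat", 230, 85,
      "repl_heifers",    "cattle",  74, 380,  7.5, "none",   0, 60,
      "home_steers",     "cattle", 270, 450,  8.5, "meat", 300, 70,
      "trade_steers",    "cattle", 155, 460,  9.0, "meat", 310, 70
    ),
    fertiliser_n = 30,
    diesel = 25000,
    electricity = 40000,
    purchased_feed_base = 50,
    pasture = pasture_params(max_growth = 55, co2_beta = 0.06,
                             root_frac_top = 0.7, root_frac_deep = 0.15),
    protein = list(meat = 0.18, wool = 0.60)
  )
}

#' Sheep-like fixture farm
#'
#' A self-replacing fine-wool and prime-lamb enterprise with a small cattle
#' herd grazing 3170 ha of native and improved pasture in a low-rainfall
#' zone; roughly 24,750 sheep in two flocks. Calibrated to printed flock
#' magnitudes without claiming to reproduce any real farm.
#'
#' @return A [farm_config()].
#' @export
sheep_farm_config <- function() {
  farm_config(
    farm_id = "sheep",
    grazed_area = 3170,
    animal_classes = tibble::tribble(
      ~class, ~species, ~head, ~liveweight_kg, ~dmi_kg_day, ~product,
      ~product_kg_head_yr, ~n_excretion_kg_yr,
      "merino_ewes",  "sheep",  8750, 55, 1.2, "wool", 5.4, 10,
      "wethers",      "sheep",  7500, 50, 1.1, "wool", 5.8, 9,
      "replacements", "sheep",  5550, 40, 0.9, "wool", 4.7, 8,
      "prime_lambs",  "sheep",  2950, 27, 0.8, "meat", 27, 5,
      "cattle",       "cattle",  400, 480, 8.0, "meat", 240, 75
    ),
    fertiliser_n = 8,
    diesel = 40000,
    electricity = 60000,
    purchased_feed_base = 120,
    pasture = pasture_params(max_growth = 26, co2_beta = 0.18,
                             water_sens = 0.8, utilisation = 0.55,
                             root_frac_top = 0.65, root_frac_deep = 0.2,
                             legume_fraction = 0.1),
    protein = list(meat = 0.18, wool = 0.60)
  )
}
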