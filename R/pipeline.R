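#' Run a scenario end to end
#'
#' Orchestrates the full model chain for one scenario and horizon:
#' synthesise (or accept) a historical monthly climate, project it with
#' the horizon's scaling factors, simulate each farm-year, run the
#' two-layer soil carbon model on the resulting carbon returns, accrue
#' tree stand removals, assemble annual emissions inventories, average
#' the net position over the analysis window after discarding the
#' spin-up years, and evaluate the economics including the hybrid carbon
#' account. 26 simulated years with the first 6 discarded is the default
#' cadence. Deterministic for fixed inputs and seed.
#'
#' @param scn A [scenario()].
#' @param horizon `"historical"`, `"2030"` or `"2050"`.
#' @param seed Integer seed driving climate synthesis, projection and the
#'   price Monte Carlo.
#' @param n_years Simulated years (>= spin_up + window).
#' @param spin_up Discarded initialisation years.
#' @param window Analysis window, years.
#' @param n_iter Monte Carlo iterations for the profit distribution.
#' @param scaling Optional [scaling_factors()]; defaults to
#'   [default_scaling_factors()] for the horizon.
#' @param site Optional site statistics for [synth_historical()];
#'   defaults by farm (high-rainfall site for beef, low-rainfall for
#'   sheep).
#' @param climate Optional pre-built historical climate series tibble
#'   (overrides `site`); must cover `n_years` full years.
#' @return Object of class `scenario_result`: list with `label`,
#'   `horizon`, `production` (window means), `profit`
#'   (a `profit_distribution`), `net_position`, `carbon_account`,
#'   `intensity`, `annual` (tibble: year, gross, soil_seq, tree_seq,
#'   net), `adoptability`, `provenance`, `seed`.
#' @export
run_scenario <- function(scn,
                         horizon = c("historical", "2030", "2050"),
                         seed = 1L,
                         n_years = 26, spin_up = 6, window = 20,
                         n_iter = 10000,
                         scaling = NULL, site = NULL, climate = NULL) {
  if (!inherits(scn, "scenario")) stop_param("`scn` must be a scenario")
  horizon <- match.arg(horizon)
  if (n_years < spin_up + window) {
    abort_grazenet(sprintf("n_years (%d) must be >= spin_up + window (%d)",
                           n_years, spin_up + window),
                   "grazenet_coverage_error")
  }
  if (is.null(scaling)) scaling <- default_scaling_factors(horizon)
  if (is.null(climate)) {
    if (is.null(site)) {
      site <- if (scn$farm$farm_id == "sheep") campbell_town_site()
              else stanley_site()
    }
    climate <- synth_historical(site, n_years, seed = derive_seed(seed, 1))
  }
  clim <- apply_scaling(climate, scaling, seed = derive_seed(seed, 2))
  years <- sort(unique(clim$year))
  if (length(years) != n_years) {
    stop_alignment(sprintf("climate covers %d years, expected %d",
                           length(years), n_years))
  }

  farm_years <- purrr::map(years, function(y) {
    simulate_farm_year(scn$farm, clim[clim$year == y, ], seed = seed)
  })
  names(farm_years) <- as.character(years)

  returns <- purrr::map2_dfr(farm_years, years, function(fy, y) {
    ci <- carbon_inputs(fy, scn$farm)
    ci$year <- y
    ci
  })
  soil <- run_soil_carbon(clim, returns, scn$soil$top, scn$soil$deep)
  area <- scn$farm$grazed_area
  soil_seq <- soil$annual$delta_soc * area * CO2_PER_C   # Mg CO2e/yr, +ve accrual

  window_start <- years[spin_up + 1]
  stands <- purrr::map(scn$stands, function(st) {
    tree_stand(species_profile = st$species_profile,
               area = st$area,
               plant_year = st$plant_year %||% window_start,
               max_stock = st$max_stock %||% NULL,
               growth_rate = st$growth_rate %||% NULL,
               perturbation = st$perturbation %||% 1)
  })
  tree_seq <- annual_removals(stands, years)$removal_co2e

  inventories <- purrr::imap(farm_years, function(fy, ynm) {
    y <- match(ynm, as.character(years))
    assemble_inventory(fy, factors = scn$factors,
                       inhibition = scn$inhibition,
                       enteric_scale = scn$enteric_scale,
                       soil_seq = soil_seq[y], tree_seq = tree_seq[y])
  })
  annual <- tibble::tibble(
    year = years,
    gross = purrr::map_dbl(inventories, "gross_co2e"),
    soil_seq = soil_seq,
    tree_seq = tree_seq,
    net = purrr::map_dbl(inventories, "net_co2e"))

  np <- net_position(annual$net, spin_up = spin_up, window = window,
                     horizon = horizon)
  win <- (spin_up + 1):(spin_up + window)
  production <- list(
    meat_mg = mean(purrr::map_dbl(farm_years[win], ~ .x$annual$meat_mg)),
    wool_mg = mean(purrr::map_dbl(farm_years[win], ~ .x$annual$wool_mg)),
    intake_mg = mean(purrr::map_dbl(farm_years[win], ~ .x$annual$intake_mg)),
    purchased_feed_mg = mean(purrr::map_dbl(farm_years[win],
                                            ~ .x$annual$purchased_feed_mg)))
  profit <- monte_carlo_profit(production, scn$prices, scn$econ,
                               n = n_iter, seed = derive_seed(seed, 3))
  account <- carbon_account(np, scn$policy,
                            pre_tax_profit = profit$summary$mean)
  products <- c(meat = production$meat_mg, wool = production$wool_mg)
  intensity <- if (any(products > 0)) {
    emissions_intensity(np$mean_net, products, scn$farm$protein)
  } else NULL

  structure(list(label = scn$label, horizon = horizon,
                 production = production, profit = profit,
                 net_position = np, carbon_account = account,
                 intensity = intensity, annual = annual,
                 adoptability = scn$adoptability,
                 provenance = scn$provenance, seed = seed),
            class = "scenario_result")
}

#' Run a named bundle from the catalog
#'
#' Convenience wrapper: stacks [intervention_catalog()]'s bundle onto the
#' baseline scenario and runs it.
#'
#' @param scn Baseline [scenario()].
#' @param bundle Bundle name (see [intervention_catalog()]).
#' @param horizon `"2030"` or `"2050"` (also selects bundle magnitudes).
#' @param ... Passed to [run_scenario()].
#' @return A `scenario_result`.
#' @export
run_bundle <- function(scn, bundle, horizon = "2030", ...) {
  ivs <- intervention_catalog(bundle, farm = scn$farm$farm_id,
                              horizon = horizon)
  stacked <- stack_interventions(scn, ivs, label = bundle)
  run_scenario(stacked, horizon = horizon, ...)
}

#' Extract comparison metrics from scenario results
#'
#' @param results List of `scenario_result` objects.
#' @return Tibble with columns `scenario`, `horizon`, `production`
#'   (Mg liveweight/yr), `wool` (Mg/yr), `profit` (pre-carbon-tax mean
#'   $/yr), `net` (mean Mg CO2e/yr), `adoptability`.
#' @export
scenario_metrics <- function(results) {
  purrr::map_dfr(results, function(r) {
    tibble::tibble(scenario = r$label, horizon = r$horizon,
                   production = r$production$meat_mg,
                   wool = r$production$wool_mg,
                   profit = r$profit$summary$mean,
                   net = r$net_position$mean_net,
                   adoptability = r$adoptability)
  })
}

#' Compare a set of scenarios on one horizon
#'
#' Produces the per-set normalised impact scores, the marginal abatement
#' cost curve against the named baseline, and a carbon tax / credit
#' ledger table.
#'
#' @param results List of `scenario_result` objects sharing one horizon.
#' @param baseline Label of the baseline result.
#' @return Object of class `scenario_comparison`: list with `scores`
#'   (normalised impact tibble), `macc`, `ledger` (tibble: scenario,
#'   pre-tax profit, mean net, tax, credit income, post-account profit)
#'   and `horizon`.
#' @export
compare_scenarios <- function(results, baseline = "baseline") {
  horizons <- unique(purrr::map_chr(results, "horizon"))
  if (length(horizons) > 1) {
    abort_grazenet(sprintf(
      "scenarios span multiple horizons (%s); compare one horizon at a time",
      paste(horizons, collapse = ", ")),
      "grazenet_grouping_error")
  }
  metrics <- scenario_metrics(results)
  ledger <- purrr::map_dfr(results, function(r) {
    tibble::tibble(scenario = r$label,
                   pre_tax_profit = r$profit$summary$mean,
                   mean_net = r$net_position$mean_net,
                   tax = r$carbon_account$tax,
                   credit_income = r$carbon_account$credit_income,
                   post_account_profit = r$carbon_account$post_account_profit)
  })
  structure(list(scores = normalize_scores(metrics),
                 macc = if (baseline %in% metrics$scenario) {
                   macc(metrics, baseline = baseline)
                 } else NULL,
                 ledger = ledger,
                 horizon = horizons),
            class = "scenario_comparison")
}

#' Solve the tree area that makes a scenario net-zero
#'
#' Bisection on stand area: the non-tree components of the annual net
#' emission series are computed once from a full pipeline run without
#' stands, and each bisection step evaluates the candidate stand's annual
#' removals against that series until the absolute window-mean net
#' emission is within `tol`. Because removals are linear in area the
#' bracket halves cleanly; the solved area is verified with a full
#' end-to-end run.
#'
#' @param scn A [scenario()] (its existing stands are ignored).
#' @param horizon,seed,n_years,spin_up,window As in [run_scenario()].
#' @param species_profile Stand profile; defaults by farm.
#' @param perturbation Sequestration perturbation factor on the candidate
#'   stand (e.g. 1.2 for +20%).
#' @param area_range Bracket for the bisection, ha.
#' @param tol Net-zero tolerance on the window mean, Mg CO2e/yr.
#' @param max_iter Maximum bisection iterations.
#' @return List with `area` (ha), `mean_net` (at the solution),
#'   `iterations`, `converged`, and `result` (the verifying
#'   `scenario_result`).
#' @export
find_net_zero_area <- function(scn, horizon = "2030", seed = 1L,
                               n_years = 26, spin_up = 6, window = 20,
                               species_profile = NULL,
                               perturbation = 1.0,
                               area_range = c(0, 5000),
                               tol = 1, max_iter = 100) {
  if (is.null(species_profile)) {
    species_profile <- if (scn$farm$farm_id == "sheep") {
      "environmental_planting"
    } else "plantation_bluegum"
  }
  base_scn <- scn
  base_scn$stands <- list()
  base <- run_scenario(base_scn, horizon = horizon, seed = seed,
                       n_years = n_years, spin_up = spin_up, window = window,
                       n_iter = 2)
  years <- base$annual$year
  win <- (spin_up + 1):(spin_up + window)
  net_wo_trees <- base$annual$net
  unit_stand <- tree_stand(species_profile, area = 1,
                           plant_year = years[spin_up + 1],
                           perturbation = perturbation)
  unit_removal <- annual_removals(list(unit_stand), years)$removal_co2e
  mean_net_at <- function(a) mean(net_wo_trees[win] - a * unit_removal[win])
  lo <- area_range[1]; hi <- area_range[2]
  f_lo <- mean_net_at(lo); f_hi <- mean_net_at(hi)
  if (f_lo < -tol) {
    abort_grazenet("scenario is already net-negative without trees",
                   "grazenet_bracket_error")
  }
  if (f_hi > tol) {
    abort_grazenet(sprintf(
      "upper area bound %.0f ha cannot reach net-zero (mean net %.1f)",
      hi, f_hi), "grazenet_bracket_error")
  }
  iter <- 0L
  mid <- lo
  f_mid <- f_lo
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    f_mid <- mean_net_at(mid)
    if (abs(f_mid) <= tol) break
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  solved_scn <- scn
  solved_scn$stands <- list(list(species_profile = species_profile,
                                 area = mid, perturbation = perturbation))
  verify <- run_scenario(solved_scn, horizon = horizon, seed = seed,
                         n_years = n_years, spin_up = spin_up,
                         window = window, n_iter = 2)
  list(area = mid, mean_net = verify$net_position$mean_net,
       iterations = iter, converged = abs(f_mid) <= tol, result = verify)
}

#' Read and validate a run configuration file
#'
#' Reads a YAML run configuration and assembles the scenario it
#' describes. Recognised keys: `farm` (`"beef"` or `"sheep"`), `horizon`,
#' `bundles` (list of catalog bundle names), `seed`, `n_iter`,
#' `policy: {tax_rate, credit_price}`, `soil: {top: {...}, deep: {...}}`
#' (passed to [soil_layer_params()]), and `inhibition`. Validation
#' failures name the offending key.
#'
#' @param path Path to a YAML file.
#' @return List with `scenario`, `horizon`, `bundles`, `seed`, `n_iter`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  farm_id <- cfg$farm
  if (is.null(farm_id) || !farm_id %in% c("beef", "sheep")) {
    note("farm: must be 'beef' or 'sheep'")
  }
  horizon <- cfg$horizon %||% "2030"
  if (!horizon %in% c("historical", "2030", "2050")) {
    note("horizon: must be historical, 2030 or 2050")
  }
  bundles <- cfg$bundles %||% list("baseline")
  known <- c("baseline", "LHF", "TCN", "ID", "Asp", "CN1", "CN2", "CN3", "CN4")
  bad <- setdiff(unlist(bundles), known)
  if (length(bad) > 0) {
    note(sprintf("bundles: unknown bundle(s) %s", paste(bad, collapse = ", ")))
  }
  seed <- cfg$seed
  if (is.null(seed)) note("seed: required (no wall-clock seeding)")
  n_iter <- cfg$n_iter %||% 10000
  if (!is.null(cfg$inhibition) &&
      (cfg$inhibition < 0 || cfg$inhibition > 1)) {
    note("inhibition: must be in [0, 1]")
  }
  if (length(problems) > 0) {
    abort_grazenet(paste0("invalid run config:\n- ",
                          paste(problems, collapse = "\n- ")),
                   "grazenet_validation_error")
  }
  farm <- if (farm_id == "beef") beef_farm_config() else sheep_farm_config()
  policy <- if (!is.null(cfg$policy)) {
    carbon_policy(tax_rate = cfg$policy$tax_rate %||% 80,
                  credit_price = cfg$policy$credit_price %||% 28)
  } else carbon_policy()
  soil_args <- function(layer) {
    user <- cfg$soil[[layer]] %||% list()
    do.call(soil_layer_params, c(list(layer = layer), user))
  }
  scn <- scenario(farm,
                  soil_top = soil_args("top"),
                  soil_deep = soil_args("deep"),
                  policy = policy,
                  inhibition = cfg$inhibition %||% 0)
  list(scenario = scn, horizon = horizon, bundles = unlist(bundles),
       seed = as.integer(seed), n_iter = n_iter)
}
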