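#' Build a scenario
#'
#' A scenario bundles everything one pipeline run needs: the farm
#' configuration, the two soil layers, tree stands, inventory factors and
#' enteric inhibition state, the carbon policy, the price model and
#' economic inputs, plus a provenance trail of the interventions applied.
#' The baseline scenario has empty provenance.
#'
#' @param farm A [farm_config()].
#' @param soil_top,soil_deep [soil_layer_params()] for the two layers.
#' @param stands List of stand specs: each a list with `species_profile`,
#'   `area`, `perturbation` and optionally `plant_year` (filled with the
#'   start of the analysis window at run time when absent).
#' @param factors An [inventory_factors()].
#' @param inhibition Enteric CH4 inhibition fraction in [0, 1].
#' @param inhibition_mode How stacked inhibitions compose: `"cap"`
#'   (default; the combined inhibition is the maximum of the stacked
#'   fractions, appropriate when interventions hit the same rumen pathway)
#'   or `"independent"` (`1 - prod(1 - f)`).
#' @param enteric_scale Multiplier on enteric CH4 after inhibition.
#' @param policy A [carbon_policy()].
#' @param prices A [price_model()].
#' @param econ Economic inputs: list with `overheads`, `variable_other`
#'   ($/yr), `capex` ($), `capex_life` (yr, straight-line), `cost_delta`,
#'   `income_delta` ($/yr).
#' @param label Scenario label.
#' @param adoptability Ordinal adoptability score (1-5) of the scenario;
#'   bundles inherit the most limiting (minimum) score of their
#'   interventions.
#' @return An object of class `scenario`.
#' @export
scenario <- function(farm,
                     soil_top = default_soil_params(farm$farm_id, "top"),
                     soil_deep = default_soil_params(farm$farm_id, "deep"),
                     stands = list(),
                     factors = inventory_factors(),
                     inhibition = 0,
                     inhibition_mode = c("cap", "independent"),
                     enteric_scale = 1,
                     policy = carbon_policy(),
                     prices = NULL,
                     econ = list(overheads = 150000, variable_other = 120000,
                                 capex = 0, capex_life = 10,
                                 cost_delta = 0, income_delta = 0),
                     label = "baseline",
                     adoptability = 5) {
  inhibition_mode <- match.arg(inhibition_mode)
  check_fraction(inhibition, "inhibition")
  if (is.null(prices)) prices <- default_price_model(farm$farm_id)
  structure(list(label = label, farm = farm,
                 soil = list(top = soil_top, deep = soil_deep),
                 stands = stands, factors = factors,
                 inhibition = inhibition, inhibition_mode = inhibition_mode,
                 enteric_scale = enteric_scale,
                 policy = policy, prices = prices, econ = econ,
                 adoptability = adoptability,
                 provenance = character(), set_paths = character()),
            class = "scenario")
}

#' Declare an intervention
#'
#' An intervention is a declarative set of parameter modifications plus
#' economic deltas and an adoptability attribute. Modifications address
#' scenario parameters by dotted paths (e.g. `farm.fce_multiplier`,
#' `farm.pasture.max_growth`, `inhibition`) with one of three modes:
#' `multiply`, `add` or `set`. The path `inhibition` is special: `set`
#' values compose across a stack by the scenario's inhibition mode rather
#' than overwriting.
#'
#' @param name Intervention label.
#' @param modifications Tibble (or data frame) with columns `path`,
#'   `mode`, `value`; may be `NULL` for purely economic interventions.
#' @param capex Capital expenditure, $ (depreciated straight-line).
#' @param annual_cost_delta Additional annual cost, $/yr.
#' @param annual_income_delta Additional annual income, $/yr.
#' @param adoptability Ordinal adoptability score 1 (hard) to 5 (easy);
#'   an input attribute, not computed.
#' @param stands List of stand specs to add (see [scenario()]).
#' @param tags Character theme tags.
#' @return An object of class `intervention`.
#' @export
intervention <- function(name, modifications = NULL, capex = 0,
                         annual_cost_delta = 0, annual_income_delta = 0,
                         adoptability = 3, stands = list(),
                         tags = character()) {
  if (is.null(modifications)) {
    modifications <- tibble::tibble(path = character(), mode = character(),
                                    value = numeric())
  }
  modifications <- tibble::as_tibble(modifications)
  stopifnot(all(c("path", "mode", "value") %in% names(modifications)))
  bad <- setdiff(modifications$mode, c("multiply", "add", "set"))
  if (length(bad) > 0) {
    stop_param(sprintf("unknown modification mode(s): %s",
                       paste(bad, collapse = ", ")))
  }
  if (any(modifications$value[modifications$mode == "multiply"] <= 0)) {
    stop_param("multiply modifications must have value > 0")
  }
  if (adoptability < 1 || adoptability > 5) {
    stop_param("adoptability must be an ordinal score in 1..5")
  }
  structure(list(name = name, modifications = modifications, capex = capex,
                 annual_cost_delta = annual_cost_delta,
                 annual_income_delta = annual_income_delta,
                 adoptability = adoptability, stands = stands, tags = tags),
            class = "intervention")
}

scenario_pluck <- function(scn, segments) {
  node <- scn
  for (s in segments) {
    if (!is.list(node) || !s %in% names(node)) return(NULL)
    node <- node[[s]]
  }
  node
}

scenario_poke <- function(scn, segments, value) {
  if (length(segments) == 1) {
    scn[[segments]] <- value
    return(scn)
  }
  scn[[segments[1]]] <- scenario_poke(scn[[segments[1]]], segments[-1], value)
  scn
}

#' Apply an intervention to a scenario
#'
#' Returns a modified copy (the input scenario is never mutated):
#' multiply/add modifications compose arithmetically, `set` overwrites
#' (with a warning recorded in provenance if the path was already set by
#' an earlier intervention), stands are appended, economic deltas
#' accumulate, adoptability takes the most limiting value, and the
#' intervention name is appended to provenance. Enteric inhibition
#' composes by the scenario's inhibition mode and never exceeds 1.
#'
#' @param scn A [scenario()].
#' @param iv An [intervention()].
#' @return The modified scenario.
#' @export
apply_intervention <- function(scn, iv) {
  if (!inherits(scn, "scenario")) stop_param("`scn` must be a scenario")
  if (!inherits(iv, "intervention")) stop_param("`iv` must be an intervention")
  out <- scn
  for (i in seq_len(nrow(iv$modifications))) {
    path <- iv$modifications$path[i]
    mode <- iv$modifications$mode[i]
    value <- iv$modifications$value[i]
    segments <- strsplit(path, ".", fixed = TRUE)[[1]]
    current <- scenario_pluck(out, segments)
    if (is.null(current)) {
      abort_grazenet(sprintf("intervention '%s': path '%s' does not resolve",
                             iv$name, path),
                     "grazenet_path_error")
    }
    if (path == "inhibition" && mode == "set") {
      new <- combine_inhibition(current, value, out$inhibition_mode)
    } else if (mode == "multiply") {
      new <- current * value
    } else if (mode == "add") {
      new <- current + value
    } else {
      if (path %in% out$set_paths) {
        out$provenance <- c(out$provenance,
                            sprintf("warning: '%s' re-set path '%s'",
                                    iv$name, path))
      }
      out$set_paths <- c(out$set_paths, path)
      new <- value
    }
    out <- scenario_poke(out, segments, new)
  }
  for (st in iv$stands) out$stands <- c(out$stands, list(st))
  out$econ$capex <- out$econ$capex + iv$capex
  out$econ$cost_delta <- out$econ$cost_delta + iv$annual_cost_delta
  out$econ$income_delta <- out$econ$income_delta + iv$annual_income_delta
  out$adoptability <- min(out$adoptability, iv$adoptability)
  out$provenance <- c(out$provenance, iv$name)
  out
}

combine_inhibition <- function(current, value, mode) {
  check_fraction(value, "inhibition")
  combined <- if (mode == "independent") 1 - (1 - current) * (1 - value)
              else max(current, value)
  min(combined, 1)
}

#' Stack interventions onto a scenario
#'
#' Left-fold of [apply_intervention()]. Multiplicative modifications
#' commute; `set`-mode modifications are order-sensitive, and two
#' interventions that `set` the same path (other than `inhibition`, which
#' composes by the inhibition rule) to different values raise a
#' composition error unless `allow_conflicts = TRUE`.
#'
#' @param scn A [scenario()].
#' @param interventions Ordered list of [intervention()] objects.
#' @param allow_conflicts Permit conflicting `set` modifications (later
#'   wins, recorded in provenance).
#' @param label Optional label for the stacked scenario.
#' @return The stacked scenario.
#' @export
stack_interventions <- function(scn, interventions, allow_conflicts = FALSE,
                                label = NULL) {
  sets <- purrr::map_dfr(interventions, function(iv) {
    dplyr::filter(iv$modifications, .data$mode == "set",
                  .data$path != "inhibition")
  })
  if (!allow_conflicts && nrow(sets) > 0) {
    dup <- sets |>
      dplyr::group_by(.data$path) |>
      dplyr::summarise(n_distinct = dplyr::n_distinct(.data$value),
                       .groups = "drop") |>
      dplyr::filter(.data$n_distinct > 1)
    if (nrow(dup) > 0) {
      abort_grazenet(sprintf(
        "conflicting set-mode modifications on path(s): %s",
        paste(dup$path, collapse = ", ")),
        "grazenet_composition_error")
    }
  }
  out <- purrr::reduce(interventions, apply_intervention, .init = scn)
  if (!is.null(label)) out$label <- label
  out
}

# ---- Shipped intervention definitions (Table-1-style catalog) -------------

iv_asparagopsis <- function(farm) {
  intervention("Asp",
               modifications = tibble::tibble(path = "inhibition",
                                              mode = "set", value = 0.80),
               annual_cost_delta = if (farm == "beef") 30000 else 70000,
               adoptability = 2, tags = "methane")
}

iv_vaccine <- function(farm) {
  intervention("CH4 vac",
               modifications = tibble::tibble(path = "inhibition",
                                              mode = "set", value = 0.30),
               annual_cost_delta = if (farm == "beef") 13000 else 50000,
               adoptability = 3, tags = "methane")
}

iv_fce <- function(horizon) {
  mult <- if (horizon == "2050") 1.15 else 1.10
  intervention("FCE",
               modifications = tibble::tibble(path = "farm.fce_multiplier",
                                              mode = "multiply", value = mult),
               annual_cost_delta = 5000, adoptability = 4, tags = "efficiency")
}

iv_tfce <- function(horizon) {
  mult <- if (horizon == "2050") 1.30 else 1.20
  intervention("TFCE",
               modifications = tibble::tibble(path = "farm.fce_multiplier",
                                              mode = "multiply", value = mult),
               annual_cost_delta = 15000, adoptability = 2, tags = "efficiency")
}

iv_biochar <- function(farm) {
  mods <- tibble::tibble(path = "enteric_scale", mode = "multiply", value = 0.90)
  if (farm == "beef") {
    mods <- dplyr::bind_rows(
      mods,
      tibble::tibble(path = "farm.production_multiplier",
                     mode = "multiply", value = 1.05))
  }
  intervention("Biochar", modifications = mods,
               annual_cost_delta = if (farm == "beef") 12000 else 25000,
               adoptability = 3, tags = "methane")
}

iv_trees <- function(farm, area, include_land = FALSE) {
  profile <- if (farm == "beef") "plantation_bluegum" else "environmental_planting"
  establish_cost <- if (farm == "beef") 3000 else 2200   # $/ha
  land_cost <- if (include_land) 12000 * area else 0     # $ for purchased land
  intervention(sprintf("Trees %g ha", area),
               stands = list(list(species_profile = profile, area = area,
                                  perturbation = 1.0)),
               capex = establish_cost * area + land_cost,
               adoptability = 3, tags = "sequestration")
}

iv_lucerne <- function(farm) {
  intervention("Lucerne",
               modifications = tibble::tribble(
                 ~path, ~mode, ~value,
                 "farm.pasture.root_frac_deep", "add", 0.05,
                 "farm.pasture.root_frac_top", "add", -0.05,
                 "farm.pasture.legume_fraction", "set", 0.35,
                 "farm.pasture.max_growth", "multiply", 1.05),
               capex = if (farm == "beef") 60000 else 180000,
               adoptability = 4, tags = "pasture")
}

iv_root_depth <- function() {
  intervention("Deep-Root",
               modifications = tibble::tribble(
                 ~path, ~mode, ~value,
                 "farm.pasture.root_frac_deep", "add", 0.03,
                 "farm.pasture.root_frac_top", "add", -0.03,
                 "farm.pasture.water_sens", "multiply", 0.95),
               adoptability = 4, tags = "pasture")
}

iv_soil_fertility <- function() {
  intervention("Soil fertility",
               modifications = tibble::tibble(path = "farm.pasture.max_growth",
                                              mode = "multiply", value = 1.03),
               annual_cost_delta = 8000, adoptability = 5, tags = "pasture")
}

iv_graze_management <- function() {
  intervention("Graze timing",
               modifications = tibble::tibble(
                 path = "farm.production_multiplier",
                 mode = "multiply", value = 1.02),
               adoptability = 5, tags = "management")
}

iv_wind_lease <- function() {
  intervention("Wind lease", annual_income_delta = 96000,
               adoptability = 3, tags = "income")
}

iv_grapes <- function() {
  intervention("Grapes", capex = 450000, annual_income_delta = 90000,
               annual_cost_delta = 35000, adoptability = 2, tags = "income")
}

iv_land_purchase <- function() {
  intervention("Land purchase", capex = 1800000, annual_income_delta = 160000,
               annual_cost_delta = 60000, adoptability = 2, tags = "income")
}

#' Catalog of intervention bundles
#'
#' Returns the ordered intervention list for a named bundle: `baseline`
#' (empty), `LHF` (low-hanging fruit: management timing, deeper-rooted
#' pasture, soil fertility, 10-15% FCE), `TCN` (LHF plus the CH4 vaccine,
#' lucerne renovation and tree planting: 50 ha plantation on the beef
#' farm, 200 ha environmental planting on the sheep farm), `ID` (income
#' diversification: wind lease plus land purchase for the beef farm or
#' grapes for the sheep farm, encoded as economic deltas), `Asp`
#' (seaweed feed supplement, 80% enteric inhibition), and the four
#' carbon-neutral packages: `CN1` = Asp + transformational FCE + trees
#' (50 ha beef / 200 ha sheep), `CN2` = Asp + transformational FCE +
#' trees (55 ha at 2030 and 110 ha at 2050 for beef / 220 ha sheep),
#' `CN3` = Asp + lucerne + trees (50 / 200 ha), `CN4` = Asp + lucerne +
#' trees (55-110 / 220 ha).
#'
#' @param theme Bundle name (see above).
#' @param farm `"beef"` or `"sheep"`.
#' @param horizon `"2030"` or `"2050"` (drives FCE magnitudes and the CN2
#'   / CN4 beef tree area).
#' @return Ordered list of [intervention()] objects.
#' @export
intervention_catalog <- function(theme, farm = c("beef", "sheep"),
                                 horizon = c("2030", "2050")) {
  farm <- match.arg(farm)
  horizon <- match.arg(horizon)
  themes <- c("baseline", "LHF", "TCN", "ID", "Asp",
              "CN1", "CN2", "CN3", "CN4")
  if (!theme %in% themes) {
    stop_param(sprintf("unknown theme '%s'; valid themes: %s",
                       theme, paste(themes, collapse = ", ")))
  }
  area_small <- if (farm == "beef") 50 else 200
  area_large <- if (farm == "beef") {
    if (horizon == "2050") 110 else 55
  } else 220
  switch(theme,
    baseline = list(),
    LHF = list(iv_graze_management(), iv_root_depth(), iv_soil_fertility(),
               iv_fce(horizon)),
    TCN = c(list(iv_graze_management(), iv_root_depth(), iv_soil_fertility(),
                 iv_fce(horizon)),
            list(iv_vaccine(farm), iv_lucerne(farm),
                 iv_trees(farm, area_small, include_land = farm == "beef"))),
    ID = if (farm == "beef") list(iv_wind_lease(), iv_land_purchase())
         else list(iv_wind_lease(), iv_grapes()),
    Asp = list(iv_asparagopsis(farm)),
    CN1 = list(iv_asparagopsis(farm), iv_tfce(horizon),
               iv_trees(farm, area_small, include_land = farm == "beef")),
    CN2 = list(iv_asparagopsis(farm), iv_tfce(horizon),
               iv_trees(farm, area_large, include_land = farm == "beef")),
    CN3 = list(iv_asparagopsis(farm), iv_lucerne(farm),
               iv_trees(farm, area_small, include_land = farm == "beef")),
    CN4 = list(iv_asparagopsis(farm), iv_lucerne(farm),
               iv_trees(farm, area_large, include_land = farm == "beef")))
}
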