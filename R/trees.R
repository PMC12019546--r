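#' Define a planted tree stand
#'
#' Stand biomass carbon follows a single-parameter saturating curve,
#' `stock(age) = perturbation * max_stock * (1 - exp(-growth_rate * age))`,
#' so annual increments diminish as the stand matures and sequestration
#' plateaus — the longitudinal behaviour expected of unharvested plantings.
#' The two shipped species profiles are illustrative calibrations for
#' temperate plantings (a fast plantation eucalypt and a slower mixed
#' environmental planting), not the output of a full carbon accounting
#' model. Only above- and below-ground biomass is counted; soil carbon
#' beneath trees is out of scope.
#'
#' @param species_profile `"plantation_bluegum"` or
#'   `"environmental_planting"`; sets defaults for `max_stock` and
#'   `growth_rate`.
#' @param area Stand area, ha (>= 0).
#' @param plant_year Calendar year of planting.
#' @param max_stock Biomass carbon at maturity, Mg C/ha (> 0).
#' @param growth_rate Approach rate to maturity, per year (> 0).
#' @param perturbation Multiplicative factor on all increments; the
#'   sensitivity envelope is [0.8, 1.2] (+/- 20%).
#' @return An object of class `tree_stand`.
#' @export
tree_stand <- function(species_profile = c("plantation_bluegum",
                                           "environmental_planting"),
                       area,
                       plant_year,
                       max_stock = NULL,
                       growth_rate = NULL,
                       perturbation = 1.0) {
  species_profile <- match.arg(species_profile)
  defaults <- switch(species_profile,
                     plantation_bluegum = list(max_stock = 180, growth_rate = 0.07),
                     environmental_planting = list(max_stock = 110, growth_rate = 0.05))
  if (is.null(max_stock)) max_stock <- defaults$max_stock
  if (is.null(growth_rate)) growth_rate <- defaults$growth_rate
  check_number(area, "area", min = 0)
  if (max_stock <= 0) stop_param("max_stock must be > 0")
  if (growth_rate <= 0) stop_param("growth_rate must be > 0")
  check_number(perturbation, "perturbation", min = 0.8, max = 1.2)
  structure(list(species_profile = species_profile, area = area,
                 plant_year = plant_year, max_stock = max_stock,
                 growth_rate = growth_rate, perturbation = perturbation),
            class = "tree_stand")
}

#' Biomass carbon stock of a stand at a given age
#'
#' @param age Stand age in years (>= 0); vectorised.
#' @param stand A [tree_stand()].
#' @return Stock, Mg C/ha.
#' @export
stand_stock <- function(age, stand) {
  if (any(age < 0)) stop_param("`age` must be >= 0")
  stand$perturbation * stand$max_stock * (1 - exp(-stand$growth_rate * age))
}

#' Annual CO2 removals of a set of tree stands
#'
#' For each calendar year, the removal is the sum over stands of
#' `area * (stock(age) - stock(age - 1)) * 44/12`, reported as a positive
#' removal magnitude in Mg CO2e/yr; a stand contributes nothing before its
#' planting year (age 1 is reached at the end of the planting year).
#'
#' @param stands A list of [tree_stand()] objects (possibly empty).
#' @param years Integer vector of calendar years.
#' @return Tibble with columns `year` and `removal_co2e` (Mg CO2e/yr).
#' @export
annual_removals <- function(stands, years) {
  removal <- numeric(length(years))
  for (stand in stands) {
    age <- years - stand$plant_year + 1
    inc <- ifelse(age >= 1,
                  stand_stock(pmax(age, 0), stand) -
                    stand_stock(pmax(age - 1, 0), stand),
                  0)
    removal <- removal + stand$area * inc * CO2_PER_C
  }
  tibble::tibble(year = years, removal_co2e = removal)
}

#' Perturb a stand's sequestration rate
#'
#' Scales the stand's perturbation factor by `(1 + factor)`; every annual
#' removal then scales linearly by the same amount. The admissible range
#' of `factor` is the +/- 20% sensitivity envelope.
#'
#' @param stand A [tree_stand()].
#' @param factor Relative change in [-0.2, 0.2].
#' @return A modified copy of the stand.
#' @export
perturb_stand <- function(stand, factor) {
  check_number(factor, "factor", min = -0.2, max = 0.2)
  out <- stand
  out$perturbation <- stand$perturbation * (1 + factor)
  out
}
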