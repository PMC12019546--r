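#' Soil layer parameters for the RothC turnover model
#'
#' Five-pool soil organic carbon turnover (DPM, RPM, BIO, HUM, IOM) is run
#' per depth layer with layer-specific decomposition rate constants. The
#' default constants are 10, 0.17, 0.66 and 0.02 per year for DPM, RPM,
#' BIO and HUM in the 0-30 cm layer and 0.33, 0.01, 0.02 and 0.00 in the
#' 30-100 cm layer; the zero deep-layer HUM rate makes deep humus inert.
#' Initial pools put 1% of initial SOC in DPM and 2.2% in microbial
#' biomass (fast 2% plus slow 0.2%, carried as a single BIO pool); the
#' remainder after subtracting inert carbon is split between RPM and HUM
#' by `rpm_frac_rem`, a stand-in for regional pool-fraction data.
#'
#' @param layer `"top"` (0-30 cm) or `"deep"` (30-100 cm); sets defaults
#'   for `k` and `depth_cm`.
#' @param clay_pct Clay content, percent.
#' @param initial_soc Initial soil organic carbon stock, Mg C/ha.
#' @param iom Inert organic matter, Mg C/ha; constant over time.
#' @param depth_cm Layer thickness, cm; scales the maximum topsoil
#'   moisture deficit (defined for a 23 cm reference layer).
#' @param k Decomposition rate constants per year, named or ordered
#'   (DPM, RPM, BIO, HUM).
#' @param dpm_rpm_ratio DPM:RPM partition of incoming fresh plant carbon
#'   (1.44 is the conventional value for grassland).
#' @param init_dpm_frac,init_bio_frac Initial DPM and BIO pools as
#'   fractions of initial SOC (defaults 0.01 and 0.022).
#' @param rpm_frac_rem Fraction of the non-inert remainder allocated to RPM
#'   at initialisation (rest goes to HUM).
#' @param dung_split Partition of incoming dung carbon over
#'   (DPM, RPM, HUM); the default 0.49/0.49/0.02 reflects partially
#'   stabilised manure (fresh plant carbon receives no direct HUM share).
#' @return An object of class `soil_layer_params`.
#' @export
soil_layer_params <- function(layer = c("top", "deep"),
                              clay_pct = 30,
                              initial_soc = 80,
                              iom = NULL,
                              depth_cm = NULL,
                              k = NULL,
                              dpm_rpm_ratio = 1.44,
                              init_dpm_frac = 0.01,
                              init_bio_frac = 0.022,
                              rpm_frac_rem = 0.12,
                              dung_split = c(dpm = 0.49, rpm = 0.49, hum = 0.02)) {
  layer <- match.arg(layer)
  if (is.null(depth_cm)) depth_cm <- if (layer == "top") 30 else 70
  if (is.null(k)) {
    k <- if (layer == "top") c(dpm = 10, rpm = 0.17, bio = 0.66, hum = 0.02)
         else c(dpm = 0.33, rpm = 0.01, bio = 0.02, hum = 0.00)
  }
  k <- stats::setNames(as.numeric(k), c("dpm", "rpm", "bio", "hum"))
  if (any(k < 0)) stop_param("decomposition rate constants must be >= 0")
  # Inert carbon defaults to the empirical power-law of total SOC.
  if (is.null(iom)) iom <- 0.049 * initial_soc^1.139
  check_number(clay_pct, "clay_pct", min = 0, max = 100)
  if (!(initial_soc > iom && iom >= 0)) {
    stop_param("need initial_soc > iom >= 0")
  }
  if (init_dpm_frac + init_bio_frac > 1) {
    stop_param("initial pool fractions sum to > 1")
  }
  if (abs(sum(dung_split) - 1) > 1e-9 || any(dung_split < 0)) {
    stop_param("dung_split must be non-negative and sum to 1")
  }
  check_fraction(rpm_frac_rem, "rpm_frac_rem")
  structure(
    list(layer = layer, clay_pct = clay_pct, depth_cm = depth_cm, k = k,
         dpm_rpm_ratio = dpm_rpm_ratio, initial_soc = initial_soc, iom = iom,
         init_dpm_frac = init_dpm_frac, init_bio_frac = init_bio_frac,
         rpm_frac_rem = rpm_frac_rem,
         dung_split = stats::setNames(as.numeric(dung_split),
                                      c("dpm", "rpm", "hum"))),
    class = "soil_layer_params")
}

#' Default soil layer parameters for the fixture farms
#'
#' Clay-rich, carbon-rich profiles for the high-rainfall beef farm
#' (ferrosol-like: 35% clay, 110 and 55 Mg C/ha in the two layers) and
#' lighter, drier-country profiles for the sheep farm (25% clay, 60 and
#' 30 Mg C/ha). Stocks sit near the turnover equilibrium implied by the
#' fixture farms' carbon returns, so baseline soil carbon drifts only
#' slowly — net emissions are then dominated by enteric methane, as in
#' temperate grazing inventories.
#'
#' @param farm_id `"beef"` or `"sheep"` (anything else gets the generic
#'   [soil_layer_params()] defaults).
#' @param layer `"top"` or `"deep"`.
#' @return A [soil_layer_params()].
#' @export
default_soil_params <- function(farm_id, layer = c("top", "deep")) {
  layer <- match.arg(layer)
  if (identical(farm_id, "beef")) {
    if (layer == "top") soil_layer_params("top", clay_pct = 35, initial_soc = 110)
    else soil_layer_params("deep", clay_pct = 35, initial_soc = 55)
  } else if (identical(farm_id, "sheep")) {
    if (layer == "top") soil_layer_params("top", clay_pct = 25, initial_soc = 60)
    else soil_layer_params("deep", clay_pct = 25, initial_soc = 30)
  } else {
    soil_layer_params(layer)
  }
}

#' Initialise RothC pools from an initial SOC stock
#'
#' @param params A [soil_layer_params()].
#' @return A soil carbon state: list with `pools` (named vector dpm, rpm,
#'   bio, hum, iom, Mg C/ha), `tsmd` (accumulated topsoil moisture
#'   deficit, mm, <= 0) and `cum_co2` (cumulative respired C, Mg C/ha).
#'   Pools sum exactly to `initial_soc`.
#' @export
rothc_init_pools <- function(params) {
  soc <- params$initial_soc
  dpm <- params$init_dpm_frac * soc
  bio <- params$init_bio_frac * soc
  rem <- soc - params$iom - dpm - bio
  if (rem < 0) stop_param("initial fractions plus IOM exceed initial SOC")
  rpm <- rem * params$rpm_frac_rem
  hum <- rem - rpm
  list(pools = c(dpm = dpm, rpm = rpm, bio = bio, hum = hum, iom = params$iom),
       tsmd = 0, cum_co2 = 0)
}

#' RothC climate rate modifiers for one month
#'
#' Computes the multiplicative decomposition rate modifiers: temperature
#' `a = 47.91 / (1 + exp(106.06 / (tmean + 18.27)))`; moisture `b`,
#' piecewise linear in the accumulated topsoil moisture deficit between 1
#' (wetter than 0.444 of the maximum deficit) and 0.2 (at the maximum
#' deficit `-(20 + 1.3 clay - 0.01 clay^2) * depth / 23` mm); and soil
#' cover `c = 0.6` under growing vegetation, 1.0 for bare soil. The
#' deficit is first updated by `rain - 0.75 * pan_evap` (open-pan
#' correction) and clamped to `[max_tsmd, 0]`.
#'
#' @param tmean Monthly mean air temperature, deg C (> -18.27).
#' @param rain Monthly rainfall, mm.
#' @param pan_evap Monthly pan evaporation, mm.
#' @param params A [soil_layer_params()] (clay and depth are used).
#' @param tsmd Accumulated moisture deficit carried from last month, mm
#'   (<= 0).
#' @param soil_covered Logical; grazed pasture is treated as covered.
#' @return List with `a`, `b`, `c`, `abc` and the updated `tsmd`.
#' @export
rothc_rate_modifiers <- function(tmean, rain, pan_evap, params,
                                 tsmd = 0, soil_covered = TRUE) {
  if (tmean <= -18.27) {
    abort_grazenet(
      sprintf("temperature modifier undefined at tmean = %.2f (needs > -18.27)",
              tmean),
      "grazenet_domain_error")
  }
  a <- 47.91 / (1 + exp(106.06 / (tmean + 18.27)))
  max_tsmd <- -(20 + 1.3 * params$clay_pct - 0.01 * params$clay_pct^2) *
    params$depth_cm / 23
  tsmd_new <- min(0, max(max_tsmd, tsmd + rain - 0.75 * pan_evap))
  wet_break <- 0.444 * max_tsmd
  b <- if (tsmd_new >= wet_break) 1
       else 0.2 + 0.8 * (max_tsmd - tsmd_new) / (max_tsmd - wet_break)
  c_mod <- if (soil_covered) 0.6 else 1.0
  list(a = a, b = b, c = c_mod, abc = a * b * c_mod, tsmd = tsmd_new)
}

# Clay-dependent CO2 : (BIO + HUM) partition ratio of decomposed carbon.
rothc_co2_ratio <- function(clay_pct) {
  1.67 * (1.85 + 1.60 * exp(-0.0786 * clay_pct))
}

#' Advance a soil carbon state by one month
#'
#' Each active pool P decomposes by `P * (1 - exp(-k * a * b * c / 12))`.
#' Decomposed carbon splits between respired CO2 and (BIO + HUM) in the
#' ratio `x : 1` with `x = 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay))`;
#' the retained share partitions 46% to BIO and 54% to HUM. Fresh plant
#' carbon enters DPM and RPM in the configured DPM:RPM ratio; dung carbon
#' enters by its own more-humified split; IOM never changes. Carbon is
#' conserved exactly: the change in total pools equals inputs minus the
#' CO2 increment.
#'
#' @param state A soil carbon state (see [rothc_init_pools()]).
#' @param plant_c Fresh plant carbon input this month, Mg C/ha.
#' @param dung_c Dung carbon input this month, Mg C/ha.
#' @param params A [soil_layer_params()].
#' @param modifiers Rate modifiers from [rothc_rate_modifiers()].
#' @return The updated state (with `tsmd` from `modifiers`).
#' @export
rothc_step <- function(state, plant_c, dung_c, params, modifiers) {
  if (plant_c < 0 || dung_c < 0) stop_param("carbon inputs must be >= 0")
  p <- state$pools
  active <- c("dpm", "rpm", "bio", "hum")
  decomposed <- p[active] * (1 - exp(-params$k[active] * modifiers$abc / 12))
  p[active] <- p[active] - decomposed
  x <- rothc_co2_ratio(params$clay_pct)
  total_dec <- sum(decomposed)
  co2 <- total_dec * x / (x + 1)
  retained <- total_dec / (x + 1)
  p["bio"] <- p["bio"] + retained * 0.46
  p["hum"] <- p["hum"] + retained * 0.54
  r <- params$dpm_rpm_ratio
  p["dpm"] <- p["dpm"] + plant_c * r / (1 + r)
  p["rpm"] <- p["rpm"] + plant_c * 1 / (1 + r)
  p["dpm"] <- p["dpm"] + dung_c * params$dung_split["dpm"]
  p["rpm"] <- p["rpm"] + dung_c * params$dung_split["rpm"]
  p["hum"] <- p["hum"] + dung_c * params$dung_split["hum"]
  if (any(p < -1e-12)) {
    abort_grazenet("internal invariant violated: negative pool after update",
                   "grazenet_internal_error")
  }
  list(pools = p, tsmd = modifiers$tsmd, cum_co2 = state$cum_co2 + co2)
}

#' Closed-form steady state of the monthly RothC update
#'
#' Under constant carbon inputs and constant rate modifiers the monthly
#' update is linear, `pools' = A pools + u`, and its fixed point is
#' `(I - A)^-1 u`, solved here over the pools with a positive effective
#' decomposition rate. A pool whose effective rate `k * a * b * c` is zero
#' but which receives a positive monthly inflow grows without bound and is
#' reported as non-convergent rather than given a number.
#'
#' @inheritParams rothc_step
#' @return Tibble with columns `pool`, `steady_state` (Mg C/ha; `NA` for a
#'   non-convergent pool) and `convergent`.
#' @export
rothc_steady_state <- function(plant_c, dung_c, params, modifiers) {
  active <- c("dpm", "rpm", "bio", "hum")
  f <- exp(-params$k[active] * modifiers$abc / 12)     # retained fraction
  x <- rothc_co2_ratio(params$clay_pct)
  bh <- 1 / (x + 1)
  r <- params$dpm_rpm_ratio
  u <- c(dpm = plant_c * r / (1 + r) + dung_c * params$dung_split[["dpm"]],
         rpm = plant_c / (1 + r) + dung_c * params$dung_split[["rpm"]],
         bio = 0,
         hum = dung_c * params$dung_split[["hum"]])
  A <- diag(f)
  rownames(A) <- colnames(A) <- active
  A["bio", ] <- A["bio", ] + (1 - f) * bh * 0.46
  A["hum", ] <- A["hum", ] + (1 - f) * bh * 0.54
  live <- params$k[active] * modifiers$abc > 0
  ss <- stats::setNames(rep(NA_real_, 4), active)
  conv <- stats::setNames(rep(TRUE, 4), active)
  if (any(live)) {
    x_live <- solve(diag(sum(live)) - A[live, live, drop = FALSE], u[live])
    ss[live] <- x_live
  }
  if (any(!live)) {
    for (pool in active[!live]) {
      # inert pool: steady only if its net monthly inflow (direct input plus
      # transfers from the live pools at their fixed point) is zero
      inflow <- u[[pool]]
      if (any(live)) {
        inflow <- inflow + sum(A[pool, live, drop = TRUE] * ss[live])
      }
      if (inflow > 1e-15) {
        conv[pool] <- FALSE
      } else {
        ss[pool] <- 0
      }
    }
  }
  tibble::tibble(pool = active, steady_state = unname(ss),
                 convergent = unname(conv))
}

#' Run the soil carbon model over a monthly climate and input series
#'
#' Steps the two depth layers independently with their own rate constants
#' and moisture budgets: the top layer receives litter, dung and topsoil
#' root carbon; the deep layer receives deep root carbon only. Warmer
#' climates raise the temperature rate modifier and therefore respiration,
#' reducing accrual.
#'
#' @param climate A climate series tibble (monthly).
#' @param returns A tibble aligned with `climate` holding monthly carbon
#'   inputs per ha: `dung_c`, `litter_c`, `root_c_top`, `root_c_deep`
#'   (e.g. [carbon_inputs()] stacked over years).
#' @param params_top,params_deep [soil_layer_params()] for the two layers.
#' @param soil_covered Logical; passed to the cover rate modifier.
#' @return Object of class `soil_carbon_run`: list with `annual` (tibble
#'   `year`, `delta_soc` Mg C/ha/yr summed over layers, `soc` end-of-year
#'   stock), `pools` (tibble `year`, `month`, `layer`, pool columns) and
#'   `final` (final states per layer).
#' @export
run_soil_carbon <- function(climate, returns,
                            params_top = soil_layer_params("top"),
                            params_deep = soil_layer_params("deep"),
                            soil_covered = TRUE) {
  n <- nrow(climate)
  if (nrow(returns) != n) {
    stop_alignment(sprintf(
      "climate (%d months) and carbon returns (%d months) differ in length",
      n, nrow(returns)))
  }
  layers <- list(top = params_top, deep = params_deep)
  states <- lapply(layers, rothc_init_pools)
  pool_names <- c("dpm", "rpm", "bio", "hum", "iom")
  rec <- matrix(NA_real_, nrow = 2L * n, ncol = 5L,
                dimnames = list(NULL, pool_names))
  soc_series <- numeric(n)
  for (i in seq_len(n)) {
    for (li in seq_along(layers)) {
      ln <- names(layers)[li]
      prm <- layers[[li]]
      mods <- rothc_rate_modifiers(climate$tmean[i], climate$rain[i],
                                   climate$pan_evap[i], prm,
                                   tsmd = states[[li]]$tsmd,
                                   soil_covered = soil_covered)
      if (ln == "top") {
        plant <- returns$litter_c[i] + returns$root_c_top[i]
        dung <- returns$dung_c[i]
      } else {
        plant <- returns$root_c_deep[i]
        dung <- 0
      }
      states[[li]] <- rothc_step(states[[li]], plant, dung, prm, mods)
      rec[(i - 1L) * 2L + li, ] <- states[[li]]$pools[pool_names]
    }
    soc_series[i] <- sum(rec[(i - 1L) * 2L + 1:2, ])
  }
  pools <- tibble::tibble(
    year = rep(climate$year, each = 2L),
    month = rep(climate$month, each = 2L),
    layer = rep(names(layers), times = n),
    tibble::as_tibble(rec))
  pools$soc <- rowSums(rec)
  soc0 <- sum(vapply(layers, function(p) p$initial_soc, numeric(1)))
  yearly <- tibble::tibble(year = climate$year, soc = soc_series) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(soc = dplyr::last(.data$soc), .groups = "drop") |>
    dplyr::mutate(delta_soc = .data$soc - dplyr::lag(.data$soc, default = soc0))
  structure(list(annual = yearly[c("year", "delta_soc", "soc")],
                 pools = pools, final = states),
            class = "soil_carbon_run")
}
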