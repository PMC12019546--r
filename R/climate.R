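#' Construct a monthly climate series
#'
#' A climate series is a tibble with one row per calendar month holding the
#' weather drivers the rest of the pipeline consumes: monthly rainfall (mm),
#' mean temperature (deg C) and Class-A pan evaporation (mm), together with
#' the atmospheric CO2 concentration (ppm) assumed for the horizon. Records
#' must be contiguous in (year, month).
#'
#' @param records Data frame with columns `year`, `month`, `rain`, `tmean`,
#'   `pan_evap`.
#' @param site_id Label identifying the site.
#' @param co2_ppm Atmospheric CO2 concentration, ppm. The three named
#'   horizons use 350 (historical), 450 (2030) and 530 (2050).
#' @return A tibble with columns `site_id`, `year`, `month`, `rain`,
#'   `tmean`, `pan_evap`, `co2_ppm`.
#' @export
climate_series <- function(records, site_id, co2_ppm = 350) {
  needed <- c("year", "month", "rain", "tmean", "pan_evap")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop_format(sprintf("climate records are missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  check_number(co2_ppm, "co2_ppm", min = 1)
  out <- tibble::as_tibble(records[needed])
  if (nrow(out) == 0) stop_format("climate series has no records")
  if (any(out$rain < 0)) stop_param("rain must be non-negative")
  if (any(out$pan_evap < 0)) stop_param("pan_evap must be non-negative")
  check_contiguous(out)
  tibble::tibble(site_id = site_id, out, co2_ppm = co2_ppm)
}

check_contiguous <- function(records) {
  idx <- records$year * 12 + (records$month - 1)
  if (nrow(records) > 1) {
    step <- diff(idx)
    bad <- which(step != 1)
    if (length(bad) > 0) {
      y <- records$year[bad[1]]
      m <- records$month[bad[1]] + 1
      if (m > 12) { y <- y + 1; m <- 1 }
      abort_grazenet(
        sprintf("climate series is not contiguous: first missing month is %04d-%02d",
                y, m),
        "grazenet_contiguity_error")
    }
  }
  invisible(records)
}

#' Read a daily or monthly weather CSV
#'
#' Reads a SILO-style CSV with header `date,rain,tmax,tmin,evap` (ISO dates,
#' units mm / deg C / mm) and aggregates it to the monthly cadence used by
#' the pipeline: rainfall and pan evaporation are summed within each month,
#' and monthly mean temperature is the mean of the daily (tmax + tmin) / 2.
#' Monthly input (one row per month) passes through the same path.
#'
#' @inheritParams climate_series
#' @param path Path to the CSV file.
#' @return A climate series tibble (see [climate_series()]).
#' @export
read_climate_csv <- function(path, site_id, co2_ppm = 350) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop_format(sprintf("empty climate file: %s", path))
  needed <- c("date", "rain", "tmax", "tmin", "evap")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop_format(sprintf("climate file %s is missing column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  dates <- as.Date(raw$date)
  if (any(is.na(dates))) stop_format("column `date` contains unparseable dates")
  monthly <- tibble::tibble(
    year = as.integer(format(dates, "%Y")),
    month = as.integer(format(dates, "%m")),
    rain = raw$rain,
    tmid = (raw$tmax + raw$tmin) / 2,
    evap = raw$evap
  ) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(rain = sum(.data$rain),
                     tmean = mean(.data$tmid),
                     pan_evap = sum(.data$evap),
                     .groups = "drop") |>
    dplyr::arrange(.data$year, .data$month)
  climate_series(monthly, site_id = site_id, co2_ppm = co2_ppm)
}

#' Monthly climate scaling factors for a horizon
#'
#' A scaling factor set holds, for each calendar month, an additive
#' temperature delta (deg C) and multiplicative rainfall and pan-evaporation
#' factors, plus an interannual variability inflation applied to rainfall.
#' The historical horizon uses identity factors.
#'
#' @param horizon One of `"historical"`, `"2030"`, `"2050"` (other labels
#'   are allowed if `co2_ppm` is given).
#' @param temp_delta Additive monthly temperature change, deg C; length 1 or 12.
#' @param rain_factor Multiplicative monthly rainfall factor (> 0); length 1 or 12.
#' @param evap_factor Multiplicative monthly pan-evaporation factor (> 0);
#'   length 1 or 12.
#' @param variability_inflation Dimensionless >= 0; extra interannual spread
#'   applied to annual rainfall (see [apply_scaling()]).
#' @param co2_ppm Atmospheric CO2 for the horizon; defaults to 350 / 450 /
#'   530 for the three named horizons.
#' @return An object of class `scaling_factors`.
#' @export
scaling_factors <- function(horizon,
                            temp_delta = 0,
                            rain_factor = 1,
                            evap_factor = 1,
                            variability_inflation = 0,
                            co2_ppm = NULL) {
  if (is.null(co2_ppm)) {
    co2_ppm <- switch(horizon,
                      historical = 350, `2030` = 450, `2050` = 530,
                      stop_param(sprintf(
                        "no default co2_ppm for horizon '%s'; supply co2_ppm", horizon)))
  }
  rep12 <- function(x, name) {
    if (!length(x) %in% c(1L, 12L)) {
      stop_param(sprintf("`%s` must have length 1 or 12", name))
    }
    rep_len(as.numeric(x), 12L)
  }
  temp_delta <- rep12(temp_delta, "temp_delta")
  rain_factor <- rep12(rain_factor, "rain_factor")
  evap_factor <- rep12(evap_factor, "evap_factor")
  if (any(rain_factor <= 0)) stop_param("rain_factor must be > 0")
  if (any(evap_factor <= 0)) stop_param("evap_factor must be > 0")
  check_number(variability_inflation, "variability_inflation", min = 0)
  structure(
    list(horizon = horizon,
         co2_ppm = co2_ppm,
         table = tibble::tibble(month = 1:12,
                                temp_delta = temp_delta,
                                rain_factor = rain_factor,
                                evap_factor = evap_factor),
         variability_inflation = variability_inflation),
    class = "scaling_factors")
}

#' Default scaling factor sets for the three horizons
#'
#' Illustrative cool-temperate delta-change sets: modest uniform warming,
#' rainfall decline and pan-evaporation rise growing from 2030 to 2050, with
#' CO2 at 350 / 450 / 530 ppm. Site-specific sets from a GCM ensemble should
#' be supplied through [scaling_factors()] when available.
#'
#' @param horizon `"historical"`, `"2030"` or `"2050"`.
#' @return A `scaling_factors` object.
#' @export
default_scaling_factors <- function(horizon = c("historical", "2030", "2050")) {
  horizon <- match.arg(horizon)
  switch(horizon,
    historical = scaling_factors("historical"),
    `2030` = scaling_factors("2030",
                             temp_delta = 0.8,
                             rain_factor = 0.95,
                             evap_factor = 1.03,
                             variability_inflation = 0.05),
    `2050` = scaling_factors("2050",
                             temp_delta = 1.6,
                             rain_factor = 0.92,
                             evap_factor = 1.06,
                             variability_inflation = 0.10))
}

#' Project a historical climate series to a future horizon
#'
#' Delta-change scaling: per month m of year y,
#' `tmean' = tmean + temp_delta(m)`,
#' `rain' = rain * rain_factor(m) * max(0, 1 + inflation * z_y)` and
#' `pan_evap' = pan_evap * evap_factor(m)`, where `z_y` is a seeded
#' standard-normal draw shared by all months of year y. The annual rain
#' perturbation is a simple stand-in for stochastic extreme-event
#' generators: it widens interannual rainfall spread without reshaping the
#' seasonal profile. With identity factors and zero inflation the weather
#' fields are returned unchanged. Deterministic given `seed`.
#'
#' @param hist A historical climate series tibble.
#' @param factors A [scaling_factors()] object.
#' @param seed Integer seed for the annual variability draws.
#' @return A climate series tibble on the target horizon.
#' @export
apply_scaling <- function(hist, factors, seed = 1L) {
  if (!inherits(factors, "scaling_factors")) {
    stop_param("`factors` must be a scaling_factors object")
  }
  years <- sort(unique(hist$year))
  z <- withr::with_seed(seed, stats::rnorm(length(years)))
  infl <- factors$variability_inflation
  year_mult <- pmax(0, 1 + infl * z)
  names(year_mult) <- as.character(years)
  tab <- factors$table
  out <- hist |>
    dplyr::mutate(
      tmean = .data$tmean + tab$temp_delta[.data$month],
      rain = .data$rain * tab$rain_factor[.data$month] *
        year_mult[as.character(.data$year)],
      pan_evap = .data$pan_evap * tab$evap_factor[.data$month],
      co2_ppm = factors$co2_ppm
    )
  out$rain <- unname(out$rain)
  out
}

#' Synthesise a historical monthly climate series
#'
#' Seeded weather generator for sites described by summary statistics:
#' annual rainfall totals are drawn from a normal distribution (clamped at
#' zero) and split across months by a seasonal fraction profile jittered
#' with multiplicative noise and renormalised, so the annual total is
#' preserved exactly; monthly mean temperature is a seasonal profile plus
#' normal noise; pan evaporation follows its seasonal profile.
#'
#' @param site A site description as returned by [stanley_site()] or
#'   [campbell_town_site()]: a list with `site_id`, `annual_rain_mean`,
#'   `annual_rain_sd`, `rain_month_frac` (12 values summing to 1),
#'   `tmean_monthly` (12), `tmean_sd`, `pan_evap_monthly` (12).
#' @param n_years Number of years to generate (>= 1).
#' @param seed Integer seed; identical inputs and seed give identical series.
#' @param start_year First calendar year of the series.
#' @return A climate series tibble with `co2_ppm = 350`.
#' @export
synth_historical <- function(site, n_years, seed = 1L, start_year = 1986L) {
  if (n_years < 1) stop_param("`n_years` must be >= 1")
  check_number(site$annual_rain_mean, "annual_rain_mean", min = 0)
  check_number(site$annual_rain_sd, "annual_rain_sd", min = 0)
  if (site$annual_rain_mean <= 0) stop_param("annual_rain_mean must be > 0")
  frac <- site$rain_month_frac
  if (length(frac) != 12 || abs(sum(frac) - 1) > 1e-6) {
    stop_param("rain_month_frac must have 12 entries summing to 1")
  }
  if (length(site$tmean_monthly) != 12 || length(site$pan_evap_monthly) != 12) {
    stop_param("tmean_monthly and pan_evap_monthly must have 12 entries")
  }
  rows <- withr::with_seed(seed, {
    annual <- pmax(0, stats::rnorm(n_years, site$annual_rain_mean,
                                   site$annual_rain_sd))
    purrr::map(seq_len(n_years), function(y) {
      jitter <- pmax(0.05, 1 + stats::rnorm(12, 0, 0.25))
      w <- frac * jitter
      w <- w / sum(w)
      tibble::tibble(
        year = start_year + y - 1L,
        month = 1:12,
        rain = annual[y] * w,
        tmean = site$tmean_monthly + stats::rnorm(12, 0, site$tmean_sd),
        pan_evap = site$pan_evap_monthly
      )
    })
  })
  climate_series(dplyr::bind_rows(rows), site_id = site$site_id, co2_ppm = 350)
}

#' Site statistics: high-rainfall cool-temperate coastal site
#'
#' Summary statistics for a high-rainfall beef site: long-term annual
#' rainfall 807 +/- 139 mm, mean daily temperatures near 16.5 deg C in
#' January and 9.1 deg C in July, winter-dominant rainfall.
#'
#' @return A site description list for [synth_historical()].
#' @export
stanley_site <- function() {
  list(
    site_id = "stanley",
    annual_rain_mean = 807,
    annual_rain_sd = 139,
    rain_month_frac = c(0.05, 0.05, 0.06, 0.08, 0.10, 0.11,
                        0.12, 0.11, 0.10, 0.09, 0.07, 0.06),
    tmean_monthly = c(16.5, 16.6, 15.5, 13.8, 11.9, 10.2,
                      9.1, 9.5, 10.6, 12.0, 13.6, 15.2),
    tmean_sd = 0.6,
    pan_evap_monthly = c(150, 125, 105, 70, 48, 36, 40, 52, 72, 98, 120, 140)
  )
}

#' Site statistics: low-rainfall midlands site
#'
#' Summary statistics for a low-rainfall sheep site: long-term annual
#' rainfall 499 +/- 103 mm, mean daily temperatures near 16.7 deg C in
#' January and 6.5 deg C in July, weakly seasonal rainfall.
#'
#' @return A site description list for [synth_historical()].
#' @export
campbell_town_site <- function() {
  list(
    site_id = "campbell_town",
    annual_rain_mean = 499,
    annual_rain_sd = 103,
    rain_month_frac = c(0.07, 0.07, 0.07, 0.08, 0.08, 0.09,
                        0.10, 0.10, 0.09, 0.09, 0.08, 0.08),
    tmean_monthly = c(16.7, 16.8, 15.2, 12.6, 9.9, 7.6,
                      6.5, 7.3, 9.2, 11.3, 13.5, 15.4),
    tmean_sd = 0.7,
    pan_evap_monthly = c(170, 140, 110, 70, 45, 30, 33, 48, 72, 105, 135, 160)
  )
}
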