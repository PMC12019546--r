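# Shared fixtures and independent oracles, all built in code.

# A constant-weather monthly climate series (n whole years).
constant_climate <- function(n_years = 1, rain = 70, tmean = 12,
                             pan_evap = 60, co2_ppm = 350,
                             start_year = 2000) {
  climate_series(
    tibble::tibble(
      year = rep(start_year + seq_len(n_years) - 1L, each = 12L),
      month = rep(1:12, times = n_years),
      rain = rain, tmean = tmean, pan_evap = pan_evap),
    site_id = "fixture", co2_ppm = co2_ppm)
}

# A two-class toy farm small enough for hand arithmetic.
toy_farm <- function(head1 = 100, head2 = 50, dmi1 = 10, dmi2 = 2,
                     fce = 1, area = 100) {
  farm_config(
    farm_id = "toy",
    grazed_area = area,
    animal_classes = tibble::tibble(
      class = c("cattle_a", "sheep_b"),
      species = c("cattle", "sheep"),
      head = c(head1, head2),
      liveweight_kg = c(500, 50),
      dmi_kg_day = c(dmi1, dmi2),
      product = c("meat", "wool"),
      product_kg_head_yr = c(250, 5),
      n_excretion_kg_yr = c(80, 10)),
    fertiliser_n = 20, diesel = 1000, electricity = 2000,
    fce_multiplier = fce)
}

# Independent RothC oracle: scalar month loop, one pool at a time,
# written as a plain spreadsheet-style iteration (no shared code with the
# package implementation).
rothc_oracle_run <- function(pools, n_months, plant, dung, k, clay, abc,
                             dpm_rpm = 1.44,
                             dung_split = c(0.49, 0.49, 0.02)) {
  dpm <- pools[1]; rpm <- pools[2]; bio <- pools[3]; hum <- pools[4]
  co2 <- 0
  x <- 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay))
  for (m in seq_len(n_months)) {
    d_dpm <- dpm * (1 - exp(-k[1] * abc / 12))
    d_rpm <- rpm * (1 - exp(-k[2] * abc / 12))
    d_bio <- bio * (1 - exp(-k[3] * abc / 12))
    d_hum <- hum * (1 - exp(-k[4] * abc / 12))
    lost <- d_dpm + d_rpm + d_bio + d_hum
    dpm <- dpm - d_dpm + plant * dpm_rpm / (1 + dpm_rpm) + dung * dung_split[1]
    rpm <- rpm - d_rpm + plant * 1 / (1 + dpm_rpm) + dung * dung_split[2]
    bio <- bio - d_bio + lost / (x + 1) * 0.46
    hum <- hum - d_hum + lost / (x + 1) * 0.54 + dung * dung_split[3]
    co2 <- co2 + lost * x / (x + 1)
  }
  list(pools = c(dpm = dpm, rpm = rpm, bio = bio, hum = hum), co2 = co2)
}

# Write a daily weather CSV fixture and return its path.
write_daily_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}
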