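#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%s)\n", x$label, x$horizon))
  cat(sprintf("  production: %.1f Mg LW, %.1f Mg wool /yr\n",
              x$production$meat_mg, x$production$wool_mg))
  cat(sprintf("  pre-tax profit (mean of %d draws): $%s /yr\n",
              x$profit$n, format(round(x$profit$summary$mean), big.mark = ",")))
  cat(sprintf("  mean net emissions: %.1f Mg CO2e /yr (%s)\n",
              x$net_position$mean_net,
              if (x$net_position$is_net_zero) "net-zero"
              else if (x$net_position$is_net_negative) "net-negative"
              else "net-positive"))
  cat(sprintf("  carbon account: tax $%s, credits $%s, post-account $%s\n",
              format(round(x$carbon_account$tax), big.mark = ","),
              format(round(x$carbon_account$credit_income), big.mark = ","),
              format(round(x$carbon_account$post_account_profit),
                     big.mark = ",")))
  if (length(x$provenance) > 0) {
    cat("  interventions:", paste(x$provenance, collapse = " + "), "\n")
  }
  invisible(x)
}

#' @export
print.emissions_inventory <- function(x, ...) {
  cat("<emissions_inventory>\n")
  print(x$items)
  cat(sprintf("  gross %.1f  - soil %.1f - trees %.1f  = net %.1f Mg CO2e/yr\n",
              x$gross_co2e, x$sequestration[["soil"]],
              x$sequestration[["trees"]], x$net_co2e))
  invisible(x)
}

#' @export
print.macc <- function(x, ...) {
  cat("<macc>\n")
  print(x$curve)
  if (nrow(x$excluded) > 0) {
    cat("zero-abatement:", paste(x$excluded$scenario, collapse = ", "), "\n")
  }
  if (nrow(x$emission_increasing) > 0) {
    cat("emission-increasing:",
        paste(x$emission_increasing$scenario, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a farm-year into a long monthly table
#'
#' @param x A `farm_year`.
#' @param ... Unused.
#' @return Long tibble (month, variable, value), one row per month per
#'   variable, units as in [simulate_farm_year()].
#' @export
tidy.farm_year <- function(x, ...) {
  x$monthly |>
    tidyr::pivot_longer(-c("month", "days"),
                        names_to = "variable", values_to = "value")
}

#' One-row summary of a farm-year
#'
#' @param x A `farm_year`.
#' @param ... Unused.
#' @return One-row tibble of annual totals.
#' @export
glance.farm_year <- function(x, ...) {
  a <- x$annual
  tibble::tibble(farm_id = x$farm_id, meat_mg = a$meat_mg,
                 wool_mg = a$wool_mg, intake_mg = a$intake_mg,
                 supplement_mg = a$supplement_mg,
                 n_excreted_kg = a$n_excreted_kg)
}

#' Tidy a soil carbon run into a long pool table
#'
#' @param x A `soil_carbon_run`.
#' @param ... Unused.
#' @return Long tibble (year, month, layer, pool, mg_c_ha).
#' @export
tidy.soil_carbon_run <- function(x, ...) {
  x$pools |>
    tidyr::pivot_longer(c("dpm", "rpm", "bio", "hum", "iom"),
                        names_to = "pool", values_to = "mg_c_ha")
}

#' Tidy a profit distribution
#'
#' @param x A `profit_distribution`.
#' @param ... Unused.
#' @return Tibble (iteration, profit).
#' @export
tidy.profit_distribution <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$iterations), profit = x$iterations)
}

#' One-row summary of a profit distribution
#'
#' @param x A `profit_distribution`.
#' @param ... Unused.
#' @return One-row tibble (mean, sd, p5, p50, p95, n, seed).
#' @export
glance.profit_distribution <- function(x, ...) {
  dplyr::mutate(x$summary, n = x$n, seed = x$seed)
}

#' Tidy a scenario result into its annual emissions ledger
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return Tibble (year, gross, soil_seq, tree_seq, net), Mg CO2e/yr.
#' @export
tidy.scenario_result <- function(x, ...) x$annual

#' One-row summary of a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return One-row tibble with production, profit, net position and
#'   carbon account headline values.
#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(scenario = x$label, horizon = x$horizon,
                 meat_mg = x$production$meat_mg,
                 wool_mg = x$production$wool_mg,
                 profit_mean = x$profit$summary$mean,
                 mean_net = x$net_position$mean_net,
                 is_net_zero = x$net_position$is_net_zero,
                 tax = x$carbon_account$tax,
                 credit_income = x$carbon_account$credit_income,
                 post_account_profit = x$carbon_account$post_account_profit,
                 adoptability = x$adoptability)
}

#' Tidy an emissions inventory into its line items
#'
#' @param x An `emissions_inventory`.
#' @param ... Unused.
#' @return Tibble (source, gas, mass_mg, co2e_mg).
#' @export
tidy.emissions_inventory <- function(x, ...) x$items

#' One-row summary of an emissions inventory
#'
#' @param x An `emissions_inventory`.
#' @param ... Unused.
#' @return One-row tibble (gross, soil_seq, tree_seq, net), Mg CO2e/yr.
#' @export
glance.emissions_inventory <- function(x, ...) {
  tibble::tibble(gross_co2e = x$gross_co2e,
                 soil_seq = x$sequestration[["soil"]],
                 tree_seq = x$sequestration[["trees"]],
                 net_co2e = x$net_co2e)
}

#' Tidy a MACC into its ordered point table
#'
#' @param x A `macc`.
#' @param ... Unused.
#' @return Tibble (scenario, abatement, cost_per_mg), cost-ordered.
#' @export
tidy.macc <- function(x, ...) x$curve

#' Step plot of a marginal abatement cost curve
#'
#' Bars span cumulative abatement on the x axis (width = each
#' intervention's abatement, Mg CO2e/yr) with height equal to its cost
#' per Mg CO2e; negative bars are profit-increasing options.
#'
#' @param object A `macc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.macc <- function(object, ...) {
  curve <- object$curve |>
    dplyr::mutate(xmax = cumsum(.data$abatement),
                  xmin = .data$xmax - .data$abatement)
  ggplot2::ggplot(curve) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = pmin(0, .data$cost_per_mg),
                                    ymax = pmax(0, .data$cost_per_mg),
                                    fill = .data$scenario),
                       colour = "grey20") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Cumulative abatement (Mg CO2e / yr)",
                  y = "Cost ($ per Mg CO2e)", fill = "Intervention") +
    ggplot2::theme_minimal()
}

#' Histogram of a Monte Carlo profit distribution
#'
#' @param object A `profit_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profit_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$profit)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$mean, linetype = 2) +
    ggplot2::labs(x = "Annual operating profit ($)", y = "Iterations") +
    ggplot2::theme_minimal()
}

#' Response surface of a sensitivity sweep
#'
#' Mean net emissions against enteric CH4 inhibition, one line per tree
#' sequestration perturbation.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$inhibition, y = .data$mean_net,
                               colour = factor(.data$tree_perturbation))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Enteric CH4 inhibition fraction",
                  y = "Mean net emissions (Mg CO2e / yr)",
                  colour = "Tree perturbation") +
    ggplot2::theme_minimal()
}

#' SOC trajectory of a soil carbon run
#'
#' @param object A `soil_carbon_run`.
#' @param ... Unused.
#' @return A ggplot object (total SOC by layer over time).
#' @export
autoplot.soil_carbon_run <- function(object, ...) {
  dat <- object$pools |>
    dplyr::mutate(t = .data$year + (.data$month - 0.5) / 12)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$soc,
                                    colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "SOC (Mg C / ha)", colour = "Layer") +
    ggplot2::theme_minimal()
}

#' Ternary plot of normalised impact scores
#'
#' Projects the three normalised components (production, profit, inverse
#' emissions) onto the 2-simplex and plots them in triangular
#' coordinates.
#'
#' @param scores A [normalize_scores()] result.
#' @return A ggplot object.
#' @export
plot_ternary <- function(scores) {
  tern <- ternary_coordinates(scores) |>
    dplyr::mutate(x = .data$tern_profit + 0.5 * .data$tern_ghg,
                  y = sqrt(3) / 2 * .data$tern_ghg)
  triangle <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(tern, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = triangle, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$scenario), size = 3) +
    ggplot2::annotate("text", x = c(0, 1, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.04),
                      label = c("Production", "Profit", "Emissions")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
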