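#' Normalised multidimensional impact scores
#'
#' Within a compared scenario set, liveweight production and pre-tax
#' profit are each normalised by the set maximum (so values lie in
#' [0, 1]); net emissions are normalised by the set maximum and
#' inverse-coded as one minus that ratio (lower emissions are better),
#' clamped to [0, 1] so net-negative scenarios cannot exceed the range.
#' The total is the equally weighted sum, ranging from 0 to 3; a scenario
#' reaches exactly 3 only when it is best in set on production and profit
#' and has zero mean net emissions. Negative profits are floored at zero
#' before normalising (flagged with a warning); a metric column whose
#' maximum is not positive yields zeros for that component with a
#' warning.
#'
#' @param results Tibble with columns `scenario`, `production`
#'   (Mg LW/yr), `profit` (pre-carbon-tax $/yr) and `net`
#'   (mean net Mg CO2e/yr); one row per compared scenario. A list of
#'   scenario results can be converted with [scenario_metrics()].
#' @return Tibble with the input columns plus `norm_production`,
#'   `norm_profit`, `norm_ghg` and `total`.
#' @export
normalize_scores <- function(results) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) stop_param("empty scenario set")
  need <- c("scenario", "production", "profit", "net")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0) {
    stop_param(sprintf("results are missing column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  profit <- results$profit
  if (any(profit < 0)) {
    rlang::warn("negative profit(s) floored at 0 before normalisation")
    profit <- pmax(0, profit)
  }
  norm_by_max <- function(x, name) {
    mx <- max(x)
    if (mx <= 0) {
      rlang::warn(sprintf(
        "all scenarios have non-positive %s; component set to 0", name))
      return(rep(0, length(x)))
    }
    pmin(1, pmax(0, x / mx))
  }
  norm_production <- norm_by_max(results$production, "production")
  norm_profit <- norm_by_max(profit, "profit")
  max_net <- max(results$net)
  norm_ghg <- if (max_net <= 0) {
    rlang::warn("all scenarios are net-negative; emissions component set to 1")
    rep(1, nrow(results))
  } else {
    pmin(1, pmax(0, 1 - results$net / max_net))
  }
  dplyr::mutate(results,
                norm_production = norm_production,
                norm_profit = norm_profit,
                norm_ghg = norm_ghg,
                total = norm_production + norm_profit + norm_ghg)
}

#' Ternary coordinates of impact scores
#'
#' Divides the three normalised components by their sum, giving
#' coordinates on the 2-simplex (summing to 1) for ternary plotting.
#'
#' @param scores A [normalize_scores()] result (or any tibble with
#'   `norm_production`, `norm_profit`, `norm_ghg`).
#' @return The input with added columns `tern_production`, `tern_profit`,
#'   `tern_ghg`.
#' @export
ternary_coordinates <- function(scores) {
  s <- scores$norm_production + scores$norm_profit + scores$norm_ghg
  if (any(s <= 0)) {
    abort_grazenet(
      "ternary point undefined for scenario(s) with all components zero",
      "grazenet_undefined_error")
  }
  dplyr::mutate(scores,
                tern_production = .data$norm_production / s,
                tern_profit = .data$norm_profit / s,
                tern_ghg = .data$norm_ghg / s)
}

#' Sensitivity sweep over enteric inhibition and tree sequestration
#'
#' Re-runs the full pipeline on a grid of enteric CH4 inhibition fractions
#' and tree sequestration perturbations, all under a shared seed so that
#' climate and production are identical across grid points. Mean net
#' emissions are non-increasing along the inhibition axis and respond
#' linearly along the tree axis.
#'
#' @param scn A [scenario()] (typically already carrying tree stands).
#' @param inhibition Grid of inhibition fractions, within [0.10, 0.99]
#'   unless `override = TRUE`.
#' @param tree_perturbation Grid of relative tree sequestration changes,
#'   within [-0.2, 0.2] unless `override = TRUE`.
#' @param seed Shared integer seed.
#' @param horizon,n_years,spin_up,window,n_iter Passed to
#'   [run_scenario()]; the default `n_iter` keeps the sweep light.
#' @param override Allow grids outside the stated envelopes.
#' @return Tibble of class `sweep_result` with columns `inhibition`,
#'   `tree_perturbation`, `mean_net` (Mg CO2e/yr), `pre_tax_profit`,
#'   `post_account_profit` ($/yr).
#' @export
sensitivity_sweep <- function(scn,
                              inhibition = seq(0.10, 0.99, length.out = 5),
                              tree_perturbation = c(-0.2, 0, 0.2),
                              seed = 1L,
                              horizon = "2030",
                              n_years = 26, spin_up = 6, window = 20,
                              n_iter = 400,
                              override = FALSE) {
  if (!override) {
    if (any(inhibition < 0.10 - 1e-12) || any(inhibition > 0.99 + 1e-12)) {
      abort_grazenet("inhibition grid outside [0.10, 0.99]; set override = TRUE",
                     "grazenet_range_error")
    }
    if (any(abs(tree_perturbation) > 0.2 + 1e-12)) {
      abort_grazenet(
        "tree perturbation grid outside [-0.2, 0.2]; set override = TRUE",
        "grazenet_range_error")
    }
  }
  grid <- tidyr::expand_grid(inhibition = inhibition,
                             tree_perturbation = tree_perturbation)
  rows <- purrr::pmap(grid, function(inhibition, tree_perturbation) {
    s <- scn
    s$inhibition <- inhibition
    s$stands <- purrr::map(s$stands, function(st) {
      st$perturbation <- (st$perturbation %||% 1) * (1 + tree_perturbation)
      st
    })
    res <- run_scenario(s, horizon = horizon, seed = seed, n_years = n_years,
                        spin_up = spin_up, window = window, n_iter = n_iter)
    tibble::tibble(inhibition = inhibition,
                   tree_perturbation = tree_perturbation,
                   mean_net = res$net_position$mean_net,
                   pre_tax_profit = res$profit$summary$mean,
                   post_account_profit = res$carbon_account$post_account_profit)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}
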