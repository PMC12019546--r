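#' Hybrid carbon tax / credit policy
#'
#' Residual net-positive emissions are taxed; net-negative emissions earn
#' credits. The default $80/Mg CO2e tax (a social-cost-of-carbon figure)
#' exceeds the default $28/Mg CO2e credit (a market spot price), placing
#' more weight on reaching net-zero than on going beyond it.
#'
#' @param tax_rate Tax on net-positive emissions, $/Mg CO2e (>= 0).
#' @param credit_price Credit for net-negative emissions, $/Mg CO2e
#'   (>= 0, <= tax_rate).
#' @return An object of class `carbon_policy`.
#' @export
carbon_policy <- function(tax_rate = 80, credit_price = 28) {
  if (tax_rate < 0 || credit_price < 0) {
    stop_param("tax_rate and credit_price must be >= 0")
  }
  if (tax_rate < credit_price) {
    stop_param("tax_rate must be >= credit_price")
  }
  structure(list(tax_rate = tax_rate, credit_price = credit_price),
            class = "carbon_policy")
}

#' Commodity price model with correlated marginals
#'
#' Marginal price distributions per commodity (normal, lognormal or PERT)
#' joined by a Gaussian copula with the given correlation matrix.
#'
#' @param marginals Tibble with columns `commodity`, `family`
#'   (`"normal"`, `"lognormal"`, `"pert"`), `p1`, `p2`, `p3`:
#'   normal uses (mean, sd), lognormal (meanlog, sdlog), PERT
#'   (min, mode, max).
#' @param correlation Correlation matrix with dimnames matching
#'   `marginals$commodity`; identity if omitted.
#' @return An object of class `price_model`.
#' @export
price_model <- function(marginals, correlation = NULL) {
  marginals <- tibble::as_tibble(marginals)
  stopifnot(all(c("commodity", "family", "p1", "p2") %in% names(marginals)))
  if (!"p3" %in% names(marginals)) marginals$p3 <- NA_real_
  bad <- setdiff(marginals$family, c("normal", "lognormal", "pert"))
  if (length(bad) > 0) {
    stop_param(sprintf("unknown distribution family: %s",
                       paste(bad, collapse = ", ")))
  }
  k <- nrow(marginals)
  if (is.null(correlation)) {
    correlation <- diag(k)
    dimnames(correlation) <- list(marginals$commodity, marginals$commodity)
  }
  correlation <- correlation[marginals$commodity, marginals$commodity]
  if (any(abs(correlation - t(correlation)) > 1e-12) ||
      any(abs(diag(correlation) - 1) > 1e-12)) {
    stop_param("correlation must be symmetric with unit diagonal")
  }
  structure(list(marginals = marginals, correlation = correlation),
            class = "price_model")
}

#' Default price model for the fixture farms
#'
#' Lognormal liveweight and wool prices (in $/kg) correlated at 0.6, and
#' an independent PERT-distributed purchased feed price in $/Mg DM.
#'
#' @param farm `"beef"` or `"sheep"`.
#' @return A [price_model()].
#' @export
default_price_model <- function(farm = c("beef", "sheep")) {
  farm <- match.arg(farm)
  marg <- if (farm == "beef") {
    tibble::tribble(
      ~commodity, ~family, ~p1, ~p2, ~p3,
      "meat", "lognormal", log(3.2), 0.15, NA,
      "wool", "lognormal", log(12), 0.25, NA,
      "feed", "pert", 250, 350, 500)
  } else {
    tibble::tribble(
      ~commodity, ~family, ~p1, ~p2, ~p3,
      "meat", "lognormal", log(2.9), 0.18, NA,
      "wool", "lognormal", log(13), 0.25, NA,
      "feed", "pert", 250, 350, 500)
  }
  corr <- diag(3)
  dimnames(corr) <- list(marg$commodity, marg$commodity)
  corr["meat", "wool"] <- corr["wool", "meat"] <- 0.6
  price_model(marg, corr)
}

marginal_quantile <- function(u, family, p1, p2, p3) {
  switch(family,
         normal = stats::qnorm(u, mean = p1, sd = p2),
         lognormal = stats::qlnorm(u, meanlog = p1, sdlog = p2),
         pert = {
           if (!(p1 <= p2 && p2 <= p3) || p3 <= p1) {
             stop_param("PERT parameters must satisfy min <= mode <= max")
           }
           a <- 1 + 4 * (p2 - p1) / (p3 - p1)
           b <- 1 + 4 * (p3 - p2) / (p3 - p1)
           p1 + (p3 - p1) * stats::qbeta(u, a, b)
         })
}

#' Sample correlated commodity prices
#'
#' Gaussian-copula sampling: correlated standard normals (via the Cholesky
#' factor of the correlation matrix) are mapped through each marginal's
#' inverse CDF, so rank correlation approaches the target as n grows while
#' each commodity keeps its marginal distribution exactly.
#'
#' @param model A [price_model()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Tibble with `n` rows, one column per commodity.
#' @export
sample_prices <- function(model, n, seed = 1L) {
  marg <- model$marginals
  k <- nrow(marg)
  eig <- eigen(model$correlation, symmetric = TRUE)
  if (any(eig$values < -1e-8)) {
    abort_grazenet(sprintf(
      "price correlation matrix is not positive semi-definite:\n%s",
      paste(utils::capture.output(print(model$correlation)), collapse = "\n")),
      "grazenet_decomposition_error")
  }
  # PSD square root (handles the perfectly correlated, singular case)
  fac <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), k)
  z <- withr::with_seed(seed,
                        matrix(stats::rnorm(n * k), nrow = n, ncol = k))
  zc <- z %*% t(fac)
  u <- stats::pnorm(zc)
  draws <- purrr::map(seq_len(k), function(j) {
    marginal_quantile(u[, j], marg$family[j], marg$p1[j], marg$p2[j], marg$p3[j])
  })
  names(draws) <- marg$commodity
  tibble::as_tibble(draws)
}

#' Annual operating profit (EBIT)
#'
#' Income (meat and wool at the drawn prices, plus diversification income
#' deltas) minus variable costs (purchased feed at the drawn feed price
#' plus other variable costs and intervention cost deltas), overheads and
#' straight-line depreciation of intervention capital. No interest or tax
#' is deducted. Negative drawn prices (possible under a normal marginal)
#' are permitted and flagged with a warning.
#'
#' @param production List with `meat_mg`, `wool_mg`, `purchased_feed_mg`
#'   (annual means over the analysis window).
#' @param prices One or more price draws: tibble with columns `meat`,
#'   `wool` ($/kg) and `feed` ($/Mg DM).
#' @param econ Economic inputs (see [scenario()]).
#' @return Numeric vector of annual operating profit, $/yr, one per draw.
#' @export
operating_profit <- function(production, prices, econ) {
  if (any(prices < 0, na.rm = TRUE)) {
    rlang::warn("negative price draw encountered (normal marginal)")
  }
  income <- production$meat_mg * 1000 * prices$meat +
    production$wool_mg * 1000 * prices$wool +
    econ$income_delta
  feed_cost <- production$purchased_feed_mg * prices$feed
  depreciation <- econ$capex / econ$capex_life
  income - feed_cost - econ$variable_other - econ$overheads -
    econ$cost_delta - depreciation
}

#' Monte Carlo profit distribution
#'
#' Draws `n` correlated price vectors and evaluates the operating profit
#' for each; bit-identical for identical inputs and seed. The standard
#' error of the mean shrinks as 1/sqrt(n).
#'
#' @param production,econ As for [operating_profit()].
#' @param model A [price_model()].
#' @param n Number of iterations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `profit_distribution`: list with `iterations`
#'   (numeric vector of profits), `summary` (tibble: mean, sd, p5, p50,
#'   p95), `n`, `seed`.
#' @export
monte_carlo_profit <- function(production, model, econ, n = 10000, seed = 1L) {
  if (n < 1) stop_param("`n` must be >= 1")
  draws <- sample_prices(model, n, seed = seed)
  profits <- operating_profit(production, draws, econ)
  structure(list(
    iterations = profits,
    summary = tibble::tibble(
      mean = mean(profits), sd = stats::sd(profits),
      p5 = unname(stats::quantile(profits, 0.05)),
      p50 = unname(stats::quantile(profits, 0.50)),
      p95 = unname(stats::quantile(profits, 0.95))),
    n = n, seed = seed),
    class = "profit_distribution")
}

#' Apply the hybrid carbon account to a profit
#'
#' The tax applies to the positive part of the 20-year mean net emission
#' and the credit to its negative part, so tax and credit are mutually
#' exclusive and the post-account profit is continuous in the mean net
#' emission at zero.
#'
#' @param net A [net_position()] or a single mean net emission
#'   (Mg CO2e/yr).
#' @param policy A [carbon_policy()].
#' @param pre_tax_profit Pre-carbon-account operating profit, $/yr.
#' @return Object of class `carbon_account`: list with `mean_net`, `tax`,
#'   `credit_income`, `post_account_profit`.
#' @export
carbon_account <- function(net, policy = carbon_policy(), pre_tax_profit = 0) {
  mean_net <- if (inherits(net, "net_position")) net$mean_net else net
  if (!is.finite(mean_net)) stop_param("mean net emission must be finite")
  tax <- policy$tax_rate * max(0, mean_net)
  credit <- policy$credit_price * max(0, -mean_net)
  structure(list(mean_net = mean_net, tax = tax, credit_income = credit,
                 post_account_profit = pre_tax_profit - tax + credit),
            class = "carbon_account")
}

#' Marginal abatement cost curve
#'
#' For each intervention scenario, abatement is the baseline mean net
#' emission minus the intervention's, and the cost per Mg CO2e is the
#' pre-carbon-tax profit forgone divided by the abatement (negative cost
#' means the intervention is profit-increasing). Points are ordered by
#' ascending cost; zero-abatement scenarios are excluded and
#' emission-increasing ones listed separately.
#'
#' @param results Tibble with columns `scenario`, `profit` (pre-tax mean
#'   $/yr) and `net` (mean net Mg CO2e/yr), including the baseline row.
#' @param baseline Label of the baseline scenario in `results`.
#' @return Object of class `macc`: list with `curve` (tibble `scenario`,
#'   `abatement`, `cost_per_mg`, sorted), `excluded` (zero abatement) and
#'   `emission_increasing` (negative abatement).
#' @export
macc <- function(results, baseline = "baseline") {
  results <- tibble::as_tibble(results)
  if (!baseline %in% results$scenario) {
    stop_param(sprintf("baseline scenario '%s' not found in results", baseline))
  }
  base <- results[results$scenario == baseline, ][1, ]
  pts <- results |>
    dplyr::filter(.data$scenario != baseline) |>
    dplyr::mutate(abatement = base$net - .data$net,
                  cost_per_mg = ifelse(.data$abatement == 0, NA_real_,
                                       (base$profit - .data$profit) /
                                         .data$abatement)) |>
    dplyr::select("scenario", "abatement", "cost_per_mg")
  structure(list(
    curve = pts |> dplyr::filter(.data$abatement > 0) |>
      dplyr::arrange(.data$cost_per_mg),
    excluded = pts |> dplyr::filter(.data$abatement == 0) |>
      dplyr::select("scenario"),
    emission_increasing = pts |> dplyr::filter(.data$abatement < 0)),
    class = "macc")
}
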