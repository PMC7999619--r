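# Individual trait-based linear profit model: itemized costs parameterised by
# each pig's simulated performance, carcass revenue through a configurable
# pricing grid, and the derived market-sensitivity and line-gap metrics.

labor_rate_eur_per_pig_day <- function(eco) {
  yearly <- eco$n_workers * eco$hours_per_worker_yr * eco$wage_multiplier * eco$min_wage_eur_per_h
  per_pig <- yearly / (eco$n_sows * eco$weaned_per_sow_yr)
  per_pig * eco$labor_fraction_growing / eco$growing_cycle_days
}

capital_rate_eur_per_pig_day <- function(eco) {
  eco$investment_per_sow_eur * eco$interest_rate_per_yr / (eco$weaned_per_sow_yr * 365)
}

#' Fattening-period cost fragment for one pig
#'
#' Feed cost is the diet price times ADFI times the fattening duration;
#' water is proportional to feed mass (fattening water:feed ratio); energy
#' is the per-kg-gain electricity requirement times the weight gain; labor
#' and capital are per-pig-per-day rates times the duration.
#'
#' @param record one-row performance tibble from [simulate_response()].
#' @param diet_price fattening diet price, EUR per kg.
#' @param config `study_config`.
#' @return one-row tibble `fat_feed`, `fat_water`, `fat_energy`,
#'   `fat_labor`, `fat_capital` (EUR).
#' @export
fattening_costs <- function(record, diet_price, config) {
  if (diet_price < 0) stop_arg("`diet_price` must be >= 0")
  eco <- config$economic
  dur <- record$duration_d
  if (dur < 0) stop_arg("duration must be >= 0")
  feed_mass <- record$adfi_kg_d * dur
  tibble(
    fat_feed = diet_price * feed_mass,
    fat_water = eco$water_ratio_fattening * feed_mass * eco$water_price_eur_per_l,
    fat_energy = eco$energy_per_kg_gain_kwh * record$adg_kg_d * dur * eco$energy_price_eur_per_kwh,
    fat_labor = labor_rate_eur_per_pig_day(eco) * dur,
    fat_capital = capital_rate_eur_per_pig_day(eco) * dur
  )
}

postweaning_costs <- function(config, pw_adfi, pw_adg) {
  eco <- config$economic
  days <- eco$starter_days + eco$postweaning_days
  feed <- pw_adfi * (eco$starter_days * eco$starter_price_eur_per_kg +
                     eco$postweaning_days * eco$postweaning_price_eur_per_kg)
  tibble(
    pw_feed = feed,
    pw_water = eco$water_ratio_postweaning * pw_adfi * days * eco$water_price_eur_per_l,
    pw_energy = eco$energy_per_kg_gain_kwh * pw_adg * days * eco$energy_price_eur_per_kwh,
    pw_labor = labor_rate_eur_per_pig_day(eco) * days,
    pw_capital = capital_rate_eur_per_pig_day(eco) * days
  )
}

#' Carcass revenue from the pricing grid
#'
#' The per-kg price is the base price of the reference carcass (100 kg, 56\%
#' lean) plus a premium/penalty per lean-meat-percentage point and a penalty
#' per kg of carcass weight outside the accepted band; revenue is price per
#' kg times carcass weight.
#'
#' @param carcass_weight carcass weight, kg (> 0).
#' @param lmp lean meat percentage, within the grid's valid range.
#' @param config `study_config` (its `pricing_grid` section is used).
#' @return revenue in EUR.
#' @export
carcass_revenue <- function(carcass_weight, lmp, config) {
  grid <- config$pricing_grid
  if (carcass_weight <= 0) stop_arg("`carcass_weight` must be > 0")
  if (lmp <= grid$lmp_valid_range[1] || lmp >= grid$lmp_valid_range[2]) {
    stop_arg(sprintf("`lmp` must lie in (%g, %g)", grid$lmp_valid_range[1], grid$lmp_valid_range[2]))
  }
  outside <- pmax(grid$weight_band_kg[1] - carcass_weight, 0) +
             pmax(carcass_weight - grid$weight_band_kg[2], 0)
  price <- grid$base_price_eur_per_kg +
    grid$lmp_premium_eur_per_point * (lmp - grid$ref_lmp_pct) -
    grid$weight_penalty_eur_per_kg_outside * outside
  price * carcass_weight
}

#' Profit for one pig
#'
#' Revenue from the carcass sale minus the full cost breakdown (weaned
#' piglet market price, postweaning feed/water/energy/labor/capital,
#' fattening components, fixed costs).  Manure handling is assumed
#' cost-neutral.
#'
#' @inheritParams fattening_costs
#' @param weaned_piglet_price piglet market price, EUR.
#' @param pw_adfi,pw_adg line-mean postweaning ADFI and ADG, kg/d.
#' @return one-row tibble: all cost components, `total_cost`, `revenue`,
#'   `profit` (EUR).
#' @export
pig_profit <- function(record, diet_price, config,
                       weaned_piglet_price = 33, pw_adfi = 0.85, pw_adg = 0.46) {
  fat <- fattening_costs(record, diet_price, config)
  pw <- postweaning_costs(config, pw_adfi, pw_adg)
  costs <- dplyr::bind_cols(
    tibble(weaned_piglet = weaned_piglet_price), pw, fat,
    tibble(fixed = config$economic$fixed_cost_eur_per_pig)
  )
  total <- sum(as.numeric(costs[1, ]))
  revenue <- carcass_revenue(record$carcass_kg, record$lmp_pct, config)
  dplyr::bind_cols(costs, tibble(total_cost = total, revenue = revenue,
                                 profit = revenue - total))
}

#' Zero-profit market sensitivity
#'
#' Percentage change in market prices that would drive the mean profit to
#' zero, under the linear profit model (profit falls one-for-one with each
#' euro of added fattening feed cost or lost revenue): the tolerable
#' fattening-diet price increase is `100 * profit / fattening feed cost`,
#' and the tolerable pig price drop is `100 * profit / revenue`.
#'
#' @param mean_profit line mean profit, EUR per pig.
#' @param mean_fattening_feed_cost line mean fattening feed cost, EUR (> 0).
#' @param mean_revenue line mean revenue, EUR (> 0).
#' @return one-row tibble `diet_price_increase_pct`, `pig_price_drop_pct`.
#' @export
zero_profit_sensitivity <- function(mean_profit, mean_fattening_feed_cost, mean_revenue) {
  if (mean_fattening_feed_cost <= 0) stop_arg("`mean_fattening_feed_cost` must be > 0")
  if (mean_revenue <= 0) stop_arg("`mean_revenue` must be > 0")
  tibble(
    diet_price_increase_pct = 100 * mean_profit / mean_fattening_feed_cost,
    pig_price_drop_pct = 100 * mean_profit / mean_revenue
  )
}

#' Relative line differences in profit and environmental impacts
#'
#' For each diet scenario present in `line_means`, the profit gap
#' `100 * (LRFI - HRFI) / LRFI` and the environmental gap, the mean over the
#' four impact categories of `100 * (HRFI - LRFI) / LRFI`.
#'
#' @param line_means tibble with columns `line_id`, `diet`, `profit`, and
#'   the four impact means `gwp`, `ap`, `ep`, `lo`; both lines must be
#'   present for every diet.
#' @return tibble with one row per diet: `diet`, `profit_gap_pct`,
#'   `env_gap_pct`.
#' @export
derived_line_metrics <- function(line_means) {
  need <- c("line_id", "diet", "profit", impact_names())
  missing <- setdiff(need, names(line_means))
  if (length(missing)) stop_arg(paste("line_means missing columns:", paste(missing, collapse = ", ")))
  purrr::map_dfr(unique(line_means$diet), function(d) {
    sub <- line_means[line_means$diet == d, ]
    lr <- sub[sub$line_id == "LRFI", ]
    hr <- sub[sub$line_id == "HRFI", ]
    if (nrow(lr) != 1 || nrow(hr) != 1) stop_arg(sprintf("diet `%s` needs both lines exactly once", d))
    if (lr$profit == 0 || any(as.numeric(lr[1, impact_names()]) == 0)) {
      stop_arg("LRFI denominators must be non-zero")
    }
    env <- mean(vapply(impact_names(), function(k) 100 * (hr[[k]] - lr[[k]]) / lr[[k]], numeric(1)))
    tibble(diet = d,
           profit_gap_pct = 100 * (lr$profit - hr$profit) / lr$profit,
           env_gap_pct = env)
  })
}
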