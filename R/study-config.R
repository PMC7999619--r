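#' Full study configuration
#'
#' Bundles every fixed constant of the study: economic configuration
#' (prices, water:feed ratios, energy per kg gain, labor and capital
#' parameters, fixed costs), the carcass pricing grid, the LCA emission and
#' characterization factors, and the growth-model constants.  All defaults
#' are documented package choices in French-farm magnitudes; every value can
#' be overridden and the whole object round-trips through YAML.
#'
#' @param seed master seed stored with the configuration.
#' @param economic,pricing_grid,lca,growth named lists of overrides for the
#'   respective sections.
#' @return nested list of class `study_config`.
#' @export
generate_study_config <- function(seed = 1, economic = list(), pricing_grid = list(),
                                  lca = list(), growth = list()) {
  eco <- list(
    starter_price_eur_per_kg = 0.45, starter_days = 12,
    postweaning_price_eur_per_kg = 0.32, postweaning_days = 35,
    water_price_eur_per_l = 0.004,
    water_ratio_postweaning = 2.5, water_ratio_fattening = 2.7,   # L per kg feed
    energy_price_eur_per_kwh = 0.10, energy_per_kg_gain_kwh = 0.42,
    n_workers = 2.3, n_sows = 200, weaned_per_sow_yr = 25,
    hours_per_worker_yr = 1600, wage_multiplier = 1.5, min_wage_eur_per_h = 10.03,
    labor_fraction_growing = 0.5, growing_cycle_days = 163,
    investment_per_sow_eur = 2500, interest_rate_per_yr = 0.06,
    fixed_cost_eur_per_pig = 3.5
  )
  grid <- list(
    base_price_eur_per_kg = 1.28, ref_lmp_pct = 56,
    lmp_premium_eur_per_point = 0.02,
    weight_band_kg = c(90, 105), weight_penalty_eur_per_kg_outside = 0.02,
    lmp_valid_range = c(30, 75)
  )
  lca_cfg <- list(
    cp_digestibility = 0.85, n_in_body_protein = 0.16,
    feed_p_g_per_kg = 5.0, feed_k_g_per_kg = 8.0,
    p_retention_g_per_kg_gain = 5.3, k_retention_g_per_kg_gain = 2.0,
    feed_dm_frac = 0.87, dm_digestibility = 0.80, om_frac_of_dm = 0.80,
    housing_n_frac = c(nh3 = 0.25, n2o = 0.01, nox = 0.01, n2 = 0.05),
    field_n_frac = c(nh3 = 0.10, n2o = 0.01, no3_leach = 0.15),
    p_leach_frac = 0.02,
    enteric_ch4_kg_per_pig = 1.5, manure_ch4_kg_per_kg_om = 0.024,
    gwp_kgco2_per_kg_ch4 = 28, gwp_kgco2_per_kg_n2o = 265,
    ap_gso2_per_kg_nh3 = 1880, ap_gso2_per_kg_nox = 700,
    ep_gp_per_kg_p_leached = 1000, ep_gp_per_kg_no3 = 0,
    fertilizer_equivalence = c(n = 0.75, p = 1.0, k = 1.0),
    fertilizer_n_impacts = c(gwp = 3.0, ap = 12, ep = 1.0, lo = 0),   # per kg N
    fertilizer_p_impacts = c(gwp = 1.5, ap = 8, ep = 2.0, lo = 0),
    fertilizer_k_impacts = c(gwp = 0.6, ap = 3, ep = 0.3, lo = 0),
    transport_km = c(farm_factory = 100, cereals = 500, factory_farm = 30),
    transport_impacts_per_tkm = c(gwp = 0.11, ap = 0.5, ep = 0.01, lo = 0.004),
    upstream_piglet_impacts = c(gwp = 85, ap = 800, ep = 30, lo = 150)
  )
  merge_over <- function(base, over, what) {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown)) stop_arg(paste0("unknown ", what, " fields: ", paste(unknown, collapse = ", ")))
    base[names(over)] <- over
    base
  }
  cfg <- list(
    seed = as.integer(seed),
    economic = merge_over(eco, economic, "economic"),
    pricing_grid = merge_over(grid, pricing_grid, "pricing_grid"),
    lca = merge_over(lca_cfg, lca, "lca"),
    growth = do.call(growth_config, growth)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  eco <- cfg$economic
  prices <- c(eco$starter_price_eur_per_kg, eco$postweaning_price_eur_per_kg,
              eco$water_price_eur_per_l, eco$energy_price_eur_per_kwh,
              eco$min_wage_eur_per_h, cfg$pricing_grid$base_price_eur_per_kg)
  if (any(prices < 0)) stop_arg("all prices must be >= 0")
  if (eco$water_ratio_postweaning <= 0 || eco$water_ratio_fattening <= 0) {
    stop_arg("water:feed ratios must be > 0")
  }
  l <- cfg$lca
  fr <- c(l$housing_n_frac, l$field_n_frac, l$p_leach_frac, l$fertilizer_equivalence,
          l$cp_digestibility, l$dm_digestibility)
  if (any(fr < 0 | fr > 1)) stop_arg("all LCA fractions must lie in [0, 1]")
  if (sum(l$housing_n_frac) > 1) stop_arg("housing N emission fractions must sum to <= 1")
  invisible(cfg)
}

#' Write / read a study configuration as YAML
#'
#' @param config `study_config` object.
#' @param path YAML file path.
#' @return `read_study_config()` returns the `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(config, path) {
  # named numeric vectors become YAML maps so their names survive the trip
  friendly <- function(x) {
    if (is.list(x)) lapply(x, friendly)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(friendly(unclass(config)), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml reads numeric vectors back as lists; restore the vector structure
  restore <- function(x) if (is.list(x) && length(x) &&
                             all(vapply(x, is.numeric, logical(1)))) unlist(x) else x
  raw$lca <- lapply(raw$lca, restore)
  raw$pricing_grid <- lapply(raw$pricing_grid, restore)
  raw$growth <- lapply(raw$growth, restore)
  cfg <- structure(raw, class = "study_config")
  validate_study_config(cfg)
  cfg
}
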