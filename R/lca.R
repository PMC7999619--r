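# Simplified cradle-to-farm-gate LCA per pig: feed-chain impacts, nutrient
# mass balance for excreta, a config-driven emission inventory with
# characterization factors, fertilizer credits, and aggregation to the
# functional unit of 1 kg live pig at the farm gate.

#' Nutrient mass balance of a pig's excreta
#'
#' Excretion is intake minus body retention.  Nitrogen intake derives from
#' the diet's digestible crude protein density and the configured CP
#' digestibility (N = CP/6.25); N retention is the protein gain times the
#' body-protein nitrogen fraction.  Phosphorus and potassium use configured
#' per-kg-feed contents and per-kg-gain retentions; dry and organic matter
#' use the configured digestibilities.  Small negative balances are floored
#' at zero with a warning; retention exceeding intake beyond tolerance is a
#' consistency error.
#'
#' @param record one-row performance tibble.
#' @param diet diet tibble.
#' @param library ingredient library.
#' @param config `study_config` (its `lca` section is used).
#' @param tol absolute tolerance (kg) before flooring becomes an error.
#' @return one-row tibble with `*_intake_kg`, `*_retained_kg`,
#'   `*_excreted_kg` for n/p/k plus `dm_excreted_kg`, `om_excreted_kg`.
#' @export
excretion_balance <- function(record, diet, library, config, tol = 1e-3) {
  l <- config$lca
  s <- diet_summary(diet, library)
  fi <- record$total_fi_kg
  gain <- record$bw_slaughter_kg - record$bw0_kg

  n_intake <- fi * (s$dcp_g_per_kg / l$cp_digestibility) / 1000 / 6.25
  n_ret <- (record$bp_kg - record$bp0_kg) * l$n_in_body_protein
  p_intake <- fi * l$feed_p_g_per_kg / 1000
  p_ret <- gain * l$p_retention_g_per_kg_gain / 1000
  k_intake <- fi * l$feed_k_g_per_kg / 1000
  k_ret <- gain * l$k_retention_g_per_kg_gain / 1000

  bal <- function(intake, ret, what) {
    ex <- intake - ret
    if (ex < -tol) {
      abort(sprintf("%s retention (%.3f kg) exceeds intake (%.3f kg); diet and record are inconsistent",
                    what, ret, intake), class = "porkopt_consistency_error")
    }
    if (ex < 0) {
      warn(sprintf("%s balance slightly negative (%.2e kg); floored at 0", what, ex))
      ex <- 0
    }
    ex
  }
  tibble(
    n_intake_kg = n_intake, n_retained_kg = n_ret, n_excreted_kg = bal(n_intake, n_ret, "N"),
    p_intake_kg = p_intake, p_retained_kg = p_ret, p_excreted_kg = bal(p_intake, p_ret, "P"),
    k_intake_kg = k_intake, k_retained_kg = k_ret, k_excreted_kg = bal(k_intake, k_ret, "K"),
    dm_excreted_kg = fi * l$feed_dm_frac * (1 - l$dm_digestibility),
    om_excreted_kg = fi * l$feed_dm_frac * (1 - l$dm_digestibility) * l$om_frac_of_dm
  )
}

#' Cradle-to-farm-gate impacts of one pig, per kg live weight
#'
#' Component structure: (1) feed chain, the incorporation-weighted ingredient
#' impacts times total feed intake plus ingredient transport
#' (farm-to-factory, extra cereal haulage, factory-to-farm, per t km);
#' (2) housing/storage/field emissions from the excreta mass balance
#' (NH3, N2O, NOx, CH4, P leaching) characterised by the configured per-kg
#' factors; (3) amortised upstream sow-litter and postweaning impacts per
#' weaned piglet; minus (4) fertilizer credits for the field-applied N, P
#' and K at the configured synthetic-fertilizer equivalences.  Land
#' occupation receives feed-chain (and upstream) contributions only.  The
#' total is divided by slaughter live weight.
#'
#' @inheritParams excretion_balance
#' @return one-row tibble with, for each category `gwp`, `ap`, `ep`, `lo`:
#'   `<cat>_feed`, `<cat>_emissions`, `<cat>_upstream`, `<cat>_credit`
#'   (subtracted) and the per-kg-LW total `<cat>`; units kg CO2 eq (GWP),
#'   g SO2 eq (AP), g P eq (EP), m2a crop eq (LO) per kg live weight.
#' @export
pig_impacts <- function(record, diet, library, config) {
  l <- config$lca
  s <- diet_summary(diet, library)
  fi <- record$total_fi_kg
  bw <- record$bw_slaughter_kg

  # feed chain: production + transport
  feed <- setNames(as.numeric(s[1, impact_cols()]) * fi, impact_names())
  cereal_share <- if ("category" %in% names(library)) {
    lib <- library[match(diet$ingredient, library$name), ]
    sum(diet$rate_kg_per_kg[lib$category == "cereal"], na.rm = TRUE)
  } else 0
  tkm <- fi / 1000 * (l$transport_km[["farm_factory"]] + l$transport_km[["factory_farm"]] +
                      cereal_share * l$transport_km[["cereals"]])
  feed <- feed + tkm * l$transport_impacts_per_tkm[impact_names()]

  # emission inventory from the excreta balance
  ex <- excretion_balance(record, diet, library, config)
  n_ex <- ex$n_excreted_kg
  n_field <- n_ex * (1 - sum(l$housing_n_frac))
  nh3_n <- n_ex * l$housing_n_frac[["nh3"]] + n_field * l$field_n_frac[["nh3"]]
  n2o_n <- n_ex * l$housing_n_frac[["n2o"]] + n_field * l$field_n_frac[["n2o"]]
  nox_n <- n_ex * l$housing_n_frac[["nox"]]
  ch4 <- l$enteric_ch4_kg_per_pig + l$manure_ch4_kg_per_kg_om * ex$om_excreted_kg
  p_field <- ex$p_excreted_kg
  emis <- c(
    gwp = ch4 * l$gwp_kgco2_per_kg_ch4 + n2o_n * 44 / 28 * l$gwp_kgco2_per_kg_n2o,
    ap = nh3_n * 17 / 14 * l$ap_gso2_per_kg_nh3 + nox_n * 46 / 14 * l$ap_gso2_per_kg_nox,
    ep = p_field * l$p_leach_frac * l$ep_gp_per_kg_p_leached,
    lo = 0
  )

  upstream <- l$upstream_piglet_impacts[impact_names()]

  # fertilizer credits for field-applied nutrients replacing synthetic fertilizer
  applied_n <- n_field * (1 - l$field_n_frac[["nh3"]] - l$field_n_frac[["n2o"]] -
                          l$field_n_frac[["no3_leach"]])
  credit <- l$fertilizer_equivalence[["n"]] * applied_n * l$fertilizer_n_impacts[impact_names()] +
    l$fertilizer_equivalence[["p"]] * p_field * (1 - l$p_leach_frac) * l$fertilizer_p_impacts[impact_names()] +
    l$fertilizer_equivalence[["k"]] * ex$k_excreted_kg * l$fertilizer_k_impacts[impact_names()]

  out <- tibble(.rows = 1)
  for (k in impact_names()) {
    out[[paste0(k, "_feed")]] <- feed[[k]] / bw
    out[[paste0(k, "_emissions")]] <- emis[[k]] / bw
    out[[paste0(k, "_upstream")]] <- upstream[[k]] / bw
    out[[paste0(k, "_credit")]] <- credit[[k]] / bw
    out[[k]] <- (feed[[k]] + emis[[k]] + upstream[[k]] - credit[[k]]) / bw
  }
  out
}

#' Farm-gate environmental score of a scenario
#'
#' Normalises a line-by-diet impact vector to the same line's least-cost
#' baseline.  Default mode is the mean of the per-category ratios (the
#' baseline scores exactly 1); `"literal_sum"` divides the plain sums of the
#' four categories, which mixes units and is provided for comparability
#' only.
#'
#' @param line_impacts named numeric (gwp, ap, ep, lo).
#' @param lc_baseline_impacts named numeric, strictly positive components.
#' @param mode `"mean_ratio"` (default) or `"literal_sum"`.
#' @return scalar score.
#' @export
farmgate_score <- function(line_impacts, lc_baseline_impacts, mode = c("mean_ratio", "literal_sum")) {
  mode <- match.arg(mode)
  x <- unlist(line_impacts)[impact_names()]
  b <- unlist(lc_baseline_impacts)[impact_names()]
  if (any(!is.finite(b)) || any(b <= 0)) {
    abort("baseline impacts must be strictly positive", class = "porkopt_division_error")
  }
  if (mode == "mean_ratio") mean(x / b) else sum(x) / sum(b)
}
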