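#' Build a diet from incorporation rates
#'
#' A diet is a tibble with one row per ingredient: `ingredient`,
#' `rate_kg_per_kg` and `is_additive`.  Non-additive rates are the decision
#' variables of diet formulation; additive rates are fixed by the library
#' (`rate_fixed_kg_per_kg`) and are appended automatically.  Rates must be
#' non-negative and total 1 kg with the additives.
#'
#' @param rates named numeric vector of non-additive incorporation rates,
#'   kg per kg of diet; names must be ingredient names in `library`.
#' @param library ingredient library tibble.
#' @param tol tolerance on the mass-balance identity.
#' @return a diet tibble.
#' @examples
#' lib <- generate_ingredient_library(1)
#' d <- reference_diet(lib)
#' diet_summary(d, lib)
#' @export
new_diet <- function(rates, library, tol = 1e-6) {
  validate_ingredient_library(library)
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) stop_arg("`rates` must be named")
  unknown <- setdiff(names(rates), library$name[!library$is_additive])
  if (length(unknown)) {
    abort(paste("unknown non-additive ingredient(s):", paste(unknown, collapse = ", ")),
          class = "porkopt_reference_error")
  }
  if (any(rates < 0)) stop_arg("incorporation rates must be >= 0")
  non_add <- library$name[!library$is_additive]
  q <- setNames(numeric(length(non_add)), non_add)
  q[names(rates)] <- rates
  adds <- library[library$is_additive, ]
  diet <- tibble(
    ingredient = c(non_add, adds$name),
    rate_kg_per_kg = c(unname(q), adds$rate_fixed_kg_per_kg),
    is_additive = c(rep(FALSE, length(non_add)), rep(TRUE, nrow(adds)))
  )
  total <- sum(diet$rate_kg_per_kg)
  if (abs(total - 1) > tol) {
    stop_arg(sprintf("diet mass is %.8f kg; non-additive rates must sum to 1 kg minus additives", total))
  }
  diet
}

#' Reference commercial diet
#'
#' The fixed cereal/soybean-meal diet used as the shared baseline for both
#' lines: barley 409.4, wheat 327, soybean meal 202, sunflower oil 23 g/kg
#' plus crystalline amino acids, and the standard additive pack.
#'
#' @param library ingredient library containing the reference ingredients.
#' @return a diet tibble.
#' @export
reference_diet <- function(library) {
  new_diet(c(
    barley = 0.4094, wheat = 0.3270, soybean_meal = 0.2020, sunflower_oil = 0.0230,
    l_lysine = 0.0035, l_threonine = 0.0014, l_tryptophan = 0.0003, dl_methionine = 0.0009
  ), library)
}

#' Summarise a diet's nutritional, economic and environmental densities
#'
#' All derived densities are incorporation-rate-weighted sums of the
#' per-ingredient contents: NE density (MJ/kg), nutrient densities (g/kg),
#' price per kg, and the four impact categories per kg and per MJ NE.  Two
#' cost measures are reported: `price_eur_per_mj` is the diet-level price
#' divided by the diet NE density (used by the environmental and joint
#' objectives and the cost cap), while `cost_index_eur_per_mj` is the sum of
#' the non-additive rates weighted by each ingredient's own price-to-NE ratio
#' (the least-cost objective).
#'
#' @param diet diet tibble from [new_diet()].
#' @param library ingredient library tibble.
#' @return one-row tibble of derived densities.
#' @export
diet_summary <- function(diet, library) {
  validate_ingredient_library(library)
  unknown <- setdiff(diet$ingredient, library$name)
  if (length(unknown)) {
    abort(paste("diet refers to unknown ingredient(s):", paste(unknown, collapse = ", ")),
          class = "porkopt_reference_error")
  }
  lib <- library[match(diet$ingredient, library$name), ]
  q <- diet$rate_kg_per_kg
  ne <- sum(q * lib$ne_mj_per_kg)
  dens <- vapply(nutrient_cols(), function(col) sum(q * lib[[col]]), numeric(1))
  imp <- vapply(impact_cols(), function(col) sum(q * lib[[col]]), numeric(1))
  price <- sum(q * lib$price_eur_per_kg)
  non_add <- !lib$is_additive
  cost_index <- sum(q[non_add] * lib$price_eur_per_kg[non_add] / lib$ne_mj_per_kg[non_add])
  out <- tibble(
    ne_mj_per_kg = ne,
    price_eur_per_kg = price,
    price_eur_per_mj = price / ne,
    cost_index_eur_per_mj = cost_index
  )
  for (i in seq_along(nutrient_names())) out[[nutrient_cols()[i]]] <- dens[[i]]
  for (i in seq_along(impact_names())) {
    out[[impact_cols()[i]]] <- imp[[i]]
    out[[paste0(impact_names()[i], "_per_mj")]] <- imp[[i]] / ne
  }
  out
}

#' Nutritional constraint system for line-tailored formulation
#'
#' Encodes the formulation constraints as linear rows over the non-additive
#' incorporation rates q: the mass balance (sum of q equals 1 kg minus the
#' fixed additive mass) and, for each of the five nutrients, the
#' NE-standardized requirement \eqn{\sum_i q_i (X_i - R \, NE_i) = 0}, i.e.
#' the diet supplies exactly R grams of the nutrient per MJ NE.  With
#' `semantics = "at_least"` the nutrient rows become lower bounds.
#'
#' @param library ingredient library.
#' @param requirements one-row tibble or named list with `dcp`, `dlys`,
#'   `dthr`, `dtrp`, `dmet` in g per MJ NE (see [line_requirements()]).
#' @param semantics `"equality"` (default) or `"at_least"` for the nutrient
#'   rows.
#' @return an object of class `constraint_system`: list with matrix `A`,
#'   senses, right-hand side `b`, variable names and the diet mass `M`.
#' @export
build_constraint_system <- function(library, requirements, semantics = c("equality", "at_least")) {
  semantics <- match.arg(semantics)
  validate_ingredient_library(library)
  req <- as.list(requirements)
  missing <- setdiff(nutrient_names(), names(req))
  if (length(missing)) stop_arg(paste("requirements missing:", paste(missing, collapse = ", ")))
  lib <- library[!library$is_additive, ]
  M <- 1 - sum(library$rate_fixed_kg_per_kg[library$is_additive], na.rm = TRUE)
  A <- rbind(rep(1, nrow(lib)))
  sense <- "="
  b <- M
  rn <- "mass"
  for (i in seq_along(nutrient_names())) {
    nm <- nutrient_names()[i]
    R <- as.numeric(req[[nm]])
    if (!is.finite(R) || R < 0) stop_arg(sprintf("requirement `%s` must be a non-negative number", nm))
    A <- rbind(A, lib[[nutrient_cols()[i]]] - R * lib$ne_mj_per_kg)
    sense <- c(sense, if (semantics == "equality") "=" else ">=")
    b <- c(b, 0)
    rn <- c(rn, nm)
  }
  rownames(A) <- rn
  colnames(A) <- lib$name
  structure(
    list(A = A, sense = sense, b = b, vars = lib$name, M = M,
         requirements = req[nutrient_names()], semantics = semantics),
    class = "constraint_system"
  )
}

#' Check a diet against a constraint system
#'
#' Independent residual checker: recomputes every constraint row from the
#' diet's non-additive rates and reports signed residuals relative to the
#' diet mass scale.
#'
#' @param diet diet tibble.
#' @param constraints `constraint_system` object.
#' @param tol tolerance for the `satisfied` flags.
#' @return tibble with one row per constraint: `constraint`, `residual`,
#'   `satisfied`.
#' @export
check_diet <- function(diet, constraints, tol = 1e-6) {
  q <- diet$rate_kg_per_kg[match(constraints$vars, diet$ingredient)]
  if (anyNA(q)) stop_data("diet does not cover all constraint-system ingredients")
  lhs <- as.numeric(constraints$A %*% q)
  resid <- lhs - constraints$b
  ok <- ifelse(constraints$sense == ">=", resid >= -tol, abs(resid) <= tol)
  tibble(constraint = rownames(constraints$A), residual = resid, satisfied = ok & all(q >= -tol))
}
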