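#' Generate a synthetic feed-ingredient library
#'
#' Draws a seeded library of feed ingredients spanning cereal-like (high net
#' energy, low digestible protein), protein-meal-like (lower NE, high
#' digestible protein), oil and pure-amino-acid profiles, plus fixed additive
#' entries (salt, minerals, vitamins analogues) whose incorporation rates are
#' fixed per kg of diet.  Nutrient contents, prices and per-kg environmental
#' impacts are drawn from truncated normal distributions around anchors of
#' published magnitude, so that downstream formulation problems live in a
#' realistic region without copying any database values.
#'
#' @param seed integer seed; identical seeds reproduce identical libraries.
#' @param n_ingredients number of non-additive ingredients (>= 3). The first
#'   anchors cover the classic reference-diet set (wheat, soybean meal,
#'   crystalline amino acids, barley, oil); beyond 14 the cereal/meal anchors
#'   are recycled with numbered names and fresh draws.
#' @param additive_mass total fixed additive mass, kg per kg of diet, in
#'   \[0, 0.2\]. Split across the four additive entries in proportion to the
#'   default 4.5/11/12/5 g split.
#' @return A tibble with one row per ingredient: `name`, `category`,
#'   `ne_mj_per_kg`, `dcp_g_per_kg`, `dlys_g_per_kg`, `dthr_g_per_kg`,
#'   `dtrp_g_per_kg`, `dmet_g_per_kg`, `price_eur_per_kg`,
#'   `gwp_kgco2_per_kg`, `ap_gso2_per_kg`, `ep_gp_per_kg`, `lo_m2a_per_kg`,
#'   `is_additive`, `rate_fixed_kg_per_kg` (additives only, else `NA`).
#' @examples
#' lib <- generate_ingredient_library(seed = 1)
#' sum(lib$rate_fixed_kg_per_kg, na.rm = TRUE)  # 0.0325
#' @export
generate_ingredient_library <- function(seed, n_ingredients = 14, additive_mass = 0.0325) {
  check_number(seed, "seed")
  if (!is.numeric(n_ingredients) || n_ingredients < 3 || n_ingredients != round(n_ingredients)) {
    stop_arg("`n_ingredients` must be an integer >= 3")
  }
  check_number(additive_mass, "additive_mass", lower = 0, upper = 0.2)

  anchors <- ingredient_anchors()
  n <- as.integer(n_ingredients)
  if (n <= nrow(anchors)) {
    base <- anchors[seq_len(n), ]
  } else {
    extra_idx <- rep(which(anchors$category %in% c("cereal", "protein_meal")),
                     length.out = n - nrow(anchors))
    extra <- anchors[extra_idx, ]
    extra$name <- paste0(extra$name, "_", seq_len(nrow(extra)) + 1L)
    base <- bind_rows(anchors, extra)
  }

  withr_seed <- derive_seed(seed, "ingredient_library")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(withr_seed)

  jitter_col <- function(x, cv) {
    out <- x
    pos <- x > 0
    out[pos] <- rnorm_trunc(sum(pos), x[pos], cv * x[pos])
    out
  }
  base$ne_mj_per_kg <- jitter_col(base$ne_mj_per_kg, 0.04)
  for (col in nutrient_cols()) base[[col]] <- jitter_col(base[[col]], 0.06)
  base$price_eur_per_kg <- jitter_col(base$price_eur_per_kg, 0.08)
  for (col in impact_cols()) base[[col]] <- jitter_col(base[[col]], 0.10)
  base$is_additive <- FALSE
  base$rate_fixed_kg_per_kg <- NA_real_

  adds <- additive_entries()
  adds$rate_fixed_kg_per_kg <- adds$rate_fixed_kg_per_kg * additive_mass / sum(adds$rate_fixed_kg_per_kg)
  if (additive_mass == 0) adds <- adds[0, ]

  lib <- bind_rows(as_tibble(base), as_tibble(adds))
  validate_ingredient_library(lib)
  lib
}

# anchor magnitudes: INRA-AFZ-style nutrient contents, 2020-era French market
# prices and Ecoalim-style per-kg impacts; values are package choices, not
# copies of any database row
ingredient_anchors <- function() {
  tribble_df(
    c("name", "category", "ne_mj_per_kg", "dcp_g_per_kg", "dlys_g_per_kg",
      "dthr_g_per_kg", "dtrp_g_per_kg", "dmet_g_per_kg", "price_eur_per_kg",
      "gwp_kgco2_per_kg", "ap_gso2_per_kg", "ep_gp_per_kg", "lo_m2a_per_kg"),
    list("wheat",          "cereal",       10.2,  85, 2.6, 2.3, 1.0, 1.5, 0.185, 0.37, 5.2, 0.45, 1.35),
    list("soybean_meal",   "protein_meal",  8.7, 450, 26.5, 16.8, 5.9, 6.1, 0.330, 0.61, 8.9, 0.75, 2.40),
    list("l_lysine",       "amino_acid",   12.1,   0, 780, 0, 0, 0, 1.45, 5.9, 28.0, 1.8, 0.45),
    list("barley",         "cereal",        9.8,  78, 2.8, 2.4, 0.9, 1.4, 0.165, 0.35, 5.0, 0.42, 1.45),
    list("sunflower_oil",  "oil",          27.5,   0, 0, 0, 0, 0, 0.720, 1.60, 11.0, 0.95, 2.90),
    list("l_threonine",    "amino_acid",   11.4,   0, 0, 760, 0, 0, 1.90, 6.6, 30.0, 2.0, 0.50),
    list("l_tryptophan",   "amino_acid",   12.8,   0, 0, 0, 750, 0, 18.5, 7.5, 34.0, 2.2, 0.55),
    list("dl_methionine",  "amino_acid",   12.5,   0, 0, 0, 0, 940, 2.35, 5.4, 26.0, 1.7, 0.40),
    list("corn",           "cereal",       10.9,  65, 1.9, 2.2, 0.5, 1.5, 0.175, 0.42, 5.6, 0.52, 1.25),
    list("oats",           "cereal",        8.3,  82, 3.2, 2.6, 1.0, 1.6, 0.150, 0.36, 4.8, 0.40, 1.75),
    list("peas",           "protein_meal", 10.0, 185, 12.6, 6.3, 1.5, 1.7, 0.230, 0.33, 4.4, 0.48, 1.95),
    list("triticale",      "cereal",       10.0,  90, 3.1, 2.5, 1.0, 1.5, 0.160, 0.34, 4.9, 0.41, 1.50),
    list("rapeseed_meal",  "protein_meal",  7.1, 280, 14.3, 10.6, 3.4, 5.3, 0.210, 0.52, 7.6, 0.66, 1.60),
    list("sunflower_meal", "protein_meal",  6.8, 250, 8.2, 8.1, 2.8, 5.0, 0.180, 0.45, 6.8, 0.60, 1.70)
  )
}

additive_entries <- function() {
  out <- tribble_df(
    c("name", "category", "price_eur_per_kg", "gwp_kgco2_per_kg",
      "ap_gso2_per_kg", "ep_gp_per_kg", "lo_m2a_per_kg", "rate_fixed_kg_per_kg"),
    list("salt",                "additive", 0.10, 0.15, 1.0, 0.05, 0.01, 0.0045),
    list("calcium_carbonate",   "additive", 0.05, 0.08, 0.5, 0.03, 0.01, 0.0110),
    list("dicalcium_phosphate", "additive", 0.55, 1.50, 9.0, 3.50, 0.05, 0.0120),
    list("vitamins_minerals",   "additive", 2.00, 2.20, 12.0, 1.20, 0.10, 0.0050)
  )
  out$ne_mj_per_kg <- 0
  for (col in nutrient_cols()) out[[col]] <- 0
  out$is_additive <- TRUE
  out
}

# minimal row-wise constructor (tibble::tribble without NSE)
tribble_df <- function(header, ...) {
  rows <- list(...)
  out <- lapply(seq_along(header), function(j) {
    vapply(rows, function(r) r[[j]], FUN.VALUE = if (is.character(rows[[1]][[j]])) character(1) else numeric(1))
  })
  names(out) <- header
  as_tibble(out)
}

#' Validate an ingredient library
#'
#' Checks the structural invariants: positive NE for non-additives,
#' non-negative nutrient contents, prices and impacts, unique names.
#'
#' @param library ingredient tibble as returned by
#'   [generate_ingredient_library()] or read from CSV.
#' @return the library, invisibly; aborts on violation.
#' @export
validate_ingredient_library <- function(library) {
  needed <- c("name", "ne_mj_per_kg", nutrient_cols(), "price_eur_per_kg",
              impact_cols(), "is_additive")
  missing <- setdiff(needed, names(library))
  if (length(missing)) stop_data(paste("library is missing columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(library$name)) stop_data("ingredient names must be unique")
  if (any(library$ne_mj_per_kg[!library$is_additive] <= 0)) {
    stop_data("non-additive ingredients must have NE > 0")
  }
  num <- c("ne_mj_per_kg", nutrient_cols(), "price_eur_per_kg", impact_cols())
  for (col in num) {
    if (any(library[[col]] < 0)) stop_data(sprintf("column `%s` must be >= 0", col))
  }
  invisible(library)
}

#' Write / read an ingredient library CSV
#'
#' Plain-text round trip in the canonical column order.
#'
#' @param library ingredient tibble.
#' @param path file path.
#' @return `read_ingredient_library()` returns the tibble;
#'   `write_ingredient_library()` returns `path` invisibly.
#' @export
write_ingredient_library <- function(library, path) {
  validate_ingredient_library(library)
  utils::write.csv(library, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ingredient_library
#' @export
read_ingredient_library <- function(path) {
  lib <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  lib$is_additive <- as.logical(lib$is_additive)
  validate_ingredient_library(lib)
  lib
}

# save/restore .Random.seed so generators do not perturb the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
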