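test_that("ingredient library is deterministic, seed-sensitive and valid", {
  lib1 <- generate_ingredient_library(seed = 1, n_ingredients = 14, additive_mass = 0.0325)
  lib1b <- generate_ingredient_library(seed = 1, n_ingredients = 14, additive_mass = 0.0325)
  lib2 <- generate_ingredient_library(seed = 2)

  expect_identical(lib1, lib1b)
  expect_equal(sum(!lib1$is_additive), 14)
  expect_equal(sum(lib1$rate_fixed_kg_per_kg, na.rm = TRUE), 0.0325, tolerance = 1e-12)
  expect_true(any(lib1$price_eur_per_kg != lib2$price_eur_per_kg))

  # invariants across random seeds
  for (s in 3:8) {
    lib <- generate_ingredient_library(s)
    expect_silent(validate_ingredient_library(lib))
    expect_true(all(lib$ne_mj_per_kg[!lib$is_additive] > 0))
    expect_true(all(lib$price_eur_per_kg >= 0))
  }
  # the anchors span cereal-like and protein-meal-like profiles
  cereal <- lib1[lib1$category == "cereal", ]
  meal <- lib1[lib1$category == "protein_meal", ]
  expect_gt(mean(cereal$ne_mj_per_kg), mean(meal$ne_mj_per_kg))
  expect_lt(mean(cereal$dcp_g_per_kg), mean(meal$dcp_g_per_kg))
})

test_that("ingredient library rejects invalid arguments and round-trips CSV", {
  expect_error(generate_ingredient_library(1, n_ingredients = 2), class = "porkopt_argument_error")
  expect_error(generate_ingredient_library(1, additive_mass = 0.5), class = "porkopt_argument_error")

  lib <- generate_ingredient_library(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ingredient_library(lib, path)
  back <- read_ingredient_library(path)
  expect_equal(back$ne_mj_per_kg, lib$ne_mj_per_kg, tolerance = 1e-12)
  expect_identical(back$is_additive, lib$is_additive)
})

test_that("population generation is deterministic with the expected contrast", {
  lib <- generate_ingredient_library(1)
  cfg <- line_config("LRFI", n_pigs = 57, seed = 7)
  pop <- generate_population(cfg, lib)
  expect_equal(nrow(pop$profiles), 57)
  expect_equal(length(unique(pop$records$pig_id)), 57)
  expect_true(all(pop$records$bw_kg > 0))
  # contiguous 0-based day indices per pig
  d1 <- pop$records$day[pop$records$pig_id == pop$profiles$pig_id[1]]
  expect_identical(d1, seq_along(d1) - 1L)

  pop_b <- generate_population(line_config("LRFI", n_pigs = 57, seed = 7), lib)
  expect_identical(pop, pop_b)

  # paired-seed line contrast on ADFI
  hr <- generate_population(line_config("HRFI", n_pigs = 57, seed = 7), lib)
  mean_adfi <- function(p) mean(tapply(p$records$fi_kg, p$records$pig_id, mean))
  expect_lt(mean_adfi(pop), mean_adfi(hr))
})

test_that("zero-variance line config yields identical pigs; bad SD errors", {
  lib <- generate_ingredient_library(1)
  cfg <- line_config("LRFI", n_pigs = 2, seed = 3,
                     p_mature_sd = 0, gompertz_b_sd = 0, intake_scale_sd = 0,
                     intake_decay_sd = 0, bw0_sd = 0)
  pop <- generate_population(cfg, lib)
  expect_equal(pop$profiles$p_mature_kg[1], pop$profiles$p_mature_kg[2])
  expect_equal(pop$profiles$intake_scale[1], pop$profiles$intake_scale[2])

  expect_error(line_config("LRFI", p_mature_sd = -1), class = "porkopt_argument_error")
  expect_error(line_config("LRFI", n_pigs = 1), class = "porkopt_argument_error")
})

test_that("LRFI mean FCR is below HRFI on the shared diet across seeds", {
  lib <- generate_ingredient_library(1)
  diet <- reference_diet(lib)
  wins <- 0L
  for (s in 1:10) {
    fcr <- sapply(c("LRFI", "HRFI"), function(l) {
      pop <- generate_population(line_config(l, n_pigs = 8, seed = s), lib)
      mean(sapply(seq_len(8), function(i) {
        simulate_response(pop$profiles[i, ], diet, lib)$fcr
      }))
    })
    wins <- wins + (fcr[["LRFI"]] < fcr[["HRFI"]])
  }
  expect_gte(wins, 9L)
})

test_that("study config carries the documented defaults and survives YAML", {
  cfg <- generate_study_config(seed = 4)
  expect_equal(cfg$economic$water_ratio_fattening, 2.7)
  expect_equal(cfg$economic$water_ratio_postweaning, 2.5)
  expect_equal(cfg$economic$energy_per_kg_gain_kwh, 0.42)
  expect_equal(unname(cfg$lca$fertilizer_equivalence["n"]), 0.75)
  expect_equal(unname(cfg$lca$fertilizer_equivalence["p"]), 1.0)
  expect_equal(unname(cfg$lca$transport_km["farm_factory"]), 100)
  expect_equal(unname(cfg$lca$transport_km["cereals"]), 500)
  expect_equal(unname(cfg$lca$transport_km["factory_farm"]), 30)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$economic, cfg$economic)
  expect_equal(back$lca, cfg$lca, tolerance = 1e-12)
  expect_equal(back$pricing_grid, cfg$pricing_grid)

  expect_error(generate_study_config(economic = list(not_a_field = 1)),
               class = "porkopt_argument_error")
})
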