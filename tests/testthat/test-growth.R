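test_that("daily NE intake is conserved across maintenance and retention", {
  lib <- rich_library()
  d <- single_diet(lib)
  rec <- simulate_response(toy_profile(), d, lib, trace = TRUE)
  tr <- attr(rec, "trace")
  cfg <- growth_config()
  resid <- tr$nei_mj - tr$maint_mj - tr$pd_kg * cfg$ne_protein_mj_per_kg -
    tr$ld_kg * cfg$ne_lipid_mj_per_kg
  expect_lt(max(abs(resid) / tr$nei_mj), 1e-6)
})

test_that("adequate diet lets protein deposition follow the Gompertz potential", {
  lib <- rich_library()
  rec <- simulate_response(toy_profile(), single_diet(lib), lib, trace = TRUE)
  tr <- attr(rec, "trace")
  expect_true(all(tr$limiting == "potential"))
})

test_that("performance record identities and slaughter-weight contract hold", {
  lib <- rich_library()
  d <- single_diet(lib)
  rec <- simulate_response(toy_profile(), d, lib)
  ne_dens <- diet_summary(d, lib)$ne_mj_per_kg
  expect_equal(rec$fcr, rec$total_fi_kg / (rec$bw_slaughter_kg - rec$bw0_kg),
               tolerance = 1e-9)
  expect_equal(rec$ecr_mj_per_kg, rec$fcr * ne_dens, tolerance = 1e-9)
  expect_equal(rec$bp_bl, rec$bp_kg / rec$bl_kg, tolerance = 1e-9)
  # final BW within [target, target + one day's gain]
  expect_gte(rec$bw_slaughter_kg, 120)
  expect_lte(rec$bw_slaughter_kg, 120 + 1.5 * rec$adg_kg_d + 0.5)
})

test_that("raising NE density at fixed nutrient-to-NE ratios only scales feed mass", {
  lib_lo <- rich_library(ne = 9)
  lib_hi <- rich_library(ne = 10.8)
  for (col in c("dcp_g_per_kg", "dlys_g_per_kg", "dthr_g_per_kg",
                "dtrp_g_per_kg", "dmet_g_per_kg")) {
    lib_hi[[col]] <- lib_lo[[col]] * 10.8 / 9     # same g per MJ NE
  }
  r_lo <- simulate_response(toy_profile(), single_diet(lib_lo), lib_lo, trace = TRUE)
  r_hi <- simulate_response(toy_profile(), single_diet(lib_hi), lib_hi, trace = TRUE)
  expect_equal(r_lo$duration_d, r_hi$duration_d)
  expect_equal(attr(r_lo, "trace")$nei_mj, attr(r_hi, "trace")$nei_mj, tolerance = 1e-9)
  expect_equal(r_hi$adfi_kg_d, r_lo$adfi_kg_d * 9 / 10.8, tolerance = 1e-9)
})

test_that("lysine deficiency lengthens fattening and fattens the carcass", {
  lib_ok <- rich_library()
  lib_def <- rich_library(dlys_scale = 0.25)   # well below the requirement
  r_ok <- simulate_response(toy_profile(), single_diet(lib_ok), lib_ok)
  r_def <- simulate_response(toy_profile(), single_diet(lib_def), lib_def)
  expect_gt(r_def$duration_d, r_ok$duration_d)
  expect_gt(r_def$bl_kg, r_ok$bl_kg)
  expect_lt(r_def$lmp_pct, r_ok$lmp_pct)
})

test_that("non-finishing pigs raise an error naming the limit", {
  lib <- rich_library()
  err <- expect_error(
    simulate_response(toy_profile(), single_diet(lib), lib, max_days = 10),
    class = "porkopt_nonfinishing_error"
  )
  expect_match(conditionMessage(err), "10 days")
  expect_error(simulate_response(toy_profile(bw0 = 125), single_diet(lib), lib),
               class = "porkopt_argument_error")
})

test_that("requirement profile peaks early and the summary is the window max", {
  prof <- toy_profile()
  rp <- pig_requirements(prof, window = c(1, 28))
  expect_s3_class(rp$daily, "tbl_df")
  expect_true(all(as.matrix(rp$daily[, -1]) >= 0))
  win <- rp$daily[rp$daily$day <= 28, ]
  expect_equal(rp$summary$dlys, max(win$dlys), tolerance = 1e-12)
  expect_gte(rp$summary$dcp, mean(win$dcp))
  # monotone-decreasing trajectories put the summary at the window start
  if (all(diff(rp$daily$dlys) <= 0)) {
    expect_equal(rp$summary$dlys, rp$daily$dlys[1], tolerance = 1e-12)
  }
  expect_error(pig_requirements(prof, window = c(5, 2)), class = "porkopt_argument_error")
})

test_that("line requirements average per-pig summaries and reject mixed lines", {
  mk <- function(line, dcp, dlys) tibble::tibble(
    pig_id = paste0(line, dcp), line_id = line, dcp = dcp, dlys = dlys,
    dthr = 0.6, dtrp = 0.18, dmet = 0.28)
  one <- line_requirements(mk("LRFI", 10, 0.9))
  expect_equal(one$dcp, 10)
  two <- line_requirements(dplyr::bind_rows(mk("LRFI", 10, 0.8), mk("LRFI", 12, 1.0)))
  expect_equal(two$dcp, 11)
  expect_equal(two$dlys, 0.9)
  expect_error(line_requirements(dplyr::bind_rows(mk("LRFI", 10, 1), mk("HRFI", 12, 1))),
               class = "porkopt_argument_error")
})

test_that("LRFI line requires more protein per MJ NE than HRFI", {
  lib <- generate_ingredient_library(1)
  req <- lapply(c("LRFI", "HRFI"), function(l) {
    pop <- generate_population(line_config(l, n_pigs = 10, seed = 5), lib)
    line_requirements(dplyr::bind_rows(lapply(seq_len(10), function(i) {
      pig_requirements(pop$profiles[i, ])$summary
    })))
  })
  expect_gt(req[[1]]$dcp, req[[2]]$dcp)
  expect_gt(req[[1]]$dlys, req[[2]]$dlys)
})

test_that("RFI regression reproduces hand-computed OLS residuals", {
  rec <- tibble::tibble(
    pig_id = paste0("p", 1:6),
    bw0_kg = c(30, 31, 29, 32, 30, 31),
    bw_slaughter_kg = c(120, 121, 119, 122, 120, 121),
    adg_kg_d = c(0.80, 0.85, 0.78, 0.90, 0.82, 0.88),
    bft_mm = c(15, 16, 14, 17, 15, 16.5),
    adfi_kg_d = c(2.0, 2.2, 1.9, 2.4, 2.1, 2.25)
  )
  out <- compute_rfi(rec)
  expect_equal(sum(out$rfi_kg_d), 0, tolerance = 1e-9)
  # normal-equations oracle
  mbw <- ((rec$bw0_kg + rec$bw_slaughter_kg) / 2)^0.60
  X <- cbind(1, mbw, rec$adg_kg_d, rec$bft_mm)
  beta <- solve(t(X) %*% X, t(X) %*% rec$adfi_kg_d)
  expect_equal(out$rfi_kg_d, as.numeric(rec$adfi_kg_d - X %*% beta), tolerance = 1e-9)

  # exact plane -> all residuals zero
  rec2 <- rec
  rec2$adfi_kg_d <- as.numeric(0.1 + 0.05 * mbw + 0.9 * rec$adg_kg_d + 0.02 * rec$bft_mm)
  expect_equal(compute_rfi(rec2)$rfi_kg_d, rep(0, 6), tolerance = 1e-9)

  expect_error(compute_rfi(rec[1:4, ]), class = "porkopt_argument_error")
  rec3 <- rec
  rec3$bft_mm <- 15
  rec3$adg_kg_d <- 0.8
  rec3$bw0_kg <- 30; rec3$bw_slaughter_kg <- 120
  expect_error(compute_rfi(rec3), class = "porkopt_numerical_error")
})
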