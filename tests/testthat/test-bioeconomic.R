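mk_record <- function(adfi = 2.0, duration = 100, adg = 0.8, carcass = 95.9,
                      lmp = 58, bw0 = 30, bw_sl = 120.5, bp = 19, bp0 = 4.8,
                      bl = 25) {
  tibble::tibble(pig_id = "p1", line_id = "LRFI", adg_kg_d = adg, adfi_kg_d = adfi,
                 total_fi_kg = adfi * duration, fcr = adfi * duration / (bw_sl - bw0),
                 ecr_mj_per_kg = NA_real_, duration_d = duration,
                 bw_slaughter_kg = bw_sl, bw0_kg = bw0, carcass_kg = carcass,
                 bp_kg = bp, bl_kg = bl, bp0_kg = bp0, bp_bl = bp / bl,
                 pd_g_d = (bp - bp0) / duration * 1000,
                 bft_mm = 7 + 0.375 * bl, lmp_pct = lmp)
}

test_that("fattening cost arithmetic matches the spreadsheet oracle", {
  cfg <- generate_study_config()
  fc <- fattening_costs(mk_record(adfi = 2.0, duration = 100), diet_price = 0.25, cfg)
  expect_equal(fc$fat_feed, 0.25 * 2.0 * 100, tolerance = 1e-12)   # 50 EUR
  expect_equal(fc$fat_water, 2.7 * 200 * 0.004, tolerance = 1e-12)
  expect_equal(fc$fat_energy, 0.42 * 0.8 * 100 * 0.10, tolerance = 1e-12)
  # labor: 2.3 workers x 1600 h x 1.5 x 10.03 EUR/h over 5000 weaned pigs,
  # half attributed to the growing phase over a 163-d cycle
  lab_day <- 2.3 * 1600 * 1.5 * 10.03 / (200 * 25) * 0.5 / 163
  expect_equal(fc$fat_labor, lab_day * 100, tolerance = 1e-12)
  cap_day <- 2500 * 0.06 / (25 * 365)
  expect_equal(fc$fat_capital, cap_day * 100, tolerance = 1e-12)

  zero <- fattening_costs(mk_record(duration = 0), diet_price = 0.25, cfg)
  expect_true(all(as.numeric(zero[1, ]) == 0))
  expect_error(fattening_costs(mk_record(), diet_price = -1, cfg),
               class = "porkopt_argument_error")
})

test_that("carcass revenue follows the pricing grid", {
  cfg <- generate_study_config()
  # base point: 100-kg carcass at 56% lean sells at base price x 100
  expect_equal(carcass_revenue(100, 56, cfg), 1.28 * 100, tolerance = 1e-12)
  # monotone in leanness with a positive premium
  expect_gt(carcass_revenue(95.9, 60.7, cfg), carcass_revenue(95.9, 58.5, cfg))
  # zero premium makes the price lean-independent
  flat <- generate_study_config(pricing_grid = list(lmp_premium_eur_per_point = 0))
  expect_equal(carcass_revenue(95, 45, flat), carcass_revenue(95, 65, flat),
               tolerance = 1e-12)
  # out-of-band weight is penalised
  expect_lt(carcass_revenue(110, 56, cfg) / 110, 1.28)
  expect_error(carcass_revenue(95, 80, cfg), class = "porkopt_argument_error")
  expect_error(carcass_revenue(0, 56, cfg), class = "porkopt_argument_error")
})

test_that("profit is revenue minus the full breakdown and decreases with FCR", {
  cfg <- generate_study_config()
  rec <- mk_record()
  pp <- pig_profit(rec, diet_price = 0.25, cfg)
  expect_equal(pp$profit + pp$total_cost, pp$revenue, tolerance = 1e-12)
  comp <- c("weaned_piglet", "pw_feed", "pw_water", "pw_energy", "pw_labor",
            "pw_capital", "fat_feed", "fat_water", "fat_energy", "fat_labor",
            "fat_capital", "fixed")
  expect_equal(sum(as.numeric(pp[1, comp])), pp$total_cost, tolerance = 1e-12)
  expect_true(all(as.numeric(pp[1, comp]) >= 0))

  # higher total FI at identical performance -> strictly lower profit
  worse <- mk_record(adfi = 2.3)
  pp2 <- pig_profit(worse, diet_price = 0.25, cfg)
  expect_lt(pp2$profit, pp$profit)
})

test_that("zero-profit sensitivities reproduce the reported line figures", {
  # minimum margin: reference-diet inefficient line
  s1 <- zero_profit_sensitivity(8.5, 55.9, 128.8)
  expect_equal(s1$diet_price_increase_pct, 15.2, tolerance = 0.02)
  # maximum margin: efficient line on its least-cost diet
  s2 <- zero_profit_sensitivity(17.75, 46.4, 128.6)
  expect_equal(s2$diet_price_increase_pct, 38.25, tolerance = 0.02)
  # joint diet, inefficient line
  s3 <- zero_profit_sensitivity(15.58, 47.8, 127.7)
  expect_equal(s3$diet_price_increase_pct, 32.6, tolerance = 0.02)
  # zero profit needs no price change at all
  s0 <- zero_profit_sensitivity(0, 50, 120)
  expect_equal(s0$diet_price_increase_pct, 0)
  expect_equal(s0$pig_price_drop_pct, 0)
  expect_error(zero_profit_sensitivity(5, 0, 100), class = "porkopt_argument_error")
  expect_error(zero_profit_sensitivity(5, 50, 0), class = "porkopt_argument_error")
})

test_that("derived line metrics match the reported gaps", {
  means <- reported_line_means()
  out <- derived_line_metrics(means)
  ref <- out[out$diet == "reference", ]
  expect_equal(ref$profit_gap_pct, 23.4, tolerance = 0.05)
  expect_equal(ref$env_gap_pct, 7.21, tolerance = 0.02)
  joint <- out[out$diet == "joint", ]
  expect_equal(joint$profit_gap_pct, 7.6, tolerance = 0.05)

  equal <- tibble::tibble(line_id = c("LRFI", "HRFI"), diet = "reference",
                          profit = 10, gwp = 2, ap = 38, ep = 1.2, lo = 4.4)
  eq <- derived_line_metrics(equal)
  expect_equal(eq$profit_gap_pct, 0)
  expect_equal(eq$env_gap_pct, 0)
  expect_error(derived_line_metrics(equal[1, ]), class = "porkopt_argument_error")
})
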