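req_default <- list(dcp = 12, dlys = 0.95, dthr = 0.62, dtrp = 0.18, dmet = 0.28)

test_that("EI score self-normalizes and is linear in the per-MJ impacts", {
  lib <- generate_ingredient_library(2)
  cs <- build_constraint_system(lib, req_default)
  lc <- optimize_least_cost(cs, lib)
  expect_equal(ei_score(lc, lib, lc), 4, tolerance = 1e-12)

  # a diet with every per-MJ impact at half the baseline's scores 2
  toy <- toy_library()
  base_a <- new_diet(c(grain_a = 0.9675), toy)
  half_b <- new_diet(c(grain_b = 0.9675), toy)
  expect_equal(ei_score(half_b, toy, base_a), 2, tolerance = 1e-12)

  # hand-computed four-term sum for an arbitrary diet
  other <- reference_diet(lib)
  s <- diet_summary(other, lib); b <- diet_summary(lc, lib)
  hand <- (s$gwp_kgco2_per_kg / s$ne_mj_per_kg) / (b$gwp_kgco2_per_kg / b$ne_mj_per_kg) +
          (s$ap_gso2_per_kg / s$ne_mj_per_kg) / (b$ap_gso2_per_kg / b$ne_mj_per_kg) +
          (s$ep_gp_per_kg / s$ne_mj_per_kg) / (b$ep_gp_per_kg / b$ne_mj_per_kg) +
          (s$lo_m2a_per_kg / s$ne_mj_per_kg) / (b$lo_m2a_per_kg / b$ne_mj_per_kg)
  expect_equal(ei_score(other, lib, lc), hand, tolerance = 1e-12)
})

test_that("joint score interpolates price ratio and EI score", {
  lib <- generate_ingredient_library(2)
  cs <- build_constraint_system(lib, req_default)
  lc <- optimize_least_cost(cs, lib)
  other <- reference_diet(lib)
  expect_equal(joint_score(lc, lib, lc, w_t = 0.5), 0.5 * 4 + 0.5 * 1, tolerance = 1e-12)
  s <- diet_summary(other, lib); b <- diet_summary(lc, lib)
  expect_equal(joint_score(other, lib, lc, w_t = 0),
               s$price_eur_per_mj / b$price_eur_per_mj, tolerance = 1e-12)
  expect_equal(joint_score(other, lib, lc, w_t = 1),
               ei_score(other, lib, lc), tolerance = 1e-12)
  expect_error(joint_score(other, lib, lc, w_t = 1.2), class = "porkopt_argument_error")
})

test_that("least-score diet beats sampled feasible diets and respects the cap", {
  lib <- generate_ingredient_library(4)
  cs <- build_constraint_system(lib, req_default)
  lc <- optimize_least_cost(cs, lib)
  ls <- optimize_least_score(cs, lib, lc, cost_cap = 1.10)
  expect_true(all(check_diet(ls, cs)$satisfied))
  s_lc <- diet_summary(lc, lib); s_ls <- diet_summary(ls, lib)
  expect_lte(s_ls$price_eur_per_mj, 1.10 * s_lc$price_eur_per_mj + 1e-9)

  # sampling oracle: random feasible mixtures of the LC and least-score diets
  # plus perturbations that stay feasible can never score lower
  score_ls <- ei_score(ls, lib, lc)
  set.seed(99)
  for (i in 1:25) {
    a <- stats::runif(1)
    q <- a * lc$rate_kg_per_kg + (1 - a) * ls$rate_kg_per_kg
    mix <- lc; mix$rate_kg_per_kg <- q
    if (diet_summary(mix, lib)$price_eur_per_mj <= 1.10 * s_lc$price_eur_per_mj + 1e-9) {
      expect_gte(ei_score(mix, lib, lc), score_ls - 1e-8)
    }
  }

  # cap = 1 returns (up to ties) the least-cost price point
  ls1 <- optimize_least_score(cs, lib, lc, cost_cap = 1.0)
  expect_equal(diet_summary(ls1, lib)$price_eur_per_mj, s_lc$price_eur_per_mj,
               tolerance = 1e-6)
})

test_that("trade-off sweep finds the analytic kink on a two-ingredient front", {
  # grain_b has half of every impact of grain_a but twice the price; equal NE
  # makes the joint objective linear, so the optimum flips from the all-a
  # (least-cost) vertex to the all-b vertex at w_t = 1/3
  lib <- toy_library()
  cs <- build_constraint_system(lib, list(dcp = 0, dlys = 0, dthr = 0, dtrp = 0,
                                          dmet = 0), semantics = "at_least")
  lc <- optimize_least_cost(cs, lib)
  expect_equal(lc$rate_kg_per_kg[lc$ingredient == "grain_a"], 0.9675, tolerance = 1e-9)
  sw <- sweep_tradeoff(cs, lib, lc, step = 0.01)
  expect_equal(sw$selected_wt, 0.34, tolerance = 1e-12)
  cv <- tidy(sw)
  expect_true(all(diff(cv$price_eur_per_mj) >= -1e-9))
  expect_true(all(diff(cv$ei_score) <= 1e-9))
  # beyond the kink the optimum is the all-b diet scoring 2
  expect_equal(cv$ei_score[cv$w_t == 0.5], 2, tolerance = 1e-9)
  expect_equal(cv$ei_score[cv$w_t == 0], 4, tolerance = 1e-9)
})

test_that("evolutionary solver reaches the LP optimum within tolerance", {
  for (s in 1:3) {
    lib <- generate_ingredient_library(s)
    cs <- build_constraint_system(lib, req_default)
    lp <- optimize_least_cost(cs, lib, solver = "lp")
    ga <- optimize_least_cost(cs, lib, solver = "nsga2",
                              control = ga_control(pop_size = 150, generations = 800,
                                                   seed = s))
    gap <- (attr(ga, "objective_value") - attr(lp, "objective_value")) /
      attr(lp, "objective_value")
    expect_lt(gap, 0.005)
    expect_true(all(abs(check_diet(ga, cs)$residual) <= 1e-3))
  }
})

test_that("evolutionary least-score run respects constraints and the cap", {
  lib <- generate_ingredient_library(9)
  cs <- build_constraint_system(lib, req_default)
  lc <- optimize_least_cost(cs, lib)
  ga <- optimize_least_score(cs, lib, lc, cost_cap = 1.10, solver = "nsga2",
                             control = ga_control(pop_size = 150, generations = 600,
                                                  seed = 2))
  expect_true(all(abs(check_diet(ga, cs)$residual) <= 1e-3))
  expect_lte(diet_summary(ga, lib)$price_eur_per_mj,
             1.10 * diet_summary(lc, lib)$price_eur_per_mj + 1e-4)
  lp <- optimize_least_score(cs, lib, lc, cost_cap = 1.10, solver = "lp")
  expect_lt(ei_score(ga, lib, lc) - ei_score(lp, lib, lc), 0.02)
})
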