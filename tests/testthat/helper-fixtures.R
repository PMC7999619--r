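# shared fixtures, built in code

# hand-set two-ingredient library with inert additives (easy arithmetic)
toy_library <- function(gwp = c(0.4, 0.2), ap = c(6, 3), ep = c(0.6, 0.3),
                        lo = c(1.5, 0.75), ne = c(10, 10),
                        price = c(0.1, 0.2), additive_mass = 0.0325) {
  tibble::tibble(
    name = c("grain_a", "grain_b", "inert_premix"),
    category = c("cereal", "cereal", "additive"),
    ne_mj_per_kg = c(ne, 0),
    dcp_g_per_kg = c(120, 120, 0),
    dlys_g_per_kg = c(9, 9, 0),
    dthr_g_per_kg = c(6, 6, 0),
    dtrp_g_per_kg = c(1.8, 1.8, 0),
    dmet_g_per_kg = c(2.8, 2.8, 0),
    price_eur_per_kg = c(price, 0),
    gwp_kgco2_per_kg = c(gwp, 0),
    ap_gso2_per_kg = c(ap, 0),
    ep_gp_per_kg = c(ep, 0),
    lo_m2a_per_kg = c(lo, 0),
    is_additive = c(FALSE, FALSE, TRUE),
    rate_fixed_kg_per_kg = c(NA, NA, additive_mass)
  )
}

# single rich ingredient that never limits protein deposition
rich_library <- function(ne = 9.7, dlys_scale = 1) {
  tibble::tibble(
    name = "complete_feed",
    category = "cereal",
    ne_mj_per_kg = ne,
    dcp_g_per_kg = 200,
    dlys_g_per_kg = 14 * dlys_scale,
    dthr_g_per_kg = 10,
    dtrp_g_per_kg = 3,
    dmet_g_per_kg = 5,
    price_eur_per_kg = 0.25,
    gwp_kgco2_per_kg = 0.5,
    ap_gso2_per_kg = 6,
    ep_gp_per_kg = 0.5,
    lo_m2a_per_kg = 1.5,
    is_additive = FALSE,
    rate_fixed_kg_per_kg = NA_real_
  )
}

single_diet <- function(library) {
  rates <- stats::setNames(1 - sum(library$rate_fixed_kg_per_kg, na.rm = TRUE),
                           library$name[!library$is_additive][1])
  new_diet(rates, library)
}

toy_profile <- function(pig_id = "pig_1", p_mature = 32, b = 0.0116,
                        s = 0.377, cdecay = 0.004, bw0 = 30) {
  tibble::tibble(
    pig_id = pig_id, line_id = "LRFI",
    p_mature_kg = p_mature, gompertz_b_per_d = b,
    intake_scale = s, intake_decay_per_kg = cdecay, bw0_kg = bw0,
    p0_kg = NA_real_, l0_kg = NA_real_
  )
}

# brute-force LP oracle: enumerate all basic solutions of {Ax = b, x >= 0}
# and return the minimum objective value
lp_vertex_oracle <- function(obj, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  best <- Inf
  for (cols in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    xb <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(xb) || any(xb < -tol)) next
    x <- numeric(n)
    x[cols] <- xb
    best <- min(best, sum(obj * x))
  }
  best
}
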