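# Line-tailored diet formulation under the nutritional constraint system for
# the three objectives: least cost, least environmental-impact score under a
# cost cap, and the joint weighted blend, each solvable exactly (simplex /
# Charnes-Cooper for the linear-fractional objectives) or with the
# evolutionary solver.

# per-ingredient coefficient vectors in the order of constraints$vars, plus
# the constant contributions of the fixed additives
formulation_coefficients <- function(library, constraints) {
  lib <- library[match(constraints$vars, library$name), ]
  adds <- library[library$is_additive, ]
  wadd <- function(col) sum(adds[[col]] * adds$rate_fixed_kg_per_kg)
  list(
    price = lib$price_eur_per_kg,
    ne = lib$ne_mj_per_kg,
    price_per_ne = lib$price_eur_per_kg / lib$ne_mj_per_kg,
    impacts = lapply(impact_cols(), function(col) lib[[col]]),
    add_price = wadd("price_eur_per_kg"),
    add_impacts = vapply(impact_cols(), wadd, numeric(1))
  )
}

solver_arg <- function(solver) match.arg(solver, c("lp", "nsga2"))

infeasible_stop <- function(res, constraints = NULL) {
  violated <- res$violated
  if (!is.null(constraints)) {
    # a homogeneous row whose coefficients share one sign can never be met by
    # a non-trivial mix; name those rows explicitly
    hopeless <- vapply(seq_len(nrow(constraints$A)), function(i) {
      constraints$b[i] == 0 &&
        (all(constraints$A[i, ] > 1e-12) || all(constraints$A[i, ] < -1e-12))
    }, logical(1))
    if (any(hopeless)) violated <- rownames(constraints$A)[hopeless]
  }
  abort(paste0("constraint system is infeasible; violated constraint(s): ",
               paste(violated, collapse = ", ")),
        class = "porkopt_infeasible_error")
}

diet_from_q <- function(q, library, objective_value, solver, extra = list()) {
  q <- pmax(q, 0)
  # snap tiny numerical residue so the diet invariant holds exactly
  M <- 1 - sum(library$rate_fixed_kg_per_kg[library$is_additive], na.rm = TRUE)
  q <- q * (M / sum(q))
  diet <- new_diet(q, library)
  attr(diet, "objective_value") <- objective_value
  attr(diet, "solver") <- solver
  attr(diet, "report") <- extra
  diet
}

#' Formulate the least-cost diet
#'
#' Minimises the NE-normalised ingredient cost
#' \eqn{\sum_i q_i \, p_i / NE_i} subject to the nutritional constraint
#' system.  The `lp` solver is exact; `nsga2` runs the evolutionary solver
#' with a constraint-violation penalty.
#'
#' @param constraints `constraint_system` from [build_constraint_system()].
#' @param library ingredient library.
#' @param solver `"lp"` (exact) or `"nsga2"` (evolutionary).
#' @param control [ga_control()] settings for the evolutionary solver.
#' @return a diet tibble; attributes `objective_value`, `solver`, `report`.
#' @export
optimize_least_cost <- function(constraints, library, solver = "lp", control = ga_control()) {
  solver <- solver_arg(solver)
  cf <- formulation_coefficients(library, constraints)
  if (solver == "lp") {
    res <- solve_lp(cf$price_per_ne, constraints$A, constraints$sense, constraints$b)
    if (res$status != "optimal") infeasible_stop(res, constraints)
    diet_from_q(res$x, library, res$value, solver)
  } else {
    res <- ga_formulate(list(type = "linear", c = cf$price_per_ne), constraints, control = control)
    diet_from_q(res$q, library, res$value, solver, list(violation = res$violation))
  }
}

#' Environmental-impact score of a diet relative to a baseline
#'
#' Weighted sum over the four impact categories of the diet's per-MJ-NE
#' impact divided by the baseline (least-cost) diet's per-MJ-NE impact.  With
#' unit weights the baseline scores exactly the number of categories (4).
#'
#' @param diet,baseline_lc diet tibbles.
#' @param library ingredient library.
#' @param weights length-4 weights for GWP, AP, EP, LO.
#' @return scalar score.
#' @export
ei_score <- function(diet, library, baseline_lc, weights = rep(1, 4)) {
  if (length(weights) != 4 || any(!is.finite(weights))) stop_arg("`weights` must be 4 finite numbers")
  s <- diet_summary(diet, library)
  b <- diet_summary(baseline_lc, library)
  per_mj <- paste0(impact_names(), "_per_mj")
  bv <- as.numeric(b[1, per_mj])
  if (any(bv <= 0)) {
    abort("baseline diet has a zero per-MJ impact component", class = "porkopt_division_error")
  }
  sum(weights * as.numeric(s[1, per_mj]) / bv)
}

#' Joint cost-environment score
#'
#' Linear blend \eqn{w_t \cdot EI + (1 - w_t) \cdot price\ ratio} where the
#' EI term is [ei_score()] and the price term is the diet's price per MJ NE
#' divided by the baseline's.
#'
#' @inheritParams ei_score
#' @param w_t trade-off weight in \[0, 1\].
#' @return scalar score.
#' @export
joint_score <- function(diet, library, baseline_lc, w_t, weights = rep(1, 4)) {
  check_number(w_t, "w_t", lower = 0, upper = 1)
  s <- diet_summary(diet, library)
  b <- diet_summary(baseline_lc, library)
  w_t * ei_score(diet, library, baseline_lc, weights) +
    (1 - w_t) * s$price_eur_per_mj / b$price_eur_per_mj
}

# fractional objective coefficients (num = c'q + const, den = ne'q) for the
# EI score or the joint score
fractional_objective <- function(cf, base, w_t = 1, weights = rep(1, 4)) {
  num <- numeric(length(cf$ne))
  const <- 0
  for (k in seq_len(4)) {
    num <- num + w_t * weights[k] * cf$impacts[[k]] / base$imp_per_mj[k]
    const <- const + w_t * weights[k] * cf$add_impacts[k] / base$imp_per_mj[k]
  }
  num <- num + (1 - w_t) * cf$price / base$price_per_mj
  const <- const + (1 - w_t) * cf$add_price / base$price_per_mj
  list(num = num, const = const, den = cf$ne)
}

# exact minimisation of (num'q + const) / (den'q) over the constraint system
# (plus optional linear cap rows) via the Charnes-Cooper substitution
# y = t q, t = 1 / den'q
solve_fractional_lp <- function(fobj, constraints, cap = NULL) {
  nq <- length(fobj$num)
  A <- cbind(constraints$A, -constraints$b)     # homogeneous rows in (y, t)
  sense <- constraints$sense
  b <- rep(0, nrow(A))
  A <- rbind(A, c(fobj$den, 0))                 # normalisation den'y = 1
  sense <- c(sense, "=")
  b <- c(b, 1)
  rownames(A) <- c(rownames(constraints$A), "normalisation")
  if (!is.null(cap)) {
    A <- rbind(A, c(cap$a, cap$const))
    sense <- c(sense, "<=")
    b <- c(b, cap$rhs)
    rownames(A)[nrow(A)] <- "cost_cap"
  }
  res <- solve_lp(c(fobj$num, fobj$const), A, sense, b)
  if (res$status != "optimal") infeasible_stop(res, constraints)
  t <- res$x[nq + 1]
  list(q = res$x[seq_len(nq)] / t, value = res$value)
}

#' Formulate the least-environmental-score diet
#'
#' Minimises [ei_score()] relative to the line's least-cost diet subject to
#' the nutritional constraints and a cost cap: the diet's price per MJ NE may
#' not exceed `cost_cap` times the least-cost diet's.
#'
#' @inheritParams optimize_least_cost
#' @param baseline_lc the same line's least-cost diet.
#' @param cost_cap maximum price-per-MJ ratio to the baseline (default 1.10).
#' @param weights impact-category weights.
#' @return a diet tibble.
#' @export
optimize_least_score <- function(constraints, library, baseline_lc, cost_cap = 1.10,
                                 solver = "lp", weights = rep(1, 4), control = ga_control()) {
  solver <- solver_arg(solver)
  check_number(cost_cap, "cost_cap", lower = 0)
  cf <- formulation_coefficients(library, constraints)
  bsum <- diet_summary(baseline_lc, library)
  base <- list(price_per_mj = bsum$price_eur_per_mj,
               imp_per_mj = as.numeric(bsum[1, paste0(impact_names(), "_per_mj")]))
  if (any(base$imp_per_mj <= 0)) {
    abort("baseline diet has a zero per-MJ impact component", class = "porkopt_division_error")
  }
  fobj <- fractional_objective(cf, base, w_t = 1, weights = weights)
  capval <- cost_cap * base$price_per_mj
  if (solver == "lp") {
    # price cap in (y, t): (p - capval * ne)'y + p_add t <= 0
    cap <- list(a = cf$price - capval * cf$ne, const = cf$add_price, rhs = 0)
    res <- solve_fractional_lp(fobj, constraints, cap = cap)
    diet_from_q(res$q, library, res$value, solver)
  } else {
    cap_q <- list(a = cf$price - capval * cf$ne, rhs = -cf$add_price)
    res <- ga_formulate(list(type = "fractional", num = fobj$num,
                             const = fobj$const, den = fobj$den),
                        constraints, extra_ineq = list(cap_q), control = control)
    diet_from_q(res$q, library, res$value, solver, list(violation = res$violation))
  }
}

#' Sweep the cost-environment trade-off weight
#'
#' Optimises the joint score on a grid of `w_t` from 0 to 1 and selects the
#' weight where the reduction in environmental score relative to the
#' least-cost diet, per unit increase in price per MJ NE, is maximal (ratio
#' rule; a discrete-slope alternative is available).  Ties break toward the
#' smaller `w_t`.
#'
#' @inheritParams optimize_least_score
#' @param step grid step for `w_t` (default 0.01).
#' @param select `"ratio"` (default) or `"slope"` selection rule.
#' @return an object of class `tradeoff_curve`: list with the grid tibble
#'   (`w_t`, `price_eur_per_mj`, `ei_score`, `joint_score`), the selected
#'   `w_t`, the selected diet and the baseline summary.
#' @export
sweep_tradeoff <- function(constraints, library, baseline_lc, step = 0.01,
                           solver = "lp", weights = rep(1, 4),
                           select = c("ratio", "slope"), control = ga_control()) {
  solver <- solver_arg(solver)
  select <- match.arg(select)
  check_number(step, "step", lower = 1e-6, upper = 1)
  grid <- seq(0, 1, by = step)
  if (tail(grid, 1) < 1) grid <- c(grid, 1)
  cf <- formulation_coefficients(library, constraints)
  bsum <- diet_summary(baseline_lc, library)
  base <- list(price_per_mj = bsum$price_eur_per_mj,
               imp_per_mj = as.numeric(bsum[1, paste0(impact_names(), "_per_mj")]))
  base_score <- ei_score(baseline_lc, library, baseline_lc, weights)

  diets <- vector("list", length(grid))
  price <- ei <- js <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fobj <- fractional_objective(cf, base, w_t = grid[i], weights = weights)
    if (solver == "lp") {
      res <- solve_fractional_lp(fobj, constraints)
      d <- diet_from_q(res$q, library, res$value, solver)
    } else {
      ctl <- control
      ctl$seed <- control$seed + i
      res <- ga_formulate(list(type = "fractional", num = fobj$num,
                               const = fobj$const, den = fobj$den),
                          constraints, control = ctl)
      d <- diet_from_q(res$q, library, res$value, solver)
    }
    s <- diet_summary(d, library)
    diets[[i]] <- d
    price[i] <- s$price_eur_per_mj
    ei[i] <- ei_score(d, library, baseline_lc, weights)
    js[i] <- res$value
  }

  dprice <- price - base$price_per_mj
  dscore <- base_score - ei
  eps <- 1e-12
  if (all(dprice <= 1e-9)) {
    warn("trade-off curve is degenerate (price constant); selecting smallest w_t with minimal score")
    sel <- which(ei <= min(ei) + 1e-9)[1]
  } else if (select == "ratio") {
    ratio <- ifelse(dprice > 1e-9, dscore / (dprice + eps), -Inf)
    sel <- which(ratio >= max(ratio) - 1e-9)[1]
  } else {
    slope <- c(-Inf, -diff(ei) / pmax(diff(price), eps))
    sel <- which(slope >= max(slope[-1]) - 1e-9)[1]
  }
  structure(
    list(
      curve = tibble(w_t = grid, price_eur_per_mj = price, ei_score = ei, joint_score = js),
      diets = diets,
      selected_wt = grid[sel],
      selected_diet = diets[[sel]],
      baseline = bsum,
      baseline_score = base_score,
      solver = solver
    ),
    class = "tradeoff_curve"
  )
}

#' @export
tidy.tradeoff_curve <- function(x, ...) x$curve

#' @export
glance.tradeoff_curve <- function(x, ...) {
  i <- match(x$selected_wt, x$curve$w_t)
  tibble(selected_wt = x$selected_wt,
         price_eur_per_mj = x$curve$price_eur_per_mj[i],
         ei_score = x$curve$ei_score[i],
         baseline_price_eur_per_mj = x$baseline$price_eur_per_mj,
         baseline_score = x$baseline_score,
         solver = x$solver)
}

#' @export
print.tradeoff_curve <- function(x, ...) {
  cat("Cost-environment trade-off sweep (", nrow(x$curve), " grid points, ",
      x$solver, " solver)\n", sep = "")
  cat("selected w_t =", format(x$selected_wt), "\n")
  print(glance(x))
  invisible(x)
}
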