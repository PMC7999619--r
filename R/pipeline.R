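# Orchestration of the full 2-line x 4-diet study: per-pig simulation,
# economics and LCA per scenario, line statistics, trade-off sweeps and the
# derived line-comparison metrics.

#' Run one line-by-diet scenario
#'
#' Simulates every pig of the line on the diet, then computes the
#' bio-economic cost breakdown, revenue, profit and per-kg-LW impact vector
#' for each pig.
#'
#' @param profiles pig profile tibble (one line).
#' @param diet diet tibble.
#' @param library ingredient library.
#' @param config `study_config`.
#' @param diet_label one of `"reference"`, `"lc"`, `"least_score"`,
#'   `"joint"`.
#' @param line_economics list with `weaned_piglet_price_eur`,
#'   `pw_adfi_kg_d`, `pw_adg_kg_d` (taken from [line_config()] defaults if
#'   omitted).
#' @param target_bw slaughter live weight.
#' @param max_days maximum fattening days per pig before it is flagged
#'   non-finishing.
#' @return object of class `scenario_result`: list with per-pig tibble
#'   `pigs` (performance + economics + impacts), one-row `means` and `sds`
#'   summaries, `line_id`, `diet_label`, and the diet's summary.
#' @export
run_scenario <- function(profiles, diet, library, config,
                         diet_label = c("reference", "lc", "least_score", "joint"),
                         line_economics = NULL, target_bw = 120, max_days = 400) {
  diet_label <- match.arg(diet_label)
  if (is.null(line_economics)) {
    lc <- line_config(profiles$line_id[1], n_pigs = max(2, nrow(profiles)))
    line_economics <- list(weaned_piglet_price_eur = lc$weaned_piglet_price_eur,
                           pw_adfi_kg_d = lc$pw_adfi_kg_d, pw_adg_kg_d = lc$pw_adg_kg_d)
  }
  dsum <- diet_summary(diet, library)
  failed <- character(0)
  rows <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    rec <- tryCatch(
      simulate_response(profiles[i, ], diet, library, config = config$growth,
                        target_bw = target_bw, max_days = max_days),
      porkopt_nonfinishing_error = function(e) e
    )
    if (inherits(rec, "error")) {
      failed <- c(failed, profiles$pig_id[i])
      next
    }
    eco <- pig_profit(rec, dsum$price_eur_per_kg, config,
                      weaned_piglet_price = line_economics$weaned_piglet_price_eur,
                      pw_adfi = line_economics$pw_adfi_kg_d,
                      pw_adg = line_economics$pw_adg_kg_d)
    imp <- pig_impacts(rec, diet, library, config)
    rows[[i]] <- dplyr::bind_cols(rec, eco, imp)
  }
  if (length(failed)) {
    abort(paste0("scenario `", diet_label, "` has non-finishing pig(s): ",
                 paste(failed, collapse = ", ")),
          class = "porkopt_scenario_error")
  }
  pigs <- bind_rows(rows)
  if (nrow(pigs) >= 5) {
    pigs <- compute_rfi(pigs)
  } else {
    pigs$rfi_kg_d <- NA_real_
  }
  num <- names(pigs)[vapply(pigs, is.numeric, logical(1))]
  means <- pigs %>% summarise(across(all_of(num), mean))
  sds <- pigs %>% summarise(across(all_of(num), sd))
  structure(
    list(line_id = profiles$line_id[1], diet_label = diet_label, pigs = pigs,
         means = means, sds = sds, diet = diet, diet_summary = dsum),
    class = "scenario_result"
  )
}

#' @export
tidy.scenario_result <- function(x, ...) x$pigs

#' @export
glance.scenario_result <- function(x, ...) {
  dplyr::bind_cols(tibble(line_id = x$line_id, diet = x$diet_label, n_pigs = nrow(x$pigs)),
                   x$means[, c("adg_kg_d", "adfi_kg_d", "fcr", "duration_d", "profit",
                               impact_names())])
}

#' Two-sample line comparison for one variable
#'
#' Welch's t-test by default (pooled-variance optional) between the same
#' variable of two scenarios sharing a diet label.  Two identical
#' zero-variance samples return p = 1 by convention.
#'
#' @param a,b `scenario_result` objects with the same diet label.
#' @param variable column of the per-pig table.
#' @param var_equal if `TRUE` use the pooled-variance t-test.
#' @return one-row tibble: `variable`, `mean_a`, `mean_b`, `difference`,
#'   `t`, `df`, `p_value`, `significant` (at 0.05).
#' @export
compare_lines <- function(a, b, variable, var_equal = FALSE) {
  if (a$diet_label != b$diet_label) stop_arg("scenarios must share a diet label")
  x <- a$pigs[[variable]]; y <- b$pigs[[variable]]
  if (is.null(x) || is.null(y)) stop_arg(sprintf("variable `%s` not found", variable))
  if (length(x) < 2 || length(y) < 2) stop_arg("need at least 2 pigs per line")
  if (sd(x) == 0 && sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(tibble(variable = variable, mean_a = mean(x), mean_b = mean(y),
                  difference = d, t = if (d == 0) 0 else Inf,
                  df = NA_real_, p_value = if (d == 0) 1 else 0,
                  significant = d != 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(variable = variable, mean_a = mean(x), mean_b = mean(y),
         difference = mean(x) - mean(y), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         significant = tt$p.value < 0.05)
}

#' Correlations of profit and impacts with performance traits
#'
#' Pearson product-moment correlations with Fisher-z 95\% confidence
#' intervals within one scenario.  Constant variables are flagged as
#' undefined rather than dropped.
#'
#' @param result `scenario_result`.
#' @param response column correlated against the traits (default
#'   `"profit"`).
#' @param traits columns to correlate with the response.
#' @return tibble: `variable`, `r`, `ci_lower`, `ci_upper`, `defined`.
#' @export
correlation_table <- function(result, response = "profit",
                              traits = c("adg_kg_d", "fcr", "duration_d", "adfi_kg_d",
                                         "bp_bl", "bft_mm", "pd_g_d", "bl_kg", "bp_kg",
                                         "lmp_pct", impact_names())) {
  pigs <- result$pigs
  if (nrow(pigs) < 4) stop_arg("correlations need at least 4 pigs")
  y <- pigs[[response]]
  purrr::map_dfr(traits, function(v) {
    x <- pigs[[v]]
    if (is.null(x)) stop_arg(sprintf("trait `%s` not found", v))
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(variable = v, r = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, defined = FALSE))
    }
    ct <- stats::cor.test(x, y)
    tibble(variable = v, r = unname(ct$estimate),
           ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2], defined = TRUE)
  })
}

#' Run the complete two-line, four-diet study
#'
#' End-to-end pipeline under a single master seed: generate the ingredient
#' library and both line populations, extract each line's NE-standardized
#' requirements from the early-growth window, formulate the least-cost,
#' least-environmental-score and joint (trade-off-selected) diets per line,
#' simulate all eight line-by-diet scenarios through the bio-economic and
#' LCA models, and derive the line statistics: t-tests, correlations,
#' zero-profit sensitivities and the relative line gaps.
#'
#' @param config `study_config`; its `seed` governs the whole run.
#' @param n_pigs pigs per line.
#' @param solver `"lp"` (default, exact) or `"nsga2"` for all formulations.
#' @param wt_step grid step of the trade-off sweep.
#' @param cost_cap cost cap of the least-score formulation.
#' @param req_window early-growth window (days) for the requirement summary.
#' @param control evolutionary-solver settings when `solver = "nsga2"`.
#' @return object of class `study_result`; see [tidy.study_result()],
#'   [glance.study_result()] and [write_study_tables()].
#' @export
run_study <- function(config = generate_study_config(), n_pigs = 57, solver = "lp",
                      wt_step = 0.01, cost_cap = 1.10, req_window = c(1, 28),
                      control = ga_control()) {
  seed <- config$seed
  library <- generate_ingredient_library(derive_seed(seed, "library"))
  ref <- reference_diet(library)

  lines <- c("LRFI", "HRFI")
  line_cfgs <- lapply(lines, function(l) line_config(l, n_pigs = n_pigs,
                                                    seed = derive_seed(seed, l)))
  names(line_cfgs) <- lines
  pops <- lapply(line_cfgs, generate_population, library = library,
                 growth = config$growth)

  reqs <- lapply(lines, function(l) {
    summaries <- purrr::map_dfr(seq_len(n_pigs), function(i) {
      pig_requirements(pops[[l]]$profiles[i, ], window = req_window,
                       config = config$growth)$summary
    })
    line_requirements(summaries)
  })
  names(reqs) <- lines

  diets <- list()
  curves <- list()
  for (l in lines) {
    cs <- build_constraint_system(library, reqs[[l]])
    lc <- optimize_least_cost(cs, library, solver = solver, control = control)
    ls <- optimize_least_score(cs, library, lc, cost_cap = cost_cap,
                               solver = solver, control = control)
    sw <- sweep_tradeoff(cs, library, lc, step = wt_step, solver = solver,
                         control = control)
    diets[[l]] <- list(reference = ref, lc = lc, least_score = ls,
                       joint = sw$selected_diet)
    curves[[l]] <- sw
  }

  scenario_labels <- c("reference", "lc", "least_score", "joint")
  scenarios <- list()
  for (l in lines) {
    eco <- list(weaned_piglet_price_eur = line_cfgs[[l]]$weaned_piglet_price_eur,
                pw_adfi_kg_d = line_cfgs[[l]]$pw_adfi_kg_d,
                pw_adg_kg_d = line_cfgs[[l]]$pw_adg_kg_d)
    for (d in scenario_labels) {
      scenarios[[paste(l, d, sep = "_")]] <-
        run_scenario(pops[[l]]$profiles, diets[[l]][[d]], library, config,
                     diet_label = d, line_economics = eco)
    }
  }

  line_means <- purrr::map_dfr(scenarios, function(sc) {
    dplyr::bind_cols(tibble(line_id = sc$line_id, diet = sc$diet_label),
                     sc$means[, c("profit", impact_names(), "fat_feed", "revenue",
                                  "fcr", "adfi_kg_d", "adg_kg_d", "duration_d")])
  })

  ttests <- purrr::map_dfr(scenario_labels, function(d) {
    a <- scenarios[[paste0("LRFI_", d)]]
    b <- scenarios[[paste0("HRFI_", d)]]
    vars <- c("adg_kg_d", "adfi_kg_d", "total_fi_kg", "fcr", "ecr_mj_per_kg",
              "duration_d", "pd_g_d", "bl_kg", "bft_mm", "bp_kg", "lmp_pct",
              "bp_bl", "profit", impact_names())
    out <- purrr::map_dfr(vars, function(v) compare_lines(a, b, v))
    out$diet <- d
    out
  })

  correlations <- purrr::map_dfr(names(scenarios), function(nm) {
    out <- correlation_table(scenarios[[nm]])
    out$line_id <- scenarios[[nm]]$line_id
    out$diet <- scenarios[[nm]]$diet_label
    out
  })

  sensitivity <- purrr::map_dfr(seq_len(nrow(line_means)), function(i) {
    zp <- zero_profit_sensitivity(line_means$profit[i], line_means$fat_feed[i],
                                  line_means$revenue[i])
    dplyr::bind_cols(line_means[i, c("line_id", "diet")], zp)
  })

  metrics <- derived_line_metrics(line_means)

  structure(
    list(config = config, library = library, populations = pops,
         requirements = bind_rows(reqs), diets = diets, tradeoff_curves = curves,
         scenarios = scenarios, line_means = line_means, ttests = ttests,
         correlations = correlations, sensitivity = sensitivity, metrics = metrics),
    class = "study_result"
  )
}

#' @export
tidy.study_result <- function(x, ...) x$line_means

#' @export
glance.study_result <- function(x, ...) {
  ref <- x$metrics[x$metrics$diet == "reference", ]
  joint <- x$metrics[x$metrics$diet == "joint", ]
  tibble(
    n_pigs_per_line = nrow(x$scenarios[[1]]$pigs),
    profit_gap_reference_pct = ref$profit_gap_pct,
    profit_gap_joint_pct = joint$profit_gap_pct,
    env_gap_reference_pct = ref$env_gap_pct,
    selected_wt_lrfi = x$tradeoff_curves$LRFI$selected_wt,
    selected_wt_hrfi = x$tradeoff_curves$HRFI$selected_wt
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("Two-line, four-diet sustainability study\n")
  print(glance(x))
  invisible(x)
}

#' Write the study report tables
#'
#' Emits the line-mean, t-test, correlation, sensitivity and derived-metric
#' tables plus the per-pig tables of every scenario as CSV, the per-line
#' diets, and a YAML manifest with the seed and configuration.
#'
#' @param result `study_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(result$line_means, "line_means.csv")
  w(result$ttests, "line_ttests.csv")
  w(result$correlations, "correlations.csv")
  w(result$sensitivity, "zero_profit_sensitivity.csv")
  w(result$metrics, "derived_line_metrics.csv")
  w(result$requirements, "line_requirements.csv")
  for (nm in names(result$scenarios)) {
    w(result$scenarios[[nm]]$pigs, paste0("pigs_", nm, ".csv"))
  }
  for (l in names(result$diets)) {
    d <- purrr::map_dfr(names(result$diets[[l]]), function(lbl) {
      dd <- result$diets[[l]][[lbl]]
      tibble(diet = lbl, ingredient = dd$ingredient,
             rate_g_per_kg = 1000 * dd$rate_kg_per_kg)
    })
    w(d, paste0("diets_", l, ".csv"))
  }
  curves <- purrr::map_dfr(names(result$tradeoff_curves), function(l) {
    cv <- tidy(result$tradeoff_curves[[l]])
    cv$line_id <- l
    cv
  })
  w(curves, "tradeoff_curves.csv")
  yaml::write_yaml(list(seed = result$config$seed,
                        n_pigs = nrow(result$scenarios[[1]]$pigs),
                        generated = "porkopt study run"),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
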