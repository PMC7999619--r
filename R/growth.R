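#' Growth-model configuration
#'
#' Constants of the simplified pig growth model.  The body is tracked as
#' protein (P) and lipid (L) masses; live weight follows the allometry
#' \eqn{BW = (P + L + w_c P^{w_e} + a P) / f} with water coefficient
#' \eqn{w_c}, water exponent \eqn{w_e}, ash fraction \eqn{a} and
#' empty-body fraction \eqn{f} (gut fill 5\%).  Protein growth potential is
#' the Gompertz differential form \eqn{dP/dt = b \, P \ln(P_{mat}/P)}; daily
#' ad libitum NE intake follows the gamma-shaped curve
#' \eqn{NE(BW) = s \, BW e^{-c \, BW}}; maintenance is \eqn{m \, BW^{0.60}}
#' MJ NE/d and retained energy costs 23.6 (protein) and 39.7 (lipid) MJ NE
#' per kg deposited.  Amino-acid-allowed protein deposition uses a fixed
#' marginal efficiency and ideal-protein body contents.  All values are
#' package defaults, exposed here for configuration.
#'
#' @param ... named overrides of the default constants.
#' @return named list of constants.
#' @export
growth_config <- function(...) {
  cfg <- list(
    empty_body_frac = 0.95,
    water_coef = 5.42, water_exp = 0.855, ash_frac = 0.15,
    maint_coef = 0.75, maint_exp = 0.60,
    ne_protein_mj_per_kg = 23.6, ne_lipid_mj_per_kg = 39.7,
    aa_efficiency = 0.72, cp_efficiency = 0.78,
    lys_in_protein = 0.07,
    ideal_ratio = c(dlys = 1, dthr = 0.65, dtrp = 0.19, dmet = 0.30),
    lmp_intercept = 35, lmp_slope = 57,
    bft_intercept = 7, bft_slope = 0.375,
    carcass_frac = 0.793,
    init_p_frac = 0.16
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_arg(paste("unknown growth constants:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

bw_from_composition <- function(p, l, cfg) {
  (p + l + cfg$water_coef * p^cfg$water_exp + cfg$ash_frac * p) / cfg$empty_body_frac
}

initial_composition <- function(bw0, cfg) {
  p0 <- cfg$init_p_frac * bw0
  l0 <- cfg$empty_body_frac * bw0 - p0 - cfg$water_coef * p0^cfg$water_exp - cfg$ash_frac * p0
  if (l0 <= 0) stop_data("initial body weight too low for the body-composition allometry")
  list(p0 = p0, l0 = l0)
}

#' Simulate a pig's response to a diet up to slaughter weight
#'
#' Daily explicit loop: ad libitum NE intake is read from the pig's intake
#' curve (pigs adjust feed intake to dietary NE density, so feed mass is NE
#' intake divided by the diet's NE density); protein deposition is the
#' minimum of the Gompertz potential and the energy-, crude-protein- and
#' amino-acid-allowed rates; lipid deposition takes the residual NE after
#' maintenance.  The loop stops on the first day end-of-day body weight
#' reaches `target_bw` (that day counts fully).
#'
#' @param profile one-row tibble or named list with `pig_id`, `p_mature_kg`,
#'   `gompertz_b_per_d`, `intake_scale`, `intake_decay_per_kg`, `bw0_kg`,
#'   optionally `p0_kg`, `l0_kg`, `line_id` and requirement multipliers
#'   `req_mult_*`.
#' @param diet diet tibble.
#' @param library ingredient library.
#' @param config growth constants from [growth_config()].
#' @param target_bw slaughter live weight, kg (default 120).
#' @param max_days maximum fattening days before a non-finishing error.
#' @param trace if `TRUE`, attach the daily state table as attribute
#'   `"trace"`.
#' @return one-row performance tibble: `pig_id`, `line_id`, `adg_kg_d`,
#'   `adfi_kg_d`, `total_fi_kg`, `fcr`, `ecr_mj_per_kg`, `duration_d`,
#'   `bw_slaughter_kg`, `carcass_kg`, `bp_kg`, `bl_kg`, `bp_bl`, `pd_g_d`,
#'   `bft_mm`, `lmp_pct` (RFI is a population-level quantity, see
#'   [compute_rfi()]).
#' @export
simulate_response <- function(profile, diet, library, config = growth_config(),
                              target_bw = 120, max_days = 400, trace = FALSE) {
  pr <- as.list(profile)
  if (target_bw <= pr$bw0_kg) stop_arg("`target_bw` must exceed the initial body weight")
  s <- diet_summary(diet, library)
  ne_dens <- s$ne_mj_per_kg
  if (ne_dens <= 0) stop_arg("diet has non-positive NE density")
  dens <- setNames(as.numeric(s[1, nutrient_cols()]), nutrient_names())

  cfg <- config
  if (is.null(pr$p0_kg) || is.na(pr$p0_kg)) {
    ic <- initial_composition(pr$bw0_kg, cfg)
    pr$p0_kg <- ic$p0; pr$l0_kg <- ic$l0
  }
  p <- pr$p0_kg; l <- pr$l0_kg
  if (pr$p_mature_kg <= pr$p0_kg) stop_arg("mature protein mass must exceed initial protein mass")
  aa_content <- cfg$lys_in_protein * cfg$ideal_ratio   # g AA per g body protein

  day <- 0L
  total_fi <- 0
  bw <- bw_from_composition(p, l, cfg)
  rows <- if (trace) vector("list", max_days) else NULL
  limiting_last <- "potential"
  repeat {
    if (day >= max_days) {
      abort(sprintf("pig %s did not reach %.0f kg in %d days (limiting factor: %s)",
                    pr$pig_id, target_bw, max_days, limiting_last),
            class = "porkopt_nonfinishing_error")
    }
    day <- day + 1L
    nei <- pr$intake_scale * bw * exp(-pr$intake_decay_per_kg * bw)
    feed <- nei / ne_dens
    maint <- cfg$maint_coef * bw^cfg$maint_exp
    pd_pot <- pr$gompertz_b_per_d * p * log(pr$p_mature_kg / p)
    allowed <- c(
      potential = pd_pot,
      energy = max(nei - maint, 0) / cfg$ne_protein_mj_per_kg,
      dcp = cfg$cp_efficiency * feed * dens[["dcp"]] / 1000,
      dlys = cfg$aa_efficiency * feed * dens[["dlys"]] / 1000 / aa_content[["dlys"]],
      dthr = cfg$aa_efficiency * feed * dens[["dthr"]] / 1000 / aa_content[["dthr"]],
      dtrp = cfg$aa_efficiency * feed * dens[["dtrp"]] / 1000 / aa_content[["dtrp"]],
      dmet = cfg$aa_efficiency * feed * dens[["dmet"]] / 1000 / aa_content[["dmet"]]
    )
    pd <- min(allowed)
    limiting_last <- names(allowed)[which.min(allowed)]
    ld <- max(nei - maint - pd * cfg$ne_protein_mj_per_kg, 0) / cfg$ne_lipid_mj_per_kg
    p <- p + pd
    l <- l + ld
    total_fi <- total_fi + feed
    bw <- bw_from_composition(p, l, cfg)
    if (trace) {
      rows[[day]] <- tibble(day = day, bw_kg = bw, fi_kg = feed, nei_mj = nei,
                            maint_mj = maint, pd_kg = pd, ld_kg = ld,
                            limiting = limiting_last)
    }
    if (bw >= target_bw) break
  }

  gain <- bw - pr$bw0_kg
  out <- tibble(
    pig_id = pr$pig_id,
    line_id = if (!is.null(pr$line_id)) pr$line_id else NA_character_,
    adg_kg_d = gain / day,
    adfi_kg_d = total_fi / day,
    total_fi_kg = total_fi,
    fcr = total_fi / gain,
    ecr_mj_per_kg = (total_fi / gain) * ne_dens,
    duration_d = day,
    bw_slaughter_kg = bw,
    bw0_kg = pr$bw0_kg,
    carcass_kg = cfg$carcass_frac * bw,
    bp_kg = p,
    bl_kg = l,
    bp0_kg = pr$p0_kg,
    bp_bl = p / l,
    pd_g_d = (p - pr$p0_kg) / day * 1000,
    bft_mm = cfg$bft_intercept + cfg$bft_slope * l,
    lmp_pct = cfg$lmp_intercept + cfg$lmp_slope * p / (p + l)
  )
  if (trace) attr(out, "trace") <- bind_rows(rows[seq_len(day)])
  out
}

#' NE-standardized nutrient requirements of a pig
#'
#' Daily requirement of digestible crude protein and the four amino acids,
#' in g per MJ NE, computed from the Gompertz protein-deposition potential
#' (what the pig could deposit under non-limiting nutrition), the marginal
#' deposition efficiencies and the body-protein amino-acid contents, divided
#' by the day's ad libitum NE intake.  The summary is the maximum over the
#' requested early-growth window, where the indicators peak.
#'
#' @param profile pig profile (see [simulate_response()]).
#' @param window integer day range `c(first, last)` for the summary.
#' @param config growth constants.
#' @param target_bw,max_days simulation horizon.
#' @return object of class `requirement_profile`: list with `daily` tibble
#'   (`day`, `dcp`, `dlys`, `dthr`, `dtrp`, `dmet` in g/MJ NE), one-row
#'   `summary` tibble, `pig_id` and `line_id`.
#' @export
pig_requirements <- function(profile, window = c(1, 28), config = growth_config(),
                             target_bw = 120, max_days = 400) {
  pr <- as.list(profile)
  if (length(window) != 2 || window[1] > window[2] || window[1] < 1) {
    stop_arg("`window` must be c(first, last) with 1 <= first <= last")
  }
  cfg <- config
  if (is.null(pr$p0_kg) || is.na(pr$p0_kg)) {
    ic <- initial_composition(pr$bw0_kg, cfg)
    pr$p0_kg <- ic$p0; pr$l0_kg <- ic$l0
  }
  p <- pr$p0_kg; l <- pr$l0_kg
  bw <- bw_from_composition(p, l, cfg)
  aa_content <- cfg$lys_in_protein * cfg$ideal_ratio
  mult <- vapply(nutrient_names(), function(nm) {
    key <- paste0("req_mult_", nm)
    if (!is.null(pr[[key]]) && is.finite(pr[[key]])) pr[[key]] else 1
  }, numeric(1))

  days <- list()
  day <- 0L
  while (bw < target_bw && day < max_days) {
    day <- day + 1L
    nei <- pr$intake_scale * bw * exp(-pr$intake_decay_per_kg * bw)
    maint <- cfg$maint_coef * bw^cfg$maint_exp
    pd_pot <- pr$gompertz_b_per_d * p * log(pr$p_mature_kg / p)
    pd_g <- pd_pot * 1000
    req <- c(
      dcp = pd_g / cfg$cp_efficiency,
      pd_g * aa_content / cfg$aa_efficiency
    ) / nei * mult
    days[[day]] <- tibble(day = day, dcp = req[["dcp"]], dlys = req[["dlys"]],
                          dthr = req[["dthr"]], dtrp = req[["dtrp"]], dmet = req[["dmet"]])
    pd <- min(pd_pot, max(nei - maint, 0) / cfg$ne_protein_mj_per_kg)
    ld <- max(nei - maint - pd * cfg$ne_protein_mj_per_kg, 0) / cfg$ne_lipid_mj_per_kg
    p <- p + pd; l <- l + ld
    bw <- bw_from_composition(p, l, cfg)
  }
  daily <- bind_rows(days)
  if (window[1] > nrow(daily)) stop_arg("`window` lies outside the simulated horizon")
  win <- daily[daily$day >= window[1] & daily$day <= min(window[2], nrow(daily)), ]
  summary <- tibble(
    pig_id = pr$pig_id,
    line_id = if (!is.null(pr$line_id)) pr$line_id else NA_character_,
    dcp = max(win$dcp), dlys = max(win$dlys), dthr = max(win$dthr),
    dtrp = max(win$dtrp), dmet = max(win$dmet)
  )
  structure(list(daily = daily, summary = summary, pig_id = pr$pig_id,
                 line_id = summary$line_id, window = window),
            class = "requirement_profile")
}

#' Representative nutrient requirements of a line
#'
#' Arithmetic mean, per nutrient, of the per-pig early-growth-window maximum
#' requirements of a single line.
#'
#' @param profiles list of `requirement_profile` objects, or a tibble of
#'   per-pig summaries with columns `line_id`, `dcp`, `dlys`, `dthr`,
#'   `dtrp`, `dmet`.
#' @return one-row tibble: `line_id`, `n_pigs`, and the five requirements in
#'   g per MJ NE.
#' @export
line_requirements <- function(profiles) {
  if (inherits(profiles, "requirement_profile")) profiles <- list(profiles)
  tab <- if (is.data.frame(profiles)) as_tibble(profiles)
         else bind_rows(lapply(profiles, function(p) p$summary))
  if (nrow(tab) < 1) stop_arg("at least one requirement profile is needed")
  lines <- unique(tab$line_id)
  if (length(lines) != 1) {
    stop_arg(paste("profiles mix lines:", paste(lines, collapse = ", ")))
  }
  out <- tibble(line_id = lines, n_pigs = nrow(tab))
  for (nm in nutrient_names()) out[[nm]] <- mean(tab[[nm]])
  out
}

#' Residual feed intake within a population
#'
#' Linear regression of ADFI on mean metabolic body weight
#' (\eqn{((BW_0 + BW_{slaughter})/2)^{0.60}}), ADG and back fat thickness;
#' RFI is the residual, so it sums to zero within the population.
#'
#' @param records performance tibble (>= 5 pigs) from [simulate_response()].
#' @param metabolic_exp exponent of the metabolic body weight term.
#' @return `records` with an `rfi_kg_d` column appended.
#' @export
compute_rfi <- function(records, metabolic_exp = 0.60) {
  if (nrow(records) < 5) stop_arg("RFI regression needs at least 5 pigs")
  mbw <- ((records$bw0_kg + records$bw_slaughter_kg) / 2)^metabolic_exp
  X <- cbind(1, mbw, records$adg_kg_d, records$bft_mm)
  if (qr(X)$rank < ncol(X)) {
    abort("RFI predictors are collinear (constant ADG or BFT?)",
          class = "porkopt_numerical_error")
  }
  fit <- lm(records$adfi_kg_d ~ mbw + records$adg_kg_d + records$bft_mm)
  dplyr::mutate(records, rfi_kg_d = as.numeric(resid(fit)))
}
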