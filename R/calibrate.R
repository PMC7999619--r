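#' Calibrate a pig profile from daily records
#'
#' Two-stage least-squares fit of the growth/intake profile to daily body
#' weight and feed intake records.  Stage 1 fits the intake curve: observed
#' NE intake (feed mass times diet NE density) satisfies
#' \eqn{\log(NE/BW) = \log s - c \, BW}, so `intake_scale` and
#' `intake_decay_per_kg` come from a linear regression.  Stage 2 fits the
#' Gompertz parameters (`p_mature_kg`, `gompertz_b_per_d`) by
#' Levenberg-Marquardt on the simulated body-weight trajectory with the
#' stage-1 intake curve.  Initial body composition follows the configured
#' allometry from the first recorded weight.
#'
#' @param records tibble with `pig_id`, `day` (0-based, contiguous),
#'   `bw_kg`, `fi_kg`; at least 20 records spanning at least 30 kg of gain.
#' @param diet diet fed during recording.
#' @param library ingredient library.
#' @param config growth constants.
#' @param start optional named list of starting values
#'   (`p_mature_kg`, `gompertz_b_per_d`).
#' @return one-row profile tibble (as consumed by [simulate_response()])
#'   with attribute `"fit"` carrying RMSEs and convergence diagnostics;
#'   [tidy()] and [glance()] methods are available on that attribute's
#'   class `profile_fit`.
#' @export
calibrate_profile <- function(records, diet, library, config = growth_config(),
                              start = NULL) {
  if (nrow(records) < 20) stop_data("calibration needs at least 20 daily records")
  records <- records[order(records$day), ]
  if (any(diff(records$day) != 1)) stop_data("day indices must be contiguous")
  if (any(records$bw_kg <= 0)) stop_data("body weights must be strictly positive")
  gain <- max(records$bw_kg) - min(records$bw_kg)
  if (gain < 30) stop_data("records must span at least 30 kg of gain")

  s <- diet_summary(diet, library)
  ne_dens <- s$ne_mj_per_kg
  nei <- records$fi_kg * ne_dens
  # records carry start-of-day BW, the weight that drives that day's intake
  bw_obs <- records$bw_kg
  ifit <- lm(log(nei / bw_obs) ~ bw_obs)
  intake_scale <- exp(unname(coef(ifit)[1]))
  intake_decay <- -unname(coef(ifit)[2])
  if (intake_scale <= 0 || !is.finite(intake_decay)) {
    abort("intake-curve fit failed", class = "porkopt_convergence_error")
  }

  bw0 <- records$bw_kg[1]
  ic <- initial_composition(bw0, config)
  pig_id <- if (!is.null(records$pig_id)) records$pig_id[1] else "pig"

  # start-of-day BW trajectory on the recording diet (same deposition rule as
  # the simulator, including nutrient limitation), aligned with the records
  dens <- setNames(as.numeric(s[1, nutrient_cols()]), nutrient_names())
  aa_content <- config$lys_in_protein * config$ideal_ratio
  sim_bw <- function(p_mat, b) {
    p <- ic$p0; l <- ic$l0
    bw <- bw_from_composition(p, l, config)
    out <- numeric(nrow(records))
    out[1] <- bw
    for (d in seq_len(nrow(records) - 1L)) {
      neid <- intake_scale * bw * exp(-intake_decay * bw)
      feed <- neid / ne_dens
      maint <- config$maint_coef * bw^config$maint_exp
      pd <- min(
        b * p * log(p_mat / p),
        max(neid - maint, 0) / config$ne_protein_mj_per_kg,
        config$cp_efficiency * feed * dens[["dcp"]] / 1000,
        min(config$aa_efficiency * feed * dens[c("dlys", "dthr", "dtrp", "dmet")] /
              1000 / aa_content)
      )
      ld <- max(neid - maint - pd * config$ne_protein_mj_per_kg, 0) / config$ne_lipid_mj_per_kg
      p <- p + pd; l <- l + ld
      bw <- bw_from_composition(p, l, config)
      out[d + 1L] <- bw
    }
    out
  }

  st <- list(p_mature_kg = 4.5 * ic$p0, gompertz_b_per_d = 0.012)
  if (!is.null(start)) st[names(start)] <- start
  res_fun <- function(par) {
    p_mat <- exp(par[1]); b <- exp(par[2])
    if (p_mat <= ic$p0 * 1.05) return(rep(1e3, nrow(records)))
    sim_bw(p_mat, b) - records$bw_kg
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(st$p_mature_kg), log(st$gompertz_b_per_d)),
    fn = res_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  )
  if (fit$info %in% c(0, 5, 9)) {
    abort(paste("Gompertz fit did not converge:", fit$message),
          class = "porkopt_convergence_error")
  }
  p_mat <- exp(fit$par[1]); b <- exp(fit$par[2])
  rmse_bw <- sqrt(mean(res_fun(fit$par)^2))
  fi_hat <- intake_scale * bw_obs * exp(-intake_decay * bw_obs) / ne_dens
  rmse_fi <- sqrt(mean((fi_hat - records$fi_kg)^2))

  prof <- tibble(
    pig_id = pig_id,
    line_id = if (!is.null(records$line_id)) records$line_id[1] else NA_character_,
    p_mature_kg = p_mat, gompertz_b_per_d = b,
    intake_scale = intake_scale, intake_decay_per_kg = intake_decay,
    bw0_kg = bw0, p0_kg = ic$p0, l0_kg = ic$l0
  )
  attr(prof, "fit") <- structure(
    list(rmse_bw_kg = rmse_bw, rmse_fi_kg = rmse_fi, n_records = nrow(records),
         nlm_info = fit$info, nlm_message = fit$message,
         deviance = fit$deviance),
    class = "profile_fit"
  )
  prof
}

#' @export
tidy.profile_fit <- function(x, ...) {
  tibble(metric = c("rmse_bw_kg", "rmse_fi_kg", "deviance"),
         value = c(x$rmse_bw_kg, x$rmse_fi_kg, x$deviance))
}

#' @export
glance.profile_fit <- function(x, ...) {
  tibble(rmse_bw_kg = x$rmse_bw_kg, rmse_fi_kg = x$rmse_fi_kg,
         n_records = x$n_records, converged = !(x$nlm_info %in% c(0, 5, 9)))
}
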