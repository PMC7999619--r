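# internal helpers shared across modules

impact_cols <- function() c("gwp_kgco2_per_kg", "ap_gso2_per_kg", "ep_gp_per_kg", "lo_m2a_per_kg")
impact_names <- function() c("gwp", "ap", "ep", "lo")
nutrient_cols <- function() c("dcp_g_per_kg", "dlys_g_per_kg", "dthr_g_per_kg", "dtrp_g_per_kg", "dmet_g_per_kg")
nutrient_names <- function() c("dcp", "dlys", "dthr", "dtrp", "dmet")

stop_arg <- function(msg) abort(msg, class = "porkopt_argument_error")
stop_data <- function(msg) abort(msg, class = "porkopt_data_error")

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_arg(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# deterministic fan-out of a master seed into per-stage seeds (kept < 2^31)
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 131) %% 2147483399) + 1L
}

# truncated-normal draw by resampling (vectorised over mean/sd);
# degenerate sd = 0 returns the mean
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (any(sd < 0)) stop_arg("standard deviations must be >= 0")
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- x <= lower
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmax(x, lower + 1e-9)
}
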