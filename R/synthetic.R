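## Synthetic multi-species phenology panels with the statistical structure
## the empirical analysis assumes: species-level trend/seasonality
## heterogeneity, per-plant random intercepts, lag-1 serial dependence and
## completely-at-random missingness.

#' Describe one species of a synthetic panel
#'
#' @param species_name Label.
#' @param n_plants Number of marked plants (>= 1).
#' @param trend_type `"none"`, `"linear"` or `"nonlinear"`.
#' @param trend_params For `"linear"`: list with `total_change` (logit change
#'   across the whole study span). For `"nonlinear"`: list with `center`
#'   (month index), `half_width` (months), `amplitude` (logit height of a
#'   smooth bump, negative for a bad period).
#' @param seasonal_amplitude Logit amplitude of the annual cosine seasonality
#'   (0 = aseasonal).
#' @param peak_month Calendar month of the seasonal peak in (0, 12].
#' @param re_sd Standard deviation of per-plant random intercepts (logit).
#' @param lag_coef Coefficient of the previous month's fruit state (logit).
#' @param baseline_logit Species baseline on the logit scale.
#' @return A `"species_profile"` list.
#' @export
species_profile <- function(species_name, n_plants,
                            trend_type = c("none", "linear", "nonlinear"),
                            trend_params = list(),
                            seasonal_amplitude = 0, peak_month = 1,
                            re_sd = 0, lag_coef = 0, baseline_logit = 0) {
  trend_type <- match.arg(trend_type)
  stopifnot(n_plants >= 1, seasonal_amplitude >= 0, re_sd >= 0)
  structure(list(species_name = species_name, n_plants = as.integer(n_plants),
                 trend_type = trend_type, trend_params = trend_params,
                 seasonal_amplitude = seasonal_amplitude,
                 peak_month = peak_month, re_sd = re_sd,
                 lag_coef = lag_coef, baseline_logit = baseline_logit),
            class = "species_profile")
}

## trend contribution of a profile at month indices t (span n_months)
profile_trend <- function(profile, t, n_months) {
  switch(profile$trend_type,
         none = rep(0, length(t)),
         linear = {
           tc <- profile$trend_params$total_change %||% 1.5
           tc * (t - (n_months + 1) / 2) / (n_months - 1)
         },
         nonlinear = {
           ctr <- profile$trend_params$center %||% (0.6 * n_months)
           hw <- profile$trend_params$half_width %||% 9
           amp <- profile$trend_params$amplitude %||% 1.5
           b <- amp * exp(-0.5 * ((t - ctr) / hw)^2)
           b - mean(amp * exp(-0.5 * ((seq_len(n_months) - ctr) / hw)^2))
         })
}

profile_seasonal <- function(profile, calendar_month) {
  profile$seasonal_amplitude *
    cos(2 * pi * (calendar_month - profile$peak_month) / 12)
}

## Which of the five core structures a profile embodies.
profile_structure <- function(profile) {
  seas <- profile$seasonal_amplitude > 0
  switch(profile$trend_type,
         nonlinear = if (seas) "M1" else "M3",
         linear = if (seas) "M2" else "M3",   # see default_bwindi_profiles
         none = if (seas) "M4" else "M5")
}

#' Default species profiles emulating the Bwindi panel structure
#'
#' Thirty-three species totalling 249 plants, 25 of which have at least five
#' plants (229 plants in total) and form the focal set for species-level
#' analyses. Generating structures for the focal species are spread over the
#' five core model types in roughly the proportions reported for the
#' empirical analysis (M1:7, M2:5, M3:9, M4:1, M5:3); the eight small
#' species are assigned structures cyclically. Effect sizes are illustrative
#' defaults on the logit scale chosen so that the structures are detectable
#' at these sample sizes: seasonal amplitude ~1.2, linear total change ~1.8,
#' nonlinear bump amplitude ~1.8, per-plant intercept sd 0.5, lag coefficient
#' 0.8.
#'
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return List of 33 [species_profile()] objects.
#' @export
default_bwindi_profiles <- function(seed = 1) {
  set.seed(seed)
  focal_sizes <- c(5, 5, 5, 6, 6, 6, 7, 7, 7, 8, 8, 8, 9, 9, 9,
                   10, 10, 11, 11, 12, 12, 13, 14, 15, 16)   # sums to 229
  small_sizes <- c(1, 2, 2, 2, 3, 3, 3, 4)                   # sums to 20
  structures <- c(rep("M1", 7), rep("M2", 5), rep("M3", 9), "M4",
                  rep("M5", 3))
  structures <- sample(structures)                            # over focal
  small_struct <- rep(c("M1", "M2", "M3", "M4", "M5"), length.out = 8)
  sizes <- c(focal_sizes, small_sizes)
  strs <- c(structures, small_struct)
  n_months <- 95L
  profiles <- vector("list", 33L)
  for (i in seq_len(33L)) {
    st <- strs[i]
    seas_amp <- if (st %in% c("M1", "M2", "M4")) stats::runif(1, 1.0, 1.5) else 0
    trend_type <- switch(st, M1 = "nonlinear", M2 = "linear",
                         M3 = "nonlinear", "none")
    tp <- switch(trend_type,
                 linear = list(total_change = sample(c(-1, 1), 1) *
                                 stats::runif(1, 1.4, 2.2)),
                 nonlinear = list(center = stats::runif(1, 0.35, 0.75) * n_months,
                                  half_width = stats::runif(1, 7, 12),
                                  amplitude = sample(c(-1, 1), 1,
                                                     prob = c(0.3, 0.7)) *
                                    stats::runif(1, 1.5, 2.2)),
                 list())
    profiles[[i]] <- species_profile(
      species_name = sprintf("sp%02d", i), n_plants = sizes[i],
      trend_type = trend_type, trend_params = tp,
      seasonal_amplitude = seas_amp,
      peak_month = stats::runif(1, 0.5, 12.5) %% 12 + 0.5,
      re_sd = 0.5, lag_coef = 0.8,
      baseline_logit = stats::rnorm(1, -0.4, 0.4))
  }
  profiles
}

#' Generate a multi-species presence/absence phenology panel
#'
#' Per plant-month, the fruiting probability is
#' `plogis(baseline + trend(t) + seasonal(calendar) + b_k +
#' lag_coef * y[t-1])` with plant intercepts `b_k ~ N(0, re_sd^2)`; the first
#' month of each plant has no lag contribution. Missingness is applied
#' completely at random at `missing_rate`.
#'
#' @param profiles List of [species_profile()]s.
#' @param n_months Number of consecutive months (default 95).
#' @param missing_rate Missing-completely-at-random rate in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param start_month Calendar month of `month_index = 1` (default 9,
#'   September).
#' @return A phenology panel data frame (plant_id, species, month_index,
#'   calendar_month, status with `NA` for missing).
#' @export
generate_panel <- function(profiles, n_months = 95L, missing_rate = 0.06,
                           seed = 1, start_month = 9) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 0.5)
    stop("'missing_rate' must be in [0, 0.5)")
  set.seed(seed)
  tvec <- seq_len(n_months)
  cal <- calendar_of(tvec, start_month)
  rows <- list()
  plant_no <- 0L
  for (pr in profiles) {
    trend <- profile_trend(pr, tvec, n_months)
    seas <- profile_seasonal(pr, cal)
    base <- pr$baseline_logit + trend + seas
    for (k in seq_len(pr$n_plants)) {
      plant_no <- plant_no + 1L
      b_k <- if (pr$re_sd > 0) stats::rnorm(1, 0, pr$re_sd) else 0
      y <- numeric(n_months)
      eta1 <- base[1L] + b_k
      y[1L] <- stats::rbinom(1L, 1L, stats::plogis(eta1))
      if (n_months > 1L) for (t in 2L:n_months) {
        eta <- base[t] + b_k + pr$lag_coef * y[t - 1L]
        y[t] <- stats::rbinom(1L, 1L, stats::plogis(eta))
      }
      rows[[plant_no]] <- data.frame(
        plant_id = sprintf("%s_p%03d", pr$species_name, plant_no),
        species = pr$species_name, month_index = tvec,
        calendar_month = cal, status = y)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  if (missing_rate > 0) {
    miss <- stats::runif(nrow(panel)) < missing_rate
    panel$status[miss] <- NA_real_
  }
  panel
}
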