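## Simulation study of P-value reliability and credible-interval coverage:
## generate monthly presence/absence data for 20 plants over 120 months from
## known interannual and seasonal component functions, fit the full additive
## model, and summarize smooth-term tests and band coverage.

#' Reconstructed data-generating component functions
#'
#' Piecewise interannual and periodic seasonal functions on the logit scale
#' used by the simulation study. The interannual component has two good
#' fruiting episodes (within study years 3 and 8) and one bad episode (year
#' 5): sub-annual plateaus of height `trend_amp` (negated for the bad
#' episode, default months 28--35, 54--59 and 88--95) with one-month linear
#' ramps at the edges, mean-centered over the 120-month span so the trend is
#' relative to the constant baseline probability of one half. The episodes
#' are deliberately shorter than a calendar year: only then does their
#' calendar-phase content leak into the seasonal smooth when the trend-only
#' structure generates the data, the behavior the simulation study
#' quantifies. The seasonal component is an annual triangular pulse with
#' minimum `seas_min` rising linearly to `seas_peak` at `peak_month` over
#' `pulse_half` months and back.
#'
#' The published study drew these component functions from archived tables
#' that are no longer available; the shapes here are reconstructions, and
#' the amplitudes were calibrated once against the published summary
#' proportions and then frozen (see the package vignette and
#' `scripts/calibrate_generating_functions.R`), so downstream summary
#' statistics are approximate by construction.
#'
#' @param trend_amp Plateau height of the interannual episodes (logit
#'   scale).
#' @param events List of episodes, each a list with `lo`/`hi` (first/last
#'   month of the plateau) and `sgn` (+1 good, -1 bad).
#' @param seas_min,seas_peak Minimum and peak of the seasonal pulse (logit).
#' @param peak_month Calendar month of the seasonal peak.
#' @param pulse_half Months from pulse onset to peak.
#' @param baseline Baseline logit (0 gives probability one half).
#' @return List of class `"generating_functions"`: `s1` (function of month
#'   index 1..120), `s2` (periodic function of calendar month), `baseline`.
#' @export
generating_functions <- function(trend_amp = 1.4,
                                 events = list(
                                   list(lo = 28, hi = 35, sgn = 1),
                                   list(lo = 54, hi = 59, sgn = -1),
                                   list(lo = 88, hi = 95, sgn = 1)),
                                 seas_min = -0.5, seas_peak = 1.2,
                                 peak_month = 2, pulse_half = 5,
                                 baseline = 0) {
  raw_s1 <- function(t) {
    v <- numeric(length(t))
    for (e in events) {
      ramp <- pmin(pmax(pmin(t - (e$lo - 1), e$hi + 1 - t), 0), 1)
      v <- v + e$sgn * trend_amp * ramp
    }
    v
  }
  ctr <- mean(raw_s1(1:120))
  s1 <- function(t) raw_s1(t) - ctr
  s2 <- function(cal) {
    d <- abs(((cal - peak_month + 6) %% 12) - 6)   # cyclic distance to peak
    seas_min + (seas_peak - seas_min) * pmax(0, 1 - d / pulse_half)
  }
  structure(list(s1 = s1, s2 = s2, baseline = baseline,
                 trend_amp = trend_amp, events = events,
                 seas_min = seas_min, seas_peak = seas_peak,
                 peak_month = peak_month, pulse_half = pulse_half),
            class = "generating_functions")
}

#' Simulate one presence/absence panel from a core model structure
#'
#' Each plant-month is an independent Bernoulli draw with logit probability
#' `baseline` plus the scenario's components: M1 = trend + seasonality,
#' M3 = trend only, M4 = seasonality only, M5 = constant. No individual
#' heterogeneity, autocorrelation or missingness (the simulation study
#' isolates smooth-term inference).
#'
#' @param scenario One of `"M1"`, `"M3"`, `"M4"`, `"M5"`.
#' @param n_plants,n_months Panel dimensions (defaults 20 plants, 120
#'   months).
#' @param funcs A [generating_functions()] list.
#' @param seed Integer seed.
#' @return A phenology panel data frame (species `"sim"`, no missingness).
#' @export
generate_sim_panel <- function(scenario = c("M1", "M3", "M4", "M5"),
                               n_plants = 20L, n_months = 120L,
                               funcs = generating_functions(), seed = 1) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  tvec <- seq_len(n_months)
  cal <- calendar_of(tvec, 1)
  eta <- rep(funcs$baseline, n_months)
  if (scenario %in% c("M1", "M3")) eta <- eta + funcs$s1(tvec)
  if (scenario %in% c("M1", "M4")) eta <- eta + funcs$s2(cal)
  p <- stats::plogis(eta)
  rows <- lapply(seq_len(n_plants), function(k) {
    data.frame(plant_id = sprintf("sim_p%02d", k), species = "sim",
               month_index = tvec, calendar_month = cal,
               status = stats::rbinom(n_months, 1L, p))
  })
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  panel
}

#' Fraction of points covered by a band
#'
#' The average coverage statistic: the fraction of evaluation points at
#' which `lower <= target <= upper`.
#'
#' @param band A [credible_band()].
#' @param target Numeric vector of the same length as the band.
#' @return A number in `[0, 1]`.
#' @export
coverage_statistic <- function(band, target) {
  stopifnot(inherits(band, "credible_band"),
            length(target) == length(band$eval_points))
  mean(band$lower <= target & target <= band$upper)
}

## centered version of a true component function on an evaluation grid, for
## comparison with the sum-to-zero-constrained fitted smooth
centered_target <- function(f, grid) {
  v <- f(grid)
  v - mean(v)
}

#' Run the smooth-term inference simulation study
#'
#' For each scenario and replicate: simulate a panel with
#' [generate_sim_panel()], fit the full model M1 (cubic trend smooth of the
#' month index plus cyclic seasonal smooth of the calendar month), and
#' record the Wald P-value of each smooth, the coverage of the true
#' (centered) component functions by each smooth's 95% credible band at the
#' monthly evaluation points, and the fraction of points whose band contains
#' the zero function. Replicate fit failures are dropped and counted.
#'
#' @param scenarios Character vector among `"M1"`, `"M3"`, `"M4"`, `"M5"`.
#' @param n_reps Replicates per scenario.
#' @param n_plants,n_months Panel dimensions.
#' @param funcs A [generating_functions()] list.
#' @param seed Master seed; per-replicate seeds are derived
#'   deterministically.
#' @param level Credible level of the bands (default 0.95).
#' @param k_trend,k_season Maximum basis dimensions of the two smooths
#'   (defaults 10 and 8).
#' @return A `"simulation_report"` list: `results` (one row per scenario and
#'   replicate with p-values, coverages and zero-containment fractions),
#'   `failed` counts, and the configuration. `summary()` aggregates the
#'   quantities of interest.
#' @export
run_sim_experiment <- function(scenarios = c("M1", "M3", "M4", "M5"),
                               n_reps = 200L, n_plants = 20L,
                               n_months = 120L,
                               funcs = generating_functions(), seed = 1,
                               level = 0.95, k_trend = 10L, k_season = 8L) {
  stopifnot(all(scenarios %in% c("M1", "M3", "M4", "M5")), n_reps >= 1L)
  tvec <- seq_len(n_months)
  cal_grid <- calendar_of(tvec, 1)
  s1_true <- centered_target(funcs$s1, tvec)
  s2_true_at <- funcs$s2(cal_grid)
  s2_true <- s2_true_at - mean(s2_true_at)
  form <- stats::as.formula(sprintf(
    "status ~ s(month_index, k = %d) + s(calendar_month, k = %d, bs = \"cc\")",
    k_trend, k_season))
  out <- list()
  failed <- stats::setNames(integer(length(scenarios)), scenarios)
  for (sc in scenarios) {
    design <- NULL
    for (r in seq_len(n_reps)) {
      rep_seed <- (seed * 1000L + match(sc, c("M1", "M3", "M4", "M5")) * 100000L
                   + r) %% .Machine$integer.max
      panel <- generate_sim_panel(sc, n_plants, n_months, funcs,
                                  seed = rep_seed)
      if (is.null(design)) {
        design <- build_design(form, panel)
      } else {
        design$y <- as.numeric(panel$status)   # same covariates every rep
      }
      fit <- tryCatch(select_lambda_ml(design), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        failed[sc] <- failed[sc] + 1L
        next
      }
      t1 <- smooth_test(fit, "s(month_index)")
      t2 <- smooth_test(fit, "s(calendar_month)")
      b1 <- credible_band(fit, "s(month_index)", tvec, level = level)
      b2 <- credible_band(fit, "s(calendar_month)", cal_grid, level = level)
      zero <- rep(0, n_months)
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, rep = r,
        p_s1 = t1$p_value, p_s2 = t2$p_value,
        edf_s1 = t1$edf, edf_s2 = t2$edf,
        cover_s1 = coverage_statistic(b1, s1_true),
        cover_s2 = coverage_statistic(b2, s2_true),
        zero_s1 = coverage_statistic(b1, zero),
        zero_s2 = coverage_statistic(b2, zero))
    }
  }
  structure(list(results = do.call(rbind, out), failed = failed,
                 config = list(scenarios = scenarios, n_reps = n_reps,
                               n_plants = n_plants, n_months = n_months,
                               seed = seed, level = level,
                               k_trend = k_trend, k_season = k_season,
                               funcs = funcs[setdiff(names(funcs),
                                                     c("s1", "s2"))])),
            class = "simulation_report")
}

#' @export
summary.simulation_report <- function(object, ...) {
  res <- object$results
  agg <- lapply(split(res, res$scenario), function(d) {
    data.frame(scenario = d$scenario[1], n = nrow(d),
               reject_s1 = mean(d$p_s1 < 0.05),
               reject_s2 = mean(d$p_s2 < 0.05),
               cover_s1 = mean(d$cover_s1), cover_s2 = mean(d$cover_s2),
               zero_s1 = mean(d$zero_s1), zero_s2 = mean(d$zero_s2))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("Simulation study: %d scenario(s) x %d replicates (%d failures)\n",
              length(x$config$scenarios), x$config$n_reps, sum(x$failed)))
  print(summary(x), digits = 3)
  invisible(x)
}
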