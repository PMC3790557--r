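## The five core model structures over a phenology panel, and the two-step
## selection procedure (likelihood ratio screening, then zero-function
## inspection of the credible bands).

model_formula <- function(label, with_mixed, k_trend, k_season) {
  s1 <- sprintf("s(month_index, k = %d)", k_trend)
  s2 <- sprintf("s(calendar_month, k = %d, bs = \"cc\")", k_season)
  rhs <- switch(label,
                M1 = paste(s1, s2, sep = " + "),
                M2 = paste("month_index", s2, sep = " + "),
                M3 = s1,
                M4 = s2,
                M5 = "1",
                stop("unknown model label '", label, "'"))
  if (with_mixed) rhs <- paste(rhs, "+ lag_status")
  stats::as.formula(paste("status ~", rhs))
}

## terms present in each structure (besides intercept/lag/random effects)
model_terms <- function(label) {
  switch(label,
         M1 = c("s1", "s2"), M2 = c("lin", "s2"), M3 = "s1",
         M4 = "s2", M5 = character(0))
}

terms_to_label <- function(terms) {
  if (setequal(terms, c("s1", "s2"))) "M1"
  else if (setequal(terms, c("lin", "s2")) || setequal(terms, "lin")) "M2"
  else if (setequal(terms, "s1")) "M3"
  else if (setequal(terms, "s2")) "M4"
  else "M5"
}

#' Assemble the design of one core model structure
#'
#' Builds the [build_design()] object for one of the five structures: M1
#' (smooth trend + cyclic seasonality), M2 (linear trend + cyclic
#' seasonality), M3 (smooth trend only), M4 (seasonality only), M5
#' (intercept only). With `with_mixed = TRUE` (the empirical-data
#' configuration) every structure additionally includes the lag-1 fruit
#' state as a parametric term and per-plant random intercepts; the first
#' month of each plant is dropped by [add_lag()].
#'
#' @param label `"M1"` to `"M5"`.
#' @param panel A complete phenology panel (impute first if needed).
#' @param with_mixed Include lag term and random intercepts?
#' @param k_trend,k_season Maximum basis dimensions (defaults 10 and 8).
#' @return A `"pgamm_design"` with attribute `label`.
#' @export
assemble_model <- function(label, panel, with_mixed = TRUE,
                           k_trend = 10L, k_season = 8L) {
  label <- match.arg(label, c("M1", "M2", "M3", "M4", "M5"))
  panel <- validate_panel(panel, complete = TRUE)
  if (with_mixed) panel <- add_lag(panel)
  design <- build_design(model_formula(label, with_mixed, k_trend, k_season),
                         panel,
                         random = if (with_mixed) ~ plant_id else NULL)
  attr(design, "label") <- label
  design
}

#' Fit one core model structure by maximum likelihood
#'
#' @inheritParams assemble_model
#' @param ... Passed to [select_lambda_ml()].
#' @return A `"pgamm"` fit with attribute `label`.
#' @export
fit_model <- function(label, panel, with_mixed = TRUE,
                      k_trend = 10L, k_season = 8L, ...) {
  design <- assemble_model(label, panel, with_mixed, k_trend, k_season)
  fit <- select_lambda_ml(design, ...)
  attr(fit, "label") <- attr(design, "label")
  fit
}

## zero-exclusion month count for one smooth of a fit
zero_exclusion <- function(fit, term, grid) {
  cb <- credible_band(fit, term, grid, level = 0.95)
  excl <- sum(cb$lower > 0 | cb$upper < 0)
  list(count = excl, fraction = excl / length(grid))
}

#' Two-step model selection for one panel
#'
#' Step 1 screens by likelihood ratio tests: the full model M1 is tested
#' against the null M5; if M5 is not rejected at `alpha` it is chosen.
#' Otherwise M1 is tested against each reduced structure M2, M3, M4 and the
#' most parsimonious structure not rejected against M1 is chosen (parsimony
#' by structural degrees of freedom, ties broken by the larger LRT P-value);
#' if all are rejected, M1 stands. Step 2 inspects the chosen structure's
#' smooths against the zero function: the trend smooth is retained only if
#' its 95% band excludes zero for at least `s1_months` months of the study
#' span, the seasonal smooth only if it excludes zero for at least
#' `s2_months` of 12 mid-calendar-month points; smooths failing the rule are
#' demoted (dropped), and the final label is the structure spanned by the
#' surviving terms.
#'
#' @param panel A complete phenology panel.
#' @param alpha Step-1 test level (default 0.05).
#' @param with_mixed Include lag + random intercepts in every structure.
#' @param s1_months,s2_months Step-2 retention thresholds (defaults 10 and
#'   2, the permissive ends of the 10--12 / 2--3 month guidance).
#' @param k_trend,k_season Basis dimensions.
#' @param keep_fits Keep all five fits in the result (memory-heavy).
#' @return A `"model_decision"`: `chosen`, `step1_choice`, `comparisons`
#'   (list of LRTs), `zero_exclusion` fractions per smooth, `demoted` flag,
#'   `fit` (the fit of the step-1 structure), `unreliable` flag if any
#'   component fit failed to converge.
#' @export
two_step_select <- function(panel, alpha = 0.05, with_mixed = TRUE,
                            s1_months = 10L, s2_months = 2L,
                            k_trend = 10L, k_season = 8L,
                            keep_fits = FALSE) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("'alpha' must be in (0, 1)")
  labels <- c("M1", "M2", "M3", "M4", "M5")
  fits <- lapply(labels, function(lb)
    fit_model(lb, panel, with_mixed, k_trend, k_season))
  names(fits) <- labels
  unreliable <- any(!vapply(fits, function(f) f$converged, TRUE))

  comparisons <- list()
  cmp_null <- lrt(fits$M1, fits$M5)
  cmp_null$full_label <- "M1"; cmp_null$nested_label <- "M5"
  comparisons[["M1_vs_M5"]] <- cmp_null
  if (cmp_null$p_value >= alpha) {
    step1 <- "M5"
  } else {
    cand <- data.frame(label = c("M2", "M3", "M4"),
                       df_struct = NA_real_, p = NA_real_)
    for (i in seq_len(nrow(cand))) {
      lb <- cand$label[i]
      cmp <- lrt(fits$M1, fits[[lb]])
      cmp$full_label <- "M1"; cmp$nested_label <- lb
      comparisons[[paste0("M1_vs_", lb)]] <- cmp
      cand$p[i] <- cmp$p_value
      cand$df_struct[i] <- structural_df(fits[[lb]])
    }
    keep <- cand[cand$p >= alpha, , drop = FALSE]
    step1 <- if (nrow(keep)) {
      keep <- keep[order(keep$df_struct, -keep$p), , drop = FALSE]
      keep$label[1]
    } else "M1"
  }

  fit1 <- fits[[step1]]
  terms <- model_terms(step1)
  ze_s1 <- ze_s2 <- NA_real_
  final_terms <- terms
  months_grid <- sort(unique(panel$month_index))
  ## the conditional (lagged) likelihood drops each plant's first month, so
  ## band inspection uses the months the model was actually fitted on
  if (with_mixed) months_grid <- months_grid[-1L]
  cal_grid <- seq(0.5, 11.5, by = 1)
  if ("s1" %in% terms) {
    ze <- zero_exclusion(fit1, "s(month_index)", months_grid)
    ze_s1 <- ze$fraction
    if (ze$count < s1_months) final_terms <- setdiff(final_terms, "s1")
  }
  if ("s2" %in% terms) {
    ze <- zero_exclusion(fit1, "s(calendar_month)", cal_grid)
    ze_s2 <- ze$fraction
    if (ze$count < s2_months) final_terms <- setdiff(final_terms, "s2")
  }
  chosen <- terms_to_label(final_terms)
  demoted <- !identical(chosen, step1)
  final_fit <- if (identical(chosen, step1)) fit1 else fits[[chosen]]
  structure(list(chosen = chosen, step1_choice = step1,
                 comparisons = comparisons,
                 zero_exclusion_fraction_s1 = ze_s1,
                 zero_exclusion_fraction_s2 = ze_s2,
                 demoted = demoted, unreliable = unreliable,
                 fit = final_fit, step1_fit = fit1,
                 fits = if (keep_fits) fits else NULL,
                 alpha = alpha),
            class = "model_decision")
}

#' @export
print.model_decision <- function(x, ...) {
  cat(sprintf("Two-step model selection: chosen %s (step 1: %s%s)%s\n",
              x$chosen, x$step1_choice,
              if (x$demoted) ", demoted at step 2" else "",
              if (x$unreliable) "  [component fit not converged]" else ""))
  for (cmp in x$comparisons)
    cat(sprintf("  %s vs %s: chi-sq = %.2f, df = %d, p = %.4g\n",
                cmp$full_label, cmp$nested_label, cmp$statistic, cmp$df,
                cmp$p_value))
  if (!is.na(x$zero_exclusion_fraction_s1))
    cat(sprintf("  trend smooth zero-exclusion fraction: %.2f\n",
                x$zero_exclusion_fraction_s1))
  if (!is.na(x$zero_exclusion_fraction_s2))
    cat(sprintf("  seasonal smooth zero-exclusion fraction: %.2f\n",
                x$zero_exclusion_fraction_s2))
  invisible(x)
}

## JSON-friendly summary of a decision
decision_to_list <- function(decision, species = NA_character_) {
  list(species = species, chosen = decision$chosen,
       step1_choice = decision$step1_choice,
       demoted = decision$demoted, unreliable = decision$unreliable,
       zero_exclusion_s1 = decision$zero_exclusion_fraction_s1,
       zero_exclusion_s2 = decision$zero_exclusion_fraction_s2,
       comparisons = lapply(decision$comparisons, function(cmp)
         list(full = cmp$full_label, nested = cmp$nested_label,
              statistic = cmp$statistic, df = cmp$df, p = cmp$p_value)))
}
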