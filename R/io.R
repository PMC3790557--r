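## Panel readers/writers, run configuration and the end-to-end pipeline.

#' Read a phenology panel from CSV
#'
#' Expects columns plant_id, species, month_index, calendar_month, status;
#' missing status encoded as `NA` or empty. The panel is validated (see
#' [validate_panel()]) with all problems reported together.
#'
#' @param path CSV file path.
#' @return A validated phenology panel data frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (file.size(path) == 0L) stop("empty panel file: ", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (nrow(panel) == 0L) stop("empty panel file (no data rows): ", path)
  validate_panel(panel)
  panel[order(panel$plant_id, panel$month_index), , drop = FALSE]
}

#' Write a phenology panel to CSV
#'
#' Round-trips with [read_panel()]: missing status written as `NA`.
#'
#' @param panel A phenology panel.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel[, panel_columns, drop = FALSE], path,
                   row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

default_config <- function() {
  list(seed = 1, alpha = 0.05, min_species_n = 5L,
       with_mixed = TRUE, k_trend = 10L, k_season = 8L,
       s1_months = 10L, s2_months = 2L,
       community = TRUE, n_months = 95L, missing_rate = 0.06,
       start_month = 9, panel_path = NULL, out_dir = NULL)
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  if (!(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1))
    stop("config: 'alpha' must be in (0, 1)")
  if (!(is.numeric(cfg$missing_rate) && cfg$missing_rate >= 0 &&
        cfg$missing_rate < 0.5))
    stop("config: 'missing_rate' must be in [0, 0.5)")
  if (cfg$k_trend < 3 || cfg$k_season < 4)
    stop("config: basis dimensions too small")
  if (!(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed)))
    stop("config: 'seed' must be an integer")
  cfg
}

#' Run the full phenology analysis pipeline
#'
#' Executes the end-to-end analysis on a panel: HMM imputation of missing
#' months, per-species two-step model selection (species at or above the
#' focal sample-size threshold), per-species trend classification, and an
#' optional community-level selection over all plants pooled. If no panel
#' path is configured, a synthetic panel is generated from
#' [default_bwindi_profiles()]. Per-species failures are isolated and
#' reported; the pipeline continues.
#'
#' @param config Named list (or YAML file path) overriding the defaults:
#'   `seed`, `alpha`, `min_species_n`, `with_mixed`, `k_trend`, `k_season`,
#'   `s1_months`, `s2_months`, `community`, `n_months`, `missing_rate`,
#'   `start_month`, `panel_path`, `out_dir`. All validation happens before
#'   any computation.
#' @return A list with the completed `panel`, per-species `decisions`,
#'   `trend_labels` matrix, `model_counts` (step-1 and final counts over
#'   M1--M5), optional `community` decision, `failures`, and the run
#'   `manifest`. When `out_dir` is set, panel, imputation mask, decisions
#'   (JSON), comparisons and labels (CSV) and the manifest (JSON) are also
#'   written there.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)

  if (!is.null(cfg$panel_path)) {
    panel <- read_panel(cfg$panel_path)
  } else {
    profiles <- default_bwindi_profiles(seed = cfg$seed)
    panel <- generate_panel(profiles, n_months = cfg$n_months,
                            missing_rate = cfg$missing_rate,
                            seed = cfg$seed, start_month = cfg$start_month)
    attr(panel, "profiles") <- profiles
  }
  message("pipeline: imputing missing months")
  completed <- impute_panel(panel)
  mask <- attr(completed, "imputation_mask")

  counts <- table(factor(completed$species,
                         levels = unique(completed$species)),
                  useNA = "no")
  plants_per_species <- tapply(completed$plant_id, completed$species,
                               function(z) length(unique(z)))
  focal <- names(plants_per_species)[plants_per_species >= cfg$min_species_n]
  months <- sort(unique(completed$month_index))
  ## with the lagged likelihood the first study month is never fitted
  if (isTRUE(cfg$with_mixed)) months <- months[-1L]

  decisions <- list()
  labels_list <- list()
  failures <- character(0)
  for (sp in focal) {
    sub <- completed[completed$species == sp, , drop = FALSE]
    message("pipeline: selecting model for ", sp,
            " (", plants_per_species[[sp]], " plants)")
    dec <- tryCatch(
      two_step_select(sub, alpha = cfg$alpha, with_mixed = cfg$with_mixed,
                      s1_months = cfg$s1_months, s2_months = cfg$s2_months,
                      k_trend = cfg$k_trend, k_season = cfg$k_season),
      error = function(e) e)
    if (inherits(dec, "error")) {
      warning("species ", sp, " failed: ", conditionMessage(dec))
      failures <- c(failures, sp)
      next
    }
    decisions[[sp]] <- dec
    labels_list[[sp]] <- classify_trend(dec, months = months)
  }
  labels <- if (length(labels_list)) {
    sort_species_by_trend(trend_label_matrix(labels_list, months))
  } else NULL

  chosen <- vapply(decisions, `[[`, "", "chosen")
  step1 <- vapply(decisions, `[[`, "", "step1_choice")
  model_counts <- data.frame(
    model = c("M1", "M2", "M3", "M4", "M5"),
    step1 = as.integer(table(factor(step1, levels = paste0("M", 1:5)))),
    final = as.integer(table(factor(chosen, levels = paste0("M", 1:5)))))

  community <- NULL
  if (isTRUE(cfg$community)) {
    message("pipeline: community-level selection (",
            length(unique(completed$plant_id)), " plants)")
    community <- tryCatch(
      two_step_select(completed, alpha = cfg$alpha,
                      with_mixed = cfg$with_mixed,
                      s1_months = cfg$s1_months, s2_months = cfg$s2_months,
                      k_trend = cfg$k_trend, k_season = cfg$k_season),
      error = function(e) {
        warning("community-level selection failed: ", conditionMessage(e))
        NULL
      })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenogamm")),
    config = cfg[order(names(cfg))],
    n_plants = length(unique(completed$plant_id)),
    n_species = length(unique(completed$species)),
    n_focal_species = length(focal),
    n_imputed = nrow(mask),
    failures = failures,
    model_counts = model_counts,
    community_chosen = if (!is.null(community)) community$chosen else NA,
    stage_status = list(impute = "ok",
                        select = if (length(failures)) "partial" else "ok",
                        classify = "ok"))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(completed, file.path(cfg$out_dir, "panel_completed.csv"))
    utils::write.csv(mask, file.path(cfg$out_dir, "imputation_mask.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(names(decisions), function(sp)
      decision_to_list(decisions[[sp]], sp)),
      file.path(cfg$out_dir, "decisions.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(labels)) {
      ldf <- data.frame(species = rep(rownames(labels), times = ncol(labels)),
                        month_index = rep(as.integer(colnames(labels)),
                                          each = nrow(labels)),
                        label = as.vector(labels))
      utils::write.csv(ldf, file.path(cfg$out_dir, "trend_labels.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(panel = completed, decisions = decisions, trend_labels = labels,
       model_counts = model_counts, community = community,
       failures = failures, manifest = manifest)
}
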