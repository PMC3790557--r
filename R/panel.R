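## Phenology panel helpers: long-format tables with one row per
## (plant, month), columns plant_id, species, month_index, calendar_month,
## status (0/1/NA).

panel_columns <- c("plant_id", "species", "month_index", "calendar_month",
                   "status")

#' Validate a phenology panel
#'
#' Checks the long-format panel contract: required columns, one row per
#' (plant, month), contiguous month indices per plant, binary (or missing)
#' status, and calendar months consistent with a common offset of the month
#' index. Problems are collected and reported together.
#'
#' @param panel A data frame.
#' @param complete If `TRUE`, missing status values are also an error.
#' @return The panel, invisibly, ordered by (plant_id, month_index).
#' @export
validate_panel <- function(panel, complete = FALSE) {
  problems <- character(0)
  if (!is.data.frame(panel) || nrow(panel) == 0L) {
    stop("empty or non-data-frame panel input")
  }
  missing_cols <- setdiff(panel_columns, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  panel <- panel[order(panel$plant_id, panel$month_index), , drop = FALSE]
  bad_status <- !(panel$status %in% c(0, 1) | is.na(panel$status))
  if (any(bad_status))
    problems <- c(problems,
                  paste0("non-binary status in row(s) ",
                         paste(utils::head(which(bad_status), 5L),
                               collapse = ", ")))
  if (complete && anyNA(panel$status))
    problems <- c(problems, "panel contains missing status values")
  key <- paste(panel$plant_id, panel$month_index)
  if (anyDuplicated(key))
    problems <- c(problems,
                  paste0("duplicated (plant, month) rows, e.g. ",
                         key[anyDuplicated(key)]))
  by_plant <- split(panel$month_index, panel$plant_id)
  noncontig <- names(by_plant)[vapply(by_plant, function(mi)
    any(diff(mi) != 1L), TRUE)]
  if (length(noncontig))
    problems <- c(problems,
                  paste0("non-contiguous month_index for plant(s) ",
                         paste(utils::head(noncontig, 5L), collapse = ", ")))
  ## calendar month must be a fixed cyclic offset of month_index
  cal <- ((panel$calendar_month - panel$month_index) %% 12)
  if (length(unique(round(cal, 8))) > 1L)
    problems <- c(problems,
                  "calendar_month is not a consistent offset of month_index")
  if (length(problems))
    stop("invalid phenology panel:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(panel)
}

#' Add the lag-1 fruit state to a completed panel
#'
#' Builds the within-plant lagged status column used to capture temporal
#' autocorrelation. The first observation of each plant's series has no lag
#' and is dropped (the model likelihood conditions on each plant's first
#' month). Lags never leak across plants.
#'
#' @param panel A complete (no missing status) phenology panel.
#' @return The panel ordered by (plant, month) with a `lag_status` column and
#'   first rows removed; the number of dropped rows is in
#'   `attr(, "dropped_first_obs")`.
#' @export
add_lag <- function(panel) {
  panel <- validate_panel(panel, complete = TRUE)
  ord <- order(panel$plant_id, panel$month_index)
  panel <- panel[ord, , drop = FALSE]
  first <- !duplicated(panel$plant_id)
  lagv <- c(NA_real_, panel$status[-nrow(panel)])
  lagv[first] <- NA_real_
  panel$lag_status <- lagv
  out <- panel[!first, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_first_obs") <- sum(first)
  out
}

## calendar month in (0, 12] for month index t and a start calendar month
calendar_of <- function(month_index, start_month = 1) {
  ((start_month - 1 + month_index - 1) %% 12) + 1
}
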