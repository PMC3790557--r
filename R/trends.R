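## Qualitative per-month trend labels from each species' final selected
## model: positive where the trend smooth's 95% band lies above zero,
## negative where it lies below, none otherwise.

#' Classify the monthly trend direction of one species
#'
#' Applies the labeling rule to a model decision: for structures with a
#' smooth interannual trend (M1, M3) the label at month `t` is `positive`
#' when the lower 95% credible limit of the trend smooth is above zero,
#' `negative` when the upper limit is below zero, `none` otherwise; for the
#' linear-trend structure M2 the label is the sign of the slope at all
#' months provided its 95% interval excludes zero (otherwise `none`, so
#' noise is not labeled as trend); for M4 and M5 the label is `none`
#' everywhere.
#'
#' @param decision A [two_step_select()] result.
#' @param fit The corresponding final fit (default `decision$fit`).
#' @param months Month indices at which to label.
#' @return Character vector over `months` with values `"positive"`,
#'   `"negative"`, `"none"`.
#' @export
classify_trend <- function(decision, fit = decision$fit, months) {
  stopifnot(inherits(decision, "model_decision"))
  chosen <- decision$chosen
  if (chosen %in% c("M4", "M5"))
    return(rep("none", length(months)))
  if (is.null(fit)) stop("no fitted model available for classification")
  if (chosen == "M2") {
    i <- match("month_index", names(fit$coefficients))
    if (is.na(i)) stop("linear trend coefficient not found in the fit")
    est <- fit$coefficients[i]
    se <- sqrt(fit$Vp[i, i])
    z <- stats::qnorm(0.975)
    lab <- if (est - z * se > 0) "positive"
    else if (est + z * se < 0) "negative"
    else "none"
    return(rep(lab, length(months)))
  }
  cb <- credible_band(fit, "s(month_index)", months, level = 0.95)
  ifelse(cb$lower > 0, "positive", ifelse(cb$upper < 0, "negative", "none"))
}

#' Build the species-by-month trend label matrix
#'
#' @param labels_list Named list (by species) of [classify_trend()] vectors,
#'   all over the same months.
#' @param months The common month indices.
#' @return A `"trend_labels"` character matrix (species x months) with the
#'   months as column names.
#' @export
trend_label_matrix <- function(labels_list, months) {
  stopifnot(length(labels_list) >= 1)
  mat <- do.call(rbind, labels_list)
  rownames(mat) <- names(labels_list)
  colnames(mat) <- months
  structure(mat, class = c("trend_labels", class(mat)))
}

#' Order species from most positive to most negative trending
#'
#' Sorts the rows of a trend label matrix by (number of positive months
#' minus number of negative months), descending; ties are broken by species
#' name.
#'
#' @param labels A [trend_label_matrix()].
#' @return The reordered matrix.
#' @export
sort_species_by_trend <- function(labels) {
  score <- rowSums(labels == "positive") - rowSums(labels == "negative")
  ord <- order(-score, rownames(labels))
  labels[ord, , drop = FALSE]
}

#' Heatmap of qualitative trend labels
#'
#' @param x A `"trend_labels"` matrix.
#' @param ... Passed to [graphics::image()].
#' @export
plot.trend_labels <- function(x, ...) {
  lv <- c(negative = 1, none = 2, positive = 3)
  z <- matrix(lv[x], nrow(x), ncol(x))
  graphics::image(x = as.numeric(colnames(x)), y = seq_len(nrow(x)),
                  z = t(z[rev(seq_len(nrow(x))), , drop = FALSE]),
                  col = c("grey40", "white", "black"),
                  xlab = "month index", ylab = "", yaxt = "n", zlim = c(1, 3),
                  ...)
  graphics::axis(2, at = seq_len(nrow(x)), labels = rev(rownames(x)),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}
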