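#' Screen heat metrics by joint significance
#'
#' First selection stage: a metric survives if the joint Wald F-test of its
#' heat regressors rejects at level `alpha`.
#'
#' @param fits a named list of [fe_lpm()] fits, one per candidate metric.
#' @param alpha significance level (default 0.05).
#' @return character vector of surviving metric names, with attribute
#'   `"screened_out"`: a named character vector of reasons.
#' @export
screen_joint_significance <- function(fits, alpha = 0.05) {
  if (!length(fits)) stop("no fitted models supplied")
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$metric, character(1))
  }
  p <- vapply(fits, function(f) f$F_heat$p_value, numeric(1))
  keep <- !is.na(p) & p < alpha
  out <- names(fits)[keep]
  reasons <- setNames(rep("failed joint F screen", sum(!keep)), names(fits)[!keep])
  reasons[is.na(p[!keep])] <- "no testable heat terms"
  attr(out, "screened_out") <- reasons
  out
}

#' Rank surviving metrics and select the preferred one
#'
#' Second selection stage: surviving metrics are ranked by AIC (lower is
#' better); the within adjusted R-squared is reported and used to annotate
#' whether the two goodness-of-fit measures agree on the winner. Ties on AIC
#' are broken by fewer regressors, then by metric name order.
#'
#' @param fits a named list of [fe_lpm()] fits for every candidate metric.
#' @param alpha screening level passed to [screen_joint_significance()].
#' @return an object of class `selection_report`: a data frame with one row
#'   per candidate (`metric`, `F`, `df1`, `df2`, `p_value`, `adj_r2_within`,
#'   `aic`, `n_regressors`, `screened_out`, `preferred`), plus attributes
#'   `preferred`, `rationale` and `fit_measures_agree`.
#' @export
rank_and_select <- function(fits, alpha = 0.05) {
  if (!length(fits)) stop("no fitted models supplied")
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$metric, character(1))
  }
  survivors <- screen_joint_significance(fits, alpha)
  reasons <- attr(survivors, "screened_out")

  report <- data.frame(
    metric = names(fits),
    F = vapply(fits, function(f) f$F_heat$F, numeric(1)),
    df1 = vapply(fits, function(f) as.integer(f$F_heat$df1), integer(1)),
    df2 = vapply(fits, function(f) as.integer(f$F_heat$df2 %||% NA_integer_), integer(1)),
    p_value = vapply(fits, function(f) f$F_heat$p_value, numeric(1)),
    adj_r2_within = vapply(fits, function(f) f$adj_r2_within, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    n_regressors = vapply(fits, function(f) length(f$heat_terms), integer(1)),
    stringsAsFactors = FALSE
  )
  report$screened_out <- ifelse(report$metric %in% survivors, "",
                                reasons[report$metric])
  rownames(report) <- NULL

  preferred <- NA_character_
  rationale <- "no metric survived the joint-significance screen"
  agree <- NA
  if (length(survivors)) {
    surv <- report[report$metric %in% survivors, , drop = FALSE]
    ord <- order(surv$aic, surv$n_regressors, surv$metric)
    preferred <- surv$metric[ord[1L]]
    best_r2 <- surv$metric[which.max(surv$adj_r2_within)]
    agree <- identical(preferred, best_r2)
    rationale <- paste0(
      "lowest AIC among metrics passing the joint F screen at alpha = ", alpha,
      if (agree) "; adjusted R-squared agrees"
      else paste0("; NOTE adjusted R-squared prefers '", best_r2, "' instead")
    )
    if (sum(surv$aic == surv$aic[ord[1L]]) > 1L) {
      rationale <- paste0(rationale, "; AIC tie broken by regressor count then name order")
    }
  }
  report$preferred <- report$metric == preferred & !is.na(preferred)
  structure(report, class = c("selection_report", "data.frame"),
            preferred = preferred, rationale = rationale,
            fit_measures_agree = agree, alpha = alpha)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Heat-metric selection report (alpha =", attr(x, "alpha"), ")\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 2)
  df$p_value <- signif(df$p_value, 3)
  df$adj_r2_within <- round(df$adj_r2_within, 4)
  df$aic <- round(df$aic, 1)
  print(df, row.names = FALSE)
  cat("preferred:", attr(x, "preferred"), "\n")
  cat(attr(x, "rationale"), "\n")
  invisible(x)
}
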