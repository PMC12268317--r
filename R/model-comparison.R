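# Error summaries on the index scale, F-test comparison of RMSEs, and
# per-pair classification of projection vs prediction.

#' Summarize prediction/projection residuals
#'
#' @param residuals numeric residuals in index units (predicted - observed).
#' @param observed,predicted optional vectors from which `residuals` arose;
#'   when both are given, the squared Pearson correlation is reported as R2.
#' @return An `error_summary`: list with `n`, `rmse`, `mad` (mean absolute
#'   deviation), `p95_abs_dev` (95th percentile of absolute deviations,
#'   linear interpolation) and `r2` (`NA` unless observed/predicted given).
#' @export
error_summary <- function(residuals, observed = NULL, predicted = NULL) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) == 0) insufficient_data("no residuals to summarize")
  r2 <- NA_real_
  if (!is.null(observed) && !is.null(predicted)) {
    ok <- !is.na(observed) & !is.na(predicted)
    if (sum(ok) >= 3 && stats::sd(observed[ok]) > 0 && stats::sd(predicted[ok]) > 0) {
      r2 <- stats::cor(observed[ok], predicted[ok])^2
    }
  }
  structure(
    list(n = length(residuals),
         rmse = sqrt(mean(residuals^2)),
         mad = mean(abs(residuals)),
         p95_abs_dev = p95(abs(residuals)),
         r2 = r2),
    class = "error_summary"
  )
}

#' F-test on the ratio of mean squared errors
#'
#' Compares the RMSEs of two residual sets by the variance-ratio test:
#' `F = MSE_larger / MSE_smaller` with degrees of freedom equal to the
#' residual counts (no mean is subtracted — these are prediction errors, not
#' deviations from a fitted mean). Two-sided p-value, no multiplicity
#' correction.
#'
#' @param residuals_a,residuals_b residual vectors (each of length >= 2).
#' @param alpha significance level (default 0.05).
#' @return List with `f_statistic`, `df` (numerator, denominator),
#'   `p_value`, `significant`, and `larger` (`"a"`, `"b"` or `"equal"`).
#' @export
f_test_rmse <- function(residuals_a, residuals_b, alpha = 0.05) {
  residuals_a <- residuals_a[!is.na(residuals_a)]
  residuals_b <- residuals_b[!is.na(residuals_b)]
  n_a <- length(residuals_a); n_b <- length(residuals_b)
  if (n_a < 2 || n_b < 2) insufficient_data("need at least 2 residuals per set")
  mse_a <- mean(residuals_a^2); mse_b <- mean(residuals_b^2)
  if (mse_a == 0 && mse_b == 0) {
    return(list(f_statistic = 1, df = c(n_a, n_b), p_value = 1,
                significant = FALSE, larger = "equal", degenerate = TRUE))
  }
  if (mse_a == 0 || mse_b == 0) {
    larger <- if (mse_a > mse_b) "a" else "b"
    return(list(f_statistic = Inf, df = c(n_a, n_b), p_value = 0,
                significant = TRUE, larger = larger, degenerate = TRUE))
  }
  if (mse_a >= mse_b) {
    f <- mse_a / mse_b; df <- c(n_a, n_b)
    larger <- if (mse_a == mse_b) "equal" else "a"
  } else {
    f <- mse_b / mse_a; df <- c(n_b, n_a)
    larger <- "b"
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(f_statistic = f, df = df, p_value = p, significant = p < alpha,
       larger = larger, degenerate = FALSE)
}

#' Classify one system pair: projection vs prediction
#'
#' Restricts both methods to the suspects for which an index value exists
#' from both (common set), compares the RMSEs by [f_test_rmse()], and issues
#' a verdict.
#'
#' @param proj data frame with columns `id`, `rti_projected`,
#'   `rti_observed` for the pair's target system.
#' @param pred data frame with columns `id`, `rti_predicted`,
#'   `rti_observed` for the same target system.
#' @param cs_source,cs_target pair labels carried into the record.
#' @param alpha significance level.
#' @param min_common minimum number of common suspects (default 3).
#' @return A `comparison_record`: list with the pair ids,
#'   `n_common_suspects`, `rmse_projection`, `rmse_prediction`,
#'   `f_statistic`, `p_value`, `verdict` in
#'   `c("projection_better", "prediction_better", "indistinguishable")`, or
#'   an excluded-pair record (`verdict = "excluded"`, `reason`).
#' @export
classify_pair <- function(proj, pred, cs_source = NA, cs_target = NA,
                          alpha = 0.05, min_common = 3) {
  prj <- proj[!is.na(proj$rti_projected) & !is.na(proj$rti_observed), ]
  prd <- pred[!is.na(pred$rti_predicted) & !is.na(pred$rti_observed), ]
  common <- intersect(prj$id, prd$id)
  base <- list(cs_source = cs_source, cs_target = cs_target,
               n_common_suspects = length(common))
  if (length(common) < min_common) {
    return(structure(c(base, list(rmse_projection = NA_real_,
                                  rmse_prediction = NA_real_,
                                  f_statistic = NA_real_, p_value = NA_real_,
                                  verdict = "excluded",
                                  reason = "fewer common suspects than required")),
                     class = "comparison_record"))
  }
  prj <- prj[match(common, prj$id), ]
  prd <- prd[match(common, prd$id), ]
  res_proj <- prj$rti_projected - prj$rti_observed
  res_pred <- prd$rti_predicted - prd$rti_observed
  ft <- f_test_rmse(res_proj, res_pred, alpha = alpha)
  rmse_proj <- sqrt(mean(res_proj^2)); rmse_pred <- sqrt(mean(res_pred^2))
  verdict <- if (!ft$significant) "indistinguishable"
             else if (rmse_proj < rmse_pred) "projection_better"
             else "prediction_better"
  structure(c(base, list(rmse_projection = rmse_proj, rmse_prediction = rmse_pred,
                         f_statistic = ft$f_statistic, p_value = ft$p_value,
                         verdict = verdict, reason = NA_character_)),
            class = "comparison_record")
}

#' Aggregate per-pair comparison records
#'
#' @param records list of `comparison_record`s.
#' @return List with `n_classified`, `n_excluded`, per-verdict `counts` and
#'   `fractions` (over classified pairs).
#' @export
aggregate_comparison <- function(records) {
  if (length(records) == 0) insufficient_data("no comparison records")
  verdicts <- vapply(records, `[[`, character(1), "verdict")
  excluded <- verdicts == "excluded"
  lev <- c("projection_better", "prediction_better", "indistinguishable")
  counts <- table(factor(verdicts[!excluded], levels = lev))
  n <- sum(!excluded)
  list(n_classified = n, n_excluded = sum(excluded),
       counts = as.list(counts),
       fractions = as.list(if (n > 0) counts / n else counts * NA_real_))
}
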