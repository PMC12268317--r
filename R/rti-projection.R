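# Calibration transfer between systems on the retention-index scale: a
# univariate penalized cubic regression spline (mgcv GAM, basis dimension 6,
# smoothing parameter by generalized cross-validation) fitted on the shared
# calibrants maps source indices to target indices. The smooth minimizes
# residuals in the target direction, so fit(A -> B) is not the inverse of
# fit(B -> A) and all ordered pairs are run.

#' Fit the source-to-target projection spline for one pair
#'
#' @param pair a `pair_rti` from [pairwise_rti()].
#' @param k spline basis dimension (default 6).
#' @param min_shared minimum number of calibrants required (default 8).
#' @return A `projection_model`: list with the fitted `mgcv` model, pair
#'   ids, `basis_dimension`, `smoothing_parameter`, `train_range` (source
#'   index range of the calibrants) and `n_train`.
#' @export
fit_projection_gam <- function(pair, k = 6, min_shared = 8) {
  stopifnot(inherits(pair, "pair_rti"))
  cal <- pair$calibrant_rti
  if (nrow(cal) < min_shared) {
    insufficient_anchors(sprintf("pair %s -> %s: %d calibrants, need %d",
                                 pair$cs_source, pair$cs_target, nrow(cal), min_shared))
  }
  x <- cal$rti_source; y <- cal$rti_target
  if (length(unique(x)) < max(3, k)) {
    degenerate_fit("too few distinct source indices to support the spline basis")
  }
  fit <- tryCatch(
    mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = data.frame(x = x, y = y),
              method = "GCV.Cp"),
    error = function(e) degenerate_fit(paste("spline fit failed:", conditionMessage(e)))
  )
  structure(
    list(fit = fit, cs_source = pair$cs_source, cs_target = pair$cs_target,
         basis_dimension = k, smoothing_parameter = unname(fit$sp),
         spline_coefficients = stats::coef(fit),
         train_range = range(x), n_train = nrow(cal)),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model %s -> %s: k = %d, n = %d, sp = %.3g>\n",
              x$cs_source, x$cs_target, x$basis_dimension, x$n_train,
              x$smoothing_parameter))
  invisible(x)
}

#' Project source indices through a fitted pair model
#'
#' Values are evaluated on the closed calibration range `[0, 1000]` only;
#' sources outside it are excluded as `out_of_range` (no extrapolation),
#' missing sources as `undetected`.
#'
#' @param model a `projection_model`.
#' @param rti_source numeric source indices.
#' @return Data frame with `rti_source`, `rti_projected` (`NA` where
#'   excluded) and `excluded_reason` (`NA`, `"out_of_range"` or
#'   `"undetected"`).
#' @export
project_rti <- function(model, rti_source) {
  stopifnot(inherits(model, "projection_model"))
  out <- data.frame(rti_source = rti_source,
                    rti_projected = rep(NA_real_, length(rti_source)),
                    excluded_reason = rep(NA_character_, length(rti_source)),
                    stringsAsFactors = FALSE)
  out$excluded_reason[is.na(rti_source)] <- "undetected"
  oor <- !is.na(rti_source) & (rti_source < 0 | rti_source > 1000)
  out$excluded_reason[oor] <- "out_of_range"
  ok <- is.na(out$excluded_reason)
  if (any(ok)) {
    out$rti_projected[ok] <- as.numeric(
      mgcv::predict.gam(model$fit, newdata = data.frame(x = rti_source[ok])))
  }
  out
}

project_pair <- function(table, cs_source, cs_target, min_shared = 8, k = 6,
                         include_out_of_range_targets = TRUE) {
  pair <- pairwise_rti(table, cs_source, cs_target, min_shared = min_shared)
  model <- fit_projection_gam(pair, k = k, min_shared = min_shared)

  sus <- pair$suspect_rti
  detected_both <- !is.na(sus$rti_source) & !is.na(sus$rti_target)
  eligible <- detected_both & sus$in_range_source
  if (!include_out_of_range_targets) eligible <- eligible & sus$in_range_target

  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  add_excl <- function(ids, reason) {
    if (length(ids)) rbind(excluded, data.frame(id = ids, reason = reason,
                                                stringsAsFactors = FALSE))
    else excluded
  }
  excluded <- add_excl(sus$id[!detected_both], "undetected")
  excluded <- add_excl(sus$id[detected_both & !sus$in_range_source], "out_of_range")
  if (!include_out_of_range_targets) {
    excluded <- add_excl(sus$id[detected_both & sus$in_range_source &
                                  !sus$in_range_target], "out_of_range")
  }

  kept <- sus[eligible, , drop = FALSE]
  proj <- project_rti(model, kept$rti_source)
  detail <- data.frame(
    id = kept$id, rti_source = kept$rti_source,
    rti_projected = proj$rti_projected,
    rti_observed_target = kept$rti_target,
    abs_dev = abs(proj$rti_projected - kept$rti_target),
    in_range_target = kept$in_range_target,
    stringsAsFactors = FALSE)

  res_post <- detail$rti_projected - detail$rti_observed_target
  res_pre <- detail$rti_source - detail$rti_observed_target
  cal_fit <- project_rti(model, pair$calibrant_rti$rti_source)
  res_cal <- cal_fit$rti_projected - pair$calibrant_rti$rti_target

  structure(
    list(cs_source = cs_source, cs_target = cs_target, model = model,
         pair = pair, detail = detail, excluded = excluded,
         error_summary_pre_gam = if (nrow(detail)) error_summary(res_pre) else NULL,
         error_summary_post_gam = if (nrow(detail))
           error_summary(res_post, observed = detail$rti_observed_target,
                         predicted = detail$rti_projected) else NULL,
         error_summary_calibrants = error_summary(res_cal)),
    class = "projection_result"
  )
}

#' Run projections for every ordered system pair
#'
#' Non-reversed-phase systems are excluded up front (projection assumes a
#' shared retention mechanism). For each remaining ordered pair the shared
#' calibrants anchor the pairwise indices, the spline is fitted, and the
#' suspects detected in both systems and eluting inside the source
#' calibration range are projected. Pre-GAM errors are the raw index
#' differences `rti_source - rti_observed_target` on the same suspect set;
#' post-GAM errors use the projected values. Pairs that cannot be run are
#' logged with a reason, never dropped silently.
#'
#' @param table a `retention_table`.
#' @param systems list of `chrom_system` objects covering the table.
#' @param min_shared minimum shared calibrants per pair (default 8).
#' @param k spline basis dimension (default 6).
#' @param include_out_of_range_targets keep suspects whose index is outside
#'   `[0, 1000]` in the target system (default TRUE; they are flagged in the
#'   detail table either way).
#' @param mechanism_filter retention mechanisms admitted (default `"RP"`).
#' @return A `projection_run`: list with `results` (named
#'   `projection_result`s, "source->target") and `skipped` (data frame
#'   `cs_source`, `cs_target`, `reason`).
#' @export
run_all_pairs <- function(table, systems, min_shared = 8, k = 6,
                          include_out_of_range_targets = TRUE,
                          mechanism_filter = "RP") {
  mech <- vapply(systems, `[[`, character(1), "mechanism")
  systems <- systems[mech %in% mechanism_filter]
  ids <- intersect(vapply(systems, `[[`, character(1), "cs_id"),
                   table_systems(table))
  if (length(ids) < 2) validation_error("need at least 2 systems after the mechanism filter")
  results <- list()
  skipped <- data.frame(cs_source = character(0), cs_target = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (src in ids) for (tgt in ids) {
    if (src == tgt) next
    r <- tryCatch(
      project_pair(table, src, tgt, min_shared = min_shared, k = k,
                   include_out_of_range_targets = include_out_of_range_targets),
      rtbridge_error = function(e) e)
    if (inherits(r, "projection_result") && nrow(r$detail) > 0) {
      results[[paste0(src, "->", tgt)]] <- r
    } else {
      reason <- if (inherits(r, "condition")) conditionMessage(r)
                else "no projectable suspects"
      skipped <- rbind(skipped, data.frame(cs_source = src, cs_target = tgt,
                                           reason = reason, stringsAsFactors = FALSE))
    }
  }
  structure(list(results = results, skipped = skipped), class = "projection_run")
}

#' Pair-level summary table of a projection run
#'
#' @param run a `projection_run`.
#' @return Data frame with one row per ordered pair: suspect counts, pre-
#'   and post-GAM RMSE, MAD and 95th-percentile absolute deviation, the
#'   calibrant RMSE, and whether the spline lowered the RMSE.
#' @export
summarize_projection_run <- function(run) {
  stopifnot(inherits(run, "projection_run"))
  if (length(run$results) == 0) insufficient_data("projection run holds no successful pairs")
  rows <- lapply(run$results, function(r) {
    res_pre <- r$detail$rti_source - r$detail$rti_observed_target
    res_post <- r$detail$rti_projected - r$detail$rti_observed_target
    p_impr <- if (nrow(r$detail) >= 2) f_test_rmse(res_pre, res_post)$p_value else NA_real_
    data.frame(cs_source = r$cs_source, cs_target = r$cs_target,
               n_suspects = nrow(r$detail),
               rmse_pre = r$error_summary_pre_gam$rmse,
               rmse_post = r$error_summary_post_gam$rmse,
               mad_post = r$error_summary_post_gam$mad,
               p95_post = r$error_summary_post_gam$p95_abs_dev,
               rmse_calibrants = r$error_summary_calibrants$rmse,
               improved = r$error_summary_post_gam$rmse < r$error_summary_pre_gam$rmse,
               p_improvement = p_impr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
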