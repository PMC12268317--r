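# Retention time indices per ordered system pair, anchored on the
# calibrants detected in BOTH systems. The index is strictly two-anchor
# linear: rti = 1000 * (rt - rt_min) / (rt_max - rt_min), where rt_min and
# rt_max are the earliest and latest shared calibrant in that system. By
# construction shared-calibrant indices span [0, 1000]; suspects may fall
# outside and are flagged.

#' Convert a retention time to a retention time index
#'
#' @param rt retention time(s) in minutes.
#' @param rt_min,rt_max anchor retention times (earliest/latest shared
#'   calibrant) in minutes; `rt_max` must exceed `rt_min`.
#' @return Numeric index value(s); 0 at `rt_min`, 1000 at `rt_max`, outside
#'   `[0, 1000]` for retention times beyond the calibrant window.
#' @export
compute_rti <- function(rt, rt_min, rt_max) {
  if (!is.numeric(rt_min) || !is.numeric(rt_max) || rt_max <= rt_min) {
    degenerate_anchors("rt_max must be strictly greater than rt_min")
  }
  # ratio first: the anchors then map to exactly 0 and 1000
  1000 * ((rt - rt_min) / (rt_max - rt_min))
}

#' Compute pairwise retention time indices for an ordered system pair
#'
#' Anchors are taken from the calibrants detected in both systems only, so
#' the index scale of each comparison adapts to the shared calibrant set.
#' Every compound detected in a system is converted on that system's scale;
#' suspects are flagged by whether their index lies inside the calibration
#' range `[0, 1000]` in each system.
#'
#' @param table a `retention_table`.
#' @param cs_source,cs_target system ids present in `table`.
#' @param min_shared minimum number of shared calibrants required (default 8;
#'   the spline used downstream has 6 basis functions and needs more support
#'   points than that).
#' @return A `pair_rti` object with elements `cs_source`, `cs_target`,
#'   `shared_calibrant_ids`, `anchors_source`, `anchors_target`,
#'   `calibrant_rti` (data frame id, rti_source, rti_target) and
#'   `suspect_rti` (id, rti_source, rti_target, in_range_source,
#'   in_range_target; `NA` index where undetected).
#' @export
pairwise_rti <- function(table, cs_source, cs_target, min_shared = 8) {
  cols <- paste0("rt_", c(cs_source, cs_target))
  if (!all(cols %in% names(table))) {
    validation_error(paste("system not present in table:",
                           paste(setdiff(c(cs_source, cs_target), table_systems(table)), collapse = ", ")))
  }
  rt_s <- table[[cols[1]]]
  rt_t <- table[[cols[2]]]
  is_cal <- table$role == "calibrant"
  shared_cal <- is_cal & !is.na(rt_s) & !is.na(rt_t)
  n_shared <- sum(shared_cal)
  if (n_shared < min_shared) {
    insufficient_anchors(sprintf(
      "pair %s -> %s: %d shared calibrants, need at least %d",
      cs_source, cs_target, n_shared, min_shared))
  }
  anchors_source <- range(rt_s[shared_cal])
  anchors_target <- range(rt_t[shared_cal])
  if (diff(anchors_source) <= 0 || diff(anchors_target) <= 0) {
    degenerate_anchors("all shared calibrants co-elute; anchors are degenerate")
  }
  rti_s <- compute_rti(rt_s, anchors_source[1], anchors_source[2])
  rti_t <- compute_rti(rt_t, anchors_target[1], anchors_target[2])
  in_range <- function(x) !is.na(x) & x >= 0 & x <= 1000
  is_sus <- table$role == "suspect"
  detected_sus <- is_sus & (!is.na(rt_s) | !is.na(rt_t))
  structure(
    list(
      cs_source = cs_source, cs_target = cs_target,
      shared_calibrant_ids = table$compound_id[shared_cal],
      anchors_source = anchors_source, anchors_target = anchors_target,
      n_shared = n_shared,
      calibrant_rti = data.frame(
        id = table$compound_id[shared_cal],
        rti_source = rti_s[shared_cal], rti_target = rti_t[shared_cal],
        stringsAsFactors = FALSE),
      suspect_rti = data.frame(
        id = table$compound_id[detected_sus],
        rti_source = rti_s[detected_sus], rti_target = rti_t[detected_sus],
        in_range_source = in_range(rti_s[detected_sus]),
        in_range_target = in_range(rti_t[detected_sus]),
        stringsAsFactors = FALSE)
    ),
    class = "pair_rti"
  )
}

#' @export
print.pair_rti <- function(x, ...) {
  cat(sprintf("<pair_rti %s -> %s: %d shared calibrants, %d suspects>\n",
              x$cs_source, x$cs_target, x$n_shared, nrow(x$suspect_rti)))
  invisible(x)
}
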