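# Distribution of peaks along each system's elution program. Retention
# times are normalized to the program length on a 0-1000 scale (no dead-time
# subtraction), then summarized by the sample standard deviation and the
# empirical cumulative distribution.

#' Normalize retention times to the elution program length
#'
#' @param rts retention times in minutes (all positive, none exceeding
#'   `run_time`).
#' @param run_time program length in minutes.
#' @return `1000 * rts / run_time` (index units on a 0-1000 scale).
#' @export
normalize_rts <- function(rts, run_time) {
  if (!is.numeric(run_time) || length(run_time) != 1 || run_time <= 0) {
    validation_error("run_time must be a single positive number")
  }
  rts <- rts[!is.na(rts)]
  if (any(rts <= 0)) validation_error("retention times must be positive")
  if (any(rts > run_time + 1e-9)) {
    validation_error("retention time exceeds the elution program length")
  }
  1000 * rts / run_time
}

#' Peak-spacing summary for one system
#'
#' Calibrants and suspects detected on the system are pooled; their
#' normalized retention times are summarized by the sample (n-1) standard
#' deviation, the empirical CDF evaluated at each observed value, and the
#' latest normalized elution.
#'
#' @param table a `retention_table`.
#' @param system a `chrom_system` whose `cs_id` has a column in `table`.
#' @return A `spacing_summary`: list with `cs_id`, `n_detected`,
#'   `normalized_rts` (sorted), `sd_normalized`, `cumulative_curve`
#'   (data frame `normalized_rt`, `fraction`), `max_normalized`.
#' @export
spacing_summary <- function(table, system) {
  col <- paste0("rt_", system$cs_id)
  if (!col %in% names(table)) validation_error(paste("system not in table:", system$cs_id))
  rts <- table[[col]]
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2) {
    insufficient_data(sprintf("system %s: %d detections, need at least 2",
                              system$cs_id, length(rts)))
  }
  nrt <- sort(normalize_rts(rts, system$run_time))
  structure(
    list(cs_id = system$cs_id, n_detected = length(nrt), normalized_rts = nrt,
         sd_normalized = stats::sd(nrt),
         cumulative_curve = data.frame(normalized_rt = nrt,
                                       fraction = seq_along(nrt) / length(nrt)),
         max_normalized = max(nrt)),
    class = "spacing_summary"
  )
}
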