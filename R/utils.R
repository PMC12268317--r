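# Internal helpers: error conditions and seed fan-out.

stop_rtbridge <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rtbridge_error")))
}

validation_error <- function(msg) stop_rtbridge(msg, "rtbridge_validation_error")
insufficient_anchors <- function(msg) stop_rtbridge(msg, "rtbridge_insufficient_anchors")
insufficient_data <- function(msg) stop_rtbridge(msg, "rtbridge_insufficient_data")
degenerate_fit <- function(msg) stop_rtbridge(msg, "rtbridge_degenerate_fit")
degenerate_anchors <- function(msg) stop_rtbridge(msg, "rtbridge_degenerate_anchors")

#' Derive a component seed from a global seed
#'
#' One global seed fans out to per-component seeds through a fixed counter
#' scheme, so that adding a stage never perturbs the random stream of an
#' existing stage. Kept below 2^31 - 1 so the result is a valid R integer.
#'
#' @param seed integer global seed.
#' @param counter integer component counter (>= 0).
#' @return An integer seed.
#' @export
fan_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483629)
}

# 95th percentile with linear interpolation between order statistics
# (quantile type 7, R's default).
p95 <- function(x) unname(stats::quantile(x, 0.95, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a
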