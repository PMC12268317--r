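# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to a tempfile.

# Small two-system retention table: 4 calibrants, 2 suspects.
tiny_rt_table <- function() {
  as_retention_table(data.frame(
    compound_id = c("c1", "c2", "c3", "c4", "s1", "s2"),
    role = c(rep("calibrant", 4), rep("suspect", 2)),
    rt_A = c(1.0, 3.0, 6.0, 11.0, 2.0, 12.0),
    rt_B = c(2.0, 5.0, 9.0, 16.0, 3.5, 18.0),
    stringsAsFactors = FALSE
  ))
}

# Single-segment linear gradient system.
linear_system <- function(cs_id = "L", run_time = 20,
                          additive_class = "formic_acid") {
  chrom_system(cs_id = cs_id, run_time = run_time,
               additive_class = additive_class,
               gradient_segments = data.frame(
                 t_start = 0, t_end = run_time,
                 phi_start = 0.05, phi_end = 0.95))
}

# Gradient with a long terminal isocratic plateau (last 40% of the run).
plateau_system <- function(cs_id = "P", run_time = 20) {
  g1 <- 0.6 * run_time
  chrom_system(cs_id = cs_id, run_time = run_time,
               gradient_segments = data.frame(
                 t_start = c(0, g1), t_end = c(g1, run_time),
                 phi_start = c(0.05, 0.95), phi_end = c(0.95, 0.95)))
}

# Retention table for two systems built from explicit rt vectors. The
# calibrants are interleaved across the elution range (including the first
# and last positions when rt vectors are sorted), so suspects sit inside
# the calibration window.
two_system_table <- function(rt_a, rt_b, n_cal, ids = NULL) {
  n <- length(rt_a)
  stopifnot(length(rt_b) == n, n_cal < n)
  role <- rep("suspect", n)
  idx <- unique(round(seq(1, n, length.out = n_cal)))
  stopifnot(length(idx) == n_cal)
  role[idx] <- "calibrant"
  as_retention_table(data.frame(
    compound_id = ids %||% sprintf("x%02d", seq_len(n)),
    role = role, rt_A = rt_a, rt_B = rt_b, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An rt_model whose predictor is an exactly known function of the
# descriptor matrix (bypasses boosting for contract tests).
fake_rt_model <- function(fun, descriptors) {
  structure(list(booster = fun, retained_descriptors = descriptors,
                 hyperparameters = list(), cv_config = list(),
                 cv_rmse = NA_real_, seed = 0L),
            class = "rt_model")
}

# Small hyperparameter grid so repeated-CV model fits stay fast in tests.
small_grid <- function() {
  expand.grid(max_depth = c(3L, 5L), eta = 0.1, nrounds = 150L,
              subsample = 0.8, KEEP.OUT.ATTRS = FALSE)
}
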