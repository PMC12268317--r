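# The prediction arm: molecular descriptors -> gradient-boosted retention
# model -> calibrant-anchored recalibration onto a target system's index
# scale. Descriptor cleaning follows the standard caret semantics: drop
# descriptors missing for more than `missing_limit` compounds, then
# compounds with any remaining gap, then near-zero-variance columns
# (frequency ratio >= 19, unique fraction <= 10%), then one member of every
# pair correlated beyond the cutoff (the one with the larger mean absolute
# correlation loses).

#' Compute molecular descriptors from SMILES
#'
#' Thin wrapper over ChemmineR/OpenBabel: each SMILES is reduced to its
#' largest covalent fragment (salt stripping), parsed, and summarized by the
#' OpenBabel property set (H-bond donors/acceptors, logP, molar
#' refractivity, molecular weight, fluorine count, TPSA). Unparseable
#' structures yield an all-missing row and are flagged, never fatal.
#' Simulated descriptors ([simulate_descriptors()]) are the first-class
#' stand-in where no chemistry backend or no structures are available.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids compound identifiers (default: the SMILES themselves).
#' @return A `descriptor_matrix` with a `failed` element listing flagged ids.
#' @export
compute_descriptors <- function(smiles, ids = smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_rtbridge("compute_descriptors needs the ChemmineR and ChemmineOB packages",
                  "rtbridge_missing_backend")
  }
  desc_names <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  one <- function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frag <- frags[which.max(nchar(frags))]
    tryCatch({
      sdf <- ChemmineR::smiles2sdf(frag)
      p <- ChemmineR::propOB(sdf)
      as.numeric(p[1, desc_names])
    }, error = function(e) rep(NA_real_, length(desc_names)))
  }
  vals <- t(vapply(smiles, one, numeric(length(desc_names))))
  dimnames(vals) <- list(ids, desc_names)
  failed <- ids[rowSums(is.na(vals)) == length(desc_names)]
  structure(list(compound_ids = ids, descriptor_names = desc_names,
                 values = vals, cleaning_log = NULL, failed = failed),
            class = "descriptor_matrix")
}

#' Clean a descriptor matrix
#'
#' Applies, in order: (1) drop descriptors missing for more than
#' `missing_limit` compounds; (2) drop compounds with any remaining missing
#' value; (3) drop near-zero-variance descriptors (`caret::nearZeroVar`
#' defaults: frequency ratio >= 19, unique fraction <= 10%); (4) from each
#' pair with absolute correlation above `corr_cutoff`, drop the member with
#' the larger mean absolute correlation (`caret::findCorrelation`,
#' exact mode — deterministic). The log records every drop per rule.
#'
#' @param m a `descriptor_matrix`.
#' @param missing_limit max tolerated missing compounds per descriptor
#'   (default 15; a descriptor missing for exactly 15 compounds is kept).
#' @param corr_cutoff pairwise absolute-correlation cutoff (default 0.7).
#' @return The cleaned `descriptor_matrix`, with `cleaning_log`.
#' @export
clean_descriptor_matrix <- function(m, missing_limit = 15, corr_cutoff = 0.7) {
  stopifnot(inherits(m, "descriptor_matrix"))
  v <- m$values
  log <- list()

  n_miss <- colSums(is.na(v))
  drop1 <- colnames(v)[n_miss > missing_limit]
  v <- v[, setdiff(colnames(v), drop1), drop = FALSE]
  log$missing_descriptors <- drop1

  bad_rows <- rowSums(is.na(v)) > 0
  log$missing_compounds <- rownames(v)[bad_rows]
  v <- v[!bad_rows, , drop = FALSE]
  if (ncol(v) == 0 || nrow(v) == 0) insufficient_data("cleaning removed everything")

  nzv <- caret::nearZeroVar(v, freqCut = 95 / 5, uniqueCut = 10)
  log$near_zero_variance <- colnames(v)[nzv]
  if (length(nzv)) v <- v[, -nzv, drop = FALSE]
  if (ncol(v) == 0) insufficient_data("all descriptors dropped as near-zero-variance")

  if (ncol(v) > 1) {
    cm <- stats::cor(v)
    hi <- caret::findCorrelation(cm, cutoff = corr_cutoff, exact = TRUE)
    log$high_correlation <- colnames(v)[hi]
    if (length(hi)) v <- v[, -hi, drop = FALSE]
  } else {
    log$high_correlation <- character(0)
  }
  if (ncol(v) == 0) insufficient_data("all descriptors dropped by the correlation filter")

  structure(list(compound_ids = rownames(v), descriptor_names = colnames(v),
                 values = v, cleaning_log = log, truth = m$truth,
                 failed = m$failed),
            class = "descriptor_matrix")
}

#' Default hyperparameter grid for the boosted-tree retention model
#'
#' @return Data frame of candidate settings (tree depth, learning rate,
#'   boosting rounds, row subsampling).
#' @export
default_xgb_grid <- function() {
  expand.grid(max_depth = c(3L, 5L, 7L), eta = c(0.05, 0.1, 0.3),
              nrounds = c(100L, 300L), subsample = 0.8,
              KEEP.OUT.ATTRS = FALSE)
}

xgb_fit <- function(x, y, par, seed) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = par$max_depth,
                  eta = par$eta, subsample = par$subsample, nthread = 1,
                  seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = par$nrounds, verbose = 0)
}

cv_rmse_grid <- function(x, y, grid, folds, repeats, seed) {
  n <- nrow(x)
  rmse <- matrix(NA_real_, nrow(grid), repeats * folds)
  for (r in seq_len(repeats)) {
    set.seed(fan_seed(seed, 100 + r))
    assign <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      tr <- assign != f
      for (g in seq_len(nrow(grid))) {
        fit <- xgb_fit(x[tr, , drop = FALSE], y[tr], grid[g, ], seed)
        pred <- stats::predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
        rmse[g, (r - 1) * folds + f] <- sqrt(mean((pred - y[!tr])^2))
      }
    }
  }
  rowMeans(rmse)
}

#' Train the gradient-boosted retention model
#'
#' Hyperparameters are selected by minimum mean RMSE over five-times
#' repeated two-fold cross-validation (ties resolved by grid order), then
#' the model is refitted on all data with the winning settings. Fully
#' reproducible given `seed`.
#'
#' @param m a cleaned `descriptor_matrix`.
#' @param rts response: retention times in minutes (or indices, for local
#'   models) aligned with `m$compound_ids`.
#' @param seed integer seed.
#' @param grid hyperparameter grid (default [default_xgb_grid()]).
#' @param folds,repeats cross-validation scheme (defaults 2 and 5).
#' @param min_n minimum training-set size (default 40).
#' @return An `rt_model`: list with the booster, `retained_descriptors`,
#'   `hyperparameters`, `cv_config`, `cv_rmse` and `seed`.
#' @export
train_rt_model <- function(m, rts, seed = 1, grid = default_xgb_grid(),
                           folds = 2, repeats = 5, min_n = 40) {
  stopifnot(inherits(m, "descriptor_matrix"))
  x <- m$values
  if (anyNA(x)) validation_error("descriptor matrix must be cleaned before training")
  if (length(rts) != nrow(x)) validation_error("rts must align with the descriptor rows")
  if (nrow(x) < min_n) {
    insufficient_data(sprintf("%d training compounds, need at least %d", nrow(x), min_n))
  }
  scores <- cv_rmse_grid(x, rts, grid, folds, repeats, seed)
  best <- which.min(scores)
  fit <- xgb_fit(x, rts, grid[best, ], seed)
  structure(
    list(booster = fit, retained_descriptors = colnames(x),
         hyperparameters = as.list(grid[best, ]),
         cv_config = list(folds = folds, repeats = repeats),
         cv_rmse = scores[best],
         cv_table = cbind(grid, cv_rmse = scores),
         seed = seed),
    class = "rt_model"
  )
}

#' @export
print.rt_model <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf("<rt_model: depth %d, eta %.2f, %d rounds, cv_rmse %.3f (%dx%d-fold)>\n",
              h$max_depth, h$eta, h$nrounds, x$cv_rmse,
              x$cv_config$repeats, x$cv_config$folds))
  invisible(x)
}

#' Predict retention from descriptors
#'
#' @param model an `rt_model`.
#' @param m a `descriptor_matrix` containing at least the model's retained
#'   descriptors.
#' @return Named numeric vector of predictions.
#' @export
predict_rt <- function(model, m) {
  stopifnot(inherits(model, "rt_model"), inherits(m, "descriptor_matrix"))
  need <- model$retained_descriptors
  if (!all(need %in% colnames(m$values))) {
    validation_error("descriptor matrix lacks columns the model was trained on")
  }
  x <- m$values[, need, drop = FALSE]
  p <- if (is.function(model$booster)) model$booster(x)
       else stats::predict(model$booster, xgboost::xgb.DMatrix(x))
  names(p) <- m$compound_ids
  p
}

#' Calibrate predicted retention onto a target system's index scale
#'
#' Predicts retention for the calibrants and suspects, fits the same spline
#' machinery used for pairwise projection (basis dimension `k`, GCV) from
#' predicted calibrant retention to the calibrants' observed target indices,
#' and evaluates it on the suspects. Suspects whose prediction falls outside
#' the calibrants' predicted range are excluded as `out_of_range`. The
#' `"linear"` variant replaces the spline with the two-anchor index rule on
#' the predicted calibrant retention range.
#'
#' @param model an `rt_model` trained on an external set.
#' @param suspects,calibrants `descriptor_matrix` objects for the target
#'   system's compounds.
#' @param calibrant_rti_target observed calibrant indices on the target
#'   system (aligned with `calibrants$compound_ids`; `NA` = undetected).
#' @param k spline basis dimension (default 6).
#' @param min_shared minimum usable calibrants (default 8).
#' @param calibration `"gam"` (default) or `"linear"`.
#' @return Data frame with `id`, `rt_predicted`, `rti_calibrated` and
#'   `excluded_reason`.
#' @export
predict_and_calibrate <- function(model, suspects, calibrants,
                                  calibrant_rti_target, k = 6, min_shared = 8,
                                  calibration = c("gam", "linear")) {
  calibration <- match.arg(calibration)
  pred_cal <- predict_rt(model, calibrants)
  pred_sus <- predict_rt(model, suspects)
  ok <- !is.na(calibrant_rti_target)
  if (sum(ok) < min_shared) {
    insufficient_anchors(sprintf("%d calibrants with observed target index, need %d",
                                 sum(ok), min_shared))
  }
  pc <- pred_cal[ok]; yc <- calibrant_rti_target[ok]
  if (stats::sd(pc) == 0) degenerate_fit("constant predictor: all calibrant predictions equal")
  rng <- range(pc)
  out <- data.frame(id = suspects$compound_ids, rt_predicted = unname(pred_sus),
                    rti_calibrated = NA_real_, excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  oor <- pred_sus < rng[1] | pred_sus > rng[2]
  out$excluded_reason[oor] <- "out_of_range"
  if (calibration == "gam") {
    if (length(unique(pc)) < max(3, k)) {
      degenerate_fit("too few distinct calibrant predictions for the spline basis")
    }
    fit <- tryCatch(
      mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = data.frame(x = pc, y = yc),
                method = "GCV.Cp"),
      error = function(e) degenerate_fit(paste("calibration fit failed:",
                                               conditionMessage(e))))
    out$rti_calibrated[!oor] <- as.numeric(
      mgcv::predict.gam(fit, newdata = data.frame(x = pred_sus[!oor])))
  } else {
    out$rti_calibrated[!oor] <- compute_rti(pred_sus[!oor], rng[1], rng[2])
  }
  out
}

#' Train a calibrant-only local model for one system
#'
#' Same learner and cross-validation scheme, trained directly on the target
#' system's calibrant indices; no recalibration step is needed since the
#' model already predicts on the target scale.
#'
#' @param calibrant_descriptors cleaned `descriptor_matrix` of the system's
#'   detected calibrants.
#' @param calibrant_rti their observed indices on that system.
#' @param seed integer seed.
#' @param grid hyperparameter grid (default [default_xgb_grid()]).
#' @param min_n minimum number of calibrants (default 10).
#' @return An `rt_model` predicting target-scale indices.
#' @export
train_local_model <- function(calibrant_descriptors, calibrant_rti, seed = 1,
                              grid = default_xgb_grid(), min_n = 10) {
  train_rt_model(calibrant_descriptors, calibrant_rti, seed = seed,
                 grid = grid, min_n = min_n)
}
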