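test_that("compute_descriptors handles valid, salty and broken SMILES", {
  d <- compute_descriptors(c("CCO", "not_a_smiles", "CC(=O)[O-].[Na+]"),
                           ids = c("ethanol", "junk", "acetate_salt"))
  expect_s3_class(d, "descriptor_matrix")
  expect_true(all(is.finite(d$values["ethanol", ])))
  expect_true(all(is.na(d$values["junk", ])))
  expect_equal(d$failed, "junk")
  # salt stripped: descriptors computed on the organic fragment
  expect_true(all(is.finite(d$values["acetate_salt", ])))
})

test_that("descriptor rows are invariant to SMILES canonicalization", {
  d <- compute_descriptors(c("CCO", "OCC", "c1ccccc1O", "Oc1ccccc1"),
                           ids = c("a", "b", "c", "d"))
  expect_equal(unname(d$values["a", ]), unname(d$values["b", ]))
  expect_equal(unname(d$values["c", ]), unname(d$values["d", ]))
})

make_polluted <- function(n = 60, seed = 1) {
  cfg <- simulation_config(n_calibrants = n / 2, n_suspects = n / 2,
                           n_systems = 2, frac_ionizable = 0, seed = seed)
  comp <- simulate_compounds(cfg)
  simulate_descriptors(comp, n_descriptors = 12, n_informative = 1, seed = seed,
                       plant_constant = 1, plant_duplicate = 1,
                       plant_missing = 1, missing_count = 16)
}

test_that("cleaning removes exactly the planted defect columns", {
  m <- make_polluted()
  cleaned <- clean_descriptor_matrix(m)
  log <- cleaned$cleaning_log
  expect_equal(log$missing_descriptors, "D_miss01")   # 16 missing > limit 15
  expect_equal(log$near_zero_variance, "D_const01")
  # the planted duplicate pair (r = 1) loses exactly one member
  expect_equal(sum(c("D_info01", "D_dup01") %in% log$high_correlation), 1)
  pure_noise <- grep("^D_noise", m$descriptor_names, value = TRUE)
  expect_true(all(pure_noise %in% cleaned$descriptor_names))
  # post-conditions
  expect_false(anyNA(cleaned$values))
  expect_lte(max(abs(cor(cleaned$values))[upper.tri(diag(ncol(cleaned$values)))]), 0.7)
})

test_that("the missing-value limit is a strict 'more than' boundary", {
  m <- make_polluted()
  at_limit <- m
  keep <- !is.na(at_limit$values[, "D_miss01"])
  fix_one <- which(!keep)[1]
  at_limit$values[fix_one, "D_miss01"] <- 0.5  # now exactly 15 missing
  cleaned <- clean_descriptor_matrix(at_limit)
  expect_false("D_miss01" %in% cleaned$cleaning_log$missing_descriptors)
  # the 15 compounds still missing it are dropped instead
  expect_equal(length(cleaned$cleaning_log$missing_compounds), 15)
})

test_that("boosted model learns informative descriptors and fails on noise", {
  train <- simulate_training_set(n = 500, seed = 42, noise_sd = 0.05,
                                 descriptor_noise = 0.05)
  dm <- clean_descriptor_matrix(train$descriptors)
  rts <- train$rt[match(dm$compound_ids, train$compounds$compound_id)]
  hold <- seq(1, length(rts), by = 5)  # 20% held out
  fit_on <- function(idx) {
    train_rt_model(rtbridge:::subset_descriptors(dm, dm$compound_ids[idx]),
                   rts[idx], seed = 9, grid = small_grid())
  }
  model <- fit_on(setdiff(seq_along(rts), hold))
  pred <- predict_rt(model, rtbridge:::subset_descriptors(dm, dm$compound_ids[hold]))
  r2 <- cor(pred, rts[hold])^2
  expect_gte(r2, 0.9)

  # permuted labels carry no signal
  set.seed(1)
  perm <- sample(rts)
  model_null <- train_rt_model(
    rtbridge:::subset_descriptors(dm, dm$compound_ids[-hold]),
    perm[-hold], seed = 9, grid = small_grid())
  pred_null <- predict_rt(model_null,
                          rtbridge:::subset_descriptors(dm, dm$compound_ids[hold]))
  expect_lte(cor(pred_null, perm[hold])^2, 0.1)
})

test_that("training is deterministic under a fixed seed", {
  train <- simulate_training_set(n = 80, seed = 5)
  dm <- clean_descriptor_matrix(train$descriptors)
  rts <- train$rt[match(dm$compound_ids, train$compounds$compound_id)]
  m1 <- train_rt_model(dm, rts, seed = 3, grid = small_grid())
  m2 <- train_rt_model(dm, rts, seed = 3, grid = small_grid())
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(predict_rt(m1, dm), predict_rt(m2, dm))
  expect_identical(m1$retained_descriptors, m2$retained_descriptors)
  expect_error(train_rt_model(dm, rts[-1], seed = 3),
               class = "rtbridge_validation_error")
  expect_error(
    train_rt_model(rtbridge:::subset_descriptors(dm, dm$compound_ids[1:20]),
                   rts[1:20], seed = 3),
    class = "rtbridge_insufficient_data")
})

test_that("a perfect predictor calibrates suspects onto the observed index scale", {
  cfg <- simulation_config(n_systems = 2, noise_sd = 0, dropout_rate = 0, seed = 8)
  comp <- simulate_compounds(cfg)
  dm <- simulate_descriptors(comp, seed = 8)
  # target system linear in u; "model" that recovers true RT exactly from u
  u <- comp$latent_u
  rt_true <- 0.5 + 14 * u
  oracle <- fake_rt_model(function(x) 0.5 + 14 * u[match(rownames(x), comp$compound_id)],
                          dm$descriptor_names)
  cal <- comp$role == "calibrant"
  cal_dm <- rtbridge:::subset_descriptors(dm, comp$compound_id[cal])
  sus_dm <- rtbridge:::subset_descriptors(dm, comp$compound_id[!cal])
  rti_cal <- compute_rti(rt_true[cal], min(rt_true[cal]), max(rt_true[cal]))
  out <- predict_and_calibrate(oracle, sus_dm, cal_dm, rti_cal)
  rti_sus_true <- compute_rti(rt_true[!cal], min(rt_true[cal]), max(rt_true[cal]))
  ok <- is.na(out$excluded_reason)
  expect_gt(sum(ok), 20)
  expect_lt(max(abs(out$rti_calibrated[ok] - rti_sus_true[ok])), 1)
  # suspects beyond the calibrant prediction range are excluded, not extrapolated
  oor <- rt_true[!cal] < min(rt_true[cal]) | rt_true[!cal] > max(rt_true[cal])
  expect_equal(out$excluded_reason[oor], rep("out_of_range", sum(oor)))

  # the linear-anchor variant agrees for a linear system
  lin <- predict_and_calibrate(oracle, sus_dm, cal_dm, rti_cal, calibration = "linear")
  expect_lt(max(abs(lin$rti_calibrated[ok] - rti_sus_true[ok])), 1e-9)
})

test_that("constant predictors and thin calibrant sets are rejected", {
  cfg <- simulation_config(n_systems = 2, seed = 9)
  comp <- simulate_compounds(cfg)
  dm <- simulate_descriptors(comp, seed = 9)
  cal <- comp$role == "calibrant"
  cal_dm <- rtbridge:::subset_descriptors(dm, comp$compound_id[cal])
  sus_dm <- rtbridge:::subset_descriptors(dm, comp$compound_id[!cal])
  flat <- fake_rt_model(function(x) rep(5, nrow(x)), dm$descriptor_names)
  expect_error(predict_and_calibrate(flat, sus_dm, cal_dm, runif(sum(cal), 0, 1000)),
               class = "rtbridge_degenerate_fit")
  good <- fake_rt_model(function(x) seq_len(nrow(x)), dm$descriptor_names)
  few <- rep(NA_real_, sum(cal)); few[1:5] <- c(0, 10, 20, 500, 1000)
  expect_error(predict_and_calibrate(good, sus_dm, cal_dm, few),
               class = "rtbridge_insufficient_anchors")
})

test_that("local calibrant-only models train and degrade with fewer calibrants", {
  cfg <- simulation_config(n_systems = 2, noise_sd = 0.05, dropout_rate = 0, seed = 12)
  st <- simulate_study(cfg)
  comp <- st$truth$compounds
  dm <- simulate_descriptors(comp, seed = 12, noise_sd = 0.05)
  rti <- system_rti(st$table, "CS01")
  cal_ids <- comp$compound_id[comp$role == "calibrant"]
  sus_ids <- comp$compound_id[comp$role == "suspect"]
  sus_dm <- rtbridge:::subset_descriptors(dm, sus_ids)
  rti_sus <- rti$rti[match(sus_ids, rti$compound_id)]

  grid <- expand.grid(max_depth = 3L, eta = 0.1, nrounds = 120L,
                      subsample = 0.8, KEEP.OUT.ATTRS = FALSE)
  rmse_at_n <- function(n_train) {
    med <- vapply(1:3, function(s) {
      set.seed(300 + s)
      use <- sample(cal_ids, n_train)
      m <- train_local_model(rtbridge:::subset_descriptors(dm, use),
                             rti$rti[match(use, rti$compound_id)],
                             seed = s, grid = grid)
      pred <- predict_rt(m, sus_dm)
      sqrt(mean((pred - rti_sus)^2))
    }, numeric(1))
    median(med)
  }
  ns <- c(10, 15, 20, 30)
  rmses <- vapply(ns, rmse_at_n, numeric(1))
  expect_true(all(is.finite(rmses)))
  expect_lt(cor(ns, rmses, method = "spearman"), 0)
  expect_error(
    train_local_model(rtbridge:::subset_descriptors(dm, cal_ids[1:5]),
                      rep(1, 5), seed = 1, grid = grid),
    class = "rtbridge_insufficient_data")
})
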