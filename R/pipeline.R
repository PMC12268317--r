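# End-to-end orchestration: simulate or ingest a study, then run indices,
# similarity, spacing, projection, prediction and the projection-vs-
# prediction comparison, writing deterministic CSV/JSON artifacts.

#' Per-system retention time indices
#'
#' Index scale anchored on the earliest and latest calibrant detected on
#' that one system (the construction used when predictions are calibrated
#' onto a single target system, as opposed to the pairwise shared-calibrant
#' scale of [pairwise_rti()]).
#'
#' @param table a `retention_table`.
#' @param cs_id system id.
#' @return Data frame `compound_id`, `role`, `rti` (`NA` where undetected).
#' @export
system_rti <- function(table, cs_id) {
  col <- paste0("rt_", cs_id)
  if (!col %in% names(table)) validation_error(paste("system not in table:", cs_id))
  rt <- table[[col]]
  cal <- table$role == "calibrant" & !is.na(rt)
  if (sum(cal) < 2) insufficient_anchors(paste("fewer than 2 detected calibrants on", cs_id))
  anchors <- range(rt[cal])
  if (diff(anchors) <= 0) degenerate_anchors("calibrants co-elute")
  data.frame(compound_id = table$compound_id, role = table$role,
             rti = compute_rti(rt, anchors[1], anchors[2]),
             stringsAsFactors = FALSE)
}

subset_descriptors <- function(m, ids) {
  keep <- m$compound_ids %in% ids
  structure(list(compound_ids = m$compound_ids[keep],
                 descriptor_names = m$descriptor_names,
                 values = m$values[keep, , drop = FALSE],
                 cleaning_log = m$cleaning_log, truth = m$truth),
            class = "descriptor_matrix")
}

#' Assemble a pipeline run configuration
#'
#' Either `sim` (a [simulation_config()]) or both `compounds_path` and
#' `systems_path` must be given. The prediction arm runs only for simulated
#' studies (it needs the synthetic descriptor mapping); file-based runs
#' cover ingestion, similarity, spacing and projection.
#'
#' @param out_dir output directory (created if needed).
#' @param sim optional [simulation_config()].
#' @param compounds_path,systems_path optional input CSVs
#'   (see [read_rt_table()], [read_cs_metadata()]).
#' @param min_shared minimum shared calibrants per pair (default 8).
#' @param alpha significance level of the F-tests (default 0.05).
#' @param k spline basis dimension (default 6).
#' @param seed global seed (default: the simulation seed, else 1).
#' @param include_out_of_range_targets see [run_all_pairs()].
#' @param calibration `"gam"` or `"linear"`, see [predict_and_calibrate()].
#' @param mechanism_filter mechanisms admitted to pair analyses
#'   (default `"RP"`).
#' @param with_prediction run the prediction arm (default TRUE).
#' @param n_training external training-set size for the prediction arm
#'   (default 400).
#' @param xgb_grid hyperparameter grid (default [default_xgb_grid()]).
#' @param make_plots write heatmap and cumulative-spacing plots
#'   (default FALSE; plots are artifacts, every test surface is tabular).
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, compounds_path = NULL,
                       systems_path = NULL, min_shared = 8, alpha = 0.05,
                       k = 6, seed = NULL, include_out_of_range_targets = TRUE,
                       calibration = "gam", mechanism_filter = "RP",
                       with_prediction = TRUE, n_training = 400,
                       xgb_grid = default_xgb_grid(), make_plots = FALSE) {
  if (is.null(sim) && (is.null(compounds_path) || is.null(systems_path))) {
    validation_error("run_config needs either `sim` or both input paths")
  }
  stopifnot(alpha > 0, alpha < 1, k >= 3)
  seed <- seed %||% (if (!is.null(sim)) sim$seed else 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest or simulate; retention-order and retention-time
#' similarity matrices with cluster order; peak-spacing summaries; all-pairs
#' spline projection; (synthetic studies) descriptor-based prediction with
#' calibrant recalibration and calibrant-only local models; per-pair
#' projection-vs-prediction F-test classification. All tabular outputs are
#' written through [write_table()], so a rerun under the same configuration
#' is byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- character(0)

  # -- ingest / simulate ------------------------------------------------
  if (!is.null(config$sim)) {
    study <- simulate_study(config$sim, min_shared = config$min_shared)
    table <- study$table; systems <- study$systems
  } else {
    study <- NULL
    table <- read_rt_table(config$compounds_path)
    systems <- read_cs_metadata(config$systems_path)
  }
  paths <- c(paths, write_rt_table(table, out("compounds.csv")),
             write_cs_metadata(systems, out("systems.csv")))

  mech <- vapply(systems, `[[`, character(1), "mechanism")
  keep_ids <- names(systems)[mech %in% config$mechanism_filter]
  pair_table <- table[, c("compound_id", "role", paste0("rt_", keep_ids))]
  pair_table <- as_retention_table(pair_table)
  pair_systems <- systems[keep_ids]

  # -- similarity -------------------------------------------------------
  sims <- list(spearman = similarity_matrix(pair_table, "spearman"),
               pearson = similarity_matrix(pair_table, "pearson"))
  for (meth in names(sims)) {
    v <- as.data.frame(sims[[meth]]$values)
    v <- cbind(cs_id = rownames(v), v)
    paths <- c(paths, write_table(v, out(paste0("similarity_", meth, ".csv")),
                                  keys = "cs_id"))
  }
  clust <- cluster_order(sims$spearman)
  writeLines(clust$order, out("cluster_order.txt"))
  paths <- c(paths, out("cluster_order.txt"))

  # -- peak spacing -----------------------------------------------------
  spacing <- lapply(pair_systems, function(s) {
    tryCatch(spacing_summary(pair_table, s), rtbridge_error = function(e) NULL)
  })
  spacing <- Filter(Negate(is.null), spacing)
  sp_rows <- do.call(rbind, lapply(spacing, function(s) {
    data.frame(cs_id = s$cs_id, n_detected = s$n_detected,
               sd_normalized = s$sd_normalized, max_normalized = s$max_normalized,
               stringsAsFactors = FALSE)
  }))
  paths <- c(paths, write_table(sp_rows, out("spacing_summary.csv"), keys = "cs_id"))
  cdf_rows <- do.call(rbind, lapply(spacing, function(s) {
    cbind(cs_id = s$cs_id, s$cumulative_curve)
  }))
  paths <- c(paths, write_table(cdf_rows, out("spacing_cdf.csv"),
                                keys = c("cs_id", "normalized_rt")))

  # -- projection -------------------------------------------------------
  run <- run_all_pairs(pair_table, pair_systems, min_shared = config$min_shared,
                       k = config$k,
                       include_out_of_range_targets = config$include_out_of_range_targets,
                       mechanism_filter = config$mechanism_filter)
  proj_pairs <- summarize_projection_run(run)
  paths <- c(paths, write_table(proj_pairs, out("projection_pairs.csv"),
                                keys = c("cs_source", "cs_target")))
  detail <- do.call(rbind, lapply(run$results, function(r) {
    cbind(cs_source = r$cs_source, cs_target = r$cs_target, r$detail)
  }))
  rownames(detail) <- NULL
  paths <- c(paths, write_table(detail, out("projection_detail.csv"),
                                keys = c("cs_source", "cs_target", "id")))
  if (nrow(run$skipped) > 0) {
    paths <- c(paths, write_table(run$skipped, out("projection_skipped.csv"),
                                  keys = c("cs_source", "cs_target")))
  }

  # -- prediction arm ---------------------------------------------------
  prediction <- NULL
  if (config$with_prediction && !is.null(study)) {
    prediction <- run_prediction_arm(study, pair_systems, config)
    paths <- c(paths,
               write_table(prediction$summary, out("prediction_summary.csv"),
                           keys = "cs_id"),
               write_table(prediction$detail, out("prediction_detail.csv"),
                           keys = c("cs_id", "id")))
  }

  # -- projection vs prediction -----------------------------------------
  comparison <- NULL
  if (!is.null(prediction)) {
    records <- lapply(run$results, function(r) {
      pd <- prediction$detail[prediction$detail$cs_id == r$cs_target, ]
      classify_pair(
        proj = data.frame(id = r$detail$id, rti_projected = r$detail$rti_projected,
                          rti_observed = r$detail$rti_observed_target),
        pred = data.frame(id = pd$id, rti_predicted = pd$rti_calibrated,
                          rti_observed = pd$rti_observed),
        cs_source = r$cs_source, cs_target = r$cs_target, alpha = config$alpha)
    })
    comp_rows <- do.call(rbind, lapply(records, function(x) {
      as.data.frame(unclass(x)[c("cs_source", "cs_target", "n_common_suspects",
                                 "rmse_projection", "rmse_prediction",
                                 "f_statistic", "p_value", "verdict")],
                    stringsAsFactors = FALSE)
    }))
    rownames(comp_rows) <- NULL
    paths <- c(paths, write_table(comp_rows, out("comparison_pairs.csv"),
                                  keys = c("cs_source", "cs_target")))
    agg <- aggregate_comparison(records)
    comparison <- list(records = records, aggregate = agg)
    summary_json <- list(
      n_pairs_projected = nrow(proj_pairs),
      frac_post_gam_improved = mean(proj_pairs$improved),
      frac_post_gam_improved_significant = mean(
        proj_pairs$improved & !is.na(proj_pairs$p_improvement) &
          proj_pairs$p_improvement < config$alpha),
      projection_rmse_suspects = sqrt(mean(detail$abs_dev^2)),
      verdict_counts = agg$counts,
      verdict_fractions = agg$fractions,
      n_excluded_pairs = agg$n_excluded)
    jsonlite::write_json(summary_json, out("comparison_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, out("comparison_summary.json"))
  }

  # -- plots ------------------------------------------------------------
  if (isTRUE(config$make_plots)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(out("heatmap_spearman.png"), width = 900, height = 800)
      pheatmap::pheatmap(sims$spearman$values,
                         clustering_distance_rows = stats::as.dist(1 - sims$spearman$values),
                         clustering_distance_cols = stats::as.dist(1 - sims$spearman$values),
                         clustering_method = "average",
                         color = grDevices::colorRampPalette(c("blue", "white", "red"))(50))
      grDevices::dev.off()
    }
    grDevices::png(out("spacing_cdf.png"), width = 900, height = 600)
    graphics::plot(NULL, xlim = c(0, 1000), ylim = c(0, 1),
                   xlab = "normalized RT (index units)", ylab = "fraction eluted")
    for (s in spacing) graphics::lines(s$cumulative_curve, col = "grey40")
    grDevices::dev.off()
  }

  manifest <- list(
    package = "rtbridge",
    package_version = as.character(utils::packageVersion("rtbridge")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    min_shared = config$min_shared, alpha = config$alpha, k = config$k,
    calibration = config$calibration,
    mechanism_filter = config$mechanism_filter,
    simulated = !is.null(config$sim),
    files = sort(basename(paths)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(table = table, systems = systems, similarity = sims,
                 cluster = clust, spacing = spacing, projection = run,
                 projection_pairs = proj_pairs, prediction = prediction,
                 comparison = comparison, paths = c(paths, out("manifest.json"))))
}

# Prediction arm over a simulated study: one external model, recalibrated
# per target system; plus calibrant-only local models.
run_prediction_arm <- function(study, systems, config) {
  seed <- config$seed
  train <- simulate_training_set(n = config$n_training,
                                 seed = fan_seed(seed, 31),
                                 descriptor_seed = fan_seed(seed, 32))
  # guard: study compounds never enter the training table
  overlap <- train$compounds$compound_id %in% study$table$compound_id
  if (any(overlap)) {
    train$rt <- train$rt[!overlap]
    train$descriptors <- subset_descriptors(train$descriptors,
                                            train$compounds$compound_id[!overlap])
    train$compounds <- train$compounds[!overlap, ]
  }
  train_dm <- clean_descriptor_matrix(train$descriptors)
  rts <- train$rt[match(train_dm$compound_ids, train$compounds$compound_id)]
  model <- train_rt_model(train_dm, rts, seed = fan_seed(seed, 33),
                          grid = config$xgb_grid)

  study_dm <- simulate_descriptors(study$truth$compounds,
                                   seed = fan_seed(seed, 32))
  cal_ids <- study$table$compound_id[study$table$role == "calibrant"]
  sus_ids <- study$table$compound_id[study$table$role == "suspect"]
  cal_dm <- subset_descriptors(study_dm, cal_ids)
  sus_dm <- subset_descriptors(study_dm, sus_ids)

  detail <- NULL; summary_rows <- NULL
  for (s in systems) {
    rti_obs <- tryCatch(system_rti(study$table, s$cs_id),
                        rtbridge_error = function(e) NULL)
    if (is.null(rti_obs)) next
    cal_rti <- rti_obs$rti[match(cal_dm$compound_ids, rti_obs$compound_id)]
    res <- tryCatch(
      predict_and_calibrate(model, sus_dm, cal_dm, cal_rti, k = config$k,
                            min_shared = config$min_shared,
                            calibration = config$calibration),
      rtbridge_error = function(e) NULL)
    if (is.null(res)) next
    res$rti_observed <- rti_obs$rti[match(res$id, rti_obs$compound_id)]
    res <- cbind(cs_id = s$cs_id, res)
    detail <- rbind(detail, res)
    ok <- !is.na(res$rti_calibrated) & !is.na(res$rti_observed)
    if (sum(ok) >= 3) {
      es <- error_summary(res$rti_calibrated[ok] - res$rti_observed[ok],
                          observed = res$rti_observed[ok],
                          predicted = res$rti_calibrated[ok])
      cal_fit <- predict_and_calibrate(model, cal_dm, cal_dm, cal_rti,
                                       k = config$k, min_shared = config$min_shared,
                                       calibration = config$calibration)
      okc <- !is.na(cal_fit$rti_calibrated) & !is.na(cal_rti)
      es_cal <- error_summary(cal_fit$rti_calibrated[okc] - cal_rti[okc])
      summary_rows <- rbind(summary_rows, data.frame(
        cs_id = s$cs_id, n_suspects = es$n, rmse_suspects = es$rmse,
        mad_suspects = es$mad, p95_suspects = es$p95_abs_dev, r2_suspects = es$r2,
        n_calibrants = es_cal$n, rmse_calibrants = es_cal$rmse,
        stringsAsFactors = FALSE))
    }
  }
  rownames(detail) <- NULL
  list(model = model, train = train, detail = detail, summary = summary_rows,
       study_descriptors = study_dm)
}
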