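# Synthetic interlaboratory retention data with known ground truth.
#
# Each compound carries a one-dimensional latent elution coordinate u in
# (0, 1) — a log-hydrophobicity surrogate. A chromatographic system turns u
# into a retention time through a strictly monotone warp derived from its
# gradient program: elution "mass" accrues with the organic sweep plus a
# small isocratic baseline, so gradient segments spread peaks and isocratic
# plateaus compress them. Mobile-phase additive chemistry acts
# in latent space: in ammonium-salt systems, basic compounds shift to later
# (and acidic compounds to earlier) effective coordinates, which reorders
# elution relative to formic-acid systems. Measurement noise and Bernoulli
# detection dropout are applied last. The truth record keeps every latent
# quantity for oracle checks.

#' Configuration for a synthetic interlaboratory study
#'
#' Defaults mirror the shape of a reversed-phase interlaboratory campaign:
#' 41 calibrants and 45 suspects shared across systems whose programs run
#' 15-54 minutes, with per-system detection dropout.
#'
#' @param n_systems number of chromatographic systems (default 20).
#' @param n_calibrants,n_suspects compound counts (defaults 41 and 45).
#' @param run_time_range range of program lengths in minutes (default 15-54).
#' @param frac_ionizable fraction of compounds that are ionizable (split
#'   evenly acid/base; default 0.4).
#' @param additive_mix fraction of systems using an ammonium-salt additive
#'   (the rest use formic acid; default 0.25).
#' @param delta_ion latent-coordinate shift magnitude for ionizables in
#'   ammonium-salt systems: bases later by `+delta_ion`, acids earlier by
#'   `-delta_ion` (default 0.08).
#' @param noise_sd retention-time measurement noise, minutes (default 0.13;
#'   on a 15-minute program this is about 10 index units).
#' @param dropout_rate per-(compound, system) probability of non-detection
#'   (default 0.15).
#' @param seed integer seed; one seed fans out to per-component streams.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_systems = 20, n_calibrants = 41, n_suspects = 45,
                              run_time_range = c(15, 54), frac_ionizable = 0.4,
                              additive_mix = 0.25, delta_ion = 0.08,
                              noise_sd = 0.13, dropout_rate = 0.15, seed = 1) {
  stopifnot(n_systems >= 2, n_calibrants >= 2, n_suspects >= 2,
            length(run_time_range) == 2, run_time_range[1] > 0,
            run_time_range[2] >= run_time_range[1],
            frac_ionizable >= 0, frac_ionizable <= 1,
            additive_mix >= 0, additive_mix <= 1,
            delta_ion >= 0, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Draw the shared compound set
#'
#' Latent coordinates are uniform on (0.02, 0.98) and tie-free; ionizable
#' compounds are split evenly into acids and bases and given pKa values
#' uniform on \[3.6, 8.1\].
#'
#' @param config a [simulation_config()].
#' @return Data frame with `compound_id`, `role`, `latent_u`, `ion_class`
#'   (`neutral`/`acid`/`base`) and `pka` (`NA` for neutrals).
#' @export
simulate_compounds <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(fan_seed(config$seed, 1))
  n <- config$n_calibrants + config$n_suspects
  u <- stats::runif(n, 0.02, 0.98)
  while (anyDuplicated(u)) u <- stats::runif(n, 0.02, 0.98)
  n_ion <- round(config$frac_ionizable * n)
  ion_class <- rep("neutral", n)
  if (n_ion > 0) {
    idx <- sample.int(n, n_ion)
    half <- seq_len(floor(n_ion / 2))
    ion_class[idx] <- "base"
    ion_class[idx[half]] <- "acid"
  }
  pka <- ifelse(ion_class == "neutral", NA_real_, stats::runif(n, 3.6, 8.1))
  data.frame(
    compound_id = c(sprintf("cal_%02d", seq_len(config$n_calibrants)),
                    sprintf("sus_%02d", seq_len(config$n_suspects))),
    role = rep(c("calibrant", "suspect"),
               c(config$n_calibrants, config$n_suspects)),
    latent_u = u, ion_class = ion_class, pka = pka,
    stringsAsFactors = FALSE
  )
}

#' Build the monotone elution warp of a system
#'
#' Maps the latent coordinate u in \[0, 1\] to a retention time in minutes.
#' Elution mass accrues at rate `|dphi/dt| + baseline` over the active
#' elution window — from the end of any initial hold (nothing elutes during
#' a low-organic hold) to the end of the last gradient segment. Inverting
#' the normalized cumulative mass, smoothed by a monotone (Hyman) cubic
#' through the segment knots the way instrument dwell volume rounds gradient
#' transitions, gives a strictly increasing warp with `RT(0)` at the
#' dead-time floor (0.5 min) and `RT(1)` at or before the end of the run.
#' A terminal isocratic plateau compresses late eluters toward the end of
#' the gradient.
#'
#' @param system a `chrom_system`.
#' @param baseline isocratic baseline elution mass over a full run
#'   (default 0.05, dimensionless).
#' @param dead_time earliest possible elution, minutes (default 0.5).
#' @return A `system_warp`: list with `fun(u)`, the `(u, rt)` knots,
#'   `reversed` (TRUE when the net organic sweep is negative), and `t_hi`.
#' @export
build_system_warp <- function(system, baseline = 0.05, dead_time = 0.5) {
  seg <- system$gradient_segments
  run_time <- system$run_time
  sweep <- seg$phi_end - seg$phi_start
  reversed <- sum(sweep) < 0
  grad <- abs(sweep) > 1e-9
  # active elution window: nothing elutes during an initial hold, and
  # elution is over by the end of the last gradient segment
  t_lo <- if (any(grad)) min(seg$t_start[grad]) else 0
  t_hi <- if (any(grad)) max(seg$t_end[grad]) else run_time
  keep <- seg$t_end > t_lo + 1e-12 & seg$t_start < t_hi - 1e-12
  seg <- seg[keep, , drop = FALSE]
  w <- abs(sweep[keep]) + baseline * (seg$t_end - seg$t_start) / run_time
  knot_t <- c(t_lo, seg$t_end)
  cum_w <- c(0, cumsum(w))
  f <- cum_w / cum_w[length(cum_w)]
  knot_rt <- dead_time + (knot_t - t_lo) * (t_hi - dead_time) / (t_hi - t_lo)
  if (any(diff(f) <= 0) || any(diff(knot_rt) <= 0)) {
    stop("internal error: constructed warp is not strictly increasing")
  }
  # monotone (Hyman-filtered) cubic through the knots: gradient transitions
  # are smoothed, as instrument dwell volume does in practice
  fun <- if (length(f) > 2) {
    stats::splinefun(f, knot_rt, method = "hyman")
  } else {
    function(u) stats::approx(f, knot_rt, xout = u, rule = 2)$y
  }
  structure(list(fun = fun, knots = data.frame(u = f, rt = knot_rt),
                 reversed = reversed, t_hi = t_hi, dead_time = dead_time),
            class = "system_warp")
}

# Additive-dependent latent shift: bases later, acids earlier in
# ammonium-salt systems; formic acid is the reference (no shift).
apply_ion_shift <- function(u, ion_class, additive_class, delta_ion) {
  if (additive_class %in% c("ammonium_salt", "mixed")) {
    u <- u + delta_ion * (ion_class == "base") - delta_ion * (ion_class == "acid")
  }
  u
}

# Affine squash into (0.02, 0.98): order-preserving, keeps the shifted
# coordinates inside the warp domain without clamping ties.
squash_unit <- function(u) 0.02 + 0.96 * (u - min(u)) / (max(u) - min(u))

random_gradient_program <- function(run_time) {
  h0 <- if (stats::runif(1) < 0.5) stats::runif(1, 0.03, 0.12) * run_time else 0
  h1 <- if (stats::runif(1) < 0.5) stats::runif(1, 0.08, 0.30) * run_time else 0
  g0 <- h0; g1 <- run_time - h1
  phi0 <- 0.05; phi1 <- 0.95
  seg <- NULL
  if (h0 > 0) seg <- rbind(seg, c(0, g0, phi0, phi0))
  if (stats::runif(1) < 0.5) {
    # two-slope gradient; slope contrast kept moderate so the elution map
    # stays within what a low-dimension smooth can represent
    tm <- g0 + stats::runif(1, 0.45, 0.55) * (g1 - g0)
    pm <- phi0 + stats::runif(1, 0.42, 0.58) * (phi1 - phi0)
    seg <- rbind(seg, c(g0, tm, phi0, pm), c(tm, g1, pm, phi1))
  } else {
    seg <- rbind(seg, c(g0, g1, phi0, phi1))
  }
  if (h1 > 0) seg <- rbind(seg, c(g1, run_time, phi1, phi1))
  seg <- as.data.frame(seg)
  names(seg) <- c("t_start", "t_end", "phi_start", "phi_end")
  seg
}

#' Simulate a full interlaboratory study
#'
#' Draws the compound set and a fleet of reversed-phase systems with random
#' gradient programs (holds, one- or two-slope gradients, terminal
#' plateaus), applies the additive-dependent latent shifts, warps, Gaussian
#' retention-time noise and detection dropout, and returns the retention
#' table together with the ground truth.
#'
#' @param config a [simulation_config()].
#' @param noise_systems cs_ids to which measurement noise is applied
#'   (default `NULL` = all systems); useful for oracle checks that need one
#'   noise-free side.
#' @param min_shared used only to warn when dropout leaves a pair with too
#'   few shared calibrants (default 8).
#' @return List with `table` (a `retention_table`), `systems` (named list of
#'   `chrom_system`), and `truth` (compounds with latent coordinates, the
#'   effective per-system coordinates, warps and config).
#' @export
simulate_study <- function(config, noise_systems = NULL, min_shared = 8) {
  stopifnot(inherits(config, "simulation_config"))
  compounds <- simulate_compounds(config)

  set.seed(fan_seed(config$seed, 2))
  n_sys <- config$n_systems
  cs_ids <- sprintf("CS%02d", seq_len(n_sys))
  run_times <- stats::runif(n_sys, config$run_time_range[1], config$run_time_range[2])
  n_amm <- round(config$additive_mix * n_sys)
  additive <- rep("formic_acid", n_sys)
  if (n_amm > 0) additive[sample.int(n_sys, n_amm)] <- "ammonium_salt"
  chem <- sample(c("C18", "C8", "biphenyl"), n_sys, replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))
  systems <- lapply(seq_len(n_sys), function(i) {
    chrom_system(cs_id = cs_ids[i], mechanism = "RP", column_chemistry = chem[i],
                 additive_class = additive[i], run_time = run_times[i],
                 gradient_segments = random_gradient_program(run_times[i]))
  })
  names(systems) <- cs_ids
  warps <- lapply(systems, build_system_warp)

  u_eff <- sapply(seq_len(n_sys), function(i) {
    u <- apply_ion_shift(compounds$latent_u, compounds$ion_class,
                         additive[i], config$delta_ion)
    u <- squash_unit(u)
    if (warps[[i]]$reversed) 1 - u else u
  })
  colnames(u_eff) <- cs_ids

  rt_clean <- sapply(seq_len(n_sys), function(i) warps[[i]]$fun(u_eff[, i]))
  set.seed(fan_seed(config$seed, 3))
  noisy <- if (is.null(noise_systems)) rep(TRUE, n_sys) else cs_ids %in% noise_systems
  rt <- rt_clean
  for (i in seq_len(n_sys)) {
    if (noisy[i] && config$noise_sd > 0) {
      rt[, i] <- rt[, i] + stats::rnorm(nrow(rt), 0, config$noise_sd)
      rt[, i] <- pmin(pmax(rt[, i], 0.05), run_times[i])
    }
  }
  set.seed(fan_seed(config$seed, 4))
  if (config$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(rt)) < config$dropout_rate, nrow = nrow(rt))
    rt[drop] <- NA
  }
  colnames(rt) <- paste0("rt_", cs_ids)

  table <- cbind(compounds[, c("compound_id", "role")], as.data.frame(rt))
  table <- as_retention_table(table)

  cal_det <- !is.na(rt[compounds$role == "calibrant", , drop = FALSE])
  shared <- crossprod(cal_det)
  if (any(shared[upper.tri(shared)] < min_shared)) {
    warning("some system pairs have fewer than ", min_shared,
            " shared calibrants and will be skipped downstream")
  }

  list(table = table, systems = systems,
       truth = list(compounds = compounds, u_eff = u_eff, warps = warps,
                    rt_clean = rt_clean, config = config))
}

#' Simulate a molecular-descriptor matrix with known informative columns
#'
#' Informative columns are monotone functions of the latent elution
#' coordinate plus noise; two ionization columns encode acid/base character
#' (the structural information a real descriptor set carries about charge
#' state); the rest are pure noise. The column-generating transforms are
#' drawn from `seed` alone, so two compound sets rendered with the same seed
#' share the same descriptor mapping and models transfer between them.
#' Defect columns (constant, duplicated, missing-polluted) can be planted to
#' exercise the cleaning rules.
#'
#' @param compounds data frame with `compound_id`, `latent_u`, `ion_class`
#'   (as from [simulate_compounds()]).
#' @param n_descriptors total number of columns before planted defects
#'   (default 40).
#' @param n_informative number of u-informative columns (default 5).
#' @param noise_sd noise on informative columns (default 0.05, relative to a
#'   unit-range signal).
#' @param seed integer seed for the descriptor mapping.
#' @param plant_constant,plant_duplicate,plant_missing numbers of planted
#'   constant / duplicated / missing-polluted columns (defaults 0).
#' @param missing_count missing cells per polluted column (default 16).
#' @return A `descriptor_matrix`: list with `compound_ids`,
#'   `descriptor_names`, `values` and a `truth` element naming the
#'   informative columns.
#' @export
simulate_descriptors <- function(compounds, n_descriptors = 40, n_informative = 5,
                                 noise_sd = 0.05, seed = 1,
                                 plant_constant = 0, plant_duplicate = 0,
                                 plant_missing = 0, missing_count = 16) {
  stopifnot(n_informative + 2 <= n_descriptors)
  n <- nrow(compounds)
  u <- compounds$latent_u
  ion_sign <- (compounds$ion_class == "base") - (compounds$ion_class == "acid")

  set.seed(fan_seed(seed, 11))
  # transform parameters drawn independently of the compound set
  types <- sample(c("linear", "sqrt", "log", "pow"), n_informative, replace = TRUE)
  scales <- stats::runif(n_informative, 0.5, 2)
  powers <- stats::runif(n_informative, 1.5, 3)

  set.seed(fan_seed(seed, 12 + n))  # noise stream depends on the set size
  vals <- matrix(stats::rnorm(n * n_descriptors), nrow = n)
  for (j in seq_len(n_informative)) {
    sig <- switch(types[j], linear = u, sqrt = sqrt(u),
                  log = log1p(4 * u) / log(5), pow = u^powers[j])
    vals[, j] <- scales[j] * sig + stats::rnorm(n, 0, noise_sd)
  }
  vals[, n_informative + 1] <- ion_sign + stats::rnorm(n, 0, 0.1)
  vals[, n_informative + 2] <- 0.5 * ion_sign + stats::rnorm(n, 0, 0.1)
  names_main <- c(sprintf("D_info%02d", seq_len(n_informative)),
                  "D_ion1", "D_ion2",
                  sprintf("D_noise%02d", seq_len(n_descriptors - n_informative - 2)))
  colnames(vals) <- names_main

  if (plant_constant > 0) {
    cc <- matrix(7.7, n, plant_constant,
                 dimnames = list(NULL, sprintf("D_const%02d", seq_len(plant_constant))))
    vals <- cbind(vals, cc)
  }
  if (plant_duplicate > 0) {
    dd <- vals[, rep("D_info01", plant_duplicate), drop = FALSE]
    colnames(dd) <- sprintf("D_dup%02d", seq_len(plant_duplicate))
    vals <- cbind(vals, dd)
  }
  if (plant_missing > 0) {
    mm <- matrix(stats::rnorm(n * plant_missing), n,
                 dimnames = list(NULL, sprintf("D_miss%02d", seq_len(plant_missing))))
    for (j in seq_len(plant_missing)) {
      mm[sample.int(n, min(missing_count, n)), j] <- NA
    }
    vals <- cbind(vals, mm)
  }
  rownames(vals) <- compounds$compound_id
  structure(list(compound_ids = compounds$compound_id,
                 descriptor_names = colnames(vals), values = vals,
                 cleaning_log = NULL,
                 truth = list(informative = names_main[seq_len(n_informative + 2)])),
            class = "descriptor_matrix")
}

#' Simulate an external training set for the prediction arm
#'
#' A stand-in for a large public (structure, RT) training table: `n` fresh
#' compounds measured on one training system with its own additive class.
#' Descriptors are rendered with the same mapping seed as the study
#' compounds so a model trained here transfers to them.
#'
#' @param n number of training compounds (default 500).
#' @param seed integer seed.
#' @param descriptor_seed seed of the shared descriptor mapping (default
#'   `seed`; pass the study's descriptor seed to share the mapping).
#' @param additive_class additive class of the training system (default
#'   `"ammonium_salt"`).
#' @param run_time training program length, minutes (default 15.5).
#' @param frac_ionizable,delta_ion,noise_sd as in [simulation_config()].
#' @param n_descriptors,n_informative,descriptor_noise forwarded to
#'   [simulate_descriptors()].
#' @return List with `descriptors` (a `descriptor_matrix`), `rt` (minutes),
#'   `compounds`, and `system` (a `chrom_system`).
#' @export
simulate_training_set <- function(n = 500, seed = 1, descriptor_seed = seed,
                                  additive_class = "ammonium_salt",
                                  run_time = 15.5, frac_ionizable = 0.4,
                                  delta_ion = 0.08, noise_sd = 0.1,
                                  n_descriptors = 40, n_informative = 5,
                                  descriptor_noise = 0.05) {
  set.seed(fan_seed(seed, 21))
  u <- stats::runif(n, 0.02, 0.98)
  n_ion <- round(frac_ionizable * n)
  ion_class <- rep("neutral", n)
  if (n_ion > 0) {
    idx <- sample.int(n, n_ion)
    ion_class[idx] <- "base"
    ion_class[idx[seq_len(floor(n_ion / 2))]] <- "acid"
  }
  compounds <- data.frame(compound_id = sprintf("trn_%04d", seq_len(n)),
                          role = "suspect", latent_u = u,
                          ion_class = ion_class, stringsAsFactors = FALSE)
  system <- chrom_system(
    cs_id = "CS_training", mechanism = "RP", column_chemistry = "C18",
    additive_class = additive_class, run_time = run_time,
    gradient_segments = data.frame(t_start = c(0, 1, run_time - 1.5),
                                   t_end = c(1, run_time - 1.5, run_time),
                                   phi_start = c(0.05, 0.05, 0.95),
                                   phi_end = c(0.05, 0.95, 0.95)))
  warp <- build_system_warp(system)
  u_eff <- squash_unit(apply_ion_shift(u, ion_class, additive_class, delta_ion))
  set.seed(fan_seed(seed, 22))
  rt <- warp$fun(u_eff) + stats::rnorm(n, 0, noise_sd)
  rt <- pmin(pmax(rt, 0.05), run_time)
  descriptors <- simulate_descriptors(compounds, n_descriptors = n_descriptors,
                                      n_informative = n_informative,
                                      noise_sd = descriptor_noise,
                                      seed = descriptor_seed)
  list(descriptors = descriptors, rt = rt, compounds = compounds, system = system)
}
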