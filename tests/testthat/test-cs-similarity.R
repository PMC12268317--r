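test_that("pairwise_correlation distinguishes linear from merely monotone agreement", {
  a <- c(1, 2.5, 4, 7, 9)
  expect_equal(pairwise_correlation(a, 2 * a + 1, "pearson"), 1)
  expect_equal(pairwise_correlation(a, 2 * a + 1, "spearman"), 1)
  # monotone but nonlinear: order preserved, linearity broken
  expect_equal(pairwise_correlation(a, exp(a), "spearman"), 1)
  expect_lt(pairwise_correlation(a, exp(a), "pearson"), 1)
})

test_that("spearman matches the closed rank-difference form", {
  # ranks (1,2,3,4) vs (2,1,3,4): 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 12/60
  expect_equal(pairwise_correlation(c(1, 2, 3, 4), c(2, 1, 3, 4), "spearman"), 0.8)
})

test_that("undefined coefficients come back as missing", {
  expect_true(is.na(pairwise_correlation(c(1, 2), c(3, 4), "pearson")))      # n < 3
  expect_true(is.na(pairwise_correlation(c(1, 2, NA), c(3, 4, 5), "pearson")))
  expect_true(is.na(pairwise_correlation(c(1, 1, 1), c(3, 4, 5), "pearson"))) # no variance
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(11)
  st <- simulate_study(simulation_config(n_systems = 6, seed = 11))
  for (method in c("pearson", "spearman")) {
    sm <- similarity_matrix(st$table, method)
    expect_equal(sm$values, t(sm$values))
    expect_equal(unname(diag(sm$values)), rep(1, 6))
    expect_true(all(abs(sm$values) <= 1 + 1e-12, na.rm = TRUE))
    expect_equal(sm$n_shared, t(sm$n_shared))
  }
})

test_that("a duplicated system correlates perfectly with its twin", {
  tab <- tiny_rt_table()
  tab$rt_C <- tab$rt_A
  sm <- similarity_matrix(as_retention_table(tab), "spearman")
  expect_equal(sm$values["A", "C"], 1)
})

test_that("spearman entries are invariant under strictly monotone warps", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 20
    rt_a <- sort(runif(n, 1, 20))
    tab <- two_system_table(rt_a, rt_a, n_cal = 10)
    # random strictly increasing warp of system B
    p <- runif(1, 0.4, 2.5); s <- runif(1, 0.5, 2)
    tab$rt_B <- s * tab$rt_B^p + runif(1, 0, 2)
    sm <- similarity_matrix(tab, "spearman")
    expect_equal(sm$values["A", "B"], 1)
  }
})

test_that("a reversed-gradient system anti-correlates with the fleet", {
  cfg <- simulation_config(n_systems = 4, additive_mix = 0, noise_sd = 0,
                           dropout_rate = 0, seed = 3)
  st <- simulate_study(cfg)
  rev_sys <- chrom_system(cs_id = "REV", run_time = 20,
                          gradient_segments = data.frame(
                            t_start = 0, t_end = 20,
                            phi_start = 0.95, phi_end = 0.05))
  w <- build_system_warp(rev_sys)
  expect_true(w$reversed)
  u <- st$truth$u_eff[, 1]
  tab <- st$table
  tab$rt_REV <- w$fun(1 - u)
  sm <- similarity_matrix(as_retention_table(tab), "spearman")
  expect_true(all(sm$values["REV", colnames(sm$values) != "REV"] < 0))
})

test_that("cluster_order merges duplicates first and is lexical under ties", {
  set.seed(9)
  rt <- sort(runif(12, 1, 18))
  tab <- data.frame(compound_id = sprintf("x%02d", 1:12),
                    role = rep(c("calibrant", "suspect"), c(8, 4)),
                    rt_E = rt, rt_B = rt^1.3, rt_D = sqrt(rt) * 4,
                    rt_C = rt^2, rt_A = rt^1.3)
  sm <- similarity_matrix(as_retention_table(tab), "pearson")
  co <- cluster_order(sm)
  # A and B are byte-identical systems: zero distance, first merge
  first <- co$tree$merge[1, ]
  expect_true(all(first < 0))
  expect_setequal(sort(co$order)[match(c("A", "B"), sort(co$order))], c("A", "B"))
  expect_equal(abs(first), match(c("A", "B"), sort(sm$cs_ids)))

  # all-identical coefficients: one flat cluster, lexical leaf order
  flat <- sm
  flat$values[] <- 1
  expect_equal(cluster_order(flat)$order, sort(sm$cs_ids))
})

test_that("clustering separates additive classes into near-pure blocks", {
  purity <- function(order, classes) {
    cls <- classes[order]
    mean(vapply(unique(cls), function(k) {
      r <- rle(cls == k)
      max(r$lengths[r$values]) / sum(cls == k)
    }, numeric(1)))
  }
  scores <- vapply(1:20, function(s) {
    st <- simulate_study(simulation_config(n_systems = 10, additive_mix = 0.4,
                                           noise_sd = 0.05, dropout_rate = 0.1,
                                           seed = 1000 + s))
    sm <- similarity_matrix(st$table, "spearman")
    co <- cluster_order(sm)
    cls <- vapply(st$systems, `[[`, character(1), "additive_class")
    purity(co$order, cls)
  }, numeric(1))
  expect_gte(median(scores), 0.9)
})

test_that("bases elute at higher rank under ammonium than under formic additives", {
  cfg <- simulation_config(n_systems = 4, additive_mix = 0.5, noise_sd = 0,
                           dropout_rate = 0, seed = 17)
  st <- simulate_study(cfg)
  add <- vapply(st$systems, `[[`, character(1), "additive_class")
  amm <- names(add)[add == "ammonium_salt"][1]
  frm <- names(add)[add == "formic_acid"][1]
  ranks_amm <- rank(st$table[[paste0("rt_", amm)]])
  ranks_frm <- rank(st$table[[paste0("rt_", frm)]])
  bases <- st$truth$compounds$ion_class == "base"
  expect_true(all(ranks_amm[bases] >= ranks_frm[bases]))
  expect_gt(mean(ranks_amm[bases] > ranks_frm[bases]), 0.8)
  acids <- st$truth$compounds$ion_class == "acid"
  expect_true(all(ranks_amm[acids] <= ranks_frm[acids]))
})
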