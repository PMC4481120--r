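test_that("toad-like template has the study's structure and scale", {
  tpl <- make_template("toad_like")
  expect_equal(dim(tpl), c(35L, 3L))
  map <- expand_sides(default_landmark_scheme())
  left <- tpl[map$side == "L", ]
  right <- tpl[map$side == "R", ]
  mirrored <- left; mirrored[, 2] <- -mirrored[, 2]
  expect_identical(right, mirrored)
  expect_equal(tpl[map$side == "M", 2], rep(0, 5))
  maxd <- max(dist(tpl))
  expect_gte(maxd, 15); expect_lte(maxd, 25)
  expect_identical(make_template("toad_like"), tpl)
})

test_that("template distances reproduce the small-distance structure of the design", {
  cf <- landmark_config("tpl", "T", 1, make_template("toad_like"))
  tab <- average_bilateral(cbind(
    data.frame(individual = "tpl", method = "T", replicate = 1),
    compute_distances(cf, default_landmark_scheme())))
  small <- tab$distance[tab$value_mm < 3]
  expect_setequal(small, c(5, 8, 10, 11, 13, 24))
  expect_equal(tab$value_mm[tab$distance == 17], 7.1, tolerance = 0.01)
})

test_that("random templates are seeded, well-conditioned, and sized as requested", {
  t1 <- make_template("random", K = 6, seed = 99)
  t2 <- make_template("random", K = 6, seed = 99)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(6L, 3L))
  expect_error(make_template("toad_like", K = 10), "35")
})

test_that("simulation is deterministic and matches the requested design", {
  p <- sim_params(n_individuals = 4, seed = 77)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1, s2)
  ds <- s1$dataset
  expect_equal(length(ds$configurations), 4 * 3 * 2)
  expect_setequal(dataset_methods(ds), c("DIG", "MED", "HIGH"))
  units <- vapply(ds$configurations, `[[`, character(1), "units")
  methods <- vapply(ds$configurations, `[[`, character(1), "method")
  expect_true(all(units[methods == "DIG"] == "mm"))
  expect_true(all(units[methods %in% c("MED", "HIGH")] == "voxel"))
  expect_equal(ds$unit_factor[["MED"]], 0.01742)
  expect_equal(ds$unit_factor[["HIGH"]], 0.00871)
})

test_that("the noiseless limit returns the template exactly", {
  p <- sim_params(n_individuals = 3,
                  methods = list(sim_method("A", error_sd = 0)),
                  individual_sd = 0, individual_size_cv = 0,
                  rigid_nuisance = FALSE, seed = 5)
  ds <- simulate_dataset(p)$dataset
  for (cf in ds$configurations)
    expect_equal(unname(cf$coords), unname(p$template))
})

test_that("replicate differences recover the requested error SDs", {
  set.seed(60)
  sdv <- rep(c(0.02, 0.08), length.out = 35)
  p <- sim_params(n_individuals = 1000, n_replicates = 2,
                  methods = list(sim_method("A", error_sd = sdv)),
                  individual_sd = 0.3, rigid_nuisance = FALSE, seed = 60)
  ds <- simulate_dataset(p)$dataset
  reps <- split(ds$configurations,
                vapply(ds$configurations, `[[`, character(1), "individual"))
  # per-coordinate SD of (rep1 - rep2)/sqrt(2) estimates the error SD
  diffs <- t(vapply(reps, function(pair)
    apply((pair[[1]]$coords - pair[[2]]$coords) / sqrt(2), 1,
          function(v) sqrt(mean(v^2))), numeric(35)))
  est <- sqrt(colMeans(diffs^2))
  expect_equal(est, sdv, tolerance = 0.05)
})

test_that("nuisance transforms are rigid by default and scale only when asked", {
  p <- sim_params(n_individuals = 5,
                  methods = list(sim_method("A", error_sd = 0)),
                  individual_sd = 0, individual_size_cv = 0,
                  rigid_nuisance = TRUE, seed = 8)
  ds <- simulate_dataset(p)$dataset
  cs0 <- centroid_size(p$template)
  for (cf in ds$configurations)
    expect_equal(centroid_size(cf$coords), cs0, tolerance = 1e-9)

  ps <- sim_params(n_individuals = 5,
                   methods = list(sim_method("A", error_sd = 0)),
                   individual_sd = 0, individual_size_cv = 0,
                   rigid_nuisance = TRUE, nuisance_scale_range = c(0.5, 2),
                   seed = 8)
  dss <- simulate_dataset(ps)$dataset
  ratios <- vapply(dss$configurations, function(cf)
    centroid_size(cf$coords) / cs0, numeric(1))
  expect_true(all(ratios >= 0.5 - 1e-9 & ratios <= 2 + 1e-9))
  expect_gt(stats::sd(ratios), 0.01)
})

test_that("analytic repeatability: ratio algebra and the error-free limit", {
  p9 <- sim_params(methods = list(sim_method("A", error_sd = 0.05)),
                   individual_sd = 0.15, individual_size_cv = 0,
                   rigid_nuisance = FALSE)
  er <- expected_repeatability(p9, "A")
  expect_equal(er$expected_r, rep(0.9, 24), tolerance = 1e-12)
  p0 <- sim_params(methods = list(sim_method("A", error_sd = 0)),
                   individual_sd = 0.15, individual_size_cv = 0)
  expect_equal(expected_repeatability(p0, "A")$expected_r, rep(1, 24))
  pb <- sim_params(methods = list(sim_method("A", 0.05, bias_sd = 0.1)))
  expect_error(expected_repeatability(pb, "A"), "bias")
})

test_that("the delta-method prediction matches empirical repeatability at large n", {
  set.seed(61)
  dsch <- default_distance_scheme()[c(1, 17, 5), ]  # long, long, small
  class(dsch) <- c("distance_scheme", "data.frame")
  p <- sim_params(n_individuals = 1000,
                  methods = list(sim_method("A", error_sd = 0.06)),
                  individual_sd = 0.12, individual_size_cv = 0,
                  rigid_nuisance = FALSE, seed = 61)
  tab <- distance_table(simulate_dataset(
    p, distance_scheme = dsch)$dataset)
  emp <- within_method_repeatability(tab, "A")$per_distance
  pred <- expected_repeatability(p, "A", distance_scheme = dsch)
  pred <- pred[match(emp$distance, pred$distance), ]
  expect_equal(emp$r, pred$expected_r, tolerance = 0.02)
})
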