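test_that("hand-computed one-way ANOVA: groups (1,3) and (5,7)", {
  vc <- variance_components(c("A", "A", "B", "B"), c(1, 3, 5, 7))
  expect_equal(vc$ms_within, 2)
  expect_equal(vc$ms_among, 16)
  expect_equal(vc$s2_A, 7)
  expect_equal(vc$r, 7 / 9, tolerance = 1e-12)
  expect_false(vc$clipped)
  expect_equal(vc$s2_A, (vc$ms_among - vc$ms_within) / vc$k,
               tolerance = 1e-12)
})

test_that("degenerate variance conventions: zero within-variance and all-constant data", {
  vc1 <- variance_components(rep(c("A", "B", "C"), each = 2),
                             c(2, 2, 5, 5, 9, 9))
  expect_equal(vc1$s2, 0, tolerance = 1e-12)
  expect_equal(vc1$r, 1, tolerance = 1e-10)
  vc2 <- variance_components(rep(c("A", "B"), each = 2), rep(4.2, 4))
  expect_equal(vc2$s2, 0)
  expect_equal(vc2$s2_A, 0)
  expect_equal(vc2$r, 0)
})

test_that("negative among-group estimates are clipped to zero and flagged", {
  set.seed(40)
  # no real group structure and large residual: raw s2_A often negative
  found <- FALSE
  for (i in 1:20) {
    v <- rnorm(8)
    vc <- variance_components(rep(letters[1:4], each = 2), v)
    expect_gte(vc$r, 0)
    expect_gte(vc$s2_A, 0)
    if (vc$clipped) {
      found <- TRUE
      expect_lt(vc$s2_A_raw, 0)
    }
  }
  expect_true(found)
})

test_that("components agree with a raw sums-of-squares oracle, balanced and unbalanced", {
  set.seed(41)
  for (i in 1:25) {
    a <- sample(3:6, 1)
    sizes <- sample(2:4, a, replace = TRUE)
    if (i <= 12) sizes <- rep(sizes[1], a)  # balanced half
    g <- rep(letters[1:a], sizes)
    v <- rnorm(length(g), mean = rep(rnorm(a, sd = 2), sizes))
    vc <- variance_components(g, v)
    oc <- oracle_anova(g, v)
    expect_equal(vc$ms_among, oc$ms_among, tolerance = 1e-10)
    expect_equal(vc$ms_within, oc$ms_within, tolerance = 1e-10)
    expect_equal(vc$s2_A, oc$s2_A, tolerance = 1e-10)
    expect_equal(vc$k, oc$k0, tolerance = 1e-12)
    expect_equal(vc$r, oc$r, tolerance = 1e-10)
    expect_true(vc$r >= 0 && vc$r <= 1)
  }
})

test_that("repeatability is invariant to location shifts, positive scaling, and replicate relabeling", {
  set.seed(42)
  g <- rep(letters[1:10], each = 2)
  v <- rnorm(20, rep(rnorm(10, sd = 3), each = 2))
  r0 <- variance_components(g, v)$r
  expect_equal(variance_components(g, v + 100)$r, r0, tolerance = 1e-10)
  expect_equal(variance_components(g, v * 7.3)$r, r0, tolerance = 1e-10)
  swap <- v
  swap[1:2] <- v[2:1]  # swap replicates within a group
  expect_equal(variance_components(g, swap)$r, r0, tolerance = 1e-12)
})

test_that("single-value groups error unless permissive", {
  expect_error(variance_components(c("a", "a", "b"), c(1, 2, 3)),
               "single value")
  expect_warning(vc <- variance_components(c("a", "a", "b", "b", "c"),
                                           c(1, 2, 5, 6, 9),
                                           permissive = TRUE), "dropping")
  expect_equal(vc$n_groups, 2L)
})

test_that("within-method repeatability recovers the simulated variance ratio", {
  set.seed(43)
  # distance-level individual:error variance 9:1 -> r = 0.9
  p <- sim_params(n_individuals = 200, n_replicates = 2,
                  methods = list(sim_method("A", error_sd = 0.05)),
                  individual_sd = 0.15, individual_size_cv = 0,
                  rigid_nuisance = FALSE, seed = 43)
  tab <- distance_table(simulate_dataset(p)$dataset)
  rep_ <- within_method_repeatability(tab, "A")
  expect_equal(rep_$mean_r, 0.9, tolerance = 0.03)
  expect_equal(mean(expected_repeatability(p, "A")$expected_r), 0.9,
               tolerance = 1e-12)
})

test_that("error-free measurements give r = 1 at every distance", {
  p <- sim_params(n_individuals = 10,
                  methods = list(sim_method("A", error_sd = 0)),
                  rigid_nuisance = FALSE, seed = 44)
  tab <- distance_table(simulate_dataset(p)$dataset)
  rep_ <- within_method_repeatability(tab, "A")
  expect_equal(rep_$per_distance$r, rep(1, 24), tolerance = 1e-8)
})

test_that("between-method join uses shared individuals and pooled replicates", {
  set.seed(45)
  # method B measured on 4 fewer individuals, as when specimens are lost
  p <- sim_params(n_individuals = 20,
                  methods = list(sim_method("A", 0.04),
                                 sim_method("B", 0.04)),
                  rigid_nuisance = FALSE, seed = 45)
  ds <- simulate_dataset(p)$dataset
  drop_ids <- sprintf("ind%02d", 17:20)
  keep <- vapply(ds$configurations, function(cf)
    !(cf$method == "B" && cf$individual %in% drop_ids), logical(1))
  ds <- landmark_dataset(ds$configurations[keep], ds$scheme,
                         ds$distance_scheme)
  tab <- distance_table(ds)
  rep_ <- between_method_repeatability(tab, "A", "B")
  expect_equal(rep_$label, "A + B")
  expect_equal(unique(rep_$per_distance$n_groups), 16L)
  expect_equal(unique(rep_$per_distance$k), 4)
})

test_that("joining an exact copy of a method adds no disagreement beyond the df change", {
  set.seed(46)
  p <- sim_params(n_individuals = 50,
                  methods = list(sim_method("A", 0.05)),
                  individual_sd = 0.15, individual_size_cv = 0,
                  rigid_nuisance = FALSE, seed = 46)
  tab <- distance_table(simulate_dataset(p)$dataset)
  tabB <- tab; tabB$method <- "B"; tabB$replicate <- tabB$replicate + 2L
  both <- rbind(tab, tabB)
  rw <- within_method_repeatability(both, "A")
  rb <- between_method_repeatability(both, "A", "B")
  # duplicating each replicate pair doubles MS_among and rescales MS_within
  # by 2/3 (df 3a vs a), so the joined estimate relates to the within-method
  # mean squares by an exact closed form; no *extra* between-method variance
  # appears
  predicted <- with(rw$per_distance,
                    (3 * (s2_A * 2 + s2) - s2) / (3 * (s2_A * 2 + s2) + 3 * s2))
  expect_equal(rb$per_distance$r, predicted, tolerance = 1e-10)
  expect_true(all(rb$per_distance$r >= rw$per_distance$r - 1e-10))
})

test_that("disjoint individuals between methods is an error", {
  tab <- rbind(
    manual_distance_table(rep("a", 2), "A", 1:2, 1, c(5, 5.1)),
    manual_distance_table(rep("b", 2), "B", 1:2, 1, c(5, 5.2)))
  expect_error(between_method_repeatability(tab, "A", "B"), "shared")
})
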