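two_rep_table <- function(values_by_ind, distance = 1, method = "A") {
  # values_by_ind: list of c(rep1, rep2) per individual
  n <- length(values_by_ind)
  manual_distance_table(
    individual = rep(sprintf("i%d", seq_len(n)), each = 2),
    method = method, replicate = rep(1:2, n),
    distance = distance,
    value_mm = unlist(values_by_ind))
}

test_that("within-method raw and absolute differences follow the replicate order", {
  tab <- two_rep_table(list(c(10.0, 10.2), c(8.0, 7.9)))
  rep_ <- within_method_differences(tab, "A")
  expect_equal(rep_$per_distance$mean_raw, -0.05)
  expect_equal(rep_$per_distance$mean_abs, 0.15)

  same <- two_rep_table(list(c(4, 4), c(9, 9)))
  rep0 <- within_method_differences(same, "A")
  expect_equal(rep0$per_distance$mean_raw, 0)
  expect_equal(rep0$per_distance$mean_abs, 0)
})

test_that("swapping replicate labels flips raw means and preserves absolute means", {
  set.seed(50)
  vals <- lapply(1:10, function(i) 5 + rnorm(2, 0, 0.2))
  tab <- two_rep_table(vals)
  swapped <- tab
  swapped$replicate <- ifelse(tab$replicate == 1, 2L, 1L)
  r1 <- within_method_differences(tab, "A")$per_distance
  r2 <- within_method_differences(swapped, "A")$per_distance
  expect_equal(r2$mean_raw, -r1$mean_raw, tolerance = 1e-12)
  expect_equal(r2$mean_abs, r1$mean_abs, tolerance = 1e-12)
})

test_that("mean absolute difference dominates the raw mean on random tables", {
  set.seed(51)
  for (i in 1:20) {
    vals <- lapply(1:8, function(j) rnorm(2, 10, 1))
    per <- within_method_differences(two_rep_table(vals), "A")$per_distance
    expect_gte(per$mean_abs, abs(per$mean_raw) - 1e-12)
  }
})

test_that("between-method differences expose a constructed bias with the A - B sign", {
  set.seed(52)
  tabA <- rbind(two_rep_table(lapply(1:6, function(i) rnorm(2, 10, 0.1))),
                two_rep_table(lapply(1:6, function(i) rnorm(2, 5, 0.1)),
                              distance = 2))
  tabB <- tabA
  tabB$method <- "B"
  tabB$value_mm <- tabB$value_mm + 0.1
  rep_ <- between_method_differences(rbind(tabA, tabB), "A", "B")
  expect_equal(rep_$per_distance$mean_raw, c(-0.1, -0.1), tolerance = 1e-12)
  expect_equal(rep_$per_distance$mean_abs, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(unique(rep_$per_distance$n), 6L)

  ident <- between_method_differences(rbind(tabA, {
    t2 <- tabA; t2$method <- "B"; t2
  }), "A", "B")
  expect_equal(ident$per_distance$mean_raw, c(0, 0))
  expect_equal(ident$per_distance$mean_abs, c(0, 0))
})

test_that("unbiased noise gives raw means near zero but positive absolute means", {
  set.seed(53)
  p <- sim_params(n_individuals = 50,
                  methods = list(sim_method("A", 0.05),
                                 sim_method("B", 0.05)),
                  individual_sd = 0.1, individual_size_cv = 0,
                  rigid_nuisance = FALSE, seed = 53)
  tab <- distance_table(simulate_dataset(p)$dataset)
  rep_ <- between_method_differences(tab, "A", "B")
  expect_lt(abs(mean(rep_$per_distance$mean_raw)), 0.02)
  expect_gt(mean(rep_$per_distance$mean_abs), 0.02)
})

test_that("percentage error is the absolute mean over the distance mean, per distance", {
  tab <- two_rep_table(list(c(1.95, 2.05), c(2.05, 1.95)))
  rep_ <- within_method_differences(tab, "A")
  rep_$per_distance$mean_abs <- 0.1  # hand arithmetic: 0.1 / 2.0 -> 5%
  out <- percentage_error(rep_, tab)
  expect_equal(out$per_distance$pct_of_mean, 5.0)

  rep0 <- rep_
  rep0$per_distance$mean_abs <- 0
  expect_equal(percentage_error(rep0, tab)$per_distance$pct_of_mean, 0)

  half <- tab; half$value_mm <- half$value_mm / 2
  outh <- percentage_error(rep_, half)
  expect_equal(outh$per_distance$pct_of_mean,
               2 * out$per_distance$pct_of_mean, tolerance = 1e-12)
})

test_that("the summary %-of-mean row averages per-distance percentages", {
  set.seed(54)
  tab <- rbind(two_rep_table(lapply(1:5, function(i) rnorm(2, 10, 0.1))),
               two_rep_table(lapply(1:5, function(i) rnorm(2, 2, 0.1)),
                             distance = 2))
  out <- percentage_error(within_method_differences(tab, "A"), tab)
  s <- out$summary
  expect_equal(s$mean[s$statistic == "pct_of_mean"],
               mean(out$per_distance$pct_of_mean), tolerance = 1e-12)
})

test_that("repeatability-length correlation matches a raw-sums Pearson oracle", {
  set.seed(55)
  p <- sim_params(n_individuals = 25,
                  methods = list(sim_method("A", 0.05),
                                 sim_method("B", 0.05, bias_sd = 0.1)),
                  rigid_nuisance = FALSE, seed = 55)
  tab <- distance_table(simulate_dataset(p)$dataset)
  rep_ <- between_method_repeatability(tab, "A", "B")
  ct <- repeatability_length_correlation(rep_, tab)
  expect_equal(ct$df, 22L)  # 24 distances
  dmeans <- tapply(tab$value_mm, tab$distance, mean)
  oc <- oracle_pearson(rep_$per_distance$r,
                       as.numeric(dmeans[as.character(rep_$per_distance$distance)]))
  expect_equal(ct$r, oc$r, tolerance = 1e-10)
  expect_equal(ct$t_statistic, oc$t, tolerance = 1e-10)
  expect_equal(ct$p_value, oc$p, tolerance = 1e-10)
  expect_equal(ct$t_statistic, ct$r * sqrt(ct$df / (1 - ct$r^2)),
               tolerance = 1e-10)
})

test_that("a perfectly linear association returns r = 1 and degenerate input errors", {
  rep_ <- structure(list(label = "A", methods = "A",
                         per_distance = data.frame(distance = 1:5,
                                                   r = seq(0.5, 0.9, 0.1))),
                    class = "repeatability_report")
  tab <- manual_distance_table(rep("i1", 5), "A", 1, 1:5,
                               2 * seq(0.5, 0.9, 0.1) + 1)
  ct <- repeatability_length_correlation(rep_, tab)
  expect_equal(ct$r, 1, tolerance = 1e-10)

  flat <- manual_distance_table(rep("i1", 5), "A", 1, 1:5, rep(3, 5))
  expect_error(repeatability_length_correlation(rep_, flat),
               "zero variance")
})
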