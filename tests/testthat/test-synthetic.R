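test_that("truth generation is deterministic and respects the seed contract", {
  spec <- default_cohort_spec()
  t1 <- generate_truth(spec, seed = 1)
  t2 <- generate_truth(spec, seed = 1)
  expect_identical(t1, t2)
  t3 <- generate_truth(spec, seed = 2)
  # same structure, different sampled parameters
  expect_identical(t1$items$indicator, t3$items$indicator)
  expect_identical(t1$dims, t3$dims)
  expect_false(all(t1$items$a == t3$items$a))
  # default cohort mirrors the study design: 10 dimensions, 5-15 indicators
  expect_identical(nrow(t1$dims), 10L)
  counts <- table(t1$items$dimension)
  expect_true(all(counts >= 5 & counts <= 15))
  expect_true(all(t1$items$a >= 0.5 & t1$items$a <= 3.5))
  expect_true(all(t1$items$b >= -1.0 & t1$items$b <= 4.5))
  # correlation matrix is a valid unit-diagonal PD matrix
  S <- t1$factor_correlations
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 10))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("degenerate generator configurations error", {
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = 1, mode = "direct",
                               n_indicators = 1))
  expect_error(generate_truth(spec, seed = 1), "configuration error")
  spec2 <- default_cohort_spec()
  spec2$dependency_pairs <- data.frame(parent = "f1_direct_i01",
                                       child = "f1_direct_i01")
  expect_error(generate_truth(spec2, seed = 1), "differ")
})

test_that("constant-discrimination spec yields constant discrimination", {
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = 1, mode = "direct",
                               n_indicators = 5, a_range = c(1, 1)))
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = 0)
  expect_equal(truth$items$a, rep(1, 5))
})

test_that("response simulation is reproducible and respects the 2PL link", {
  mk <- make_cohort(n = 400, seed = 3)
  again <- make_cohort(n = 400, seed = 3)
  expect_identical(mk$cohort$values, again$cohort$values)
  expect_identical(mk$cohort$feature_labels, again$cohort$feature_labels)
  # flat items (a = 0) give column means near 0.5 regardless of theta
  mk0 <- make_cohort(n = 4000, n_ind = 5, seed = 4, a_range = c(0, 0),
                     missing_rate = 0)
  expect_true(all(abs(colMeans(mk0$cohort$values) - 0.5) < 0.03))
  # an extremely difficult item is almost never endorsed
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = 1, mode = "direct",
                               n_indicators = 4))
  spec$b_range <- c(0, 1)
  spec$dimensions[[1]]$b_range <- NULL
  spec$missing_rate <- 0
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = 5)
  truth$items$b[1] <- 6
  cohort <- simulate_responses(truth, 2000, seed = 6)
  expect_lt(mean(cohort$values[, 1]), 0.01)
})

test_that("column endorsement decreases in difficulty at fixed a", {
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = 1, mode = "direct",
                               n_indicators = 6, a_range = c(1.5, 1.5)))
  spec$missing_rate <- 0
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = 7)
  truth$items$b <- seq(-1, 3, length.out = 6)  # fixed difficulty grid
  cohort <- simulate_responses(truth, 6000, seed = 8)
  props <- colMeans(cohort$values)
  expect_true(all(diff(props) < 0))
})

test_that("label prevalence is calibrated to the positivity threshold", {
  # threshold at the (1 - p) normal quantile with no noise -> prevalence p
  p_target <- 0.2
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = 1, mode = "direct",
                               n_indicators = 5, labeling = TRUE))
  spec$positivity_thresholds <- rep(qnorm(1 - p_target), 4)
  spec$positivity_noise <- 0
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = 9)
  prev <- replicate(20, {
    i <- sample.int(10000, 1)
    mean(simulate_responses(truth, 2000, seed = i)$feature_labels[, 1])
  })
  se <- sqrt(p_target * (1 - p_target) / 2000)
  expect_lt(abs(mean(prev) - p_target), 3 * se / sqrt(20))
})

test_that("logical dependency injection creates the structural void", {
  y <- matrix(c(1, 1, 0, 0, 1,
                0, 1, 1, 0, 1), ncol = 2,
              dimnames = list(NULL, c("parent", "child")))
  rm <- delbank:::new_response_matrix(y)
  out <- inject_logical_dependency(rm, "parent", "child")
  expect_equal(out$values[, "child"], c(0, 1, 0, 0, 1),
               ignore_attr = TRUE)
  tab <- table(factor(out$values[, "parent"], 0:1),
               factor(out$values[, "child"], 0:1))
  expect_identical(unname(tab["0", "1"]), 0L)
  # parent all 1 leaves the child untouched
  y2 <- cbind(parent = rep(1L, 5), child = c(0L, 1L, 0L, 1L, 1L))
  rm2 <- delbank:::new_response_matrix(y2)
  expect_identical(inject_logical_dependency(rm2, "parent", "child")$values,
                   rm2$values)
  # parent all 0 suppresses the child entirely
  y3 <- cbind(parent = rep(0L, 5), child = c(0L, 1L, 0L, 1L, 1L))
  rm3 <- delbank:::new_response_matrix(y3)
  expect_true(all(
    inject_logical_dependency(rm3, "parent", "child")$values[, "child"] == 0))
  expect_error(inject_logical_dependency(rm, "parent", "parent"), "differ")
  expect_error(inject_logical_dependency(rm, "parent", "absent"), "present")
})

test_that("simulated matrices have no fully missing rows or columns and complete labels", {
  mk <- make_cohort(n = 50, n_ind = 4, seed = 11, missing_rate = 0.4)
  v <- mk$cohort$values
  expect_true(all(rowSums(!is.na(v)) > 0))
  expect_true(all(colSums(!is.na(v)) > 0))
  expect_false(anyNA(mk$cohort$feature_labels))
})
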