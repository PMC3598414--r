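test_that("the CAM rule requires features 1 and 2 plus 3 or 4", {
  grid <- expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1, f4 = 0:1)
  got <- with(grid, cam_algorithm(f1, f2, f3, f4))
  expected <- grid$f1 == 1 & grid$f2 == 1 & (grid$f3 == 1 | grid$f4 == 1)
  expect_identical(got, expected)
  expect_true(cam_algorithm(1, 1, 1, 0))
  expect_false(cam_algorithm(1, 0, 1, 1))
  expect_false(cam_algorithm(1, 1, 0, 0))
})

test_that("the anchor is the requested percentile of the positive sub-group", {
  eap <- c(1, 2, 3, -1, -2)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(theta_anchor(eap, labels, 50), 2)
  expect_equal(theta_anchor(eap, rep(TRUE, 5), 50),
               unname(quantile(eap, 0.5)))
  expect_error(theta_anchor(eap, rep(FALSE, 5), 50), "positive")
  # quantile monotonicity across the three percentiles
  set.seed(61)
  eap2 <- rnorm(200)
  lab2 <- eap2 > 0.3
  anchors <- sapply(c(25, 50, 75), function(p) theta_anchor(eap2, lab2, p))
  expect_true(all(diff(anchors) >= 0))
})

test_that("anchor of a synthetic cohort exceeds the cohort median", {
  mk <- make_cohort(n = 4598, n_ind = 10, seed = 62)
  fit <- fit_2pl(mk$cohort)
  sc <- eap_scores(mk$cohort, fit)
  labels <- mk$cohort$feature_labels[, 1] == 1
  anchor <- theta_anchor(sc, labels, 50)
  expect_gt(anchor, median(sc$eap))
  # positives sit well above the generating threshold region on average
  expect_gt(anchor, 0.5)
})

test_that("information ranking prefers discrimination at a shared location", {
  params <- data.frame(indicator = c("hi_a", "lo_a"), a = c(2, 1),
                       b = c(0, 0), D = 1.7)
  rk <- rank_by_information(params, theta_star = 0)
  expect_identical(rk$ranking, c("hi_a", "lo_a"))
  # translation invariance: shifting all b and theta* together
  params2 <- params
  params2$b <- params2$b + 1.3
  rk2 <- rank_by_information(params2, theta_star = 1.3)
  expect_identical(rk2$ranking, rk$ranking)
  expect_equal(unname(rk2$info_at_star), unname(rk$info_at_star))
})

test_that("printed attention-item parameters rank correctly at the printed anchor", {
  # the five inattention second-factor indicators, ranked at theta* = 0.27
  items <- data.frame(
    indicator = c("days_backwards", "months_backwards", "digit_back3",
                  "digit_back4", "digit_fwd4"),
    a = c(1.65, 1.17, 1.12, 1.20, 1.11),
    b = c(1.29, 0.20, 0.85, -0.34, 2.09),
    D = 1.7)
  oracle_info <- (1.7 * items$a)^2 *
    plogis(1.7 * items$a * (0.27 - items$b)) *
    (1 - plogis(1.7 * items$a * (0.27 - items$b)))
  oracle_order <- items$indicator[order(-oracle_info)]
  rk <- rank_by_information(items, theta_star = 0.27)
  expect_identical(rk$ranking, oracle_order)
  expect_equal(unname(rk$info_at_star),
               sort(oracle_info, decreasing = TRUE))
  # a well-placed modest item outranks a sharper but misplaced one
  expect_true(which(rk$ranking == "months_backwards") <
                which(rk$ranking == "days_backwards"))
})

test_that("severe high-discrimination items lose to anchored moderate items", {
  th <- 0.4
  params <- data.frame(indicator = c("severe", "anchored"),
                       a = c(2, 1.2), b = c(th + 2, th), D = 1.7)
  rk <- rank_by_information(params, theta_star = th)
  i_severe <- item_information(th, 2, th + 2)
  i_anchor <- item_information(th, 1.2, th)
  expect_identical(rk$ranking[1],
                   c("severe", "anchored")[which.max(c(i_severe, i_anchor))])
  expect_identical(rk$ranking[1], "anchored")
})

test_that("top-k selection is a deterministic prefix", {
  rk <- list(ranking = paste0("i", 1:15))
  expect_identical(select_top_k(rk, 5), paste0("i", 1:5))
  expect_identical(select_top_k(paste0("i", 1:3), 5), paste0("i", 1:3))
  expect_identical(select_top_k(rk, 5), select_top_k(rk, 5))
})

test_that("sensitivity analysis detects common-location invariance and reports overlap", {
  set.seed(63)
  eap <- rnorm(500)
  labels <- eap > 0.2
  same_b <- data.frame(indicator = paste0("i", 1:6),
                       a = runif(6, 0.8, 2.4), b = 0.9, D = 1.7)
  sens <- sensitivity_analysis(eap, labels, same_b)
  expect_identical(sens$rankings$p25, sens$rankings$p50)
  expect_identical(sens$rankings$p50, sens$rankings$p75)
  expect_true(all(sens$top_k_overlap == 5))
  expect_true(sens$stable)
  expect_true(all(diff(sens$anchors) >= 0))
})

test_that("the low-information fallback re-anchors at the 75th percentile", {
  set.seed(64)
  eap <- rnorm(400)
  labels <- eap > 0.5
  strong <- data.frame(indicator = paste0("s", 1:5),
                       a = runif(5, 1.2, 2), b = runif(5, 0.5, 1.5), D = 1.7)
  sel <- select_indicators(eap, labels, strong)
  kept <- apply_fallback(sel, eap, labels, strong)
  expect_false(kept$fallback_triggered)
  expect_identical(kept$selected, sel$selected)
  # all difficulties far above the anchor with weak slopes: fallback fires
  weak <- data.frame(indicator = paste0("w", 1:5), a = rep(0.5, 5),
                     b = theta_anchor(eap, labels, 50) + 3 + (0:4) / 10,
                     D = 1.7)
  sel2 <- select_indicators(eap, labels, weak)
  fb <- apply_fallback(sel2, eap, labels, weak)
  expect_true(fb$fallback_triggered)
  expect_identical(fb$percentile_used, 75)
  expect_gte(fb$theta_star, sel2$theta_star)
})
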