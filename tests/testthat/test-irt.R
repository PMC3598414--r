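test_that("2PL response curve has its defining closed-form properties", {
  expect_equal(prob_correct(0.7, a = 2.1, b = 0.7), 0.5)
  expect_equal(prob_correct(-3, a = 0, b = 1), 0.5)
  expect_equal(prob_correct(1, a = 1, b = 0, D = 1.7),
               1 / (1 + exp(-1.7)))
  th <- seq(-3, 3, 0.5)
  expect_true(all(diff(prob_correct(th, a = 1.3, b = 0.4)) > 0))
})

test_that("item information peaks at b with value (D a)^2 / 4 and is symmetric", {
  a <- 1.65  # printed discrimination of a days-of-week attention item
  expect_lt(abs(item_information(1.29, a, 1.29) - (1.7 * a)^2 / 4), 1e-10)
  expect_equal(item_information(1.29 + 0.8, a, 1.29),
               item_information(1.29 - 0.8, a, 1.29))
  # matches the finite-difference expected Fisher information
  fisher_fd <- function(theta, a, b, D = 1.7, h = 1e-4) {
    ll <- function(th, y) {
      p <- prob_correct(th, a, b, D)
      ifelse(y == 1, log(p), log(1 - p))
    }
    d2 <- function(y) {
      (ll(theta + h, y) - 2 * ll(theta, y) + ll(theta - h, y)) / h^2
    }
    p <- prob_correct(theta, a, b, D)
    -(p * d2(1) + (1 - p) * d2(0))
  }
  for (th in c(-1, 0.3, 2)) {
    expect_equal(item_information(th, 1.2, 0.5), fisher_fd(th, 1.2, 0.5),
                 tolerance = 1e-6)
  }
})

test_that("test information is additive, order-free, and zero on empty sets", {
  params <- data.frame(indicator = c("x", "y"), a = c(1.2, 1.2),
                       b = c(0.5, 0.5), D = 1.7)
  expect_equal(test_information(0.1, params, "x"),
               item_information(0.1, 1.2, 0.5))
  expect_equal(test_information(0.1, params),
               2 * test_information(0.1, params, "x"))
  expect_equal(test_information(0.1, params, c("y", "x")),
               test_information(0.1, params, c("x", "y")))
  expect_equal(test_information(0.1, params, character(0)), 0)
})

test_that("2PL EM recovers generating parameters at scale", {
  mk <- make_cohort(n = 4598, n_ind = 10, seed = 51)
  fit <- fit_2pl(mk$cohort)
  co <- coef(fit)
  expect_gt(cor(co[, "a"], mk$truth$items$a), 0.9)
  expect_gt(cor(co[, "b"], mk$truth$items$b), 0.98)
  expect_lt(sqrt(mean((co[, "b"] - mk$truth$items$b)^2)), 0.15)
  # the EM log-likelihood never decreased
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$convergence$converged)
})

test_that("flipping all responses negates difficulties and keeps slopes", {
  mk <- make_cohort(n = 1500, n_ind = 6, seed = 52, missing_rate = 0)
  y <- mk$cohort$values
  f1 <- fit_2pl(y)
  f2 <- fit_2pl(1L - y)
  expect_equal(coef(f2)[, "a"], coef(f1)[, "a"], tolerance = 1e-6)
  expect_equal(coef(f2)[, "b"], -coef(f1)[, "b"], tolerance = 1e-6)
})

test_that("difficulties are centred when all true b are zero", {
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = 1, mode = "direct",
                               n_indicators = 8, b_range = c(0, 0)))
  spec$a_range <- c(1, 2)
  spec$missing_rate <- 0
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = 53)
  cohort <- simulate_responses(truth, 10000, seed = 54)
  fit <- fit_2pl(cohort)
  expect_lt(abs(mean(coef(fit)[, "b"])), 0.05)
})

test_that("parameters are stable to quadrature resolution", {
  mk <- make_cohort(n = 1200, n_ind = 6, seed = 55)
  f49 <- fit_2pl(mk$cohort, n_quad = 49, tol = 1e-6)
  f101 <- fit_2pl(mk$cohort, n_quad = 101, tol = 1e-6)
  expect_lt(max(abs(coef(f49) - coef(f101))), 1e-3)
})

test_that("degenerate indicators are refused by name", {
  y <- cbind(ok = rbinom(50, 1, 0.5), bad = rep(1L, 50),
             ok2 = rbinom(50, 1, 0.5), ok3 = rbinom(50, 1, 0.5))
  expect_error(fit_2pl(y), "bad")
})

test_that("EAP scoring matches the fine-grid posterior oracle", {
  set.seed(56)
  a <- runif(8, 0.8, 2.5)
  b <- runif(8, -0.5, 2.5)
  params <- data.frame(indicator = paste0("i", 1:8), a = a, b = b, D = 1.7)
  y <- matrix(rbinom(30 * 8, 1, 0.5), 30, 8,
              dimnames = list(NULL, params$indicator))
  y[1, ] <- NA  # all-missing person receives the prior
  y[2, 1:4] <- NA
  sc <- eap_scores(y, params)
  expect_equal(sc$eap[1], 0)
  expect_equal(sc$sd[1], 1)
  for (i in 2:30) {
    expect_lt(abs(sc$eap[i] - oracle_eap(y[i, ], a, b)), 1e-5)
  }
  # posterior is sharper than the prior once something is observed
  expect_true(all(sc$sd[-1] < 1))
})

test_that("an additional positive response never lowers the EAP score", {
  params <- data.frame(indicator = paste0("i", 1:5),
                       a = c(1.5, 1.2, 0.9, 2, 1.1),
                       b = c(-0.5, 0.2, 0.8, 1.5, 2.5), D = 1.7)
  base <- c(1L, 0L, 0L, NA, 0L)
  with_pos <- base
  with_pos[4] <- 1L
  y <- rbind(base, with_pos)
  colnames(y) <- params$indicator
  sc <- eap_scores(y, params)
  expect_gt(sc$eap[2], sc$eap[1])
})

test_that("EAP posterior spread is consistent with test information", {
  mk <- make_cohort(n = 600, n_ind = 12, seed = 57, missing_rate = 0)
  fit <- fit_2pl(mk$cohort)
  sc <- eap_scores(mk$cohort, fit)
  pred_sd <- 1 / sqrt(test_information(sc$eap, fit) + 1)
  ratio <- sc$sd / pred_sd
  expect_lt(median(abs(ratio - 1)), 0.1)
})

test_that("marginal reliability follows the information identity", {
  params <- data.frame(indicator = c("x", "y", "z"), a = c(1.5, 1.2, 2),
                       b = c(0, 0.5, 1), D = 1.7)
  expect_equal(marginal_reliability(params, character(0), theta_star = 0), 0)
  ti <- test_information(0.4, params)
  expect_equal(marginal_reliability(params, theta_star = 0.4), ti / (ti + 1))
  # adding indicators never lowers reliability
  r1 <- marginal_reliability(params, "x", theta_star = 0.4)
  r2 <- marginal_reliability(params, c("x", "y"), theta_star = 0.4)
  r3 <- marginal_reliability(params, c("x", "y", "z"), theta_star = 0.4)
  expect_true(r1 <= r2 && r2 <= r3)
  # closed-form point: TI = 3 gives 0.75
  one <- data.frame(indicator = "w", a = sqrt(3) * 2 / 1.7, b = 0, D = 1.7)
  expect_equal(marginal_reliability(one, theta_star = 0), 0.75)
})
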