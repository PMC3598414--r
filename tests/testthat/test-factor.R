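test_that("fit indices follow the closed-form definitions", {
  expect_equal(unname(fit_indices(50, 50, 500, 55, 1000)), c(1, 0))
  fi <- fit_indices(100, 50, 1050, 55, n = 1001)
  expect_equal(unname(fi["RMSEA"]), sqrt(50 / (50 * 1000)))
  # df = 0 and saturated baseline edge cases
  expect_equal(unname(fit_indices(0, 0, 10, 5, 100)), c(1, 0))
  expect_equal(unname(fit_indices(5, 10, 8, 10, 100)), c(1, 0))
  # random triples against the hand-coded oracle
  set.seed(41)
  for (i in 1:25) {
    chisq <- runif(1, 0, 500)
    df <- sample(1:100, 1)
    bchisq <- chisq + runif(1, 0, 2000)
    bdf <- df + sample(1:20, 1)
    n <- sample(50:5000, 1)
    expect_equal(fit_indices(chisq, df, bchisq, bdf, n),
                 oracle_fit_indices(chisq, df, bchisq, bdf, n),
                 tolerance = 1e-10)
  }
})

test_that("single-factor EFA recovers known loadings", {
  mk <- make_cohort(n = 4598, n_ind = 8, seed = 42,
                    a_range = c(1.0, 2.0), b_range = c(-0.5, 1.5),
                    missing_rate = 0)
  tet <- tetrachoric_matrix(mk$cohort)
  fit <- fit_efa(tet, m = 1)
  # true normal-ogive loading: lambda = a* / sqrt(1 + a*^2), a* = D a / 1.7
  astar <- mk$truth$items$a
  lam_true <- astar / sqrt(1 + astar^2)
  expect_lt(max(abs(fit$loadings[, 1] - lam_true)), 0.05)
  expect_identical(fit$m_factors, 1L)
})

test_that("two-block EFA separates disjoint item blocks", {
  R <- diag(10)
  R[1:5, 1:5] <- 0.64
  R[6:10, 6:10] <- 0.49
  diag(R) <- 1
  dimnames(R) <- list(paste0("i", 1:10), paste0("i", 1:10))
  fit <- fit_efa(R, m = 2, n = 2000)
  pat <- assign_simple_structure(fit)
  expect_identical(length(unique(pat[1:5])), 1L)
  expect_identical(length(unique(pat[6:10])), 1L)
  expect_false(pat[1] == pat[10])
  own <- abs(fit$loadings[cbind(1:10, pat)])
  cross <- abs(fit$loadings[cbind(1:10, 3 - pat)])
  expect_true(all(own >= 0.4))
  expect_true(all(cross < 0.2))
})

test_that("simple-structure assignment uses largest absolute loading with ties to the lower factor", {
  L <- rbind(i1 = c(0.8, 0.1), i2 = c(0.3, -0.6), i3 = c(0.5, 0.5))
  pat <- assign_simple_structure(L)
  expect_identical(unname(pat), c(1L, 2L, 1L))
})

test_that("CFA reproduces its own implied single-factor matrix exactly", {
  lam <- c(0.8, 0.7, 0.6, 0.75, 0.65)
  Sigma <- tcrossprod(lam)
  diag(Sigma) <- 1
  dimnames(Sigma) <- list(paste0("i", 1:5), paste0("i", 1:5))
  pat <- setNames(rep(1L, 5), rownames(Sigma))
  fit <- fit_cfa(Sigma, pat, n = 1000)
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(fit$CFI, 1)
  expect_equal(fit$RMSEA, 0, tolerance = 1e-4)
  expect_equal(unname(fit$loadings[, 1]), lam, tolerance = 1e-4)
})

test_that("single-factor CFA fits clean unidimensional data well", {
  mk <- make_cohort(n = 4598, n_ind = 10, seed = 43, missing_rate = 0)
  tet <- tetrachoric_matrix(mk$cohort)
  ids <- colnames(tet$matrix)
  fit <- fit_cfa(tet, setNames(rep(1L, 10), ids))
  expect_gt(fit$CFI, 0.94)
  expect_lt(fit$RMSEA, 0.05)
})

test_that("misfit shows up against the true model on two-factor data", {
  spec <- default_cohort_spec()
  spec$dimensions <- list(
    list(name = "d1", feature = 1, mode = "direct", n_indicators = 6,
         labeling = TRUE),
    list(name = "d2", feature = 2, mode = "direct", n_indicators = 6,
         labeling = TRUE))
  spec$a_range <- c(1.2, 2.2)
  spec$b_range <- c(-1, 1.5)
  spec$factor_correlations <- list(within = 0.6, between = 0.3)
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = 44)
  cohort <- simulate_responses(truth, 3000, seed = 45)
  tet <- tetrachoric_matrix(cohort)
  ids <- colnames(tet$matrix)
  pat1 <- setNames(rep(1L, 12), ids)
  pat2 <- setNames(rep(c(1L, 2L), each = 6), ids)
  cfa1 <- fit_cfa(tet, pat1)
  cfa2 <- fit_cfa(tet, pat2)
  expect_gt(cfa2$CFI, cfa1$CFI)
  # the recovered factor correlation is near the generating value
  expect_lt(abs(cfa2$factor_correlations[1, 2] - 0.3), 0.15)
  # bifactor nests the CFA: at least as good a fit, and the dominant
  # specific blocks are detected
  bfa <- fit_bifactor(tet, pat2)
  expect_gte(bfa$CFI, cfa1$CFI)
})

test_that("bifactor on pure single-common-factor data shows no large secondary loadings", {
  lam <- rep(0.7, 8)
  Sigma <- tcrossprod(lam)
  diag(Sigma) <- 1
  dimnames(Sigma) <- list(paste0("i", 1:8), paste0("i", 1:8))
  pat <- setNames(rep(c(1L, 2L), each = 4), rownames(Sigma))
  fit <- fit_bifactor(Sigma, pat, n = 1000)
  expect_false(fit$large_secondary)
  expect_lt(max(abs(fit$loadings[, -1])), 0.1)
  # a dominant specific block flips the signal; heterogeneous loadings on
  # three specific factors keep the bifactor solution identified
  g <- c(0.40, 0.45, 0.35, 0.42, 0.38, 0.44, 0.36, 0.41, 0.39)
  s <- c(0.80, 0.75, 0.85, 0.30, 0.25, 0.28, 0.27, 0.32, 0.24)
  blocks <- rep(1:3, each = 3)
  Sigma2 <- tcrossprod(g) + tcrossprod(s) * outer(blocks, blocks, "==")
  diag(Sigma2) <- 1
  dimnames(Sigma2) <- list(paste0("j", 1:9), paste0("j", 1:9))
  pat2 <- setNames(blocks, rownames(Sigma2))
  fit2 <- fit_bifactor(Sigma2, pat2, n = 1000)
  expect_true(fit2$large_secondary)
  expect_gt(max(abs(fit2$loadings[1:3, "S1"])), 0.6)
})

test_that("dimensionality adjudication applies the preponderance rule", {
  pa1 <- structure(list(m_significant = 1L), class = "parallel_analysis")
  pa2 <- structure(list(m_significant = 2L), class = "parallel_analysis")
  mk_fit <- function(kind, cfi, large = NULL) {
    f <- list(model_kind = kind, CFI = cfi, large_secondary = large,
              loadings = matrix(0, 8, 1,
                                dimnames = list(paste0("i", 1:8), NULL)))
    class(f) <- "factor_fit"
    f
  }
  pat <- setNames(rep(c(1L, 2L), each = 4), paste0("i", 1:8))
  # one significant root, good single-factor fit: one dimension
  adj <- adjudicate_dimensions(pa1, list(cfa1 = mk_fit("CFA", 0.99)))
  expect_identical(adj$m_retained, 1L)
  # two roots + large secondary loadings: split
  adj2 <- adjudicate_dimensions(
    pa2, list(cfa1 = mk_fit("CFA", 0.97), cfam = mk_fit("CFA", 0.975),
              bfa = mk_fit("BFA", 0.99, large = TRUE)), pat)
  expect_identical(adj2$m_retained, 2L)
  expect_identical(lengths(adj2$subsets), c(factor1 = 4L, factor2 = 4L))
  expect_true(all(adj2$modeled))
  # two roots but no CFI gain and no large secondary: stay unidimensional
  adj3 <- adjudicate_dimensions(
    pa2, list(cfa1 = mk_fit("CFA", 0.97), cfam = mk_fit("CFA", 0.975),
              bfa = mk_fit("BFA", 0.98, large = FALSE)), pat)
  expect_identical(adj3$m_retained, 1L)
  # sub-sets below the modeling floor are flagged
  pat_small <- setNames(c(rep(1L, 5), rep(2L, 3)), paste0("i", 1:8))
  adj4 <- adjudicate_dimensions(
    pa2, list(cfa1 = mk_fit("CFA", 0.9), cfam = mk_fit("CFA", 0.95),
              bfa = mk_fit("BFA", 0.96, large = TRUE)), pat_small)
  expect_identical(unname(adj4$modeled), c(TRUE, FALSE))
})
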