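# Independent oracles used to validate the package's estimators. These are
# deliberately slow, brute-force implementations sharing no code with the
# package internals.

# Upper-quadrant probability P(Z1 > t1, Z2 > t2; rho) by 2-D Gauss-Legendre
# integration of the bivariate normal density over [t1, 8] x [t2, 8].
oracle_bvn_upper <- function(t1, t2, rho, n_nodes = 80) {
  g1 <- pracma::gaussLegendre(n_nodes, t1, 8)
  g2 <- pracma::gaussLegendre(n_nodes, t2, 8)
  om <- 1 - rho^2
  f <- outer(g1$x, g2$x, function(x, y) {
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * om)) / (2 * pi * sqrt(om))
  })
  as.numeric(g1$w %*% f %*% g2$w)
}

# Tetrachoric correlation by bisection on rho until the model upper-quadrant
# probability matches the observed p11 (thresholds fixed at the margins).
oracle_tetrachoric <- function(tab, tol = 1e-10) {
  n <- sum(tab)
  p1 <- (tab[2, 1] + tab[2, 2]) / n
  p2 <- (tab[1, 2] + tab[2, 2]) / n
  t1 <- qnorm(1 - p1)
  t2 <- qnorm(1 - p2)
  p11 <- tab[2, 2] / n
  lo <- -0.9999
  hi <- 0.9999
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (oracle_bvn_upper(t1, t2, mid) > p11) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# EAP posterior mean by brute force on a 10,001-point uniform grid.
oracle_eap <- function(y_vec, a, b, D = 1.7, lim = 8, n_grid = 10001) {
  grid <- seq(-lim, lim, length.out = n_grid)
  lp <- dnorm(grid, log = TRUE)
  for (j in seq_along(y_vec)) {
    if (is.na(y_vec[j])) next
    pj <- plogis(D * a[j] * (grid - b[j]))
    lp <- lp + if (y_vec[j] == 1) log(pj) else log(1 - pj)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  sum(w * grid)
}

# Hand-coded CFI / RMSEA formulas.
oracle_fit_indices <- function(chisq, df, bchisq, bdf, n) {
  num <- max(chisq - df, 0)
  den <- max(bchisq - bdf, 0)
  cfi <- if (den <= 0) 1 else min(max(1 - num / den, 0), 1)
  rmsea <- if (df == 0) 0 else sqrt(num / (df * (n - 1)))
  c(CFI = cfi, RMSEA = rmsea)
}

# Small single-dimension synthetic cohort for reuse in tests.
make_cohort <- function(n = 1000, n_ind = 8, seed = 1,
                        a_range = c(0.8, 2.5), b_range = c(-0.5, 2.5),
                        missing_rate = 0.02, feature = 1) {
  spec <- default_cohort_spec()
  spec$dimensions <- list(list(name = "d1", feature = feature,
                               mode = "direct", n_indicators = n_ind,
                               labeling = TRUE))
  spec$a_range <- a_range
  spec$b_range <- b_range
  spec$missing_rate <- missing_rate
  spec$dependency_pairs <- NULL
  truth <- generate_truth(spec, seed = seed)
  list(truth = truth,
       cohort = simulate_responses(truth, n, seed = seed + 1000))
}
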