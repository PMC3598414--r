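# Factor models on tetrachoric correlation matrices, fit by (unweighted)
# least squares on the unique correlations, with the chi-square
# approximated as (n - 1) * F_min. All models keep a unit diagonal, the
# standard parameterization for categorical indicators, so uniquenesses are
# implied by the communalities.

# Least-squares discrepancy over unique off-diagonal correlations.
uls_discrepancy <- function(R, Sigma) {
  d <- (R - Sigma)[lower.tri(R)]
  sum(d * d)
}

baseline_discrepancy <- function(R) {
  r <- R[lower.tri(R)]
  sum(r * r)
}

#' CFI and RMSEA from least-squares chi-square approximations
#'
#' `CFI = 1 - max(chisq - df, 0) / max(chisq_B - df_B, 0)` against the
#' independence baseline, and `RMSEA = sqrt(max(chisq - df, 0) / (df (n -
#' 1)))`. The chi-squares are `(n - 1) * F_min` from the least-squares
#' discrepancy; this is an approximation to a likelihood-ratio statistic
#' and is used for comparing models, not for formal testing.
#'
#' @param chi_square,df Model statistic and degrees of freedom.
#' @param baseline_chi_square,baseline_df Independence-model statistic and
#'   degrees of freedom.
#' @param n Sample size (>= 2).
#' @return Named numeric vector with `CFI` and `RMSEA`.
#' @examples
#' fit_indices(100, 50, 1050, 55, n = 1001)
#' @export
fit_indices <- function(chi_square, df, baseline_chi_square, baseline_df, n) {
  stopifnot(df >= 0, n >= 2)
  num <- max(chi_square - df, 0)
  den <- max(baseline_chi_square - baseline_df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  rmsea <- if (df == 0) 0 else sqrt(num / (df * (n - 1)))
  c(CFI = cfi, RMSEA = rmsea)
}

new_factor_fit <- function(model_kind, m_factors, loadings, pattern,
                           factor_correlations, discrepancy, n, n_free,
                           p, extra = list()) {
  df <- p * (p - 1) / 2 - n_free
  chisq <- (n - 1) * discrepancy
  base_f <- extra$baseline_discrepancy
  base_chisq <- (n - 1) * base_f
  base_df <- p * (p - 1) / 2
  fi <- fit_indices(chisq, df, base_chisq, base_df, n)
  structure(
    c(list(model_kind = model_kind,
           m_factors = as.integer(m_factors),
           loadings = loadings,
           pattern = pattern,
           factor_correlations = factor_correlations,
           discrepancy = discrepancy,
           chi_square = chisq,
           df = df,
           CFI = unname(fi["CFI"]),
           RMSEA = unname(fi["RMSEA"]),
           n = n),
      extra[setdiff(names(extra), "baseline_discrepancy")]),
    class = "factor_fit"
  )
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("%s model, %d factor(s): chi2 = %.2f (df = %d), CFI = %.3f, RMSEA = %.3f\n",
              x$model_kind, x$m_factors, x$chi_square, x$df, x$CFI, x$RMSEA))
  if (isTRUE(x$heywood)) cat("  note: Heywood case clipped\n")
  if (!is.null(x$large_secondary)) {
    cat("  large secondary loadings:",
        if (x$large_secondary) "yes" else "no", "\n")
  }
  invisible(x)
}

#' Exploratory factor analysis of a tetrachoric matrix
#'
#' Minimum-residual (unweighted least squares) extraction of `m` factors
#' from the PSD-repaired tetrachoric correlation matrix, with promax
#' rotation for `m >= 2` (no rotation for a single factor). Communalities
#' greater than 1 (Heywood cases) are clipped with a warning.
#'
#' @param tet A `tetrachoric_result` or correlation matrix.
#' @param m Number of factors, `1 <= m < p`.
#' @param n Sample size used for fit statistics; taken from `tet` when
#'   available.
#' @param rotation `"promax"` (default, only applied when `m >= 2`) or
#'   `"none"`.
#' @return A `factor_fit` with rotated `loadings`, `factor_correlations`
#'   (identity for orthogonal solutions), `pattern` (largest-|loading|
#'   assignment), and CFI/RMSEA.
#' @export
fit_efa <- function(tet, m, n = NULL, rotation = c("promax", "none")) {
  rotation <- match.arg(rotation)
  R <- if (inherits(tet, "tetrachoric_result")) tet$repaired else tet
  if (is.null(n)) {
    n <- if (inherits(tet, "tetrachoric_result")) tet$n else
      stop("supply n", call. = FALSE)
  }
  p <- ncol(R)
  if (m < 1 || m >= p) stop("need 1 <= m < p", call. = FALSE)

  extract <- function(psi) {
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    lam <- e$values[seq_len(m)]
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(lam, 0)), m)
    L
  }
  objective <- function(psi) {
    L <- extract(psi)
    uls_discrepancy(R, tcrossprod(L))
  }
  start <- pmax(1 - 0.5 * (1 - 1 / diag(solve(R + diag(1e-3, p)))), 0.2)
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = rep(1e-3, p), upper = rep(1, p))
  L <- extract(opt$par)
  heywood <- any(rowSums(L^2) > 1 + 1e-8)
  if (heywood) {
    warning("Heywood case: communality > 1 clipped")
    h <- rowSums(L^2)
    L[h > 1, ] <- L[h > 1, , drop = FALSE] / sqrt(h[h > 1])
  }
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(m))
  Phi <- diag(m)
  if (m >= 2 && rotation == "promax") {
    pm <- promax(L)
    L <- unclass(pm$loadings)
    U <- pm$rotmat
    Phi <- cov2cor(solve(crossprod(U)))
    dimnames(L) <- list(rownames(R), paste0("F", seq_len(m)))
    dimnames(Phi) <- list(colnames(L), colnames(L))
  }
  # resolve factor sign indeterminacy: majority-positive loadings
  signs <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, signs, "*")
  Phi <- Phi * tcrossprod(signs)
  fit <- new_factor_fit(
    "EFA", m, L, pattern = apply(abs(L), 1, which.max),
    factor_correlations = Phi,
    discrepancy = opt$value, n = n,
    n_free = p * m - m * (m - 1) / 2, p = p,
    extra = list(baseline_discrepancy = baseline_discrepancy(R),
                 uniquenesses = setNames(opt$par, rownames(R)),
                 heywood = heywood))
  fit
}

#' Simple-structure assignment from an EFA solution
#'
#' Assigns each indicator to the factor on which it has the largest
#' absolute loading; exact ties go to the lower factor index.
#'
#' @param fit A `factor_fit` from [fit_efa()] with `m >= 2`, or a loading
#'   matrix.
#' @return Named integer vector mapping each indicator to a factor.
#' @export
assign_simple_structure <- function(fit) {
  L <- if (inherits(fit, "factor_fit")) fit$loadings else fit
  pattern <- apply(abs(L), 1, which.max) # which.max takes the first on ties
  setNames(as.integer(pattern), rownames(L))
}

# Shared ULS optimizer for structured models.
fit_structured <- function(R, n, par0, lower, upper, implied, finish) {
  objective <- function(par) uls_discrepancy(R, implied(par))
  opt <- optim(par0, objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 500, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stop("factor model did not converge (code ", opt$convergence, "): ",
         opt$message, call. = FALSE)
  }
  finish(opt)
}

#' Simple-structure confirmatory factor analysis
#'
#' Fits a correlated-factors CFA in which each indicator loads on exactly
#' one factor, by unweighted least squares on the tetrachoric matrix with a
#' unit-diagonal constraint (uniquenesses implied as `1 - loading^2`).
#'
#' @param tet A `tetrachoric_result` or correlation matrix.
#' @param pattern Named integer vector assigning each indicator to a factor
#'   (as from [assign_simple_structure()]); every factor needs >= 2
#'   indicators. A single-factor model is fit when all assignments equal 1.
#' @param n Sample size for fit statistics.
#' @return A `factor_fit` with `loadings` (p x m, zeros off-pattern),
#'   `factor_correlations`, CFI and RMSEA.
#' @export
fit_cfa <- function(tet, pattern, n = NULL) {
  R <- if (inherits(tet, "tetrachoric_result")) tet$repaired else tet
  if (is.null(n)) {
    n <- if (inherits(tet, "tetrachoric_result")) tet$n else
      stop("supply n", call. = FALSE)
  }
  p <- ncol(R)
  pattern <- pattern[rownames(R)]
  if (anyNA(pattern)) stop("pattern must cover all indicators", call. = FALSE)
  m <- max(pattern)
  counts <- tabulate(pattern, m)
  if (any(counts < 2)) {
    stop("every factor in the pattern needs at least 2 indicators",
         call. = FALSE)
  }
  n_phi <- m * (m - 1) / 2
  phi_idx <- which(lower.tri(diag(m)))
  implied <- function(par) {
    lam <- par[seq_len(p)]
    Phi <- diag(m)
    if (n_phi) {
      Phi[phi_idx] <- par[p + seq_len(n_phi)]
      Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
    }
    Lf <- base::matrix(0, p, m)
    Lf[cbind(seq_len(p), pattern)] <- lam
    Sigma <- Lf %*% Phi %*% t(Lf)
    diag(Sigma) <- 1
    Sigma
  }
  par0 <- c(rep(0.6, p), rep(0.4, n_phi))
  fit_structured(
    R, n, par0,
    lower = c(rep(-0.999, p), rep(-0.95, n_phi)),
    upper = c(rep(0.999, p), rep(0.95, n_phi)),
    implied = implied,
    finish = function(opt) {
      lam <- opt$par[seq_len(p)]
      Phi <- diag(m)
      if (n_phi) {
        Phi[phi_idx] <- opt$par[p + seq_len(n_phi)]
        Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
      }
      L <- base::matrix(0, p, m,
                        dimnames = list(rownames(R), paste0("F", seq_len(m))))
      L[cbind(seq_len(p), pattern)] <- lam
      dimnames(Phi) <- list(colnames(L), colnames(L))
      new_factor_fit("CFA", m, L, pattern, Phi, opt$value, n,
                     n_free = p + n_phi, p = p,
                     extra = list(baseline_discrepancy =
                                    baseline_discrepancy(R)))
    })
}

#' Bifactor model with orthogonal specific factors
#'
#' Fits a bifactor analysis: every indicator loads on a general factor and
#' on exactly one specific factor given by `pattern`; all factors are
#' mutually orthogonal. Fit is by unweighted least squares with a
#' unit-diagonal constraint. `large_secondary` records whether any
#' indicator's specific loading exceeds its general-factor loading in
#' absolute value, the signal used to retain multidimensionality.
#'
#' @inheritParams fit_cfa
#' @return A `factor_fit` with `loadings` (general in column `G`, specific
#'   in `S1..Sm`), zero `factor_correlations`, `large_secondary`, CFI and
#'   RMSEA.
#' @export
fit_bifactor <- function(tet, pattern, n = NULL) {
  R <- if (inherits(tet, "tetrachoric_result")) tet$repaired else tet
  if (is.null(n)) {
    n <- if (inherits(tet, "tetrachoric_result")) tet$n else
      stop("supply n", call. = FALSE)
  }
  p <- ncol(R)
  pattern <- pattern[rownames(R)]
  if (anyNA(pattern)) stop("pattern must cover all indicators", call. = FALSE)
  m <- max(pattern)
  if (m < 2) stop("bifactor model needs >= 2 specific factors", call. = FALSE)
  same <- outer(pattern, pattern, "==")
  implied <- function(par) {
    g <- par[seq_len(p)]
    s <- par[p + seq_len(p)]
    Sigma <- tcrossprod(g) + tcrossprod(s) * same
    diag(Sigma) <- 1
    Sigma
  }
  par0 <- c(rep(0.5, p), rep(0.4, p))
  fit_structured(
    R, n, par0,
    lower = rep(-0.999, 2 * p), upper = rep(0.999, 2 * p),
    implied = implied,
    finish = function(opt) {
      g <- opt$par[seq_len(p)]
      s <- opt$par[p + seq_len(p)]
      L <- base::matrix(0, p, m + 1,
                        dimnames = list(rownames(R),
                                        c("G", paste0("S", seq_len(m)))))
      L[, 1] <- g
      L[cbind(seq_len(p), pattern + 1L)] <- s
      Phi <- diag(m + 1)
      dimnames(Phi) <- list(colnames(L), colnames(L))
      new_factor_fit("BFA", m, L, pattern, Phi, opt$value, n,
                     n_free = 2 * p, p = p,
                     extra = list(
                       baseline_discrepancy = baseline_discrepancy(R),
                       large_secondary = any(abs(s) > abs(g))))
    })
}

#' Adjudicate the number of retained dimensions and split the indicator set
#'
#' Applies the preponderance rule to the parallel-analysis result and the
#' fitted factor models: one dimension is retained when parallel analysis
#' finds a single significant root; otherwise `m > 1` dimensions are
#' retained when at least two of (i) more than one significant root,
#' (ii) the m-factor CFA improves CFI over the single-factor model by at
#' least `cfi_improvement`, (iii) the bifactor model shows large secondary
#' loadings, hold. On a split, indicators are partitioned by the
#' simple-structure pattern; sub-sets with fewer than `min_subset`
#' indicators are flagged as not modeled.
#'
#' @param pa A `parallel_analysis` result.
#' @param fits Named list of `factor_fit`s on the same indicator subset:
#'   `cfa1` (single factor) and, when `m > 1` was examined, `cfam`
#'   (m-factor CFA) and `bfa`.
#' @param pattern Simple-structure assignment used for the split (required
#'   when multidimensionality can be retained).
#' @param cfi_improvement CFI gain treated as evidence (default 0.01).
#' @param min_subset Minimum sub-set size that will be IRT-modeled
#'   (default 4).
#' @return List with `m_retained`, `subsets` (list of indicator-id
#'   vectors), `modeled` (logical per sub-set), and `evidence`.
#' @export
adjudicate_dimensions <- function(pa, fits, pattern = NULL,
                                  cfi_improvement = 0.01, min_subset = 4) {
  stopifnot(inherits(pa, "parallel_analysis"))
  m_sig <- pa$m_significant
  ids <- names(pattern) %||% rownames(fits$cfa1$loadings)
  evidence <- c(multiple_roots = m_sig > 1,
                cfi_gain = FALSE, large_secondary = FALSE)
  if (!is.null(fits$cfam) && !is.null(fits$cfa1)) {
    evidence["cfi_gain"] <-
      (fits$cfam$CFI - fits$cfa1$CFI) >= cfi_improvement
  }
  if (!is.null(fits$bfa)) {
    evidence["large_secondary"] <- isTRUE(fits$bfa$large_secondary)
  }
  retain_multi <- m_sig > 1 && sum(evidence) >= 2
  if (!retain_multi) {
    return(list(m_retained = 1L, subsets = list(ids),
                modeled = TRUE, evidence = evidence))
  }
  if (is.null(pattern)) {
    stop("pattern required to split a multidimensional set", call. = FALSE)
  }
  subsets <- split(names(pattern), pattern)
  names(subsets) <- paste0("factor", names(subsets))
  modeled <- vapply(subsets, length, 1L) >= min_subset
  list(m_retained = length(subsets), subsets = subsets,
       modeled = modeled, evidence = evidence)
}
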