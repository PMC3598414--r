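#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood tetrachoric correlation under the bivariate-normal
#' model, with thresholds fixed at the observed margins: the estimate solves
#' the upper-quadrant probability equation P(Z1 > tau1, Z2 > tau2; rho) =
#' p11. Empty cells receive a 0.5 continuity correction before estimation
#' so sparse tables yield finite interior estimates rather than boundary
#' jumps. Pairs whose correlation cannot be estimated are flagged rather
#' than returned at a boundary: a zero off-diagonal cell (the structural void a
#' logical dependency produces), a degenerate margin (fewer than
#' `min_margin` positive or negative responses on either variable), or an
#' estimate driven to |rho| > `boundary` all yield `estimable = FALSE`.
#'
#' @param table A 2x2 matrix of non-negative counts, rows = first variable
#'   (0, 1), columns = second variable (0, 1).
#' @param min_margin Minimum count of positive and of negative responses
#'   required on each margin (default 5).
#' @param boundary Absolute correlation above which the estimate is treated
#'   as a boundary solution (default 0.995).
#' @return A list with `rho` (NA when no interior estimate exists),
#'   `estimable`, `thresholds` (normal quantiles of the negative-response
#'   proportions), and `n` (table total).
#' @examples
#' tetrachoric(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
#' @export
tetrachoric <- function(table, min_margin = 5, boundary = 0.995) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) == 2)
  if (any(table < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(table != round(table))) {
    stop("cell counts must be integers", call. = FALSE)
  }
  n <- sum(table)
  if (n < 1) stop("table total must be >= 1", call. = FALSE)
  n00 <- table[1, 1]; n01 <- table[1, 2]
  n10 <- table[2, 1]; n11 <- table[2, 2]
  p1 <- (n10 + n11) / n
  p2 <- (n01 + n11) / n
  thresholds <- c(qnorm(1 - p1), qnorm(1 - p2))
  rho <- .tetra_ml_cpp(n00, n01, n10, n11)
  degenerate_margin <-
    min(n00 + n01, n10 + n11, n00 + n10, n01 + n11) < min_margin
  void <- (n01 == 0 || n10 == 0)
  estimable <- !is.na(rho) && !void && !degenerate_margin &&
    abs(rho) <= boundary
  list(rho = rho, estimable = estimable, thresholds = thresholds, n = n)
}

# Pairwise complete-case 2x2 cell counts for a 0/1/NA matrix, as four
# p x p matrices, via cross-products of the observation masks.
pairwise_counts <- function(y) {
  obs <- !is.na(y)
  y1 <- y
  y1[!obs] <- 0
  y0 <- (1 - y)
  y0[!obs] <- 0
  list(
    n00 = crossprod(y0),
    n01 = crossprod(y0, y1),
    n10 = crossprod(y1, y0),
    n11 = crossprod(y1)
  )
}

#' Tetrachoric correlation matrix with estimability screening
#'
#' Computes all pairwise tetrachoric correlations of a set of dichotomous
#' indicators using pairwise complete cases, classifies every pair as
#' estimable or not (see [tetrachoric()] for the criteria), and provides an
#' eigenvalue-clipped positive-semidefinite repair of the matrix for
#' eigen-analysis and factoring alongside the raw estimates.
#'
#' Boundary and inestimable-pair correlations are retained (clamped near
#' +/-1) in the raw matrix so a full spectrum is always available; the
#' `estimable` mask records which entries a downstream analysis should
#' trust.
#'
#' @param matrix A `response_matrix` or a persons x indicators 0/1/NA matrix.
#' @param subset Optional character vector of indicator ids (>= 2).
#' @param min_margin,boundary Passed to the per-pair estimability rules.
#' @return An object of class `tetrachoric_result`: list with `matrix` (raw
#'   correlations, unit diagonal), `repaired` (PSD-repaired copy),
#'   `estimable` (logical mask, diagonal TRUE), `thresholds` (per-indicator
#'   normal quantile of the negative-response proportion), `n_pairs`
#'   (complete cases per pair), and `n`.
#' @examples
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' cohort <- simulate_responses(truth, 400, seed = 2)
#' tet <- tetrachoric_matrix(cohort, subset = paste0("f2_obs_i0", 1:8))
#' tet
#' @export
tetrachoric_matrix <- function(matrix, subset = NULL, min_margin = 5,
                               boundary = 0.995) {
  y <- if (inherits(matrix, "response_matrix")) matrix$values else matrix
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, colnames(y))
    if (length(missing_ids)) {
      stop("unknown indicator(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    y <- y[, subset, drop = FALSE]
  }
  p <- ncol(y)
  if (p < 2) stop("need at least 2 indicators", call. = FALSE)
  ids <- colnames(y)

  cnt <- pairwise_counts(y)
  lower <- which(lower.tri(cnt$n11))
  rho_vec <- .tetra_ml_cpp(cnt$n00[lower], cnt$n01[lower],
                           cnt$n10[lower], cnt$n11[lower])
  n_pair <- cnt$n00 + cnt$n01 + cnt$n10 + cnt$n11

  R <- diag(p)
  est <- base::matrix(TRUE, p, p)
  min_marg <- pmin(cnt$n00 + cnt$n01, cnt$n10 + cnt$n11,
                   cnt$n00 + cnt$n10, cnt$n01 + cnt$n11)
  void <- (cnt$n01 == 0 | cnt$n10 == 0)
  R[lower] <- rho_vec
  est[lower] <- !is.na(rho_vec) & !void[lower] &
    min_marg[lower] >= min_margin & abs(rho_vec) <= boundary
  # indicators with zero complete cases against a partner: flagged, not fatal
  est[lower][n_pair[lower] == 0] <- FALSE
  R[lower][is.na(rho_vec)] <- 0
  R <- R + t(R) - diag(p)
  est[upper.tri(est)] <- t(est)[upper.tri(est)]
  dimnames(R) <- dimnames(est) <- list(ids, ids)

  marg <- colMeans(y == 1, na.rm = TRUE)
  structure(
    list(matrix = R,
         repaired = repair_psd(R),
         estimable = est,
         thresholds = setNames(qnorm(1 - marg), ids),
         n_pairs = n_pair,
         n = nrow(y)),
    class = "tetrachoric_result"
  )
}

#' @export
print.tetrachoric_result <- function(x, ...) {
  p <- ncol(x$matrix)
  bad <- sum(!x$estimable[lower.tri(x$estimable)])
  cat("Tetrachoric correlation matrix:", p, "indicators,",
      p * (p - 1) / 2, "pairs (", bad, "inestimable )\n")
  off <- x$matrix[lower.tri(x$matrix)]
  cat(sprintf("  correlations: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Eigenvalues of a tetrachoric correlation matrix
#'
#' Full spectrum (descending) of the PSD-repaired tetrachoric matrix, the
#' latent roots compared against permuted-data roots in parallel analysis.
#'
#' @param tet A `tetrachoric_result`, or a correlation matrix.
#' @return Numeric vector of eigenvalues in descending order.
#' @export
eigenvalues <- function(tet) {
  R <- if (inherits(tet, "tetrachoric_result")) tet$repaired else tet
  sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}
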