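#' Permuted parallel analysis on tetrachoric correlations
#'
#' Decides how many latent roots of the observed tetrachoric correlation
#' matrix are significant by comparing each observed eigenvalue with the
#' 97.5th percentile of the matching root under column-wise permutation.
#' Each permutation independently shuffles every indicator's responses
#' across persons, which preserves each indicator's margin exactly while
#' destroying all inter-indicator association; the tetrachoric matrix and
#' its spectrum are then recomputed. The count of significant roots `m`
#' scans the leading roots and stops at the first root that does not exceed
#' its permutation quantile.
#'
#' Permutations whose tetrachoric matrix contains an incomputable entry
#' (a fully degenerate pairwise margin) are redrawn and logged.
#'
#' @param matrix A `response_matrix` or 0/1/NA matrix.
#' @param subset Optional indicator ids (post-screening set).
#' @param n_permutations Number of permutations (>= 40 so the 97.5th
#'   percentile is resolved; default 100).
#' @param seed Integer seed for the permutation stream.
#' @param quantile_prob Permutation quantile defining significance
#'   (default 0.975).
#' @return An object of class `parallel_analysis`: list with
#'   `observed_eigenvalues`, `permutation_quantiles`, `permuted` (the full
#'   permutations x roots matrix), `m_significant`, `significant` (per-root
#'   logical, marginal test), `n_permutations`, `n_redrawn`, and `seed`.
#' @examples
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' cohort <- simulate_responses(truth, 600, seed = 2)
#' pa <- permuted_parallel_analysis(cohort, sprintf("f2_obs_i%02d", 1:8),
#'                                  n_permutations = 50, seed = 3)
#' pa
#' @export
permuted_parallel_analysis <- function(matrix, subset = NULL,
                                       n_permutations = 100, seed = 1,
                                       quantile_prob = 0.975) {
  if (n_permutations < 40) {
    stop("need at least 40 permutations to resolve the 97.5th percentile",
         call. = FALSE)
  }
  y <- if (inherits(matrix, "response_matrix")) matrix$values else matrix
  if (!is.null(subset)) y <- y[, subset, drop = FALSE]
  p <- ncol(y)
  n <- nrow(y)

  obs <- eigenvalues(tetrachoric_matrix(y))
  perm_eig <- base::matrix(NA_real_, n_permutations, p)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      for (attempt in 1:10) {
        yp <- y
        for (j in seq_len(p)) yp[, j] <- y[sample.int(n), j]
        tet <- tetrachoric_matrix(yp)
        if (!anyNA(tet$matrix)) break
        n_redrawn <- n_redrawn + 1L
      }
      perm_eig[b, ] <- eigenvalues(tet)
    }
  })

  q <- apply(perm_eig, 2, quantile, probs = quantile_prob, names = FALSE)
  sig <- obs > q
  m <- 0L
  for (j in seq_len(p)) {
    if (sig[j]) m <- m + 1L else break
  }
  structure(
    list(observed_eigenvalues = obs,
         permutation_quantiles = q,
         permuted = perm_eig,
         m_significant = m,
         significant = sig,
         n_permutations = as.integer(n_permutations),
         n_redrawn = n_redrawn,
         quantile_prob = quantile_prob,
         seed = as.integer(seed)),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("Permuted parallel analysis:", x$m_significant,
      "significant eigenvalue(s) of", length(x$observed_eigenvalues),
      sprintf("(%d permutations)\n", x$n_permutations))
  k <- min(5L, length(x$observed_eigenvalues))
  tab <- rbind(observed = x$observed_eigenvalues[1:k],
               `perm q97.5` = x$permutation_quantiles[1:k])
  print(round(tab, 3))
  invisible(x)
}

#' Scree plot of observed versus permuted eigenvalues
#'
#' @param x A `parallel_analysis` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.parallel_analysis <- function(x, ...) {
  p <- length(x$observed_eigenvalues)
  graphics::plot(seq_len(p), x$observed_eigenvalues, type = "b", pch = 19,
                 xlab = "Root", ylab = "Eigenvalue", ...)
  graphics::lines(seq_len(p), x$permutation_quantiles, type = "b", lty = 2,
                  pch = 1)
  graphics::legend("topright", legend = c("observed", "permuted 97.5%"),
                   lty = c(1, 2), pch = c(19, 1), bty = "n")
  invisible(x)
}
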