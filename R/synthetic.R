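#' Default synthetic screening-cohort specification
#'
#' Returns the packaged generator configuration emulating a large post-acute
#' delirium screening cohort: ten latent dimensions organised into seven
#' CAM-feature-by-mode indicator sets, uniform discrimination and difficulty
#' ranges, cross-feature latent correlations, per-feature positivity
#' thresholds calibrated so that the CAM Boolean rule labels about 13.3% of
#' persons delirium-positive, 2% completely-at-random missingness, and two
#' logically dependent indicator pairs that produce structural voids in the
#' pairwise cross-tabulations.
#'
#' Each dimension spec gives the CAM feature (1-4), the collection mode
#' (\code{"direct"} or \code{"observational"}), the number of indicators, and
#' whether the dimension is the feature's labeling dimension (the latent
#' trait that is thresholded to produce the feature-positive rating).
#'
#' @return A list with components \code{dimensions}, \code{a_range},
#'   \code{b_range}, \code{factor_correlations} (list with \code{within} and
#'   \code{between} feature correlations), \code{positivity_thresholds}
#'   (length 4), \code{positivity_noise}, \code{missing_rate},
#'   \code{dependency_pairs}, and the link scaling constant \code{D}.
#' @seealso [generate_truth()], [simulate_responses()]
#' @export
default_cohort_spec <- function() {
  dim_spec <- function(name, feature, mode, n, labeling = FALSE) {
    list(name = name, feature = feature, mode = mode,
         n_indicators = n, labeling = labeling)
  }
  list(
    dimensions = list(
      dim_spec("f1_direct",   1L, "direct",        15L, labeling = TRUE),
      dim_spec("f1_obs",      1L, "observational", 11L),
      dim_spec("f2_direct_a", 2L, "direct",         8L, labeling = TRUE),
      dim_spec("f2_direct_b", 2L, "direct",         7L),
      dim_spec("f2_obs",      2L, "observational",  8L),
      dim_spec("f3_direct",   3L, "direct",        13L, labeling = TRUE),
      dim_spec("f3_obs_a",    3L, "observational", 10L),
      dim_spec("f3_obs_b",    3L, "observational",  5L),
      dim_spec("f4_obs_a",    4L, "observational",  9L, labeling = TRUE),
      dim_spec("f4_obs_b",    4L, "observational",  5L)
    ),
    a_range = c(0.5, 3.5),
    b_range = c(-1.0, 4.5),
    factor_correlations = list(within = 0.6, between = 0.5),
    # Solved so that P(f1 & f2 & (f3 | f4)) = 0.133 for unit-normal labeling
    # traits with cross-feature correlation 0.5 and no label noise.
    positivity_thresholds = rep(0.509610, 4L),
    positivity_noise = 0,
    missing_rate = 0.02,
    dependency_pairs = data.frame(
      parent = c("f1_direct_i01", "f3_obs_a_i01"),
      child  = c("f1_direct_i02", "f3_obs_a_i02"),
      stringsAsFactors = FALSE
    ),
    D = 1.7
  )
}

# Build the full inter-dimension correlation matrix from a within/between
# feature specification (or pass a user-supplied matrix through).
build_factor_correlations <- function(spec, dims) {
  fc <- spec$factor_correlations
  k <- nrow(dims)
  if (is.matrix(fc)) {
    if (nrow(fc) != k || ncol(fc) != k) {
      stop("factor_correlations matrix must be ", k, "x", k, call. = FALSE)
    }
    S <- fc
  } else {
    within <- fc$within %||% 0.6
    between <- fc$between %||% 0.5
    same_feature <- outer(dims$feature, dims$feature, "==")
    S <- matrix(between, k, k)
    S[same_feature] <- within
    diag(S) <- 1
  }
  dimnames(S) <- list(dims$dimension, dims$dimension)
  if (any(abs(S - t(S)) > 1e-12) || any(diag(S) != 1)) {
    stop("factor_correlations must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("factor_correlations is not positive definite", call. = FALSE)
  }
  S
}

#' Generate the true parameters of a synthetic screening cohort
#'
#' Draws true 2PL discrimination and difficulty parameters for every
#' indicator of every latent dimension in `spec`, and assembles the complete
#' generative truth: dimension structure, inter-dimension correlation
#' matrix, per-feature positivity thresholds and label noise, missingness
#' rate, and logically dependent indicator pairs. Identical `(spec, seed)`
#' yield identical truth objects.
#'
#' @param spec A generator configuration, as returned by
#'   [default_cohort_spec()]. Per-dimension `a_range`/`b_range` entries
#'   override the global ranges.
#' @param seed Integer seed for parameter sampling.
#' @return An object of class `synthetic_truth` with components `items`
#'   (data frame: indicator, dimension, feature, mode, a, b), `dims`
#'   (data frame: dimension, feature, mode, labeling),
#'   `factor_correlations`, `positivity_thresholds`, `positivity_noise`,
#'   `missing_rate`, `dependency_pairs`, `D`, and `seed`.
#' @examples
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' truth
#' @export
generate_truth <- function(spec, seed) {
  if (is.null(spec$dimensions) || length(spec$dimensions) < 1L) {
    stop("spec must name at least one dimension", call. = FALSE)
  }
  n_ind <- vapply(spec$dimensions, function(d) as.integer(d$n_indicators), 1L)
  if (any(n_ind < 2L)) {
    stop("configuration error: every dimension needs at least 2 indicators",
         call. = FALSE)
  }
  if (any(n_ind < 4L)) {
    warning("dimensions with fewer than 4 indicators cannot be IRT-modeled")
  }
  dims <- data.frame(
    dimension = vapply(spec$dimensions, `[[`, "", "name"),
    feature = vapply(spec$dimensions, function(d) as.integer(d$feature), 1L),
    mode = vapply(spec$dimensions, `[[`, "", "mode"),
    labeling = vapply(spec$dimensions, function(d) isTRUE(d$labeling), TRUE),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(dims$dimension)) {
    stop("dimension names must be unique", call. = FALSE)
  }
  for (f in unique(dims$feature)) {
    rows <- which(dims$feature == f)
    if (!any(dims$labeling[rows])) dims$labeling[rows[1L]] <- TRUE
    if (sum(dims$labeling[rows]) > 1L) {
      stop("feature ", f, " has more than one labeling dimension",
           call. = FALSE)
    }
  }
  S <- build_factor_correlations(spec, dims)
  items <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(spec$dimensions), function(i) {
      d <- spec$dimensions[[i]]
      ni <- n_ind[i]
      ar <- d$a_range %||% spec$a_range %||% c(0.5, 3.5)
      br <- d$b_range %||% spec$b_range %||% c(-1.0, 4.5)
      data.frame(
        indicator = sprintf("%s_i%02d", d$name, seq_len(ni)),
        dimension = d$name,
        feature = as.integer(d$feature),
        mode = d$mode,
        a = runif(ni, ar[1], ar[2]),
        b = runif(ni, br[1], br[2]),
        stringsAsFactors = FALSE
      )
    }))
  })
  dep <- spec$dependency_pairs
  if (!is.null(dep) && nrow(dep)) {
    if (any(dep$parent == dep$child)) {
      stop("dependency child must differ from parent", call. = FALSE)
    }
    missing_ids <- setdiff(c(dep$parent, dep$child), items$indicator)
    if (length(missing_ids)) {
      stop("dependency pair references unknown indicator(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  thr <- spec$positivity_thresholds %||% rep(0.509610, 4L)
  if (length(thr) == 1L) thr <- rep(thr, 4L)
  structure(
    list(
      items = items,
      dims = dims,
      factor_correlations = S,
      positivity_thresholds = thr,
      positivity_noise = spec$positivity_noise %||% 0,
      missing_rate = spec$missing_rate %||% 0.02,
      dependency_pairs = dep,
      D = spec$D %||% 1.7,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic cohort truth:", nrow(x$items), "indicators on",
      nrow(x$dims), "dimensions\n")
  tab <- table(x$items$dimension)[x$dims$dimension]
  for (i in seq_len(nrow(x$dims))) {
    cat(sprintf("  %-14s feature %d, %-13s %2d indicators%s\n",
                x$dims$dimension[i], x$dims$feature[i], x$dims$mode[i],
                tab[i], if (x$dims$labeling[i]) "  [labeling]" else ""))
  }
  cat(sprintf("D = %g, missing rate %.3f, label noise %.3f, %d dependency pair(s)\n",
              x$D, x$missing_rate, x$positivity_noise,
              if (is.null(x$dependency_pairs)) 0L else nrow(x$dependency_pairs)))
  invisible(x)
}

#' Simulate a dichotomous indicator-response matrix from a synthetic truth
#'
#' Draws person latent traits from a multivariate normal with unit variances
#' and the truth's inter-dimension correlations, generates each response as
#' Bernoulli with the 2PL probability `plogis(D * a * (theta - b))`, rates
#' each person positive on a CAM feature when their trait on that feature's
#' labeling dimension exceeds the positivity threshold (flipped with the
#' truth's label-noise probability), applies completely-at-random
#' missingness, and enforces logical dependency pairs (the child indicator
#' is forced to 0 wherever the parent is 0).
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param n_persons Number of persons to simulate (>= 1).
#' @param seed Integer seed; identical `(truth, n_persons, seed)` yield
#'   bit-identical matrices.
#' @return An object of class `response_matrix`: list with `values`
#'   (persons x indicators 0/1/NA matrix), `person_ids`, `indicator_ids`,
#'   `feature_labels` (persons x 4 matrix of 0/1 feature ratings), `theta`
#'   (true traits) and `truth`.
#' @examples
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' cohort <- simulate_responses(truth, n_persons = 500, seed = 2)
#' cohort
#' @export
simulate_responses <- function(truth, n_persons, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_persons <- as.integer(n_persons)
  if (n_persons < 1L) stop("n_persons must be >= 1", call. = FALSE)
  S <- truth$factor_correlations
  ch <- tryCatch(chol(S), error = function(e) {
    stop("factor_correlations is not positive definite", call. = FALSE)
  })
  items <- truth$items
  p <- nrow(items)
  dim_index <- match(items$dimension, truth$dims$dimension)

  with_seed(seed, {
    theta <- matrix(rnorm(n_persons * ncol(S)), n_persons) %*% ch
    colnames(theta) <- colnames(S)
    eta <- truth$D * outer(rep(1, n_persons), items$a) *
      (theta[, dim_index, drop = FALSE] -
         outer(rep(1, n_persons), items$b))
    prob <- plogis(eta)
    y <- matrix(rbinom(n_persons * p, 1L, prob), n_persons, p)

    labels <- matrix(0L, n_persons, 4L,
                     dimnames = list(NULL, paste0("feature", 1:4)))
    for (f in 1:4) {
      row <- which(truth$dims$feature == f & truth$dims$labeling)
      if (!length(row)) next
      pos <- theta[, row] > truth$positivity_thresholds[f]
      if (truth$positivity_noise > 0) {
        flip <- runif(n_persons) < truth$positivity_noise
        pos <- xor(pos, flip)
      }
      labels[, f] <- as.integer(pos)
    }

    if (truth$missing_rate > 0) {
      mask <- matrix(runif(n_persons * p) < truth$missing_rate, n_persons, p)
      # keep the matrix free of all-missing rows and columns
      bad_rows <- which(rowSums(!mask) == 0L)
      for (i in bad_rows) mask[i, sample.int(p, 1L)] <- FALSE
      bad_cols <- which(colSums(!mask) == 0L)
      for (j in bad_cols) mask[sample.int(n_persons, 1L), j] <- FALSE
      y[mask] <- NA_integer_
    }

    dep <- truth$dependency_pairs
    if (!is.null(dep) && nrow(dep)) {
      for (r in seq_len(nrow(dep))) {
        pa <- match(dep$parent[r], items$indicator)
        chl <- match(dep$child[r], items$indicator)
        suppress <- !is.na(y[, pa]) & y[, pa] == 0L & !is.na(y[, chl])
        y[suppress, chl] <- 0L
      }
    }

    dimnames(y) <- list(sprintf("p%05d", seq_len(n_persons)), items$indicator)
    new_response_matrix(y, feature_labels = labels, theta = theta,
                        truth = truth)
  })
}

# Constructor with invariant checks shared by the generator and readers.
new_response_matrix <- function(values, feature_labels = NULL, theta = NULL,
                                truth = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("ind%03d", seq_len(ncol(values)))
  }
  ok <- values %in% c(0L, 1L) | is.na(values)
  if (!all(ok)) stop("responses must be 0, 1 or missing", call. = FALSE)
  if (nrow(values) && any(rowSums(!is.na(values)) == 0L)) {
    warning("response matrix contains fully missing rows")
  }
  if (nrow(values) && any(colSums(!is.na(values)) == 0L)) {
    warning("response matrix contains fully missing columns")
  }
  if (!is.null(feature_labels)) {
    feature_labels <- as.matrix(feature_labels)
    stopifnot(nrow(feature_labels) == nrow(values))
    if (anyNA(feature_labels)) {
      stop("feature labels must be complete (0/1, no missing)", call. = FALSE)
    }
  }
  structure(
    list(values = values,
         person_ids = rownames(values),
         indicator_ids = colnames(values),
         feature_labels = feature_labels,
         theta = theta,
         truth = truth),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  v <- x$values
  cat("Response matrix:", nrow(v), "persons x", ncol(v), "indicators\n")
  cat(sprintf("  missing: %.1f%%; mean positive: %.3f\n",
              100 * mean(is.na(v)), mean(v, na.rm = TRUE)))
  if (!is.null(x$feature_labels)) {
    prev <- colMeans(x$feature_labels)
    cat("  feature-positive rates:",
        paste(sprintf("%s=%.3f", colnames(x$feature_labels), prev),
              collapse = ", "), "\n")
    cam <- cam_algorithm(x$feature_labels[, 1], x$feature_labels[, 2],
                         x$feature_labels[, 3], x$feature_labels[, 4])
    cat(sprintf("  CAM delirium-positive: %.1f%%\n", 100 * mean(cam)))
  }
  invisible(x)
}

#' Inject a logical dependency between two indicators
#'
#' Forces the child indicator to 0 wherever the parent indicator is 0,
#' creating a structural void (an empty parent=0, child=1 cell) in the
#' pairwise cross-tabulation, as arises from skip patterns such as a
#' symptom-frequency probe that follows a symptom-presence gate.
#'
#' @param matrix A `response_matrix`.
#' @param parent,child Indicator ids present in the matrix; must differ.
#' @return The modified `response_matrix`.
#' @export
inject_logical_dependency <- function(matrix, parent, child) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (identical(parent, child)) {
    stop("parent and child must differ", call. = FALSE)
  }
  ids <- matrix$indicator_ids
  if (!(parent %in% ids) || !(child %in% ids)) {
    stop("parent and child must both be present in the matrix",
         call. = FALSE)
  }
  v <- matrix$values
  suppress <- !is.na(v[, parent]) & v[, parent] == 0L & !is.na(v[, child])
  v[suppress, child] <- 0L
  matrix$values <- v
  matrix
}
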