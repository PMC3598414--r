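#' Two-parameter logistic response probability
#'
#' `P(y = 1 | theta) = 1 / (1 + exp(-D a (theta - b)))`: probability that a
#' person at trait level `theta` expresses the symptom, for discrimination
#' `a`, difficulty (symptom severity) `b`, and scaling constant `D`
#' (1.7 makes the logistic curve approximate the normal ogive).
#'
#' @param theta Trait level(s).
#' @param a Discrimination parameter.
#' @param b Difficulty parameter.
#' @param D Scaling constant (default 1.7).
#' @return Probability, recycled over the longest argument.
#' @examples
#' prob_correct(1, a = 1, b = 0, D = 1.7)
#' @export
prob_correct <- function(theta, a, b, D = 1.7) {
  plogis(D * a * (theta - b))
}

#' Item information function
#'
#' Fisher information an item contributes about the latent trait:
#' `I(theta) = (D a)^2 P (1 - P)` in the logistic-with-D metric. The curve
#' peaks at `theta = b` with value `(D a)^2 / 4`; information is additive
#' over locally independent items.
#'
#' @inheritParams prob_correct
#' @return Information, recycled over the longest argument.
#' @examples
#' item_information(0.27, a = 1.65, b = 1.29)
#' @export
item_information <- function(theta, a, b, D = 1.7) {
  p <- prob_correct(theta, a, b, D)
  (D * a)^2 * p * (1 - p)
}

#' Test information
#'
#' Sum of item information over a set of fitted indicators at `theta`.
#'
#' @param theta Trait level (scalar or vector).
#' @param params An `irt_2pl` fit or a data frame with columns
#'   `indicator`, `a`, `b` and an attribute/element `D`.
#' @param subset Optional indicator ids (default: all fitted items).
#' @return Total information at each `theta` (0 for an empty subset).
#' @export
test_information <- function(theta, params, subset = NULL) {
  tab <- item_param_table(params)
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, tab$indicator)
    if (length(missing_ids)) {
      stop("subset contains unfitted indicator(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    tab <- tab[tab$indicator %in% subset, , drop = FALSE]
  }
  if (!nrow(tab)) return(rep(0, length(theta)))
  vapply(theta, function(th) {
    sum(item_information(th, tab$a, tab$b, tab$D))
  }, numeric(1))
}

# Normalize an irt_2pl object or bare parameter table to a data frame with
# indicator, a, b, D columns.
item_param_table <- function(params) {
  if (inherits(params, "irt_2pl")) {
    tab <- params$coefficients
    tab$D <- params$D
    return(tab)
  }
  tab <- as.data.frame(params)
  if (is.null(tab$D)) tab$D <- attr(params, "D") %||% 1.7
  stopifnot(all(c("indicator", "a", "b") %in% names(tab)))
  tab
}

#' Fit a two-parameter logistic IRT model by marginal maximum likelihood
#'
#' EM estimation of the 2PL for a sufficiently unidimensional indicator
#' set, with a standard-normal latent trait integrated over fixed
#' Gauss-Hermite quadrature. Missing responses contribute nothing to a
#' person's likelihood. The E-step computes expected per-node counts; the
#' M-step solves each item's weighted logistic likelihood by Newton's
#' method, so the marginal log-likelihood is non-decreasing across
#' iterations (asserted every iteration).
#'
#' The latent scale is identified by the N(0, 1) prior; if the averaged
#' slope comes out negative (inversely coded data) the trait is reflected
#' so that discriminations are positive by the majority-positive
#' convention.
#'
#' @param matrix A `response_matrix` or persons x indicators 0/1/NA matrix.
#' @param subset Optional indicator ids (>= 4 for a stable fit).
#' @param D Scaling constant for the reported parameterization
#'   (default 1.7).
#' @param n_quad Number of quadrature nodes (default 49).
#' @param tol Convergence: maximum absolute parameter change (default 1e-4).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `irt_2pl`: `coefficients` (data frame
#'   indicator/a/b), `D`, `link`, `quadrature`, `loglik`, `loglik_trace`,
#'   `convergence`, `n_persons`, `n_items`.
#' @examples
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' cohort <- simulate_responses(truth, 1000, seed = 2)
#' fit <- fit_2pl(cohort, subset = sprintf("f2_obs_i%02d", 1:8))
#' fit
#' @export
fit_2pl <- function(matrix, subset = NULL, D = 1.7, n_quad = 49,
                    tol = 1e-4, max_iter = 500) {
  y <- if (inherits(matrix, "response_matrix")) matrix$values else matrix
  if (!is.null(subset)) y <- y[, subset, drop = FALSE]
  p <- ncol(y)
  if (p < 2) stop("need at least 2 indicators", call. = FALSE)
  if (p < 4) warning("fewer than 4 indicators: 2PL fit may be unstable")
  ids <- colnames(y)
  pbar <- colMeans(y, na.rm = TRUE)
  degenerate <- which(pbar <= 0 | pbar >= 1 | is.nan(pbar))
  if (length(degenerate)) {
    stop("degenerate indicator(s) with a single observed category: ",
         paste(ids[degenerate], collapse = ", "), call. = FALSE)
  }

  quad <- normal_quadrature(n_quad)
  th <- quad$nodes
  lw <- log(quad$weights)
  obs <- !is.na(y)
  y1 <- y; y1[!obs] <- 0
  y0 <- (1 - y); y0[!obs] <- 0
  storage.mode(y1) <- "double"
  storage.mode(y0) <- "double"
  obs_d <- obs
  storage.mode(obs_d) <- "double"

  # internal slope-intercept parameterization: logit = c_j + d_j * theta
  dpar <- rep(1, p)
  cpar <- qlogis(pmin(pmax(pbar, 0.02), 0.98))

  person_posterior <- function(cpar, dpar) {
    eta <- outer(th, dpar)             # q x p
    eta <- sweep(eta, 2, cpar, "+")
    logP <- -log1p(exp(-eta))
    logQ <- -log1p(exp(eta))
    ll <- y1 %*% t(logP) + y0 %*% t(logQ)  # n x q
    ll <- sweep(ll, 2, lw, "+")
    mx <- apply(ll, 1, max)
    w <- exp(ll - mx)
    norm <- rowSums(w)
    list(post = w / norm, loglik = sum(mx + log(norm)))
  }

  mstep_item <- function(Nq, Rq, cj, dj) {
    for (it in 1:30) {
      pq <- plogis(cj + dj * th)
      res <- Rq - Nq * pq
      g <- c(sum(res), sum(res * th))
      wq <- Nq * pq * (1 - pq)
      h11 <- sum(wq); h12 <- sum(wq * th); h22 <- sum(wq * th * th)
      det <- h11 * h22 - h12 * h12
      if (!is.finite(det) || det < 1e-12) break
      step <- c(h22 * g[1] - h12 * g[2], -h12 * g[1] + h11 * g[2]) / det
      step <- pmin(pmax(step, -2), 2)
      cj <- cj + step[1]
      dj <- dj + step[2]
      if (max(abs(step)) < 1e-9) break
    }
    c(cj, dj)
  }

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    es <- person_posterior(cpar, dpar)
    if (es$loglik < ll_prev - 1e-6) {
      stop("EM log-likelihood decreased at iteration ", iter, call. = FALSE)
    }
    ll_prev <- es$loglik
    ll_trace <- c(ll_trace, es$loglik)
    Nq <- crossprod(es$post, obs_d)   # q x p expected counts
    Rq <- crossprod(es$post, y1)      # q x p expected positives
    old <- c(cpar, dpar)
    for (j in seq_len(p)) {
      upd <- mstep_item(Nq[, j], Rq[, j], cpar[j], dpar[j])
      cpar[j] <- upd[1]
      dpar[j] <- upd[2]
    }
    delta <- max(abs(c(cpar, dpar) - old))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM did not reach tolerance ", tol, " in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  }
  if (mean(dpar > 0) < 0.5) {  # reflect the trait: majority-positive slopes
    dpar <- -dpar
  }
  a <- dpar / D
  b <- -cpar / dpar
  coefs <- data.frame(indicator = ids, a = a, b = b,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(coefficients = coefs,
         D = D,
         link = "logistic",
         quadrature = quad,
         loglik = ll_prev,
         loglik_trace = ll_trace,
         convergence = list(converged = converged,
                            iterations = length(ll_trace),
                            tol = tol, last_change = delta),
         n_persons = nrow(y),
         n_items = p),
    class = "irt_2pl"
  )
}

#' @export
print.irt_2pl <- function(x, digits = 3, ...) {
  cat(sprintf("2PL IRT model (MML-EM, logistic link, D = %g): %d items, %d persons\n",
              x$D, x$n_items, x$n_persons))
  cat(sprintf("  log-likelihood %.2f after %d iterations%s\n",
              x$loglik, x$convergence$iterations,
              if (x$convergence$converged) "" else " (not converged)"))
  print(cbind(a = round(x$coefficients$a, digits),
              b = round(x$coefficients$b, digits)))
  invisible(x)
}

#' @export
coef.irt_2pl <- function(object, ...) {
  m <- as.matrix(object$coefficients[, c("a", "b")])
  rownames(m) <- object$coefficients$indicator
  m
}

#' @export
logLik.irt_2pl <- function(object, ...) {
  structure(object$loglik, df = 2 * object$n_items,
            nobs = object$n_persons, class = "logLik")
}

#' @export
summary.irt_2pl <- function(object, ...) {
  tab <- object$coefficients
  tab$peak_information <- (object$D * tab$a)^2 / 4
  out <- list(table = tab, D = object$D,
              convergence = object$convergence,
              loglik = object$loglik)
  class(out) <- "summary.irt_2pl"
  out
}

#' @export
print.summary.irt_2pl <- function(x, ...) {
  cat(sprintf("2PL item parameters (D = %g):\n", x$D))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot item characteristic or information curves
#'
#' @param x An `irt_2pl` fit.
#' @param type `"icc"` for response curves or `"information"`.
#' @param theta_range Trait range to plot.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.irt_2pl <- function(x, type = c("icc", "information"),
                         theta_range = c(-4, 4), ...) {
  type <- match.arg(type)
  th <- seq(theta_range[1], theta_range[2], length.out = 200)
  tab <- x$coefficients
  curves <- sapply(seq_len(nrow(tab)), function(j) {
    if (type == "icc") prob_correct(th, tab$a[j], tab$b[j], x$D)
    else item_information(th, tab$a[j], tab$b[j], x$D)
  })
  graphics::matplot(th, curves, type = "l", lty = 1,
                    xlab = expression(theta),
                    ylab = if (type == "icc") "P(y = 1)" else "Information",
                    ...)
  invisible(x)
}

#' Expected a posteriori trait scores
#'
#' Posterior mean and standard deviation of the latent trait for each
#' person under the fitted 2PL and a standard-normal prior, computed on a
#' Gauss-Hermite grid. Persons with no observed responses receive the
#' prior (`theta = 0`, `sd = 1`).
#'
#' @param matrix A `response_matrix` or 0/1/NA matrix.
#' @param params An `irt_2pl` fit (or parameter table with `D`).
#' @param subset Optional indicator ids; defaults to the fitted items.
#' @param n_quad Quadrature size for the posterior grid (default 201).
#' @return A data frame of class `theta_estimate` with `person_id`, `eap`,
#'   `sd`, `n_items`.
#' @export
eap_scores <- function(matrix, params, subset = NULL, n_quad = 201) {
  y <- if (inherits(matrix, "response_matrix")) matrix$values else matrix
  tab <- item_param_table(params)
  ids <- if (is.null(subset)) intersect(colnames(y), tab$indicator) else subset
  missing_ids <- setdiff(ids, tab$indicator)
  if (length(missing_ids)) {
    stop("no fitted parameters for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  y <- y[, ids, drop = FALSE]
  tab <- tab[match(ids, tab$indicator), , drop = FALSE]

  quad <- normal_quadrature(n_quad)
  th <- quad$nodes
  lw <- log(quad$weights)
  eta <- tab$D[1] * outer(th, tab$a) -
    rep(tab$D[1] * tab$a * tab$b, each = n_quad)
  logP <- -log1p(exp(-eta))
  logQ <- -log1p(exp(eta))
  obs <- !is.na(y)
  y1 <- y; y1[!obs] <- 0
  y0 <- (1 - y); y0[!obs] <- 0
  storage.mode(y1) <- "double"
  storage.mode(y0) <- "double"
  ll <- y1 %*% t(logP) + y0 %*% t(logQ)
  ll <- sweep(ll, 2, lw, "+")
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)
  norm <- rowSums(w)
  post <- w / norm
  eap <- as.vector(post %*% th)
  second <- as.vector(post %*% (th * th))
  psd <- sqrt(pmax(second - eap^2, 0))
  none <- rowSums(obs) == 0L
  eap[none] <- 0
  psd[none] <- 1
  out <- data.frame(person_id = rownames(y) %||% seq_len(nrow(y)),
                    eap = eap, sd = psd, n_items = rowSums(obs),
                    stringsAsFactors = FALSE)
  class(out) <- c("theta_estimate", "data.frame")
  out
}

#' Marginal reliability at a target trait level
#'
#' `rel(theta*) = TI(theta*) / (TI(theta*) + 1)`, i.e. one minus the error
#' variance of the trait estimate under the unit-variance prior, evaluated
#' at the screening anchor.
#'
#' @param params An `irt_2pl` fit or parameter table.
#' @param subset Optional indicator ids.
#' @param theta_star Trait level at which reliability is evaluated.
#' @return Reliability in `[0, 1)` (0 for an empty subset).
#' @export
marginal_reliability <- function(params, subset = NULL, theta_star) {
  stopifnot(is.finite(theta_star))
  ti <- test_information(theta_star, params, subset)
  ti / (ti + 1)
}
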