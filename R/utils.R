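# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a reproducible child seed from a base seed (kept below 2^31).
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 2011L
}

# Gauss-Hermite quadrature transformed to the standard-normal measure:
# theta = sqrt(2) x, weights w / sqrt(pi), renormalized to sum exactly 1.
normal_quadrature <- function(n_nodes) {
  stopifnot(n_nodes >= 3)
  gh <- pracma::gaussHermite(n_nodes)
  nodes <- sqrt(2) * gh$x
  weights <- gh$w / sqrt(pi)
  list(nodes = nodes, weights = weights / sum(weights))
}

# Eigenvalue clipping repair for indefinite correlation matrices; rescales
# back to unit diagonal. Used for eigen-analysis and factoring only.
repair_psd <- function(mat, floor = 1e-6) {
  ev <- eigen(mat, symmetric = TRUE)
  if (min(ev$values) >= floor) {
    return(mat)
  }
  vals <- pmax(ev$values, floor)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- cov2cor(out)
  dimnames(out) <- dimnames(mat)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
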