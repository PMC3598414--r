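#' Iterative multicollinearity / local-dependency screening
#'
#' Ranks indicators by the number of pairwise tetrachoric correlations that
#' cannot be estimated (structural voids, degenerate margins, boundary
#' solutions) and repeatedly drops the most-involved indicator until no
#' inestimable pairs remain, honouring a forced-retention list of
#' clinically important indicators that must never be dropped.
#'
#' Ties on the inestimable count are broken by dropping the indicator whose
#' marginal positive proportion is farther from 0.5 (the worse-targeted
#' indicator), then lexicographically by id, so the result is deterministic
#' and invariant to input column order. If every remaining inestimable pair
#' involves only forced indicators, screening stops with a warning status
#' rather than dropping anything further.
#'
#' @param matrix A `response_matrix` or 0/1/NA matrix.
#' @param subset Optional indicator ids to screen (default: all columns;
#'   at least 3).
#' @param forced_retain Indicator ids that must be kept.
#' @param min_margin,boundary Estimability rules, see [tetrachoric()].
#' @return An object of class `screening_log`: list with `dropped` (data
#'   frame: indicator, inestimable count at drop time, iteration),
#'   `retained_forced`, `final_set`, `status` (`"clean"` or
#'   `"unresolved_forced"`), and `iterations`.
#' @examples
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' cohort <- simulate_responses(truth, 800, seed = 2)
#' iterative_screen(cohort, subset = sprintf("f1_direct_i%02d", 1:15))
#' @export
iterative_screen <- function(matrix, subset = NULL,
                             forced_retain = character(),
                             min_margin = 5, boundary = 0.995) {
  y <- if (inherits(matrix, "response_matrix")) matrix$values else matrix
  current <- if (is.null(subset)) colnames(y) else subset
  if (length(current) < 3) stop("need at least 3 indicators", call. = FALSE)
  unknown <- setdiff(forced_retain, current)
  if (length(unknown)) {
    stop("forced_retain not in subset: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  current <- sort(current)
  marg <- colMeans(y == 1, na.rm = TRUE)

  dropped <- data.frame(indicator = character(), count = integer(),
                        iteration = integer(), stringsAsFactors = FALSE)
  status <- "clean"
  iter <- 0L
  repeat {
    iter <- iter + 1L
    tet <- tetrachoric_matrix(y, subset = current,
                              min_margin = min_margin, boundary = boundary)
    inest <- !tet$estimable
    diag(inest) <- FALSE
    counts <- rowSums(inest)
    if (sum(counts) == 0L) break
    is_forced <- current %in% forced_retain
    # pairs fixable by dropping a non-forced member
    fixable <- inest
    fixable[is_forced, is_forced] <- FALSE
    if (sum(fixable) == 0L) {
      status <- "unresolved_forced"
      warning("inestimable pairs remain among forced-retain indicators")
      break
    }
    cand <- which(!is_forced & counts > 0L)
    if (!length(cand)) {
      status <- "unresolved_forced"
      warning("no droppable indicator left with inestimable pairs")
      break
    }
    extremity <- abs(marg[current] - 0.5)
    ord <- order(-counts[cand], -extremity[cand], current[cand])
    pick <- cand[ord[1L]]
    dropped <- rbind(dropped, data.frame(
      indicator = current[pick], count = counts[pick], iteration = iter,
      stringsAsFactors = FALSE))
    current <- current[-pick]
    if (length(current) < 2L) break
  }

  structure(
    list(dropped = dropped,
         retained_forced = intersect(forced_retain, current),
         final_set = current,
         status = status,
         iterations = iter),
    class = "screening_log"
  )
}

#' @export
print.screening_log <- function(x, ...) {
  cat("Indicator screening:", length(x$final_set), "retained,",
      nrow(x$dropped), "dropped [status:", x$status, "]\n")
  if (nrow(x$dropped)) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  dropped %-20s (%d inestimable pair(s), iteration %d)\n",
                  x$dropped$indicator[i], x$dropped$count[i],
                  x$dropped$iteration[i]))
    }
  }
  if (length(x$retained_forced)) {
    cat("  forced retained:", paste(x$retained_forced, collapse = ", "), "\n")
  }
  invisible(x)
}
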