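#' CAM Boolean diagnostic algorithm
#'
#' The Confusion Assessment Method rates delirium present when both
#' feature 1 (acute change in mental status with a fluctuating course) and
#' feature 2 (inattention) are present, together with either feature 3
#' (disorganized thinking) or feature 4 (altered level of consciousness).
#'
#' @param f1,f2,f3,f4 Logical (or 0/1) vectors of feature presence.
#' @return Logical vector: delirium present.
#' @examples
#' cam_algorithm(1, 1, 1, 0)  # TRUE
#' cam_algorithm(1, 0, 1, 1)  # FALSE: inattention required
#' @export
cam_algorithm <- function(f1, f2, f3, f4) {
  as.logical(f1) & as.logical(f2) & (as.logical(f3) | as.logical(f4))
}

#' Screening anchor: trait percentile of the feature-positive sub-group
#'
#' The stated percentile (linear-interpolation, type-7 quantile) of EAP
#' trait scores among persons rated positive on the CAM feature. The 50th
#' percentile is the screening anchor at which item information is
#' evaluated.
#'
#' @param scores A `theta_estimate` data frame (or numeric vector of EAPs).
#' @param labels Logical/0-1 vector of feature-positive ratings, one per
#'   person.
#' @param percentile One of 25, 50, 75.
#' @return The anchor trait level.
#' @export
theta_anchor <- function(scores, labels, percentile = 50) {
  stopifnot(percentile %in% c(25, 50, 75))
  eap <- if (is.data.frame(scores)) scores$eap else as.numeric(scores)
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(eap))
  if (!any(labels)) {
    stop("no feature-positive persons: supply labels with at least one ",
         "positive before anchoring the selection", call. = FALSE)
  }
  unname(quantile(eap[labels], probs = percentile / 100, type = 7,
                  na.rm = TRUE))
}

#' Rank indicators by information at the screening anchor
#'
#' Sorts indicators by item information evaluated at `theta_star`,
#' descending. Ties are broken by the smaller distance `|b - theta_star|`
#' (the better-centred item), then lexicographically by id.
#'
#' @param params An `irt_2pl` fit or parameter table.
#' @param theta_star Anchor trait level.
#' @param subset Optional indicator ids.
#' @return List with `ranking` (indicator ids, descending information) and
#'   `info_at_star` (named, in ranking order).
#' @export
rank_by_information <- function(params, theta_star, subset = NULL) {
  tab <- item_param_table(params)
  if (!is.null(subset)) tab <- tab[tab$indicator %in% subset, , drop = FALSE]
  info <- item_information(theta_star, tab$a, tab$b, tab$D)
  ord <- order(-info, abs(tab$b - theta_star), tab$indicator)
  list(ranking = tab$indicator[ord],
       info_at_star = setNames(info[ord], tab$indicator[ord]))
}

#' Select the top-k indicators from a ranking
#'
#' @param ranking Indicator ids in descending information order (or the
#'   list returned by [rank_by_information()]).
#' @param k Maximum number to keep (default 5).
#' @return The first `min(k, length(ranking))` ids.
#' @export
select_top_k <- function(ranking, k = 5) {
  stopifnot(k >= 1)
  if (is.list(ranking) && !is.null(ranking$ranking)) {
    ranking <- ranking$ranking
  }
  head(ranking, k)
}

#' Sensitivity of the selection to the anchor percentile
#'
#' Re-ranks the indicators with the anchor placed at the 25th, 50th and
#' 75th percentiles of the feature-positive trait distribution, and
#' summarizes agreement: pairwise top-`k` overlap counts and Kendall tau
#' over the full rankings. `stable` records whether the selections are
#' essentially the same (every pairwise top-`k` overlap at least
#' `overlap_threshold`).
#'
#' @param scores A `theta_estimate` (or numeric EAP vector).
#' @param labels Feature-positive ratings per person.
#' @param params An `irt_2pl` fit or parameter table.
#' @param subset Optional indicator ids.
#' @param k Selection size compared (default 5).
#' @param overlap_threshold Minimum top-`k` overlap counted as agreement
#'   (default 4).
#' @return List with `anchors`, `rankings`, `selected`, `top_k_overlap`,
#'   `kendall_tau`, and `stable`.
#' @export
sensitivity_analysis <- function(scores, labels, params, subset = NULL,
                                 k = 5, overlap_threshold = 4) {
  pct <- c(25, 50, 75)
  anchors <- vapply(pct, function(p) theta_anchor(scores, labels, p),
                    numeric(1))
  names(anchors) <- paste0("p", pct)
  rankings <- lapply(anchors, function(th) {
    rank_by_information(params, th, subset)
  })
  selected <- lapply(rankings, function(r) select_top_k(r$ranking, k))
  pairs <- utils::combn(names(rankings), 2)
  overlap <- apply(pairs, 2, function(pr) {
    length(intersect(selected[[pr[1]]], selected[[pr[2]]]))
  })
  names(overlap) <- apply(pairs, 2, paste, collapse = "_vs_")
  tau <- apply(pairs, 2, function(pr) {
    r1 <- rankings[[pr[1]]]$ranking
    r2 <- rankings[[pr[2]]]$ranking
    cor(match(r1, r1), match(r1, r2), method = "kendall")
  })
  names(tau) <- names(overlap)
  list(anchors = anchors,
       rankings = lapply(rankings, `[[`, "ranking"),
       selected = selected,
       top_k_overlap = overlap,
       kendall_tau = tau,
       stable = all(overlap >= min(overlap_threshold, k)))
}

#' Build a selection result at the 50th-percentile anchor
#'
#' Computes the screening anchor, ranks indicators by information at the
#' anchor, selects the top `k`, and attaches the percentile sensitivity
#' block.
#'
#' @inheritParams sensitivity_analysis
#' @param percentile Anchor percentile (default 50).
#' @return An object of class `selection_result` with `theta_star`,
#'   `percentile_used`, `info_at_star`, `ranking`, `selected`,
#'   `fallback_triggered`, and `sensitivity`.
#' @export
select_indicators <- function(scores, labels, params, subset = NULL, k = 5,
                              percentile = 50) {
  th <- theta_anchor(scores, labels, percentile)
  rk <- rank_by_information(params, th, subset)
  structure(
    list(theta_star = th,
         percentile_used = percentile,
         info_at_star = rk$info_at_star,
         ranking = rk$ranking,
         selected = select_top_k(rk$ranking, k),
         k = k,
         fallback_triggered = FALSE,
         sensitivity = sensitivity_analysis(scores, labels, params, subset,
                                            k = k)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Indicator selection at the %dth percentile anchor (theta* = %.3f%s)\n",
              x$percentile_used, x$theta_star,
              if (x$fallback_triggered) ", fallback" else ""))
  info <- x$info_at_star[x$selected]
  for (i in seq_along(x$selected)) {
    cat(sprintf("  %d. %-22s I(theta*) = %.3f\n", i, x$selected[i], info[i]))
  }
  cat("  sensitivity 25/50/75 top-k overlaps:",
      paste(x$sensitivity$top_k_overlap, collapse = ", "),
      if (x$sensitivity$stable) "(stable)\n" else "(unstable)\n")
  invisible(x)
}

#' Low-information fallback to the 75th-percentile anchor
#'
#' When every indicator's information at the 50th-percentile anchor falls
#' below `floor`, the anchor is recomputed at the 75th percentile of the
#' feature-positive trait distribution and the ranking and selection are
#' redone there, with `fallback_triggered` set. The default floor, 0.25,
#' is the peak information of an item with discrimination about 0.59 under
#' D = 1.7.
#'
#' @param result A `selection_result` computed at the 50th percentile.
#' @param scores,labels,params,subset As in [select_indicators()].
#' @param floor Information threshold triggering the fallback.
#' @return The (possibly re-anchored) `selection_result`.
#' @export
apply_fallback <- function(result, scores, labels, params, subset = NULL,
                           floor = 0.25) {
  stopifnot(inherits(result, "selection_result"))
  if (max(result$info_at_star) >= floor) {
    return(result)
  }
  out <- select_indicators(scores, labels, params, subset, k = result$k,
                           percentile = 75)
  out$fallback_triggered <- TRUE
  out
}
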