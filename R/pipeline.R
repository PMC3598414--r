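#' Pipeline configuration
#'
#' Collects the tunable parameters of the item-bank construction pipeline
#' with their defaults: permutation count for parallel analysis, RNG seed
#' (mandatory), scaling constant, quadrature size, selection size, the
#' low-information fallback floor, dimensionality-adjudication thresholds,
#' and the estimability rules for the screening stage.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param n_permutations Permutations for parallel analysis (default 100).
#' @param D Logistic scaling constant (default 1.7).
#' @param n_quad EM quadrature nodes (default 49).
#' @param k Indicators selected per dimension (1-10, default 5).
#' @param fallback_floor Information floor triggering the 75th-percentile
#'   fallback (default 0.25).
#' @param cfi_improvement CFI gain counted as multidimensionality evidence
#'   (default 0.01).
#' @param min_subset Smallest sub-set that is IRT-modeled (default 4).
#' @param min_margin,boundary Tetrachoric estimability rules.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, n_permutations = 100, D = 1.7,
                            n_quad = 49, k = 5, fallback_floor = 0.25,
                            cfi_improvement = 0.01, min_subset = 4,
                            min_margin = 5, boundary = 0.995) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(k >= 1, k <= 10, n_permutations >= 40, fallback_floor >= 0,
            cfi_improvement >= 0, min_subset >= 2)
  structure(list(seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 D = D, n_quad = as.integer(n_quad), k = as.integer(k),
                 fallback_floor = fallback_floor,
                 cfi_improvement = cfi_improvement,
                 min_subset = as.integer(min_subset),
                 min_margin = min_margin, boundary = boundary),
            class = "pipeline_config")
}

# Analysis of one feature-by-mode indicator set: screening, parallel
# analysis, factor models, adjudication, then per-dimension 2PL, EAP,
# anchored selection with fallback, and marginal reliability.
analyze_indicator_set <- function(y, labels, ids, feature, forced, config,
                                  set_seed) {
  screen <- iterative_screen(y, subset = ids, forced_retain = forced,
                             min_margin = config$min_margin,
                             boundary = config$boundary)
  kept <- screen$final_set
  out <- list(screening = screen, n_proposed = length(ids),
              n_modeled = length(kept))
  if (length(kept) < 3) {
    out$status <- "too_few_indicators"
    out$dimensions <- list()
    return(out)
  }
  pa <- permuted_parallel_analysis(y, subset = kept,
                                   n_permutations = config$n_permutations,
                                   seed = set_seed)
  out$parallel_analysis <- pa
  tet <- tetrachoric_matrix(y, subset = kept,
                            min_margin = config$min_margin,
                            boundary = config$boundary)
  pattern1 <- setNames(rep(1L, length(kept)), kept)
  fits <- list(cfa1 = fit_cfa(tet, pattern1))
  pattern <- NULL
  if (pa$m_significant > 1) {
    efa <- fit_efa(tet, m = pa$m_significant)
    pattern <- assign_simple_structure(efa)
    fits$efa <- efa
    if (all(tabulate(pattern, max(pattern)) >= 2)) {
      fits$cfam <- fit_cfa(tet, pattern)
      fits$bfa <- fit_bifactor(tet, pattern)
    }
  }
  out$fits <- fits
  adj <- adjudicate_dimensions(pa, fits, pattern,
                               cfi_improvement = config$cfi_improvement,
                               min_subset = config$min_subset)
  out$adjudication <- adj

  feat_labels <- labels[, feature]
  dims <- list()
  for (d in seq_along(adj$subsets)) {
    sub <- adj$subsets[[d]]
    dim_name <- if (length(adj$subsets) == 1) "factor1" else
      names(adj$subsets)[d]
    entry <- list(indicators = sub, modeled = FALSE)
    if (length(sub) < config$min_subset) {
      entry$status <- "not_modeled"
      dims[[dim_name]] <- entry
      next
    }
    res <- tryCatch({
      fit <- fit_2pl(y, subset = sub, D = config$D,
                     n_quad = config$n_quad)
      scores <- eap_scores(y, fit, subset = sub)
      sel <- select_indicators(scores, feat_labels, fit, subset = sub,
                               k = config$k)
      sel <- apply_fallback(sel, scores, feat_labels, fit, subset = sub,
                            floor = config$fallback_floor)
      rel <- marginal_reliability(fit, subset = sub,
                                  theta_star = sel$theta_star)
      list(fit = fit, scores = scores, selection = sel,
           marginal_reliability = rel, modeled = TRUE, status = "ok")
    }, error = function(e) {
      list(modeled = FALSE, status = paste("error:", conditionMessage(e)))
    })
    dims[[dim_name]] <- c(entry[setdiff(names(entry), "modeled")], res)
  }
  out$dimensions <- dims
  out$status <- "ok"
  out
}

#' Run the full item-bank construction pipeline
#'
#' For every CAM-feature-by-mode indicator set defined by the indicator
#' configuration: screen out locally dependent indicators, run permuted
#' parallel analysis, fit the single-factor CFA and (when more than one
#' root is significant) the m-factor EFA/CFA and bifactor models,
#' adjudicate the number of retained dimensions, split the set, and for
#' each sufficiently large sub-set fit the 2PL, score persons by EAP,
#' anchor the selection at the median trait of the feature-positive
#' sub-group (falling back to the 75th percentile when information there
#' is uniformly low), select the top-k indicators, and evaluate marginal
#' reliability at the anchor. A failure in one set is recorded in that
#' set's status; other sets still complete. Results are deterministic
#' given `(inputs, config)`.
#'
#' @param matrix A `response_matrix` with complete per-feature labels, or a
#'   0/1/NA matrix (then supply `feature_labels`).
#' @param indicator_config Data frame mapping indicators to features and
#'   modes (see [read_indicator_config()]); defaults to the configuration
#'   implied by the matrix's attached synthetic truth, if any.
#' @param config A [pipeline_config()].
#' @param feature_labels Persons x 4 matrix of 0/1 feature ratings, if not
#'   carried by `matrix`.
#' @return An object of class `pipeline_report`: per-set results,
#'   a dimensionality `summary` data frame, a `selection` listing, the
#'   indicator `accounting` (disposition of every input indicator), and
#'   the `config`.
#' @examples
#' \donttest{
#' truth <- generate_truth(default_cohort_spec(), seed = 1)
#' cohort <- simulate_responses(truth, 1500, seed = 2)
#' report <- run_pipeline(cohort, config = pipeline_config(seed = 3))
#' report
#' }
#' @export
run_pipeline <- function(matrix, indicator_config = NULL, config,
                         feature_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- if (inherits(matrix, "response_matrix")) matrix$values else matrix
  labels <- feature_labels %||%
    (if (inherits(matrix, "response_matrix")) matrix$feature_labels else NULL)
  if (is.null(labels)) {
    stop("per-feature positive labels are required", call. = FALSE)
  }
  if (is.null(indicator_config)) {
    truth <- if (inherits(matrix, "response_matrix")) matrix$truth else NULL
    if (is.null(truth)) {
      stop("supply an indicator_config (no attached truth to derive one)",
           call. = FALSE)
    }
    indicator_config <- indicator_config_from_truth(truth)
  }
  unknown <- setdiff(indicator_config$indicator_id, colnames(y))
  if (length(unknown)) {
    stop("indicator_config references absent indicator(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  sets <- unique(indicator_config[, c("feature", "mode")])
  sets <- sets[order(sets$feature, sets$mode), , drop = FALSE]
  results <- list()
  for (i in seq_len(nrow(sets))) {
    f <- sets$feature[i]
    mo <- sets$mode[i]
    set_id <- sprintf("f%d_%s", f, mo)
    rows <- indicator_config$feature == f & indicator_config$mode == mo
    ids <- indicator_config$indicator_id[rows]
    forced <- indicator_config$indicator_id[rows &
                                              indicator_config$forced_retain]
    results[[set_id]] <- tryCatch(
      c(list(feature = f, mode = mo),
        analyze_indicator_set(y, labels, ids, f, forced, config,
                              set_seed = child_seed(config$seed, i))),
      error = function(e) {
        list(feature = f, mode = mo, status = paste("error:",
                                                    conditionMessage(e)),
             n_proposed = length(ids), n_modeled = NA_integer_,
             dimensions = list())
      })
  }

  report <- structure(
    list(sets = results,
         summary = build_summary(results),
         selection = build_selection_table(results),
         accounting = build_accounting(results, indicator_config),
         config = config),
    class = "pipeline_report"
  )
  report
}

build_summary <- function(results) {
  rows <- lapply(names(results), function(set_id) {
    s <- results[[set_id]]
    fits <- s$fits %||% list()
    rel <- NA_real_
    modeled_dims <- Filter(function(d) isTRUE(d$modeled), s$dimensions)
    if (length(modeled_dims)) {
      rel <- mean(vapply(modeled_dims, `[[`, numeric(1),
                         "marginal_reliability"))
    }
    data.frame(
      set = set_id, feature = s$feature, mode = s$mode,
      n_proposed = s$n_proposed, n_modeled = s$n_modeled,
      m_significant = s$parallel_analysis$m_significant %||% NA_integer_,
      marginal_reliability = rel,
      cfi_1 = fits$cfa1$CFI %||% NA_real_,
      rmsea_1 = fits$cfa1$RMSEA %||% NA_real_,
      cfi_m = fits$cfam$CFI %||% NA_real_,
      rmsea_m = fits$cfam$RMSEA %||% NA_real_,
      large_secondary = fits$bfa$large_secondary %||% NA,
      retained_dimensions = s$adjudication$m_retained %||% NA_integer_,
      status = s$status,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

build_selection_table <- function(results) {
  rows <- list()
  for (set_id in names(results)) {
    s <- results[[set_id]]
    for (dim_name in names(s$dimensions)) {
      d <- s$dimensions[[dim_name]]
      if (!isTRUE(d$modeled)) next
      sel <- d$selection
      co <- coef(d$fit)
      for (r in seq_along(sel$selected)) {
        ind <- sel$selected[r]
        rows[[length(rows) + 1L]] <- data.frame(
          set = set_id, dimension = dim_name,
          theta_star = sel$theta_star,
          percentile = sel$percentile_used,
          rank = r, indicator = ind,
          a = co[ind, "a"], b = co[ind, "b"],
          information = unname(sel$info_at_star[ind]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(set = character(), dimension = character(),
                      theta_star = numeric(), percentile = integer(),
                      rank = integer(), indicator = character(),
                      a = numeric(), b = numeric(),
                      information = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Disposition of every configured indicator within its set:
# selected / unselected / dropped_at_screening / not_modeled.
build_accounting <- function(results, indicator_config) {
  rows <- list()
  for (set_id in names(results)) {
    s <- results[[set_id]]
    rows_cfg <- indicator_config$feature == s$feature &
      indicator_config$mode == s$mode
    ids <- indicator_config$indicator_id[rows_cfg]
    disp <- setNames(rep("not_modeled", length(ids)), ids)
    if (!is.null(s$screening)) {
      disp[s$screening$dropped$indicator] <- "dropped_at_screening"
    }
    for (d in s$dimensions) {
      if (isTRUE(d$modeled)) {
        disp[d$selection$ranking] <- "unselected"
        disp[d$selection$selected] <- "selected"
      }
    }
    rows[[set_id]] <- data.frame(set = set_id, indicator = ids,
                                 disposition = unname(disp),
                                 stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Item-bank construction pipeline:", nrow(x$summary),
      "indicator set(s)\n\n")
  cols <- c("set", "n_proposed", "n_modeled", "m_significant",
            "retained_dimensions", "marginal_reliability", "status")
  print(x$summary[, cols], row.names = FALSE, digits = 3)
  cat("\nSelected indicators:", nrow(x$selection), "rows across",
      length(unique(paste(x$selection$set, x$selection$dimension))),
      "dimension(s)\n")
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) {
  object$summary
}

#' Render a pipeline report to files
#'
#' Writes the canonical JSON report, the dimensionality-summary CSV, the
#' selection-listing CSV, and a plain-text log of every screening drop and
#' adjudication decision with the rule that produced it.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_render <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_as_list(report), json_path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  t1 <- file.path(dir, "table_dimensionality.csv")
  write.csv(report$summary, t1, row.names = FALSE)
  t3 <- file.path(dir, "table_selection.csv")
  write.csv(report$selection, t3, row.names = FALSE)
  log_path <- file.path(dir, "run.log")
  writeLines(report_log_lines(report), log_path)
  invisible(c(json_path, t1, t3, log_path))
}

# JSON-friendly view of the report (stable ordering, no S3 classes).
report_as_list <- function(report) {
  sets <- lapply(report$sets, function(s) {
    dims <- lapply(s$dimensions, function(d) {
      out <- list(indicators = d$indicators, modeled = isTRUE(d$modeled),
                  status = d$status %||% "ok")
      if (isTRUE(d$modeled)) {
        out$item_parameters <- d$fit$coefficients
        out$theta_star <- d$selection$theta_star
        out$percentile_used <- d$selection$percentile_used
        out$fallback_triggered <- d$selection$fallback_triggered
        out$selected <- d$selection$selected
        out$information_at_anchor <-
          as.list(d$selection$info_at_star[d$selection$selected])
        out$sensitivity <- list(
          anchors = as.list(d$selection$sensitivity$anchors),
          top_k_overlap = as.list(d$selection$sensitivity$top_k_overlap),
          stable = d$selection$sensitivity$stable)
        out$marginal_reliability <- d$marginal_reliability
      }
      out
    })
    list(feature = s$feature, mode = s$mode, status = s$status,
         n_proposed = s$n_proposed, n_modeled = s$n_modeled,
         screening = if (!is.null(s$screening)) list(
           dropped = s$screening$dropped,
           retained_forced = s$screening$retained_forced,
           status = s$screening$status),
         parallel_analysis = if (!is.null(s$parallel_analysis)) list(
           observed = s$parallel_analysis$observed_eigenvalues,
           quantiles = s$parallel_analysis$permutation_quantiles,
           m_significant = s$parallel_analysis$m_significant),
         dimensions = dims)
  })
  list(config = unclass(report$config), sets = sets,
       summary = report$summary, selection = report$selection,
       accounting = report$accounting)
}

report_log_lines <- function(report) {
  lines <- character(0)
  for (set_id in names(report$sets)) {
    s <- report$sets[[set_id]]
    lines <- c(lines, sprintf("[%s] status=%s proposed=%d modeled=%s",
                              set_id, s$status, s$n_proposed,
                              s$n_modeled %||% NA))
    if (!is.null(s$screening) && nrow(s$screening$dropped)) {
      lines <- c(lines, sprintf(
        "[%s] screening drop %s (%d inestimable pairs) [rule: highest inestimable count, extremity/id tie-break]",
        set_id, s$screening$dropped$indicator, s$screening$dropped$count))
    }
    if (!is.null(s$adjudication)) {
      ev <- s$adjudication$evidence
      lines <- c(lines, sprintf(
        "[%s] retained %d dimension(s) [evidence: roots=%s, cfi_gain=%s, large_secondary=%s; rule: m>1 needs 2 of 3]",
        set_id, s$adjudication$m_retained, ev["multiple_roots"],
        ev["cfi_gain"], ev["large_secondary"]))
    }
    for (dim_name in names(s$dimensions)) {
      d <- s$dimensions[[dim_name]]
      if (isTRUE(d$modeled)) {
        lines <- c(lines, sprintf(
          "[%s/%s] anchor=%.4f (percentile %d%s) selected: %s",
          set_id, dim_name, d$selection$theta_star,
          d$selection$percentile_used,
          if (d$selection$fallback_triggered) ", fallback" else "",
          paste(d$selection$selected, collapse = ", ")))
      } else {
        lines <- c(lines, sprintf("[%s/%s] %s (%d indicator(s))",
                                  set_id, dim_name,
                                  d$status %||% "not_modeled",
                                  length(d$indicators)))
      }
    }
  }
  lines
}
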