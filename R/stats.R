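#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) form with the Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param xs,ys numeric samples, each with at least 2 values.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(xs, ys) {
  if (length(xs) < 2L || length(ys) < 2L)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(c(xs, ys)))) stop("inputs must be finite")
  if (stats::var(xs) == 0 && stats::var(ys) == 0) {
    # degenerate: identical constants compare as equal
    return(list(t = 0, df = length(xs) + length(ys) - 2, p = 1))
  }
  ht <- stats::t.test(xs, ys, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-squared test on a contingency table
#'
#' Standard Pearson chi-squared without continuity correction;
#' df = (r-1)(c-1).
#'
#' @param table r x c matrix of nonnegative integer counts with no zero row
#'   or column margin.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total: test undefined")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' 5th-95th percentile interval
#'
#' Percentiles with linear interpolation between order statistics, the
#' spread summary reported alongside group means of per-mass stiffness
#' indices.
#'
#' @param xs numeric sample, n >= 2.
#' @return length-2 numeric (5th, 95th percentile).
#' @export
percentile_interval_5_95 <- function(xs) {
  if (length(xs) < 2L) stop("need at least 2 observations")
  stats::quantile(xs, c(0.05, 0.95), type = 7, names = FALSE)
}

#' Pairwise group comparisons of mass metrics
#'
#' For each stratum (size class x filtered flag) present in the records,
#' compares cancer vs cyst, cancer vs fibroadenoma and cyst vs fibroadenoma
#' on the stiffness index and on GLCM homogeneity, using the Welch t-test,
#' with per-group means and 5-95 percentile intervals. Raw p-values are
#' always reported; the significance flag applies the stated threshold with
#' no multiple-testing correction.
#'
#' @param records data frame of \code{\link{measure_mass}} rows.
#' @param alpha significance threshold (default 0.05).
#' @return data frame of class \code{group_comparison}; strata with fewer
#'   than 2 masses in either group are skipped with a message.
#' @export
compare_mass_groups <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  need <- c("histology", "size_class", "filtered", "stiffness_index", "homogeneity")
  if (!all(need %in% names(records)))
    stop("records must carry columns: ", paste(need, collapse = ", "))
  pairs <- list(c("cancer", "cyst"), c("cancer", "fibroadenoma"),
                c("cyst", "fibroadenoma"))
  out <- list()
  for (sz in intersect(c("small", "large"), unique(records$size_class))) {
    for (fl in sort(unique(records$filtered))) {
      stratum <- records[records$size_class == sz & records$filtered == fl, ]
      for (metric in c("stiffness_index", "homogeneity")) {
        for (pr in pairs) {
          xa <- stratum[[metric]][stratum$histology == pr[1]]
          xb <- stratum[[metric]][stratum$histology == pr[2]]
          xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
          if (length(xa) < 2L || length(xb) < 2L) {
            message(sprintf("skipping %s %s/%s vs %s (filtered=%s): <2 per group",
                            metric, sz, pr[1], pr[2], fl))
            next
          }
          tt <- welch_t_test(xa, xb)
          ia <- percentile_interval_5_95(xa)
          ib <- percentile_interval_5_95(xb)
          out[[length(out) + 1L]] <- data.frame(
            size_class = sz, filtered = fl, metric = metric,
            group_a = pr[1], group_b = pr[2],
            n_a = length(xa), n_b = length(xb),
            mean_a = mean(xa), mean_b = mean(xb),
            lo_a = ia[1], hi_a = ia[2], lo_b = ib[1], hi_b = ib[2],
            t = tt$t, df = tt$df, p = tt$p,
            significant = tt$p < alpha,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(size_class = character(), filtered = logical(),
               metric = character(), group_a = character(),
               group_b = character(), n_a = integer(), n_b = integer(),
               mean_a = numeric(), mean_b = numeric(), lo_a = numeric(),
               hi_a = numeric(), lo_b = numeric(), hi_b = numeric(),
               t = numeric(), df = numeric(), p = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' Write report tables
#'
#' Emits the analysis outputs as plain CSV files with deterministic row
#' ordering: the six-component volume table (stiffness-by-tissue layout),
#' the per-mass records, the pairwise group comparisons, and the mean
#' six-component distributions per histology x size class x filtered flag
#' (the mass-distribution bar-chart data).
#'
#' @param volumes a \code{component_volume_table} (or \code{NULL}).
#' @param records per-mass records data frame (or \code{NULL}).
#' @param comparisons a \code{group_comparison} data frame (or \code{NULL}).
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
render_reports <- function(volumes = NULL, records = NULL,
                           comparisons = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written[[name]] <<- path
  }
  if (!is.null(volumes)) wr(volume_report(volumes, digits = 6), "component_volumes.csv")
  if (!is.null(records) && nrow(records)) {
    ord <- order(records$histology, records$size_class, records$filtered,
                 records$breast_id)
    wr(records[ord, ], "mass_records.csv")
    agg_cols <- paste0("pct_", six_component_names())
    if (all(agg_cols %in% names(records))) {
      agg <- stats::aggregate(records[agg_cols],
                              by = records[c("histology", "size_class", "filtered")],
                              FUN = mean)
      agg <- agg[order(agg$histology, agg$size_class, agg$filtered), ]
      wr(agg, "mass_component_distributions.csv")
    }
  }
  if (!is.null(comparisons) && nrow(comparisons))
    wr(as.data.frame(comparisons), "mass_comparisons.csv")
  invisible(unlist(written))
}
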