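#' Tukey boxplot statistics with explicit whisker/outlier semantics
#'
#' Quartiles are computed either by linear interpolation of the
#' empirical quantile function (`"linear"`, the type-7 rule; default)
#' or by Tukey hinges (`"hinges"`, the `fivenum()` convention) — the
#' convention behind a published whisker range is often unstated, so
#' both are exposed for sensitivity checks. An outlier is a value more
#' than 1.5 x IQR beyond the box; the whiskers run to the furthest
#' observations within that fence (not to the fence itself).
#'
#' @param values Numeric vector, `n >= 1`, finite.
#' @param quartile_method `"linear"` (type 7) or `"hinges"`.
#' @param whisker_coef Fence coefficient, default 1.5.
#' @return An object of class `boxplot_stats`: `n`, `median`, `q1`,
#'   `q3`, `iqr`, `whisker_low`, `whisker_high`, `whisker_span`,
#'   `outliers`, `low_n` (flag for `n < 4`), `quartile_method`.
#' @export
boxplot_stats <- function(values, quartile_method = c("linear", "hinges"),
                          whisker_coef = 1.5) {
  quartile_method <- match.arg(quartile_method)
  if (!is.numeric(values) || length(values) < 1L) {
    stop_field("values", "must contain at least one value")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_field("values", "must be finite and non-missing")
  }
  if (quartile_method == "linear") {
    q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    q1 <- q[1]; med <- q[2]; q3 <- q[3]
  } else {
    fn <- stats::fivenum(values)
    q1 <- fn[2]; med <- fn[3]; q3 <- fn[4]
  }
  iqr <- q3 - q1
  lo_fence <- q1 - whisker_coef * iqr
  hi_fence <- q3 + whisker_coef * iqr
  inside <- values >= lo_fence & values <= hi_fence
  outliers <- sort(values[!inside])
  whisker_low <- min(values[inside])
  whisker_high <- max(values[inside])
  structure(
    list(n = length(values), median = med, q1 = q1, q3 = q3, iqr = iqr,
         whisker_low = whisker_low, whisker_high = whisker_high,
         whisker_span = whisker_high - whisker_low, outliers = outliers,
         low_n = length(values) < 4L, quartile_method = quartile_method),
    class = "boxplot_stats"
  )
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf(
    "Boxplot stats (n = %d%s): median %.3g [Q1 %.3g, Q3 %.3g], whiskers [%.3g, %.3g] (span %.3g), %d outlier(s)\n",
    x$n, if (x$low_n) ", low n" else "", x$median, x$q1, x$q3,
    x$whisker_low, x$whisker_high, x$whisker_span, length(x$outliers)))
  invisible(x)
}

#' Whisker span (heterogeneity metric)
#'
#' Distance between the lower and upper whiskers of a Tukey boxplot —
#' the furthest observations within 1.5 x IQR of the box. Used as the
#' scalar measure of inactivation-delay heterogeneity: broader span,
#' more heterogeneous kinetics.
#'
#' @param stats A [boxplot_stats()] object, or a numeric vector (then
#'   the stats are computed first).
#' @param ... Passed to [boxplot_stats()] when `stats` is numeric.
#' @return Whisker span in the data's units.
#' @export
whisker_span <- function(stats, ...) {
  if (is.numeric(stats)) stats <- boxplot_stats(stats, ...)
  stopifnot(inherits(stats, "boxplot_stats"))
  stats$whisker_high - stats$whisker_low
}

#' Pearson product-moment correlation with domain checks
#'
#' Used as the diagnostic that inactivation width is not a by-product
#' of current amplitude: across cells, `inac_width` vs `I_max` should
#' show no systematic correlation.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with
#'   non-zero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_field("y", "must match length of x")
  if (length(x) < 3L) stop_field("x", "needs at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_field("x", "must be non-missing")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in x or y", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Compare inactivation-delay heterogeneity across conditions
#'
#' Builds per-condition boxplot statistics of the inactivation widths,
#' the whisker spans, span ratios against a designated reference
#' condition (`span_ratio = span_condition / span_reference`), and the
#' per-condition Pearson correlation between width and peak current.
#' Censored (window-limited) widths are included by default with their
#' truncated value; `include_censored = FALSE` drops them for
#' sensitivity analysis.
#'
#' @param measurements Data frame from [measure_cohort()] (needs
#'   `condition`, `inac_width_ms`, `analysable`; `i_max_nA` and
#'   `censored` are used when present).
#' @param reference Reference condition label (must be present).
#' @param quartile_method Passed to [boxplot_stats()].
#' @param include_censored Keep censored widths (default `TRUE`).
#' @return An object of class `heterogeneity_report`: `table` (one row
#'   per condition: `condition`, `n`, `n_censored`, `median`, `q1`,
#'   `q3`, `iqr`, `whisker_low`, `whisker_high`, `whisker_span`,
#'   `n_outliers`, `span_ratio`, `width_imax_corr`), `stats` (named
#'   list of `boxplot_stats`), `reference`, and — when the measurement
#'   table carries them — the normalized `overlay` matrix and
#'   `overlay_time`.
#' @export
compare_conditions <- function(measurements, reference = "control",
                               quartile_method = c("linear", "hinges"),
                               include_censored = TRUE) {
  quartile_method <- match.arg(quartile_method)
  stopifnot(is.data.frame(measurements),
            all(c("condition", "inac_width_ms") %in% names(measurements)))
  keep <- if ("analysable" %in% names(measurements)) {
    measurements$analysable
  } else rep(TRUE, nrow(measurements))
  if (!include_censored && "censored" %in% names(measurements)) {
    keep <- keep & !measurements$censored
  }
  meas <- measurements[keep, , drop = FALSE]
  conds <- unique(meas$condition)
  if (!reference %in% conds) {
    stop(sprintf("unknown reference condition '%s'; present: %s", reference,
                 paste(conds, collapse = ", ")), call. = FALSE)
  }
  stats_list <- list()
  rows <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    sub <- meas[meas$condition == conds[i], , drop = FALSE]
    bs <- boxplot_stats(sub$inac_width_ms, quartile_method = quartile_method)
    stats_list[[conds[i]]] <- bs
    r <- if ("i_max_nA" %in% names(sub) && nrow(sub) >= 3 &&
             stats::sd(sub$inac_width_ms) > 0 && stats::sd(sub$i_max_nA) > 0) {
      pearson_corr(sub$inac_width_ms, sub$i_max_nA)
    } else NA_real_
    rows[[i]] <- data.frame(
      condition = conds[i], n = bs$n,
      n_censored = if ("censored" %in% names(sub)) sum(sub$censored) else
        NA_integer_,
      median = bs$median, q1 = bs$q1, q3 = bs$q3, iqr = bs$iqr,
      whisker_low = bs$whisker_low, whisker_high = bs$whisker_high,
      whisker_span = bs$whisker_span, n_outliers = length(bs$outliers),
      span_ratio = NA_real_, width_imax_corr = r,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ref_span <- tab$whisker_span[tab$condition == reference]
  tab$span_ratio <- if (ref_span > 0) tab$whisker_span / ref_span else
    NA_real_
  out <- list(table = tab, stats = stats_list, reference = reference,
              quartile_method = quartile_method,
              overlay = attr(measurements, "overlay"),
              overlay_time = attr(measurements, "overlay_time"))
  class(out) <- "heterogeneity_report"
  out
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Heterogeneity report (reference: %s, quartiles: %s)\n",
              x$reference, x$quartile_method))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-14s n = %2d  median %7.2f ms  whisker span %7.2f ms  (ratio vs ref %.3g)\n",
      tab$condition[i], tab$n[i], tab$median[i], tab$whisker_span[i],
      tab$span_ratio[i]))
  }
  invisible(x)
}
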