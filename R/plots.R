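#' Overlay plot of normalized current traces
#'
#' Draws the window-restricted, peak-normalized traces of every
#' analysable cell (optionally one condition) on a common time base —
#' the standard visual of inactivation-delay heterogeneity.
#'
#' @param report A `heterogeneity_report` carrying an overlay matrix,
#'   or a measurement data frame from [measure_cohort()].
#' @param condition Optional condition label to restrict to.
#' @param col Trace colour.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted overlay matrix.
#' @export
plot_overlay <- function(report, condition = NULL,
                         col = grDevices::grey(0.2, alpha = 0.35), ...) {
  if (inherits(report, "heterogeneity_report")) {
    ov <- report$overlay
    tt <- report$overlay_time
  } else {
    ov <- attr(report, "overlay")
    tt <- attr(report, "overlay_time")
  }
  if (is.null(ov)) stop("no overlay matrix attached", call. = FALSE)
  if (!is.null(condition) && is.data.frame(report)) {
    ids <- report$cell_id[report$condition == condition & report$analysable]
    ov <- ov[, intersect(colnames(ov), ids), drop = FALSE]
  }
  graphics::matplot(tt, ov, type = "l", lty = 1, col = col,
                    xlab = "time (ms)", ylab = expression(I / I[max]),
                    main = if (is.null(condition)) "Normalized overlay" else
                      paste("Normalized overlay:", condition), ...)
  invisible(ov)
}

#' Boxplots of inactivation widths per condition
#'
#' Renders the already-computed Tukey statistics (so the displayed
#' whiskers are exactly the ones the whisker-span metric uses).
#'
#' @param report A `heterogeneity_report`.
#' @param ... Passed to [graphics::bxp()].
#' @return Invisibly, the `bxp` input structure.
#' @export
plot_width_boxplots <- function(report, ...) {
  stopifnot(inherits(report, "heterogeneity_report"))
  st <- report$stats
  z <- list(
    stats = vapply(st, function(b) {
      c(b$whisker_low, b$q1, b$median, b$q3, b$whisker_high)
    }, numeric(5)),
    n = vapply(st, `[[`, numeric(1), "n"),
    conf = vapply(st, function(b) {
      c(b$median - 1.58 * b$iqr / sqrt(b$n),
        b$median + 1.58 * b$iqr / sqrt(b$n))
    }, numeric(2)),
    out = unlist(lapply(st, `[[`, "outliers")),
    group = rep(seq_along(st),
                vapply(st, function(b) length(b$outliers), integer(1))),
    names = names(st)
  )
  graphics::bxp(z, ylab = "Inac-width (ms)", ...)
  invisible(z)
}
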