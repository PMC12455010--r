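#' Extract the sweep at a target step potential
#'
#' @param cell A `cell_recording`.
#' @param target_potential Step potential in mV (default +80, the
#'   conventional analysis step).
#' @return List with `time` (ms) and `current` (pA); an absent
#'   potential raises an error listing the available steps.
#' @export
extract_target_sweep <- function(cell, target_potential = 80) {
  stopifnot(inherits(cell, "cell_recording"))
  steps <- as.numeric(colnames(cell$sweeps))
  j <- which(abs(steps - target_potential) < 1e-9)
  if (!length(j)) {
    stop(sprintf(
      "cell '%s': no sweep at %g mV; available step potentials: %s",
      cell$cell_id, target_potential,
      paste(steps, collapse = ", ")), call. = FALSE)
  }
  scale <- if (identical(cell$current_unit, "nA")) 1000 else 1
  list(time = cell$times, current = cell$sweeps[, j[1]] * scale)
}

#' Normalize a sweep to its windowed peak
#'
#' Restricts the sweep to the analysis window (default 70-599 ms,
#' sweep-relative), finds the peak current `I_max` within that window,
#' and returns the window-restricted trace divided by `I_max`, so the
#' normalized maximum is exactly 1 at the peak sample. Peak search and
#' normalization are confined to the window by default; set
#' `whole_sweep_peak = TRUE` to normalize by the whole-sweep maximum
#' instead. Optional baseline subtraction removes the pre-window mean.
#'
#' @param sweep List with `time` (ms) and `current` (pA), as returned by
#'   [extract_target_sweep()].
#' @param window Length-2 numeric, analysis window in ms.
#' @param whole_sweep_peak Use the whole-sweep maximum for `I_max`.
#' @param baseline `"none"` (default) or `"pre_window"` (subtract the
#'   mean current before the window start).
#' @return List with `time`, `normalized` (unitless), `i_max_nA`,
#'   `i_max_pA`, `window`.
#' @export
normalize_trace <- function(sweep, window = c(70, 599),
                            whole_sweep_peak = FALSE,
                            baseline = c("none", "pre_window")) {
  baseline <- match.arg(baseline)
  stopifnot(is.list(sweep), length(window) == 2L, window[1] < window[2])
  t <- sweep$time
  y <- sweep$current
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
    stop(sprintf("analysis window [%g, %g] ms exceeds sweep span [%g, %g] ms",
                 window[1], window[2], t[1], t[length(t)]), call. = FALSE)
  }
  if (baseline == "pre_window") {
    pre <- y[t < window[1]]
    if (length(pre)) y <- y - mean(pre)
  }
  sel <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
  tw <- t[sel]
  yw <- y[sel]
  i_max <- if (whole_sweep_peak) max(y) else max(yw)
  if (i_max <= 0) {
    stop("unanalysable sweep: non-positive peak current", call. = FALSE)
  }
  list(time = tw, normalized = yw / i_max, i_max_nA = i_max / 1000,
       i_max_pA = i_max, window = window)
}

# Linearly interpolated crossing time between samples i and i+1.
interp_crossing <- function(t, y, i, level) {
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

#' Inactivation width at a fractional level of the normalized peak
#'
#' The core delay-heterogeneity statistic: the temporal width of the
#' normalized current trace at `level` (default 0.70) of its peak.
#' `t_up` is the first upward crossing of `level` (linear interpolation
#' between the bracketing samples; if the trace starts at or above
#' `level`, `t_up` is the window start). `t_down` is the last downward
#' crossing. If the trace never falls back below `level` before the
#' window ends, the measurement is right-censored at the window end:
#' `censored = TRUE` and `inac_width = window_end - t_up`. A trace that
#' never reaches `level` raises a "no peak above level" error. The
#' first-up/last-down rule makes the width robust to brief noise dips
#' through the level.
#'
#' @param normalized A list from [normalize_trace()] (fields `time`,
#'   `normalized`, `window`, optionally `i_max_nA`).
#' @param level Fraction of peak in (0, 1), default 0.7.
#' @param cell_id Identifier carried into the result.
#' @return An object of class `inactivation_measurement`: `cell_id`,
#'   `i_max_nA`, `window`, `level`, `t_up`, `t_down`, `inac_width` (ms),
#'   `censored`, `n_level_crossings`.
#' @export
inac_width <- function(normalized, level = 0.7, cell_id = NA_character_) {
  stopifnot(is.list(normalized))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_field("level", "must lie strictly in (0, 1)")
  }
  t <- normalized$time
  y <- normalized$normalized
  n <- length(y)
  above <- y >= level
  if (!any(above)) {
    stop("no peak above level: trace never reaches the crossing level",
         call. = FALSE)
  }
  d <- diff(above)
  up_idx <- which(d == 1L)    # y[i] < level <= y[i+1]
  down_idx <- which(d == -1L) # y[i] >= level > y[i+1]
  n_crossings <- length(up_idx) + length(down_idx)
  if (above[1L]) {
    t_up <- t[1L]
  } else {
    i <- up_idx[1L]
    t_up <- interp_crossing(t, y, i, level)
  }
  censored <- above[n]
  if (censored) {
    t_down <- t[n]
  } else {
    i <- down_idx[length(down_idx)]
    t_down <- interp_crossing(t, y, i, level)
  }
  width <- t_down - t_up
  structure(
    list(cell_id = cell_id,
         i_max_nA = if (is.null(normalized$i_max_nA)) NA_real_ else
           normalized$i_max_nA,
         window = if (is.null(normalized$window))
           c(t[1L], t[n]) else normalized$window,
         level = level, t_up = t_up, t_down = t_down, inac_width = width,
         censored = censored, n_level_crossings = n_crossings),
    class = "inactivation_measurement"
  )
}

#' @export
print.inactivation_measurement <- function(x, ...) {
  cat(sprintf(
    "Inac-width %s: %.2f ms at %g%% of peak (t_up %.2f, t_down %.2f)%s\n",
    ifelse(is.na(x$cell_id), "", paste0("[", x$cell_id, "]")),
    x$inac_width, 100 * x$level, x$t_up, x$t_down,
    if (x$censored) " [censored at window end]" else ""))
  invisible(x)
}

#' Measure inactivation widths across a cohort
#'
#' For each cell: extract the target-potential sweep, optionally
#' zero-phase low-pass filter it, normalize within the analysis window,
#' and measure the width at `level` of the normalized peak. Cells whose
#' sweep is unanalysable (no positive peak, never reaching the level)
#' are reported with `analysable = FALSE` and the error message, not
#' dropped silently.
#'
#' @param cells List of `cell_recording` objects.
#' @param target_potential Analysis step potential, mV.
#' @param window Analysis window, ms (sweep-relative).
#' @param level Fractional crossing level in (0, 1).
#' @param lowpass_kHz Optional zero-phase Butterworth low-pass cutoff in
#'   kHz applied before crossing detection (requires the `signal`
#'   package); `NULL` (default) disables filtering.
#' @param whole_sweep_peak,baseline Passed to [normalize_trace()].
#' @return Data frame, one row per cell: `cell_id`, `condition`,
#'   `i_max_nA`, `t_up_ms`, `t_down_ms`, `inac_width_ms`, `censored`,
#'   `n_level_crossings`, `analysable`, `note`; the normalized overlay
#'   traces (time x cell matrix, analysable cells) are attached as
#'   attributes `"overlay"` and `"overlay_time"`.
#' @export
measure_cohort <- function(cells, target_potential = 80,
                           window = c(70, 599), level = 0.7,
                           lowpass_kHz = NULL, whole_sweep_peak = FALSE,
                           baseline = c("none", "pre_window")) {
  baseline <- match.arg(baseline)
  if (inherits(cells, "cell_recording")) cells <- list(cells)
  rows <- vector("list", length(cells))
  overlay <- list()
  overlay_time <- NULL
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    row <- data.frame(cell_id = cell$cell_id, condition = cell$condition,
                      i_max_nA = NA_real_, t_up_ms = NA_real_,
                      t_down_ms = NA_real_, inac_width_ms = NA_real_,
                      censored = NA, n_level_crossings = NA_integer_,
                      analysable = FALSE, note = "",
                      stringsAsFactors = FALSE)
    m <- tryCatch({
      sweep <- extract_target_sweep(cell, target_potential)
      if (!is.null(lowpass_kHz)) {
        sweep$current <- lowpass_filter(sweep$current, sweep$time, lowpass_kHz)
      }
      norm <- normalize_trace(sweep, window = window,
                              whole_sweep_peak = whole_sweep_peak,
                              baseline = baseline)
      list(norm = norm,
           meas = inac_width(norm, level = level, cell_id = cell$cell_id))
    }, error = function(e) e)
    if (inherits(m, "error")) {
      row$note <- conditionMessage(m)
    } else {
      row$i_max_nA <- m$meas$i_max_nA
      row$t_up_ms <- m$meas$t_up
      row$t_down_ms <- m$meas$t_down
      row$inac_width_ms <- m$meas$inac_width
      row$censored <- m$meas$censored
      row$n_level_crossings <- m$meas$n_level_crossings
      row$analysable <- TRUE
      overlay[[cell$cell_id]] <- m$norm$normalized
      if (is.null(overlay_time)) overlay_time <- m$norm$time
    }
    rows[[i]] <- row
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(out)) {
    out <- data.frame(cell_id = character(0), condition = character(0),
                      i_max_nA = numeric(0), t_up_ms = numeric(0),
                      t_down_ms = numeric(0), inac_width_ms = numeric(0),
                      censored = logical(0), n_level_crossings = integer(0),
                      analysable = logical(0), note = character(0),
                      stringsAsFactors = FALSE)
  }
  if (length(overlay)) {
    attr(out, "overlay") <- do.call(cbind, overlay)
    attr(out, "overlay_time") <- overlay_time
  }
  out
}

# Zero-phase Butterworth low-pass (order 4), cutoff in kHz.
lowpass_filter <- function(current, time, cutoff_kHz) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop("low-pass filtering requires the 'signal' package", call. = FALSE)
  }
  fs <- 1 / mean(diff(time))  # kHz
  wc <- 2 * cutoff_kHz / fs
  if (wc >= 1) return(current)
  bf <- signal::butter(4, wc, type = "low")
  as.numeric(signal::filtfilt(bf, current))
}
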