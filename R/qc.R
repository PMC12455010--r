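#' Quality-control thresholds
#'
#' Stage-1 screens the amplifier/seal metadata with strict inequalities
#' as conventionally reported: |V-offset| < 45 mV, seal resistance
#' > 200 MOhm, series resistance < 15 MOhm, slow capacitance < 35 pF.
#' Stage-2 keeps cells whose peak current lies in the inclusive
#' 0.5-45 nA window. All six values are overridable.
#'
#' @param v_offset_max Max |V-offset|, mV (exclusive).
#' @param r_seal_min Min seal resistance, MOhm (exclusive).
#' @param r_series_max Max series resistance, MOhm (exclusive).
#' @param c_slow_max Max slow capacitance, pF (exclusive).
#' @param i_max_min,i_max_max Stage-2 peak-current window, nA
#'   (inclusive).
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(v_offset_max = 45, r_seal_min = 200,
                          r_series_max = 15, c_slow_max = 35,
                          i_max_min = 0.5, i_max_max = 45) {
  structure(list(v_offset_max = v_offset_max, r_seal_min = r_seal_min,
                 r_series_max = r_series_max, c_slow_max = c_slow_max,
                 i_max_min = i_max_min, i_max_max = i_max_max),
            class = "qc_thresholds")
}

# One stage-1 criterion check; returns NULL on pass, else a failure
# record (criterion, observed, threshold).
check_criterion <- function(name, observed, threshold, pass_when) {
  if (is.null(observed) || is.na(observed)) {
    return(list(criterion = name, observed = NA_real_,
                threshold = threshold, note = "missing"))
  }
  if (pass_when(observed, threshold)) return(NULL)
  list(criterion = name, observed = observed, threshold = threshold,
       note = "out of range")
}

#' Stage-1 QC: recording-metadata screen
#'
#' A cell passes iff `|v_offset| < v_offset_max` and
#' `r_seal > r_seal_min` and `r_series < r_series_max` and
#' `c_slow < c_slow_max` (strict inequalities; values exactly at a
#' threshold fail). Missing metadata fail the corresponding criterion
#' with a "missing" note rather than raising an error.
#'
#' @param cell A `cell_recording`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A `qc_result` list: `cell_id`, `stage1_pass`, `stage2_pass`
#'   (`NA`, not yet evaluated), `failed_criteria` (list of failure
#'   records), `manually_excluded`.
#' @export
stage1_qc <- function(cell, thresholds = qc_thresholds()) {
  stopifnot(inherits(cell, "cell_recording"))
  fails <- list(
    check_criterion("v_offset", abs(cell$v_offset), thresholds$v_offset_max,
                    function(x, th) x < th),
    check_criterion("r_seal", cell$r_seal, thresholds$r_seal_min,
                    function(x, th) x > th),
    check_criterion("r_series", cell$r_series, thresholds$r_series_max,
                    function(x, th) x < th),
    check_criterion("c_slow", cell$c_slow, thresholds$c_slow_max,
                    function(x, th) x < th)
  )
  fails <- fails[!vapply(fails, is.null, TRUE)]
  structure(list(cell_id = cell$cell_id, stage1_pass = length(fails) == 0L,
                 stage2_pass = NA, failed_criteria = fails,
                 manually_excluded = FALSE),
            class = "qc_result")
}

#' Stage-2 QC: peak-current amplitude screen
#'
#' Evaluated only for stage-1 passers: the cell is kept iff
#' `i_max_min <= i_max <= i_max_max` (inclusive bounds).
#'
#' @param result A `qc_result` from [stage1_qc()].
#' @param i_max Peak current of the target sweep, nA.
#' @param thresholds A [qc_thresholds()] object.
#' @return The updated `qc_result`.
#' @export
stage2_qc <- function(result, i_max, thresholds = qc_thresholds()) {
  stopifnot(inherits(result, "qc_result"))
  if (!result$stage1_pass) return(result)
  if (is.null(i_max) || is.na(i_max)) {
    result$stage2_pass <- FALSE
    result$failed_criteria <- c(result$failed_criteria, list(
      list(criterion = "i_max", observed = NA_real_,
           threshold = thresholds$i_max_min, note = "missing")))
    return(result)
  }
  if (i_max < thresholds$i_max_min) {
    result$stage2_pass <- FALSE
    result$failed_criteria <- c(result$failed_criteria, list(
      list(criterion = "i_max", observed = i_max,
           threshold = thresholds$i_max_min,
           note = sprintf("I_max below %g nA", thresholds$i_max_min))))
  } else if (i_max > thresholds$i_max_max) {
    result$stage2_pass <- FALSE
    result$failed_criteria <- c(result$failed_criteria, list(
      list(criterion = "i_max", observed = i_max,
           threshold = thresholds$i_max_max,
           note = sprintf("I_max above %g nA", thresholds$i_max_max))))
  } else {
    result$stage2_pass <- TRUE
  }
  result
}

format_failures <- function(fails) {
  if (!length(fails)) return("")
  paste(vapply(fails, function(f) {
    sprintf("%s (observed %s, threshold %g)", f$criterion,
            ifelse(is.na(f$observed), "missing", sprintf("%g", f$observed)),
            f$threshold)
  }, character(1)), collapse = "; ")
}

#' Apply two-stage QC to a cohort
#'
#' Runs [stage1_qc()] on every cell, optionally [stage2_qc()] where peak
#' currents are available, and applies a manual exclusion list (the
#' analyst's review of unstable recordings). The report conserves
#' counts: every input cell appears in exactly one row.
#'
#' @param cells List of `cell_recording` objects.
#' @param thresholds A [qc_thresholds()] object.
#' @param exclusion_list Character vector of manually excluded
#'   `cell_id`s; unknown ids raise a warning, not an error.
#' @param i_max Optional named numeric vector of peak currents (nA) per
#'   `cell_id`; when supplied, stage-2 is evaluated for stage-1 passers.
#' @return List with `cells` (recordings passing all evaluated stages
#'   and not excluded), `report` (data frame: `cell_id`, `condition`,
#'   `stage1_pass`, `stage2_pass`, `manually_excluded`, `pass`,
#'   `failed_criteria`), and `results` (the `qc_result` objects).
#' @export
apply_qc <- function(cells, thresholds = qc_thresholds(),
                     exclusion_list = character(0), i_max = NULL) {
  if (inherits(cells, "cell_recording")) cells <- list(cells)
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  unknown <- setdiff(exclusion_list, ids)
  if (length(unknown)) {
    warning("exclusion list names unknown cell_id(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  results <- vector("list", length(cells))
  rows <- vector("list", length(cells))
  keep <- logical(length(cells))
  for (i in seq_along(cells)) {
    res <- stage1_qc(cells[[i]], thresholds)
    if (res$stage1_pass && !is.null(i_max) &&
        cells[[i]]$cell_id %in% names(i_max)) {
      res <- stage2_qc(res, i_max[[cells[[i]]$cell_id]], thresholds)
    }
    res$manually_excluded <- cells[[i]]$cell_id %in% exclusion_list
    results[[i]] <- res
    pass <- res$stage1_pass && !isFALSE(res$stage2_pass) &&
      !res$manually_excluded
    keep[i] <- pass
    rows[[i]] <- data.frame(
      cell_id = res$cell_id, condition = cells[[i]]$condition,
      stage1_pass = res$stage1_pass, stage2_pass = res$stage2_pass,
      manually_excluded = res$manually_excluded, pass = pass,
      failed_criteria = format_failures(res$failed_criteria),
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(report)) {
    report <- data.frame(cell_id = character(0), condition = character(0),
                         stage1_pass = logical(0), stage2_pass = logical(0),
                         manually_excluded = logical(0), pass = logical(0),
                         failed_criteria = character(0),
                         stringsAsFactors = FALSE)
  }
  list(cells = cells[keep], report = report, results = results)
}
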