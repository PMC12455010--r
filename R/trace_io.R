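#' Write a cohort to the portable on-disk layout
#'
#' Layout: `manifest.tsv` (one row per cell: `cell_id`, `condition`,
#' `temperature`, `v_offset`, `r_seal`, `r_series`, `c_slow`,
#' `trace_file`) plus `traces/<cell_id>.tsv` in long format with columns
#' `step_potential_mV`, `time_ms`, `current_pA`, and — when any cell
#' carries simulation ground truth — a `ground_truth.tsv` sidecar
#' (`cell_id`, `component`, `weight`, `k`, `lambda`, `tau_m`, `g_max`).
#' Cells are written in sorted `cell_id` order; currents are formatted
#' at 6 significant digits and times at 10, the package's canonical
#' formats, so re-writing a read cohort is byte-identical. Currents
#' supplied in nA are converted to pA on write.
#'
#' @param cells List of `cell_recording` objects.
#' @param out_dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cells, out_dir) {
  if (inherits(cells, "cell_recording")) cells <- list(cells)
  stopifnot(all(vapply(cells, inherits, TRUE, "cell_recording")))
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) {
    stop("duplicate cell_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ok <- dir.create(file.path(out_dir, "traces"), recursive = TRUE,
                   showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "traces"))) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  cells <- cells[order(ids, method = "radix")]
  man_lines <- "cell_id\tcondition\ttemperature\tv_offset\tr_seal\tr_series\tc_slow\ttrace_file"
  gt_lines <- character(0)
  for (cell in cells) {
    trace_rel <- file.path("traces", paste0(cell$cell_id, ".tsv"))
    scale <- if (identical(cell$current_unit, "nA")) 1000 else 1
    steps <- as.numeric(colnames(cell$sweeps))
    nt <- length(cell$times)
    step_col <- rep(steps, each = nt)
    time_col <- rep(cell$times, times = length(steps))
    cur_col <- as.vector(cell$sweeps) * scale
    lines <- c("step_potential_mV\ttime_ms\tcurrent_pA",
               paste(fmt_time(step_col), fmt_time(time_col),
                     fmt_current(cur_col), sep = "\t"))
    con <- file(file.path(out_dir, trace_rel), open = "wb")
    writeLines(lines, con, sep = "\n")
    close(con)
    man_lines <- c(man_lines, paste(
      cell$cell_id, cell$condition, fmt_meta(cell$temperature),
      fmt_meta(cell$v_offset), fmt_meta(cell$r_seal),
      fmt_meta(cell$r_series), fmt_meta(cell$c_slow), trace_rel,
      sep = "\t"))
    if (!is.null(cell$ground_truth)) {
      gt <- cell$ground_truth
      gt_lines <- c(gt_lines, paste(
        cell$cell_id, gt$component, fmt_time(gt$weight), gt$k,
        fmt_time(gt$lambda), fmt_time(gt$tau_m), fmt_time(gt$g_max),
        sep = "\t"))
    }
  }
  man_path <- file.path(out_dir, "manifest.tsv")
  con <- file(man_path, open = "wb")
  writeLines(man_lines, con, sep = "\n")
  close(con)
  if (length(gt_lines)) {
    con <- file(file.path(out_dir, "ground_truth.tsv"), open = "wb")
    writeLines(c("cell_id\tcomponent\tweight\tk\tlambda\ttau_m\tg_max",
                 gt_lines), con, sep = "\n")
    close(con)
  }
  invisible(man_path)
}

read_trace_table <- function(path, cell_id) {
  tab <- utils::read.delim(path, colClasses = "numeric")
  need <- c("step_potential_mV", "time_ms", "current_pA")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("trace file '%s' (cell '%s'): missing column(s) %s",
                 path, cell_id, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  tab
}

#' Read a cohort from the portable on-disk layout
#'
#' Inverse of [write_cohort()]: validates the manifest (unique
#' `cell_id`s, existing trace files), parses each long-format trace
#' table, checks that every sweep shares one uniform time grid, and
#' rebuilds `cell_recording` objects in pA/ms units. A
#' `ground_truth.tsv` sidecar, if present, is re-attached per cell.
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return List of `cell_recording` objects, in manifest order.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  root <- dirname(manifest_path)
  man <- utils::read.delim(manifest_path, colClasses = c(
    cell_id = "character", condition = "character", trace_file = "character"))
  need <- c("cell_id", "condition", "temperature", "v_offset", "r_seal",
            "r_series", "c_slow", "trace_file")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(man$cell_id)) {
    stop("manifest has duplicate cell_id: ",
         paste(unique(man$cell_id[duplicated(man$cell_id)]), collapse = ", "),
         call. = FALSE)
  }
  gt_path <- file.path(root, "ground_truth.tsv")
  gt_all <- if (file.exists(gt_path)) {
    utils::read.delim(gt_path, colClasses = c(cell_id = "character"))
  } else NULL
  cells <- vector("list", nrow(man))
  for (r in seq_len(nrow(man))) {
    trace_path <- file.path(root, man$trace_file[r])
    if (!file.exists(trace_path)) {
      stop(sprintf("trace file for cell '%s' not found: %s",
                   man$cell_id[r], trace_path), call. = FALSE)
    }
    tab <- read_trace_table(trace_path, man$cell_id[r])
    steps <- unique(tab$step_potential_mV)
    times <- tab$time_ms[tab$step_potential_mV == steps[1]]
    if (length(times) > 1) {
      dts <- diff(times)
      if (any(abs(dts - dts[1]) > 1e-9 * max(dts[1], 1))) {
        stop(sprintf("trace file '%s' (cell '%s'): non-uniform time grid",
                     trace_path, man$cell_id[r]), call. = FALSE)
      }
    }
    sweeps <- matrix(NA_real_, nrow = length(times), ncol = length(steps),
                     dimnames = list(NULL, fmt_time(steps)))
    for (j in seq_along(steps)) {
      sel <- tab$step_potential_mV == steps[j]
      if (sum(sel) != length(times) ||
          any(abs(tab$time_ms[sel] - times) > 1e-9)) {
        stop(sprintf(
          "trace file '%s' (cell '%s'): sweeps do not share one time base",
          trace_path, man$cell_id[r]), call. = FALSE)
      }
      sweeps[, j] <- tab$current_pA[sel]
    }
    colnames(sweeps) <- as.character(steps)
    gt <- NULL
    if (!is.null(gt_all)) {
      sub <- gt_all[gt_all$cell_id == man$cell_id[r], , drop = FALSE]
      if (nrow(sub)) {
        gt <- sub[, setdiff(names(sub), "cell_id"), drop = FALSE]
        rownames(gt) <- NULL
      }
    }
    cells[[r]] <- cell_recording(
      cell_id = man$cell_id[r], condition = man$condition[r],
      sweeps = sweeps, times = times, v_offset = man$v_offset[r],
      r_seal = man$r_seal[r], r_series = man$r_series[r],
      c_slow = man$c_slow[r], temperature = man$temperature[r],
      current_unit = "pA", ground_truth = gt)
  }
  cells
}
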