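# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_field(field, "must be a single positive finite number")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_field(field, "must be a single non-negative finite number")
  }
  invisible(x)
}

# Canonical on-disk number formats (see write_cohort): currents at 6
# significant digits, times at 10 (lossless for standard sampling grids).
fmt_current <- function(x) sprintf("%.6g", x)
fmt_time <- function(x) sprintf("%.10g", x)
fmt_meta <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

# Locale-independent ordering for deterministic file layout.
sort_c <- function(x) sort(x, method = "radix")
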