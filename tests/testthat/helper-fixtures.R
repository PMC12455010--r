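# Shared fixtures and independent oracles, built in code at test time.

# Small protocol for I/O and unit tests: 3 steps, 30 ms sweeps.
tiny_protocol <- function() {
  make_protocol(step_potentials = c(-90, 0, 80), pre_step_duration = 5,
                step_duration = 20, post_step_duration = 5,
                sampling_rate = 10)
}

# Single-step protocol at the analysis potential (fast cohort studies).
step80_protocol <- function() {
  make_protocol(step_potentials = 80)
}

# Hand-built recording with prescribed sweeps and QC metadata.
manual_cell <- function(cell_id = "cell_A", condition = "control",
                        v_offset = 10, r_seal = 500, r_series = 8,
                        c_slow = 20, sweeps = NULL, times = NULL,
                        current_unit = "pA") {
  if (is.null(times)) times <- (0:299) / 10
  if (is.null(sweeps)) {
    sweeps <- cbind(`-90` = rep(0, length(times)),
                    `80` = sin(seq(0, pi, length.out = length(times))) * 100)
  }
  cell_recording(cell_id = cell_id, condition = condition, sweeps = sweeps,
                 times = times, v_offset = v_offset, r_seal = r_seal,
                 r_series = r_series, c_slow = c_slow, temperature = 25,
                 current_unit = current_unit)
}

# Idealized normalized trace on the standard analysis window: zero
# until t_rise, instant rise to 1, exponential decay with constant tau.
ideal_norm_trace <- function(tau = 50, t_rise = 100, window = c(70, 599),
                             dt = 0.1) {
  t <- seq(window[1], window[2], by = dt)
  y <- ifelse(t < t_rise, 0, exp(-(t - t_rise) / tau))
  list(time = t, normalized = y, window = window, i_max_nA = 1)
}

# Independent chain-ODE oracle for the Erlang docking survival:
# integrates the k-stage chain with lsoda at tight tolerance.
chain_ode_survival <- function(times, k, lambda) {
  derivs <- function(t, y, parms) {
    dy <- -lambda * y
    if (k > 1) dy[2:k] <- dy[2:k] + lambda * y[1:(k - 1)]
    list(dy)
  }
  sol <- deSolve::lsoda(y = c(1, rep(0, k - 1)), times = times,
                        func = derivs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  rowSums(sol[, -1, drop = FALSE])
}

# Brute-force Tukey boxplot reference, written independently of the
# package: explicit type-7 quantile formula plus a classification loop.
brute_force_box <- function(values) {
  x <- sort(values)
  n <- length(x)
  q_type7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- q_type7(0.25)
  q3 <- q_type7(0.75)
  iqr <- q3 - q1
  out <- logical(n)
  for (i in seq_len(n)) {
    out[i] <- x[i] < q1 - 1.5 * iqr || x[i] > q3 + 1.5 * iqr
  }
  list(q1 = q1, median = q_type7(0.5), q3 = q3,
       outliers = x[out],
       whisker_low = min(x[!out]), whisker_high = max(x[!out]))
}

# Per-cell expected (mixture) docking latency from embedded ground
# truth: sum_i w_i * k_i / lambda_i.
gt_mean_latency <- function(cell) {
  gt <- cell$ground_truth
  sum(gt$weight * gt$k / gt$lambda)
}
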