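#' Build a voltage-step stimulation protocol
#'
#' Describes the standard family of depolarizing steps used to elicit
#' outward K+ currents: the cell is held at a hyperpolarized holding
#' potential, stepped for `step_duration` ms to each test potential in
#' turn, and returned to holding. The default grid is the 18-step
#' protocol from -90 mV to +80 mV in 10 mV increments with 500 ms steps
#' sampled at 10 kHz, the conventional stimulus for fast-inactivating
#' Kv3-family channels.
#'
#' The sweep time base starts at 0 ms (first sample at t = 0) and spans
#' `pre_step_duration + step_duration + post_step_duration` ms. With the
#' 100 ms default pre-step the depolarizing step occupies 100-600 ms, so
#' the standard 70-599 ms analysis window covers the last 30 ms of
#' holding plus the full step.
#'
#' @param step_potentials Test potentials in mV, strictly increasing.
#' @param holding_potential Holding potential in mV.
#' @param pre_step_duration Holding segment before the step, ms.
#' @param step_duration Duration of the depolarizing step, ms.
#' @param post_step_duration Holding segment after the step, ms.
#' @param sampling_rate Sampling rate in kHz (samples per ms).
#' @return An object of class `voltage_protocol`.
#' @examples
#' p <- make_protocol()
#' length(p$step_potentials)  # 18
#' @export
make_protocol <- function(step_potentials = seq(-90, 80, by = 10),
                          holding_potential = -90,
                          pre_step_duration = 100,
                          step_duration = 500,
                          post_step_duration = 0,
                          sampling_rate = 10) {
  if (!is.numeric(step_potentials) || length(step_potentials) < 1L ||
      anyNA(step_potentials)) {
    stop_field("step_potentials", "must be a non-empty numeric vector")
  }
  if (length(step_potentials) > 1L && any(diff(step_potentials) <= 0)) {
    stop_field("step_potentials", "must be strictly increasing")
  }
  check_positive(step_duration, "step_duration")
  check_positive(sampling_rate, "sampling_rate")
  check_nonneg(pre_step_duration, "pre_step_duration")
  check_nonneg(post_step_duration, "post_step_duration")
  total <- pre_step_duration + step_duration + post_step_duration
  n_samples <- as.integer(round(total * sampling_rate))
  structure(
    list(
      step_potentials = as.numeric(step_potentials),
      holding_potential = holding_potential,
      pre_step_duration = pre_step_duration,
      step_duration = step_duration,
      post_step_duration = post_step_duration,
      sampling_rate = sampling_rate,
      total_duration = total,
      n_samples = n_samples
    ),
    class = "voltage_protocol"
  )
}

#' Sample times of a protocol sweep
#'
#' @param protocol A `voltage_protocol`.
#' @return Numeric vector of sample times in ms, starting at 0.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  (seq_len(protocol$n_samples) - 1L) / protocol$sampling_rate
}

#' Command voltage at each sample of one sweep
#'
#' @param protocol A `voltage_protocol`.
#' @param step_potential One of the protocol's step potentials, mV.
#' @return Numeric vector of command voltages (mV) on the sweep time base.
#' @export
protocol_voltage <- function(protocol, step_potential) {
  t <- protocol_times(protocol)
  on_step <- t >= protocol$pre_step_duration &
    t < protocol$pre_step_duration + protocol$step_duration
  v <- rep(protocol$holding_potential, length(t))
  v[on_step] <- step_potential
  v
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "Voltage protocol: %d step(s) %g to %g mV, hold %g mV\n  pre %g ms | step %g ms | post %g ms @ %g kHz (%d samples)\n",
    length(x$step_potentials), min(x$step_potentials), max(x$step_potentials),
    x$holding_potential, x$pre_step_duration, x$step_duration,
    x$post_step_duration, x$sampling_rate, x$n_samples
  ))
  invisible(x)
}
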