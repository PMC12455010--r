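#' Nernst reversal potential for potassium
#'
#' Computes `(R*T/F) * ln(K_out/K_in)` in mV. With the standard automated
#' patch-clamp solutions (4 mM external K+, 110 mM internal K+ from
#' 50 mM KCl + 60 mM K-fluoride) this gives approximately -85 mV at 25
#' degrees C, the package-wide default `E_K`.
#'
#' @param K_out External K+ concentration, mM.
#' @param K_in Internal K+ concentration, mM.
#' @param temperature Temperature in degrees Celsius.
#' @return Reversal potential in mV.
#' @examples
#' nernst_reversal(4, 110, 25)
#' @export
nernst_reversal <- function(K_out, K_in, temperature = 25) {
  check_positive(K_out, "K_out")
  check_positive(K_in, "K_in")
  R <- 8.314462618   # J / (mol K)
  F <- 96485.33212   # C / mol
  T_kelvin <- temperature + 273.15
  1000 * (R * T_kelvin / F) * log(K_out / K_in)
}

#' Gating model for one channel sub-population (glycoform)
#'
#' Macroscopic open probability is modelled as a Hodgkin-Huxley
#' activation gate raised to an integer power, `m(t)^p`, multiplied by an
#' inactivation survival gate `h(t)`. Activation follows first-order
#' kinetics towards the Boltzmann steady state
#' `m_inf(V) = 1/(1 + exp(-(V - v_half)/slope))` with time constant
#' `tau_m`. Inactivation models the N-terminal "ball-and-chain" block as
#' a `k`-stage docking chain with per-stage rate `lambda` (1/ms), so the
#' docking latency is Erlang(`k`, `lambda`)-distributed with mean
#' `k/lambda` and coefficient of variation `1/sqrt(k)`; a fraction
#' `f_ss` of the current never inactivates. Distinct glycoforms of the
#' same channel are represented by distinct (`k`, `lambda`) pairs.
#'
#' @param g_max Maximal conductance, nS.
#' @param p Integer activation exponent (>= 1).
#' @param v_half Activation midpoint, mV.
#' @param slope Activation slope factor, mV (> 0).
#' @param tau_m Activation time constant, ms.
#' @param k Integer inactivation chain length (>= 1).
#' @param lambda Per-stage chain rate, 1/ms.
#' @param f_ss Non-inactivating steady-state fraction in `[0, 1]`.
#' @param E_K Potassium reversal potential, mV.
#' @return An object of class `gating_model`.
#' @export
gating_model <- function(g_max = 40, p = 4, v_half = 0, slope = 9,
                         tau_m = 2, k = 1, lambda = 0.1, f_ss = 0,
                         E_K = nernst_reversal(4, 110, 25)) {
  check_nonneg(g_max, "g_max")
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    stop_field("p", "must be a positive integer")
  }
  check_positive(slope, "slope")
  check_positive(tau_m, "tau_m")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop_field("k", "must be an integer >= 1")
  }
  check_positive(lambda, "lambda")
  if (!is.numeric(f_ss) || length(f_ss) != 1L || f_ss < 0 || f_ss > 1) {
    stop_field("f_ss", "must lie in [0, 1]")
  }
  structure(
    list(g_max = g_max, p = as.integer(p), v_half = v_half, slope = slope,
         tau_m = tau_m, k = as.integer(k), lambda = lambda, f_ss = f_ss,
         E_K = E_K),
    class = "gating_model"
  )
}

#' Steady-state activation
#'
#' @param model A `gating_model`.
#' @param V Membrane potential, mV (vectorised).
#' @return `m_inf(V)` in (0, 1).
#' @export
m_inf <- function(model, V) {
  1 / (1 + exp(-(V - model$v_half) / model$slope))
}

#' Erlang-chain inactivation survival
#'
#' Fraction of channels not yet inactivated at time `t` after engaging
#' the docking chain:
#' `h(t) = f_ss + (1 - f_ss) * exp(-lambda t) * sum_{j=0}^{k-1} (lambda t)^j / j!`.
#' The sum is the upper tail of an Erlang(`k`, `lambda`) distribution and
#' is evaluated through the gamma survival function. `h` is monotone
#' non-increasing with `h(0) = 1` and limit `f_ss`.
#'
#' @param t Time since chain onset, ms (vectorised, `t >= 0`).
#' @param k Integer chain length >= 1.
#' @param lambda Per-stage rate, 1/ms.
#' @param f_ss Non-inactivating fraction in `[0, 1]`.
#' @return Survival fraction in `[f_ss, 1]`.
#' @examples
#' inactivation_survival(50, k = 4, lambda = 0.05)
#' @export
inactivation_survival <- function(t, k, lambda, f_ss = 0) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop_field("t", "must be non-negative")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop_field("k", "must be an integer >= 1")
  }
  check_positive(lambda, "lambda")
  if (!is.numeric(f_ss) || length(f_ss) != 1L || f_ss < 0 || f_ss > 1) {
    stop_field("f_ss", "must lie in [0, 1]")
  }
  f_ss + (1 - f_ss) * stats::pgamma(t, shape = k, rate = lambda,
                                    lower.tail = FALSE)
}

#' Open probability time course at constant voltage
#'
#' Returns `P_open(t) = m(t)^p * h(t)` on a uniform grid, with
#' `m` relaxing exponentially from `m0` towards `m_inf(V)` and `h` the
#' Erlang-chain survival started at `t = 0`. Two routes are provided:
#' the default `"analytic"` path uses the exact constant-voltage
#' solutions; the `"ode"` path integrates the activation gate and the
#' `k + 1`-state docking chain with `deSolve::lsoda` and exists both for
#' cross-validation and as the extension point for time-varying rates.
#'
#' A grid step larger than `tau_m / 2` or `1 / (2 lambda)` under-resolves
#' the gating transients; depending on `on_coarse_grid` this raises a
#' warning (default), an error, or is ignored.
#'
#' @param model A `gating_model`.
#' @param V Step potential, mV.
#' @param duration Simulated duration, ms.
#' @param dt Output grid step, ms.
#' @param m0 Initial activation in `[0, 1]` (default 0: fully
#'   deactivated, as after a long hyperpolarized holding period).
#' @param method `"analytic"` or `"ode"`.
#' @param on_coarse_grid `"warn"`, `"error"` or `"ignore"`.
#' @return Numeric vector of open probabilities at
#'   `t = seq(0, duration, by = dt)`, with the time grid as attribute
#'   `"time"`.
#' @export
simulate_open_probability <- function(model, V, duration, dt = 0.1, m0 = 0,
                                      method = c("analytic", "ode"),
                                      on_coarse_grid = c("warn", "error",
                                                         "ignore")) {
  stopifnot(inherits(model, "gating_model"))
  method <- match.arg(method)
  on_coarse_grid <- match.arg(on_coarse_grid)
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  if (dt > duration) stop_field("dt", "must not exceed duration")
  if (m0 < 0 || m0 > 1) stop_field("m0", "must lie in [0, 1]")
  if (dt > model$tau_m / 2 || dt > 1 / (2 * model$lambda)) {
    msg <- sprintf(
      "grid step dt = %g ms under-resolves gating (tau_m = %g ms, 1/lambda = %g ms)",
      dt, model$tau_m, 1 / model$lambda)
    if (on_coarse_grid == "error") stop(msg, call. = FALSE)
    if (on_coarse_grid == "warn") warning(msg, call. = FALSE)
  }
  t <- seq(0, duration, by = dt)
  if (method == "analytic") {
    minf <- m_inf(model, V)
    m <- minf + (m0 - minf) * exp(-t / model$tau_m)
    h <- inactivation_survival(t, model$k, model$lambda, model$f_ss)
    p_open <- m^model$p * h
  } else {
    p_open <- open_probability_ode(model, V, t, m0)
  }
  p_open <- pmin(pmax(p_open, 0), 1)
  attr(p_open, "time") <- t
  p_open
}

# ODE route: activation gate plus k+1-state docking chain
# (s_0 ... s_{k-1} undocked stages, absorbing docked state).
open_probability_ode <- function(model, V, times, m0) {
  k <- model$k
  minf <- m_inf(model, V)
  derivs <- function(t, y, parms) {
    m <- y[1L]
    s <- y[-1L]
    dm <- (minf - m) / model$tau_m
    ds <- -model$lambda * s
    if (k > 1L) ds[2:k] <- ds[2:k] + model$lambda * s[1:(k - 1L)]
    list(c(dm, ds))
  }
  y0 <- c(m0, 1, rep(0, k - 1L))
  sol <- deSolve::lsoda(y = y0, times = times, func = derivs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  m <- sol[, 2L]
  surv <- rowSums(sol[, 2L + seq_len(k), drop = FALSE])
  h <- model$f_ss + (1 - model$f_ss) * surv
  m^model$p * h
}
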