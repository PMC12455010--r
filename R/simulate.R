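#' Glycoform mixture
#'
#' A whole-cell current is modelled as a weighted sum of channel
#' sub-populations ("glycoforms"), each with its own gating model. The
#' weights are the fractional conductance contributed by each
#' sub-population and must sum to 1.
#'
#' @param models List of [gating_model()] objects.
#' @param weights Numeric weights, non-negative, summing to 1 (within
#'   1e-9).
#' @return An object of class `glycoform_mixture`.
#' @export
glycoform_mixture <- function(models, weights) {
  if (inherits(models, "gating_model")) models <- list(models)
  if (!length(models) || !all(vapply(models, inherits, TRUE, "gating_model"))) {
    stop_field("models", "must be a non-empty list of gating_model objects")
  }
  if (length(weights) != length(models)) {
    stop_field("weights", "must match the number of models")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_field("weights", "must be non-negative and sum to 1 within 1e-9")
  }
  structure(list(models = models, weights = as.numeric(weights)),
            class = "glycoform_mixture")
}

#' Baseline-noise and leak model
#'
#' @param baseline_sd Gaussian baseline noise SD, pA.
#' @param leak_conductance Ohmic leak conductance, nS.
#' @param leak_reversal Leak reversal potential, mV.
#' @param rng_seed Optional default seed used when a simulation call does
#'   not supply one.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_sd = 5, leak_conductance = 0.5,
                        leak_reversal = 0, rng_seed = NULL) {
  check_nonneg(baseline_sd, "baseline_sd")
  check_nonneg(leak_conductance, "leak_conductance")
  structure(list(baseline_sd = baseline_sd,
                 leak_conductance = leak_conductance,
                 leak_reversal = leak_reversal,
                 rng_seed = rng_seed),
            class = "noise_model")
}

# Glycoform component library used by the built-in presets. Mean docking
# latency is k/lambda; CV is 1/sqrt(k). The aglycosylated channel
# inactivates fast with an almost memoryless latency; high-mannose and
# complex glycoforms add progressively longer, sharper delays.
kv34_glycoform_table <- function() {
  data.frame(
    glycoform = c("aglyco", "high_mannose", "complex"),
    k = c(1L, 4L, 12L),
    lambda = c(0.12, 0.05, 0.04),  # mean delays ~8, 80, 300 ms
    stringsAsFactors = FALSE
  )
}

make_component <- function(k, lambda, g_max, tau_m = 2, f_ss = 0) {
  gating_model(g_max = g_max, p = 4, v_half = 0, slope = 9, tau_m = tau_m,
               k = k, lambda = lambda, f_ss = f_ss)
}

#' Per-cell mixture samplers (cohort presets)
#'
#' Each factory returns a closure that, when called, draws one cell's
#' `glycoform_mixture` from the RNG in effect. The `"control"` preset
#' draws Dirichlet(1,1,1) weights over the aglyco / high-mannose /
#' complex component library, reproducing the broad cell-to-cell spread
#' of inactivation delays seen when all glycoforms coexist. The
#' `"deglyco"` preset (tunicamycin-like: glycosylation blocked) is a
#' single fast aglyco component, collapsing the spread. The
#' `"delay_sd"` preset gives every cell a single Erlang component whose
#' mean docking latency is drawn from a truncated normal with chosen SD
#' — the knob used for heterogeneity-recovery studies. Per-cell maximal
#' conductance is log-normal for all presets, keeping peak currents in
#' the accepted 0.5-45 nA range.
#'
#' @param g_max_meanlog,g_max_sdlog Log-normal parameters of the
#'   per-cell total conductance, nS scale.
#' @param alpha Dirichlet concentration for the control weights.
#' @param mean_delay,delay_sd,min_delay Mean, SD and lower truncation of
#'   the per-cell mean docking latency, ms (`"delay_sd"` preset).
#' @param k Chain length of the `"delay_sd"` preset component.
#' @param lambda_sdlog Log-normal SD of a mild per-cell jitter on the
#'   chain rates (control/deglyco presets), modelling biological
#'   cell-to-cell kinetic variability within a glycoform.
#' @return A function of no arguments returning a `glycoform_mixture`.
#' @name mixture_samplers
NULL

#' @rdname mixture_samplers
#' @export
sampler_control <- function(g_max_meanlog = log(40), g_max_sdlog = 0.35,
                            alpha = c(1, 1, 1), lambda_sdlog = 0.1) {
  tab <- kv34_glycoform_table()
  stopifnot(length(alpha) == nrow(tab))
  function() {
    w <- stats::rgamma(length(alpha), shape = alpha)
    w <- w / sum(w)
    g <- signif(stats::rlnorm(1, g_max_meanlog, g_max_sdlog), 6)
    models <- lapply(seq_len(nrow(tab)), function(i) {
      lam <- signif(tab$lambda[i] * stats::rlnorm(1, 0, lambda_sdlog), 6)
      make_component(tab$k[i], lam, g_max = g)
    })
    glycoform_mixture(models, w)
  }
}

#' @rdname mixture_samplers
#' @export
sampler_deglyco <- function(g_max_meanlog = log(40), g_max_sdlog = 0.35,
                            lambda_sdlog = 0.1) {
  tab <- kv34_glycoform_table()
  function() {
    g <- signif(stats::rlnorm(1, g_max_meanlog, g_max_sdlog), 6)
    lam <- signif(tab$lambda[1] * stats::rlnorm(1, 0, lambda_sdlog), 6)
    glycoform_mixture(list(make_component(tab$k[1], lam, g_max = g)), 1)
  }
}

#' @rdname mixture_samplers
#' @export
sampler_delay_sd <- function(mean_delay = 150, delay_sd = 0, k = 6,
                             min_delay = 10, g_max_meanlog = log(40),
                             g_max_sdlog = 0.35) {
  function() {
    mu <- max(min_delay, stats::rnorm(1, mean_delay, delay_sd))
    g <- signif(stats::rlnorm(1, g_max_meanlog, g_max_sdlog), 6)
    glycoform_mixture(list(make_component(as.integer(k),
                                          signif(k / mu, 6), g_max = g)), 1)
  }
}

resolve_sampler <- function(preset, params = list()) {
  switch(preset,
         control = do.call(sampler_control, params),
         deglyco = do.call(sampler_deglyco, params),
         delay_sd = do.call(sampler_delay_sd, params),
         stop_field("preset", sprintf("unknown preset '%s'", preset)))
}

#' Condition specification for cohort simulation
#'
#' @param label Condition label (e.g. `"control"`, `"tunicamycin"`).
#' @param n_cells Number of cells to simulate (>= 1).
#' @param preset One of `"control"`, `"deglyco"`, `"delay_sd"`, or
#'   `"custom"` (then supply `sampler`).
#' @param params Parameter list passed to the preset factory.
#' @param sampler Custom per-cell mixture sampler (function of no
#'   arguments), used when `preset = "custom"`.
#' @param qc_fail_fraction Fraction of cells planted to fail stage-1 QC.
#' @return An object of class `cohort_condition`.
#' @export
cohort_condition <- function(label, n_cells, preset = "control",
                             params = list(), sampler = NULL,
                             qc_fail_fraction = 0) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_field("label", "must be a non-empty string")
  }
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells)) {
    stop_field("n_cells", "must be an integer >= 1")
  }
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1) {
    stop_field("qc_fail_fraction", "must lie in [0, 1]")
  }
  if (is.null(sampler)) {
    if (identical(preset, "custom")) {
      stop_field("sampler", "must be supplied when preset = 'custom'")
    }
    sampler <- resolve_sampler(preset, params)
  } else {
    preset <- "custom"
  }
  structure(list(label = label, n_cells = as.integer(n_cells),
                 preset = preset, params = params, sampler = sampler,
                 qc_fail_fraction = qc_fail_fraction),
            class = "cohort_condition")
}

#' Default QC-metadata sampling specification
#'
#' Ranges from which per-cell recording-quality metadata are drawn
#' uniformly. `pass` ranges sit safely inside the stage-1 acceptance
#' thresholds (|V-offset| < 45 mV, R-seal > 200 MOhm, R-series < 15
#' MOhm, C-slow < 35 pF); `fail` ranges sit outside them and are used
#' for cells planted to fail a (randomly chosen) criterion.
#'
#' @param temperature Recording temperature metadata, degrees C.
#' @return A list with elements `pass`, `fail`, `temperature`.
#' @export
default_qc_spec <- function(temperature = 25) {
  list(
    pass = list(v_offset = c(-20, 20), r_seal = c(500, 2000),
                r_series = c(4, 12), c_slow = c(10, 30)),
    fail = list(v_offset = c(50, 80), r_seal = c(20, 150),
                r_series = c(20, 40), c_slow = c(40, 60)),
    temperature = temperature
  )
}

draw_qc_metadata <- function(qc_spec, fail_criterion = NULL) {
  vals <- lapply(qc_spec$pass, function(r) signif(stats::runif(1, r[1], r[2]), 6))
  if (!is.null(fail_criterion)) {
    r <- qc_spec$fail[[fail_criterion]]
    vals[[fail_criterion]] <- signif(stats::runif(1, r[1], r[2]), 6)
  }
  vals$temperature <- qc_spec$temperature
  vals
}

#' Construct a cell recording
#'
#' Container for one cell's sweep family plus recording-quality
#' metadata. Sweeps are stored as a samples-by-steps matrix with one
#' column per step potential, on a shared time base in ms.
#'
#' @param cell_id Unique cell identifier.
#' @param condition Condition label.
#' @param sweeps Numeric matrix (samples x steps), columns named by step
#'   potential in mV; currents in `current_unit`.
#' @param times Sample times, ms.
#' @param v_offset,r_seal,r_series,c_slow,temperature QC metadata
#'   (mV, MOhm, MOhm, pF, degrees C); `NA` if unrecorded.
#' @param current_unit `"pA"` (canonical) or `"nA"`.
#' @param ground_truth Optional per-component data frame (simulation
#'   ground truth).
#' @param protocol Optional `voltage_protocol` the sweeps follow.
#' @return An object of class `cell_recording`.
#' @export
cell_recording <- function(cell_id, condition, sweeps, times,
                           v_offset = NA_real_, r_seal = NA_real_,
                           r_series = NA_real_, c_slow = NA_real_,
                           temperature = NA_real_, current_unit = "pA",
                           ground_truth = NULL, protocol = NULL) {
  if (!is.matrix(sweeps) || is.null(colnames(sweeps))) {
    stop_field("sweeps", "must be a matrix with step-potential column names")
  }
  if (nrow(sweeps) != length(times)) {
    stop_field("times", "must match the sweep sample count")
  }
  current_unit <- match.arg(current_unit, c("pA", "nA"))
  structure(
    list(cell_id = cell_id, condition = condition, sweeps = sweeps,
         times = times, v_offset = v_offset, r_seal = r_seal,
         r_series = r_series, c_slow = c_slow, temperature = temperature,
         current_unit = current_unit, ground_truth = ground_truth,
         protocol = protocol),
    class = "cell_recording"
  )
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf(
    "Cell recording '%s' (%s): %d sweeps x %d samples [%s]\n",
    x$cell_id, x$condition, ncol(x$sweeps), nrow(x$sweeps), x$current_unit))
  invisible(x)
}

mixture_ground_truth <- function(mixture) {
  data.frame(
    component = seq_along(mixture$models),
    weight = mixture$weights,
    k = vapply(mixture$models, `[[`, integer(1), "k"),
    lambda = vapply(mixture$models, `[[`, numeric(1), "lambda"),
    tau_m = vapply(mixture$models, `[[`, numeric(1), "tau_m"),
    g_max = vapply(mixture$models, `[[`, numeric(1), "g_max")
  )
}

# Deterministic current for one component over a full sweep: steady
# state at holding during the pre-step, exact exponential activation and
# Erlang-survival inactivation during the step (chain engages at step
# onset — ball docking requires depolarization-driven opening), and
# exponential deactivation with the docking state frozen after the step
# (recovery between sweeps is treated as complete).
component_sweep_current <- function(model, protocol, step_potential, times) {
  pre <- protocol$pre_step_duration
  stepdur <- protocol$step_duration
  vh <- protocol$holding_potential
  m_hold <- m_inf(model, vh)
  I <- numeric(length(times))
  seg_pre <- times < pre
  seg_step <- times >= pre & times < pre + stepdur
  seg_post <- times >= pre + stepdur
  drive_h <- vh - model$E_K
  I[seg_pre] <- model$g_max * m_hold^model$p * drive_h
  trel <- times[seg_step] - pre
  minf_s <- m_inf(model, step_potential)
  m <- minf_s + (m_hold - minf_s) * exp(-trel / model$tau_m)
  h <- inactivation_survival(trel, model$k, model$lambda, model$f_ss)
  I[seg_step] <- model$g_max * m^model$p * h * (step_potential - model$E_K)
  if (any(seg_post)) {
    m_end <- minf_s + (m_hold - minf_s) * exp(-stepdur / model$tau_m)
    h_end <- inactivation_survival(stepdur, model$k, model$lambda, model$f_ss)
    trel2 <- times[seg_post] - pre - stepdur
    m_post <- m_hold + (m_end - m_hold) * exp(-trel2 / model$tau_m)
    I[seg_post] <- model$g_max * m_post^model$p * h_end * drive_h
  }
  I
}

#' Simulate one cell's voltage-clamp recording
#'
#' Produces the full sweep family for `protocol`: for each step
#' potential the channel current is the weight-summed contribution of
#' the mixture components, `g_max * P_open(t) * (V - E_K)`, plus ohmic
#' leak and Gaussian baseline noise. Currents are emitted in pA and
#' canonicalised to 6 significant digits, the resolution of the
#' portable on-disk format, so written cohorts round-trip bit-exactly.
#'
#' @param mixture A `glycoform_mixture`.
#' @param protocol A `voltage_protocol`.
#' @param noise A `noise_model`.
#' @param qc_spec QC-metadata sampling spec, see [default_qc_spec()].
#' @param seed Integer seed; identical seeds give bit-identical cells.
#' @param cell_id,condition Identifiers stored in the recording.
#' @param qc_values Optional pre-drawn QC metadata (list), bypassing
#'   `qc_spec`.
#' @param fail_criterion Optional name of a stage-1 criterion this cell
#'   is planted to fail (`"v_offset"`, `"r_seal"`, `"r_series"`,
#'   `"c_slow"`).
#' @return A `cell_recording` with ground truth embedded.
#' @export
simulate_cell <- function(mixture, protocol, noise = noise_model(),
                          qc_spec = default_qc_spec(), seed = NULL,
                          cell_id = "cell_001", condition = "control",
                          qc_values = NULL, fail_criterion = NULL) {
  stopifnot(inherits(mixture, "glycoform_mixture"),
            inherits(protocol, "voltage_protocol"),
            inherits(noise, "noise_model"))
  if (is.null(seed)) seed <- noise$rng_seed
  if (is.null(seed)) stop_field("seed", "must be supplied")
  times <- protocol_times(protocol)
  n <- length(times)
  steps <- protocol$step_potentials
  clean <- matrix(0, nrow = n, ncol = length(steps),
                  dimnames = list(NULL, as.character(steps)))
  for (j in seq_along(steps)) {
    I <- numeric(n)
    for (i in seq_along(mixture$models)) {
      I <- I + mixture$weights[i] *
        component_sweep_current(mixture$models[[i]], protocol, steps[j], times)
    }
    v_cmd <- protocol_voltage(protocol, steps[j])
    clean[, j] <- I + noise$leak_conductance * (v_cmd - noise$leak_reversal)
  }
  with_seed(seed, {
    if (is.null(qc_values)) qc_values <- draw_qc_metadata(qc_spec, fail_criterion)
    noisy <- clean
    if (noise$baseline_sd > 0) {
      noisy <- noisy + matrix(stats::rnorm(length(clean), 0, noise$baseline_sd),
                              nrow = n)
    }
  })
  noisy <- signif(noisy, 6)
  gt <- mixture_ground_truth(mixture)
  gt$planted_qc_fail <- if (is.null(fail_criterion)) "" else fail_criterion
  cell_recording(cell_id = cell_id, condition = condition, sweeps = noisy,
                 times = times, v_offset = qc_values$v_offset,
                 r_seal = qc_values$r_seal, r_series = qc_values$r_series,
                 c_slow = qc_values$c_slow,
                 temperature = qc_values$temperature,
                 ground_truth = gt, protocol = protocol)
}

#' Simulate a multi-condition cohort
#'
#' Simulates `n_cells` recordings per condition with full ground truth.
#' Determinism contract: the cell with global index `i` (1-based, in
#' condition order) draws its ground-truth parameters and QC metadata
#' under seed `param_seed + i` and its baseline noise under seed
#' `seed + i`. Holding `param_seed` fixed while varying `seed` therefore
#' yields identical ground truth with fresh noise realisations. Cells
#' planted to fail stage-1 QC (per `qc_fail_fraction`) are chosen by a
#' seeded draw within each condition; each failing cell violates one
#' randomly chosen criterion.
#'
#' @param conditions List of [cohort_condition()] objects (a single one
#'   is accepted).
#' @param protocol A `voltage_protocol`.
#' @param noise A `noise_model`.
#' @param seed Integer master seed for noise.
#' @param param_seed Integer master seed for ground-truth parameters and
#'   QC metadata; defaults to `seed`.
#' @param qc_spec QC-metadata sampling spec.
#' @return List of `cell_recording` objects.
#' @export
simulate_cohort <- function(conditions, protocol = make_protocol(),
                            noise = noise_model(), seed = 1,
                            param_seed = seed,
                            qc_spec = default_qc_spec()) {
  if (inherits(conditions, "cohort_condition")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1,
            all(vapply(conditions, inherits, TRUE, "cohort_condition")))
  cells <- list()
  idx <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    n_fail <- round(cond$qc_fail_fraction * cond$n_cells)
    fail_set <- if (n_fail > 0) {
      with_seed(param_seed + 900000L + ci,
                sample(cond$n_cells, n_fail))
    } else integer(0)
    for (i in seq_len(cond$n_cells)) {
      idx <- idx + 1L
      planted <- i %in% fail_set
      drawn <- with_seed(param_seed + idx, {
        mix <- cond$sampler()
        crit <- if (planted) sample(names(qc_spec$fail), 1) else NULL
        qc <- draw_qc_metadata(qc_spec, crit)
        list(mix = mix, crit = crit, qc = qc)
      })
      cid <- sprintf("%s_%03d", gsub("[^A-Za-z0-9._-]", "_", cond$label), i)
      cells[[idx]] <- simulate_cell(
        mixture = drawn$mix, protocol = protocol, noise = noise,
        seed = seed + idx, cell_id = cid, condition = cond$label,
        qc_values = drawn$qc, fail_criterion = drawn$crit)
    }
  }
  cells
}
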