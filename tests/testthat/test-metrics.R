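test_that("target-sweep extraction finds the requested step or errors helpfully", {
  cell <- manual_cell()
  sw <- extract_target_sweep(cell, 80)
  expect_equal(sw$current, unname(cell$sweeps[, "80"]))
  # holding-level sweep returned unchanged
  sw2 <- extract_target_sweep(cell, -90)
  expect_equal(sw2$current, unname(cell$sweeps[, "-90"]))
  # absent potential lists the available steps
  expect_error(extract_target_sweep(cell, 75), "-90, 80")
  # nA recordings are scaled to pA on extraction
  cellnA <- manual_cell(current_unit = "nA")
  expect_equal(extract_target_sweep(cellnA, 80)$current,
               unname(cellnA$sweeps[, "80"]) * 1000)
})

test_that("normalization is confined to the window and scale-invariant", {
  t <- (0:5999) / 10
  y <- 100 * exp(-abs(t - 300) / 80)  # peak 100 pA at 300 ms
  sweep <- list(time = t, current = y)
  norm <- normalize_trace(sweep)
  expect_equal(max(norm$normalized), 1)
  expect_equal(range(norm$time), c(70, 599))
  expect_equal(norm$i_max_nA, 0.1)
  # scaling by 3 leaves the normalized trace unchanged, scales i_max
  norm3 <- normalize_trace(list(time = t, current = 3 * y))
  expect_equal(norm3$normalized, norm$normalized)
  expect_equal(norm3$i_max_nA, 0.3)
  # constant positive sweep normalizes to 1 everywhere
  const <- normalize_trace(list(time = t, current = rep(5, length(t))))
  expect_true(all(const$normalized == 1))
  # all-negative sweep is unanalysable
  expect_error(normalize_trace(list(time = t, current = -y)),
               "unanalysable")
  # window outside the sweep errors
  expect_error(normalize_trace(sweep, window = c(70, 7000)), "window")
})

test_that("width of an instant-rise exponential decay matches tau*ln(1/level)", {
  norm <- ideal_norm_trace(tau = 50, t_rise = 100)
  m <- inac_width(norm, level = 0.7)
  expect_lt(abs(m$inac_width - 50 * log(1 / 0.7)), 0.2)
  expect_lt(abs(m$t_up - 100), 0.15)
  expect_false(m$censored)
  # closed form at another level: lowering the level widens the cut
  m5 <- inac_width(norm, level = 0.5)
  expect_lt(abs(m5$inac_width - 50 * log(1 / 0.5)), 0.2)
  expect_gt(m5$inac_width, m$inac_width)
})

test_that("non-inactivating traces are censored at the window end", {
  t <- seq(70, 599, by = 0.1)
  y <- ifelse(t < 150, 0, 1)
  m <- inac_width(list(time = t, normalized = y, window = c(70, 599)))
  expect_true(m$censored)
  expect_equal(m$inac_width, 599 - m$t_up, tolerance = 1e-9)
  # a trace already above level at window start: t_up = window start
  m2 <- inac_width(list(time = t, normalized = rep(1, length(t)),
                        window = c(70, 599)))
  expect_equal(m2$t_up, 70)
  expect_true(m2$censored)
})

test_that("width is equivariant under time translation", {
  a <- inac_width(ideal_norm_trace(tau = 40, t_rise = 120))
  b <- inac_width(ideal_norm_trace(tau = 40, t_rise = 150))
  expect_equal(b$inac_width, a$inac_width, tolerance = 1e-6)
  expect_equal(b$t_up - a$t_up, 30, tolerance = 1e-6)
})

test_that("traces never reaching the level raise the documented error", {
  t <- seq(70, 599, by = 0.1)
  expect_error(
    inac_width(list(time = t, normalized = rep(0.5, length(t)))),
    "no peak above level")
  expect_error(inac_width(ideal_norm_trace(), level = 1.2), "level")
})

test_that("noisy multi-crossing traces use first-up/last-down semantics", {
  t <- seq(70, 599, by = 0.1)
  y <- ifelse(t < 100, 0, exp(-(t - 100) / 50))
  set.seed(7)
  y_noisy <- pmin(y + rnorm(length(y), 0, 0.01), 1)
  m <- inac_width(list(time = t, normalized = y_noisy, window = c(70, 599)))
  clean <- inac_width(list(time = t, normalized = y, window = c(70, 599)))
  expect_lt(abs(m$inac_width - clean$inac_width), 2)
  expect_gte(m$n_level_crossings, 2)
})

test_that("measured width matches the analytic open-probability width", {
  # noise-free single-component cells: geometric width on the simulated
  # trace agrees with the width computed on the analytic P_open curve
  p <- make_protocol()
  for (kk in c(2L, 6L)) {
    model <- gating_model(g_max = 40, k = kk, lambda = kk / 150)
    cell <- simulate_cell(glycoform_mixture(model, 1), p,
                          noise_model(baseline_sd = 0,
                                      leak_conductance = 0), seed = 1)
    meas <- inac_width(normalize_trace(extract_target_sweep(cell, 80)))
    # analytic oracle on a dense grid, shifted to sweep-relative time
    po <- simulate_open_probability(model, 80, duration = 500, dt = 0.01)
    tt <- attr(po, "time") + p$pre_step_duration
    keep <- tt >= 70 & tt <= 599
    oracle <- inac_width(list(time = tt[keep],
                              normalized = as.numeric(po)[keep] /
                                max(po[keep]),
                              window = c(70, 599)))
    expect_lt(abs(meas$inac_width - oracle$inac_width), 0.2)
  }
})

test_that("peak current matches the forward model and width grows with delay", {
  p <- make_protocol()
  leak <- 0.5
  model <- gating_model(g_max = 40, k = 4, lambda = 0.05)
  cell <- simulate_cell(glycoform_mixture(model, 1), p,
                        noise_model(baseline_sd = 0,
                                    leak_conductance = leak), seed = 1)
  norm <- normalize_trace(extract_target_sweep(cell, 80))
  po <- simulate_open_probability(model, 80, duration = 500, dt = 0.1)
  expected_pA <- model$g_max * max(po) * (80 - model$E_K) + leak * 80
  expect_equal(norm$i_max_pA, expected_pA, tolerance = 1e-3)
  # width monotone non-decreasing in the Erlang mean delay k/lambda
  widths <- sapply(c(30, 80, 160, 320), function(delay) {
    m <- gating_model(g_max = 40, k = 4, lambda = 4 / delay)
    cl <- simulate_cell(glycoform_mixture(m, 1), p,
                        noise_model(baseline_sd = 0, leak_conductance = 0),
                        seed = 1)
    inac_width(normalize_trace(extract_target_sweep(cl, 80)))$inac_width
  })
  expect_true(all(diff(widths) > 0))
})

test_that("cohort measurement reports unanalysable cells instead of dropping them", {
  cells <- simulate_cohort(cohort_condition("control", 3, "control"),
                           seed = 6)
  # sabotage one cell: all-negative target sweep
  cells[[2]]$sweeps[, "80"] <- -abs(cells[[2]]$sweeps[, "80"])
  meas <- measure_cohort(cells)
  expect_equal(nrow(meas), 3)
  expect_equal(sum(meas$analysable), 2)
  expect_match(meas$note[!meas$analysable], "unanalysable")
  ov <- attr(meas, "overlay")
  expect_equal(ncol(ov), 2)
  expect_equal(nrow(ov), length(attr(meas, "overlay_time")))
})
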