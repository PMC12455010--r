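test_that("mixture and noise model validation", {
  m1 <- gating_model(k = 1, lambda = 0.1)
  m2 <- gating_model(k = 8, lambda = 0.04)
  expect_s3_class(glycoform_mixture(list(m1, m2), c(0.3, 0.7)),
                  "glycoform_mixture")
  expect_error(glycoform_mixture(list(m1, m2), c(0.3, 0.6)), "weights")
  expect_error(glycoform_mixture(list(m1, m2), c(-0.1, 1.1)), "weights")
  expect_error(glycoform_mixture(list(), numeric(0)), "models")
  expect_error(noise_model(baseline_sd = -1), "baseline_sd")
})

test_that("fixed seed gives bit-identical cells; different seeds differ", {
  mix <- glycoform_mixture(gating_model(g_max = 40, k = 4, lambda = 0.05), 1)
  p <- tiny_protocol()
  a <- simulate_cell(mix, p, noise_model(), seed = 11)
  b <- simulate_cell(mix, p, noise_model(), seed = 11)
  expect_identical(a, b)
  c <- simulate_cell(mix, p, noise_model(), seed = 12)
  expect_false(identical(a$sweeps, c$sweeps))
})

test_that("null model: zero conductance, zero leak, zero noise gives zero sweeps", {
  mix <- glycoform_mixture(gating_model(g_max = 0, k = 2, lambda = 0.05), 1)
  cell <- simulate_cell(mix, tiny_protocol(),
                        noise_model(baseline_sd = 0, leak_conductance = 0),
                        seed = 1)
  expect_true(all(cell$sweeps == 0))
})

test_that("zero driving force: stepping to E_K elicits no channel current", {
  ek <- nernst_reversal(4, 110, 25)
  model <- gating_model(g_max = 40, k = 2, lambda = 0.05, E_K = ek)
  p <- make_protocol(step_potentials = c(-90, ek, 80),
                     pre_step_duration = 5, step_duration = 20,
                     post_step_duration = 0)
  cell <- simulate_cell(glycoform_mixture(model, 1), p,
                        noise_model(baseline_sd = 0, leak_conductance = 0),
                        seed = 1)
  t <- cell$times
  on_step <- t >= 5 & t < 25
  expect_true(all(abs(cell$sweeps[on_step, 2]) < 1e-9))
})

test_that("cohorts have requested sizes, labels and passing QC by construction", {
  cells <- simulate_cohort(
    cohort_condition("control", 29, "control"),
    protocol = tiny_protocol(), seed = 3)
  expect_length(cells, 29)
  expect_true(all(vapply(cells, `[[`, character(1), "condition") == "control"))
  expect_length(unique(vapply(cells, `[[`, character(1), "cell_id")), 29)
  # qc_fail_fraction = 0: every cell passes stage-1 thresholds
  s1 <- vapply(cells, function(cl) stage1_qc(cl)$stage1_pass, logical(1))
  expect_true(all(s1))
})

test_that("parameter sub-seed fixes ground truth while the noise seed varies", {
  cond <- cohort_condition("control", 5, "control")
  a <- simulate_cohort(cond, protocol = tiny_protocol(), seed = 1,
                       param_seed = 99)
  b <- simulate_cohort(cond, protocol = tiny_protocol(), seed = 2,
                       param_seed = 99)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$ground_truth, b[[i]]$ground_truth)
    expect_identical(a[[i]]$v_offset, b[[i]]$v_offset)
    expect_false(identical(a[[i]]$sweeps, b[[i]]$sweeps))
  }
  # same both seeds: fully identical
  expect_identical(a, simulate_cohort(cond, protocol = tiny_protocol(),
                                      seed = 1, param_seed = 99))
})

test_that("control preset spreads ground-truth latencies; deglyco collapses them", {
  p <- tiny_protocol()
  ctrl <- simulate_cohort(cohort_condition("control", 25, "control"),
                          protocol = p, seed = 5)
  degl <- simulate_cohort(cohort_condition("deglyco", 25, "deglyco"),
                          protocol = p, seed = 5)
  lat_c <- vapply(ctrl, gt_mean_latency, numeric(1))
  lat_d <- vapply(degl, gt_mean_latency, numeric(1))
  expect_gt(stats::var(lat_c), stats::var(lat_d))
  expect_gt(stats::var(lat_c) / stats::var(lat_d), 10)
})

test_that("planted stage-1 failures are embedded in the ground truth", {
  cells <- simulate_cohort(
    cohort_condition("control", 30, "control", qc_fail_fraction = 1 / 6),
    protocol = tiny_protocol(), seed = 8)
  planted <- vapply(cells, function(cl) cl$ground_truth$planted_qc_fail[1],
                    character(1))
  expect_equal(sum(nzchar(planted)), 5)
})

test_that("delay-sd preset controls the spread of per-cell mean latencies", {
  p <- tiny_protocol()
  sds <- c(0, 20, 60)
  spread <- sapply(seq_along(sds), function(i) {
    cells <- simulate_cohort(
      cohort_condition("g", 20, "delay_sd", params = list(delay_sd = sds[i])),
      protocol = p, seed = 21)
    stats::sd(vapply(cells, gt_mean_latency, numeric(1)))
  })
  expect_equal(spread[1], 0)
  expect_true(all(diff(spread) > 0))
})
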