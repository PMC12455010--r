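test_that("boxplot statistics match hand-worked small sets", {
  # symmetric set: whiskers at the extremes, no outliers
  b <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 5)
  expect_length(b$outliers, 0)
  # far point flagged: with linear (type-7) quartiles q1 = 2, q3 = 4,
  # fence 4 + 1.5*2 = 7, so 100 is an outlier and the whisker stops at 4
  b2 <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(b2$q1, 2)
  expect_equal(b2$q3, 4)
  expect_equal(b2$outliers, 100)
  expect_equal(b2$whisker_high, 4)
  expect_equal(b2$whisker_low, 1)
  # degenerate all-equal data
  b3 <- boxplot_stats(rep(7.5, 6))
  expect_equal(b3$median, 7.5)
  expect_equal(b3$iqr, 0)
  expect_equal(b3$whisker_span, 0)
  expect_length(b3$outliers, 0)
  # low-n flag and validation
  expect_true(boxplot_stats(c(1, 2, 3))$low_n)
  expect_false(b$low_n)
  expect_error(boxplot_stats(numeric(0)), "values")
  expect_error(boxplot_stats(c(1, NA)), "values")
})

test_that("boxplot invariants hold over random draws in both conventions", {
  set.seed(11)
  for (i in 1:30) {
    x <- rlnorm(sample(4:40, 1), meanlog = 4, sdlog = runif(1, 0.1, 1.2))
    for (qm in c("linear", "hinges")) {
      b <- boxplot_stats(x, quartile_method = qm)
      expect_lte(b$q1, b$median)
      expect_lte(b$median, b$q3)
      expect_equal(b$iqr, b$q3 - b$q1)
      # whiskers reach at least to the box edge whenever that side has
      # an observation inside its fence (always true without outliers)
      if (!any(b$outliers < b$q1)) expect_lte(b$whisker_low, b$q1)
      if (!any(b$outliers > b$q3)) expect_gte(b$whisker_high, b$q3)
      expect_gte(b$whisker_low, b$q1 - 1.5 * b$iqr)
      expect_lte(b$whisker_high, b$q3 + 1.5 * b$iqr)
      # conservation: every point is inside the whiskers or an outlier
      inside <- x >= b$whisker_low & x <= b$whisker_high
      expect_equal(sum(inside) + length(b$outliers), b$n)
      expect_setequal(b$outliers, x[!inside])
    }
  }
})

test_that("whisker span is translation-invariant and scale-equivariant", {
  set.seed(3)
  x <- rgamma(25, 2, 0.02)
  s <- whisker_span(boxplot_stats(x))
  expect_equal(whisker_span(boxplot_stats(x + 40)), s)
  expect_equal(whisker_span(boxplot_stats(2 * x)), 2 * s)
  expect_equal(whisker_span(rep(3, 10)), 0)
  # numeric input is accepted directly
  expect_equal(whisker_span(x), s)
})

test_that("outlier classification matches an exhaustive brute-force reference", {
  pool <- c(1, 2, 2.5, 3, 3.2, 4, 5, 6.5, 7, 30, 55, 100)
  n_checked <- 0
  for (size in 1:8) {
    idx_sets <- utils::combn(length(pool), size)
    for (j in seq_len(ncol(idx_sets))) {
      x <- pool[idx_sets[, j]]
      b <- boxplot_stats(x)
      ref <- brute_force_box(x)
      expect_equal(b$q1, ref$q1)
      expect_equal(b$q3, ref$q3)
      expect_equal(b$outliers, ref$outliers)
      expect_equal(b$whisker_low, ref$whisker_low)
      expect_equal(b$whisker_high, ref$whisker_high)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 3000)
})

test_that("pearson_corr recovers exact linear relations and rejects degenerate input", {
  x <- c(1, 2.5, 3, 4.2, 5)
  expect_equal(pearson_corr(x, 2 * x + 1), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_error(pearson_corr(x, rep(1, 5)), "zero variance")
  expect_error(pearson_corr(x, x[1:3]), "length")
  expect_error(pearson_corr(x[1:2], x[1:2]), "3 observations")
})

test_that("independent width and amplitude draws give near-null correlations", {
  # null-distribution check: with width and I_max generated
  # independently, |r| < 2/sqrt(n) in at least ~95% of seeded replicates
  n <- 30
  inside <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    widths <- rlnorm(n, log(80), 0.6)
    imax <- rlnorm(n, log(4), 0.4)
    abs(pearson_corr(widths, imax)) < 2 / sqrt(n)
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("condition comparison reports spans, ratios and conserved counts", {
  set.seed(5)
  w1 <- rlnorm(20, log(80), 0.5)
  meas <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    condition = rep(c("a", "b"), each = 20),
    inac_width_ms = c(w1, w1),  # identical groups
    i_max_nA = rlnorm(40, log(4), 0.3),
    censored = FALSE, analysable = TRUE,
    stringsAsFactors = FALSE)
  rep <- compare_conditions(meas, reference = "a")
  expect_equal(nrow(rep$table), 2)
  expect_equal(rep$table$span_ratio, c(1, 1))
  expect_equal(rep$table$n, c(20, 20))
  expect_error(compare_conditions(meas, reference = "zzz"), "zzz")
  # censored exclusion mode drops flagged rows
  meas$censored[1:5] <- TRUE
  rep2 <- compare_conditions(meas, reference = "a",
                             include_censored = FALSE)
  expect_equal(rep2$table$n[rep2$table$condition == "a"], 15)
})

test_that("whisker span recovers the ground-truth delay-spread ordering", {
  p <- step80_protocol()
  spans <- sapply(c(0, 40, 120), function(sdv) {
    cells <- simulate_cohort(
      cohort_condition("g", 15, "delay_sd",
                       params = list(delay_sd = sdv)),
      protocol = p, seed = 31)
    whisker_span(boxplot_stats(measure_cohort(cells)$inac_width_ms))
  })
  expect_true(all(diff(spans) > 0))
})
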