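test_that("default mean-dispersion curve has the declared parametric form", {
  expect_equal(default_dispersion(1), 2.01)
  expect_equal(default_dispersion(1e9), 0.01, tolerance = 1e-6)
  mu = sort(stats::runif(50, 0.01, 1e5))
  a = default_dispersion(mu)
  expect_true(all(a > 0))
  expect_true(all(diff(a) <= 0))                  # non-increasing in mu
  expect_equal(default_dispersion(10, alpha0 = 0.2, alpha1 = 5), 0.7)
  expect_error(default_dispersion(0), "positive")
  expect_error(default_dispersion(-3), "positive")
})

test_that("gaussian draws match their first two moments", {
  set.seed(101)
  n = 20000L
  y = sample_gaussian(rep(10, n), sd = 1)
  expect_lt(abs(mean(y) - 10), 3 / sqrt(n))
  expect_lt(abs(stats::sd(y) - 1), 3 / sqrt(2 * n))
  expect_error(sample_gaussian(0, sd = 0), "positive")
  # degenerate-noise limit collapses onto the expected abundance
  expect_equal(sample_gaussian(0, sd = 1e-9), 0, tolerance = 1e-7)
  set.seed(5); a = sample_gaussian(rep(0, 10))
  set.seed(5); b = sample_gaussian(rep(0, 10))
  expect_identical(a, b)
})

test_that("negative binomial draws honor the (mu, alpha) variance contract", {
  set.seed(202)
  n = 100000L
  mu = 100; alpha = 0.01
  y = sample_negbinom(rep(log2(mu), n), dispersion = function(m) alpha)
  expect_true(all(y >= 0))
  expect_true(all(y == round(y)))
  target_var = mu + alpha * mu^2                  # 200
  s2 = stats::var(y)
  # SE of the sample variance from the empirical fourth moment
  m4 = mean((y - mean(y))^4)
  se_var = sqrt((m4 - s2^2) / n)
  expect_lt(abs(s2 - target_var), 3 * se_var)
  expect_lt(abs(mean(y) - mu), 3 * sqrt(target_var / n))
})

test_that("zero dispersion degenerates to Poisson sampling", {
  set.seed(203)
  y = sample_negbinom(rep(0, 100000L), dispersion = function(m) 0)
  expect_lt(abs(mean(y) - 1), 0.01)
  expect_lt(abs(stats::var(y) - 1), 0.02)
})

test_that("negative binomial sampling rejects invalid inputs", {
  expect_error(sample_negbinom(63), "overflow")
  expect_error(sample_negbinom(Inf), "finite")
  expect_error(sample_negbinom(5, dispersion = function(m) -1), "negative")
})

test_that("gaussian prediction intervals are normal quantile bands", {
  pi0 = prediction_interval(0, level = 0.90)
  expect_equal(unname(pi0[1, ]), c(-1.644854, 1.644854), tolerance = 1e-6)
  # width grows without bound as the level approaches 1
  lv = c(0.5, 0.9, 0.99, 0.999999)
  w = vapply(lv, function(l) diff(prediction_interval(0, l)[1, ]),
             numeric(1L))
  expect_true(all(diff(w) > 0))
  expect_gt(w[4], 9)
  expect_error(prediction_interval(0, level = 1), "level")
  expect_error(prediction_interval(0, level = 0), "level")
})

test_that("negative binomial prediction intervals are conservative integer quantiles", {
  m = c(2, 5, 8)
  band = prediction_interval(m, level = 0.90, family = "negbinom")
  expect_true(all(band == floor(band)))
  expect_true(all(band >= 0))
  # coverage at least the nominal level despite discreteness
  set.seed(404)
  n = 20000L
  for (mm in m) {
    y = sample_negbinom(rep(mm, n))
    b = prediction_interval(mm, level = 0.90, family = "negbinom")
    expect_gte(mean(y >= b[1, "lo"] & y <= b[1, "hi"]), 0.90)
  }
  # intervals shrink, relative to the mean, as expression increases
  rel_width = (band[, "hi"] - band[, "lo"]) / 2^m
  expect_true(all(diff(rel_width) < 0))
})

test_that("the simulator is reproducible and leaves the caller's RNG alone", {
  g = feature_group(2, amp = 1, base = 8, family = "negbinom")
  s1 = simulate_rhythms(groups = g, seed = 9)
  s2 = simulate_rhythms(groups = g, seed = 9)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$features$phase, s2$features$phase)
  set.seed(77)
  expected = stats::rnorm(2)
  set.seed(77)
  invisible(simulate_rhythms(groups = g, seed = 1))
  expect_identical(stats::rnorm(2), expected)
})

test_that("simulated abundance follows the expected trajectory by family", {
  sim = simulate_rhythms(groups = feature_group(1, amp = 0, base = 0),
                         seed = 3)
  expect_equal(nrow(sim$abundance), 34L)          # default design
  nb = simulate_rhythms(groups = feature_group(3, amp = 1, base = 6,
                                               family = "negbinom"),
                        seed = 4)
  expect_true(all(nb$abundance$abund >= 0))
  expect_true(all(nb$abundance$abund == round(nb$abundance$abund)))
  expect_equal(nb$abundance$mu[nb$abundance$feature == "feature_1"],
               expected_abundance(nb$design$time, amp = 1, base = 6))
})

test_that("condition-specific phases produce anti-phase trajectories", {
  groups = list(list(feature_group(1, amp = 1, phase = 0)),
                list(feature_group(1, amp = 1, phase = 12)))
  d = design_spec(mode = "explicit", times = seq(0, 21, by = 3),
                  n_per_timepoint = 1, n_conditions = 2)
  sim = simulate_rhythms(d, groups, seed = 8)
  ab = sim$abundance
  m1 = ab$mu[ab$cond == 1]
  m2 = ab$mu[ab$cond == 2]
  t1 = ab$time[ab$cond == 1]
  # m_cond1(t) = m_cond2(t + 12) for f = sin, tau = 24
  expect_equal(m1, expected_abundance(t1 + 12, amp = 1, phase = 12),
               tolerance = 1e-9)
  expect_equal(m1, -m2, tolerance = 1e-9)
})

test_that("abundance tables round-trip through the tab-delimited format", {
  sim = simulate_rhythms(groups = list(
    feature_group(2, amp = 1),
    feature_group(2, amp = 0, base = 8, family = "negbinom")), seed = 12)
  path = withr::local_tempfile(fileext = ".tsv")
  write_abundance(sim$abundance, path)
  back = read_abundance(path)
  expect_equal(back$feature, sim$abundance$feature)
  expect_equal(back$time, sim$abundance$time)
  expect_equal(back$mu, sim$abundance$mu, tolerance = 1e-5)
  expect_equal(back$abund, sim$abundance$abund, tolerance = 1e-5)
  # counts are written exactly
  nbrows = back$feature %in% c("feature_3", "feature_4")
  expect_identical(back$abund[nbrows],
                   as.numeric(sim$abundance$abund[nbrows]))
  expect_error(read_abundance(withr::local_tempfile(lines = "feature\tsample")),
               "missing column")
})
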