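test_that("expected abundance follows the rhythmic model equation", {
  expect_equal(expected_abundance(6, amp = 1), 1)          # sin(pi/2)
  expect_equal(expected_abundance(13, amp = 0, base = 5, phase = 3,
                                  period = 7, waveform = cos), 5)
  # damped rhythm: a(t) = exp(-t/24); direct evaluation of the closed form
  expect_equal(expected_abundance(30, amp = function(t) exp(-t / 24)),
               exp(-30 / 24) * sin(2 * pi * 30 / 24))
  expect_equal(expected_abundance(30, amp = function(t) exp(-t / 24)),
               0.2865048, tolerance = 1e-6)
})

test_that("constant-parameter trajectories are periodic and scale with amplitude", {
  t = seq(0, 48, by = 0.37)
  for (tau in c(24, 20.5, 8)) {
    m = expected_abundance(t, amp = 1.3, phase = 4, period = tau, base = 2)
    m_shift = expected_abundance(t + tau, amp = 1.3, phase = 4, period = tau,
                                 base = 2)
    expect_equal(m, m_shift, tolerance = 1e-9)
  }
  m1 = expected_abundance(t, amp = 1, phase = 5, base = 3)
  m2 = expected_abundance(t, amp = 2, phase = 5, base = 3)
  expect_equal(m2 - 3, 2 * (m1 - 3), tolerance = 1e-12)
})

test_that("amplitude 0 removes all dependence on phase, period and waveform", {
  t = seq(-10, 60, by = 1.1)
  base_m = expected_abundance(t, amp = 0, base = 7)
  for (args in list(list(phase = 9), list(period = 3),
                    list(waveform = function(x) sign(sin(x))))) {
    m = do.call(expected_abundance,
                c(list(t = t, amp = 0, base = 7), args))
    expect_identical(m, base_m)
  }
})

test_that("sine trajectories span exactly baseline +/- amplitude", {
  tau = 24
  grid = seq(0, tau, by = 0.001 * tau)
  m = expected_abundance(grid, amp = 2.5, phase = 3, base = 1)
  expect_equal(max(m), 1 + 2.5, tolerance = 1e-6)
  expect_equal(min(m), 1 - 2.5, tolerance = 1e-6)
})

test_that("non-finite model components and aperiodic waveforms are rejected", {
  expect_error(expected_abundance(1, amp = function(t) 1 / (t - 1)),
               "non-finite")
  expect_error(feature_group(1, waveform = function(x) x), "periodic")
  expect_error(feature_group(1, period = -24), "period")
  expect_error(feature_group(1, family = "gaussian", sd = 0), "sd")
  expect_error(feature_group(3, amp = c(1, 2)), "length")
})

test_that("feature table realizes per-feature parameters and group structure", {
  g = list(feature_group(3, amp = c(1, 2, 3), phase = c(0, 6, 12)),
           feature_group(2, amp = 0, base = 8, family = "negbinom"))
  ft = build_feature_table(g, n_conditions = 2)
  expect_equal(nrow(ft), 5L * 2L)
  expect_equal(sum(ft$cond == 1), 5L)
  f1 = ft[ft$cond == 1, ]
  expect_equal(unlist(f1$amp[f1$group == 1]), c(1, 2, 3))
  expect_equal(f1$phase[f1$group == 1], c(0, 6, 12))
  expect_equal(f1$family, c(rep("gaussian", 3), rep("negbinom", 2)))
  # same feature ids appear once per condition
  expect_equal(table(ft$feature), table(rep(unique(ft$feature), 2)))
})

test_that("inconsistent group structure across conditions is rejected", {
  expect_error(build_feature_table(
    list(list(feature_group(3)), list(feature_group(4))), n_conditions = 2),
    "sizes must match")
  expect_error(build_feature_table(
    list(list(feature_group(2, family = "gaussian")),
         list(feature_group(2, family = "negbinom"))), n_conditions = 2),
    "family")
  expect_error(build_feature_table(
    list(list(feature_group(2)), list(feature_group(2), feature_group(2))),
    n_conditions = 2), "same number")
})

test_that("trajectory matrix applies each sample's condition and time", {
  ft = build_feature_table(feature_group(1, amp = 0, base = 3))
  d = build_design(design_spec(mode = "explicit", times = c(0, 5, 11, 20),
                               n_per_timepoint = 1))
  m = evaluate_trajectories(ft, d)
  expect_equal(dim(m), c(1L, 4L))
  expect_equal(unname(m[1, ]), rep(3, 4))

  # two samples one period apart see identical expected abundance
  d2 = build_design(design_spec(mode = "explicit", times = c(5, 29),
                                n_per_timepoint = 1))
  ft2 = build_feature_table(feature_group(1, amp = 2, phase = 3))
  m2 = evaluate_trajectories(ft2, d2)
  expect_equal(m2[1, 1], m2[1, 2], tolerance = 1e-9)
})

test_that("each sine rhythm peaks at tau/4 - phase (mod tau)", {
  set.seed(31)
  n = 60
  amps = stats::runif(n, 0.5, 3)
  phases = stats::runif(n, 0, 24)
  ft = build_feature_table(feature_group(n, amp = amps, phase = phases))
  d = build_design(design_spec(mode = "explicit",
                               times = seq(0, 23.99, by = 0.01),
                               n_per_timepoint = 1))
  m = evaluate_trajectories(ft, d)
  peak_t = d$time[apply(m, 1L, which.max)]
  expected = (24 / 4 - phases) %% 24
  dd = abs(peak_t - expected)
  expect_lt(max(pmin(dd, 24 - dd)), 0.011)        # grid resolution
})

test_that("feature tables serialize with t = 0 snapshots of functional parameters", {
  g = list(feature_group(1, amp = function(t) 2 * exp(-t / 24), base = 1),
           feature_group(2, amp = 0, base = 8, family = "negbinom"))
  ft = build_feature_table(g)
  path = withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back = read_feature_table(path)
  expect_equal(back$amp0, c(2, 0, 0))
  expect_equal(back$base0, c(1, 8, 8))
  expect_equal(back$family, c("gaussian", "negbinom", "negbinom"))
  expect_equal(back$feature, ft$feature)
})
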