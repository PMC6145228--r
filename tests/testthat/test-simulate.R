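test_that("ground-truth geometry follows from the recovery fraction", {
  # recovered height 0.869 x initial at 50% strain: (0.869 - 0.5)/0.5 = 0.738
  cv <- simulate_curve(tpa_protocol(),
                       fillet_params(14.47, recovery_fraction = 0.738))
  expect_equal(cv$truth$springiness, 73.8)
  expect_equal(cv$truth$thickness2, 0.738 * cv$truth$thickness1)
  expect_equal(cv$truth$thickness1, 14.47)
})

test_that("perfectly elastic fillet gives cohesiveness 1 and springiness 100", {
  fp <- fillet_params(15, recovery_fraction = 1, hardness2_ratio = 1,
                      stiffness_shape2 = 2.5)
  cv <- simulate_curve(tpa_protocol(), fp)
  expect_equal(cv$truth$cohesiveness, 1)
  expect_equal(cv$truth$springiness, 100)
})

test_that("default parameters land hardness-1 in the published cohort range", {
  cv <- simulate_curve(tpa_protocol(), fillet_params(15.73), seed = 42)
  h1 <- extract_tpa(cv)$hardness1
  expect_lt(abs(h1 - 200.34), 3 * 42.19)
})

test_that("degenerate second-compression geometry is rejected", {
  expect_error(simulate_curve(tpa_protocol(strain = 0.5),
                              fillet_params(0.3, recovery_fraction = 0.5)),
               "second-compression")
  expect_error(fillet_params(15, recovery_fraction = 0.2,
                             unload_fraction = 0.3),
               "unload_fraction")
  expect_error(tpa_protocol(strain = 1.2), "strain")
  expect_error(tpa_protocol(sample_rate = 10), "sample_rate")
})

test_that("identical seeds give byte-identical noisy curves", {
  fp <- fillet_params(15, noise_sd = 1)
  c1 <- simulate_curve(tpa_protocol(), fp, seed = 7)
  c2 <- simulate_curve(tpa_protocol(), fp, seed = 7)
  c3 <- simulate_curve(tpa_protocol(), fp, seed = 8)
  expect_identical(c1$force, c2$force)
  expect_false(identical(c1$force, c3$force))
})

test_that("noiseless round trip recovers every attribute within 0.5%", {
  cases <- list(
    fillet_params(9.5), fillet_params(19),
    fillet_params(15.73, recovery_fraction = 0.6977),
    ff_fillet()
  )
  for (fp in cases) {
    cv <- simulate_curve(tpa_protocol(), fp)
    prof <- extract_tpa(cv)
    for (a in tpa_attribute_names())
      expect_rel_equal(prof[[a]], cv$truth[[a]], 0.005)
  }
})

test_that("round trip survives instrument-scale force noise", {
  # 0.05 N noise is the same order as the 5 g trigger itself.  Peaks are
  # noise-biased upward by at most a few SDs; work ratios are essentially
  # untouched; distances are biased low because the trigger crossing can
  # only be localized where force clears the noise band of the flat
  # contact toe.
  for (s in c(3, 10, 17)) {
    fp <- fillet_params(14, noise_sd = 0.05)
    cv <- simulate_curve(tpa_protocol(), fp, seed = s)
    prof <- extract_tpa(cv)
    expect_lt(abs(prof$hardness1 - cv$truth$hardness1), 4 * 0.05)
    expect_rel_equal(prof$cohesiveness, cv$truth$cohesiveness, 0.005)
    expect_rel_equal(prof$adhesiveness, cv$truth$adhesiveness, 0.02)
    expect_lte(prof$springiness, cv$truth$springiness)
    expect_rel_equal(prof$springiness, cv$truth$springiness, 0.10)
  }
})

test_that("calibration inverse reproduces prescribed attribute values", {
  fp <- fillet_from_attributes(thickness1 = 14.47, hardness1 = 220.51,
                               hardness2 = 194.68, cohesiveness = 0.47,
                               springiness = 73.84, resilience = 23.50,
                               adhesiveness = -1.17)
  tr <- simulate_curve(tpa_protocol(), fp)$truth
  expect_equal(tr$thickness1, 14.47, tolerance = 1e-10)
  expect_equal(tr$hardness1, 220.51)
  expect_equal(tr$hardness2, 194.68, tolerance = 1e-10)
  expect_equal(tr$cohesiveness, 0.47, tolerance = 1e-10)
  expect_equal(tr$springiness, 73.84, tolerance = 1e-10)
  expect_equal(tr$resilience, 23.50, tolerance = 1e-10)
  expect_equal(tr$adhesiveness, -1.17, tolerance = 1e-10)
})
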