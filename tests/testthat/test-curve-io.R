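test_that("curve CSV round trip preserves channels, metadata and protocol", {
  cv <- simulate_curve(tpa_protocol(), fillet_params(12), seed = 1,
                       meta = list(fish_id = "F001", treatment = "IQF",
                                   point = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, f)
  cv2 <- read_curve(f)
  expect_equal(cv2$time, cv$time, tolerance = 1e-5)
  expect_equal(cv2$force, cv$force, tolerance = 1e-5)
  expect_equal(cv2$displacement, cv$displacement, tolerance = 1e-5)
  expect_equal(cv2$meta$fish_id, "F001")
  expect_equal(cv2$meta$point, 3)
  expect_equal(cv2$protocol$trigger_force, 5)
})

test_that("gram-force and centimetre dialects are normalized on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,fg,dcm", paste(seq(0, 9.9, 0.1),
                                 round(seq(0, 990, 10), 4),
                                 seq(0, 0.99, 0.01), sep = ",")), f)
  cv <- read_curve(f, curve_dialect(time = "t", force = "fg",
                                    distance = "dcm", force_unit = "g",
                                    distance_unit = "cm"))
  expect_rel_equal(max(cv$force), 990 / 101.97, 1e-4)
  expect_equal(max(cv$displacement), 9.9)
  # normalization is idempotent: a file already in N/mm is untouched
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, f2)
  cv2 <- read_curve(f2)
  expect_equal(cv2$force, cv$force, tolerance = 1e-5)
})

test_that("malformed curve files are rejected with the offending location", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,force_N", paste(1:200, 1:200, sep = ",")), f)
  expect_error(read_curve(f), "missing column 'distance_mm'")

  shuffled <- simulate_curve(tpa_protocol(), fillet_params(12))
  shuffled$time <- sample(shuffled$time)
  f2 <- withr::local_tempfile(fileext = ".csv")
  # bypass the constructor to write an invalid file
  writeLines(c("time_s,force_N,distance_mm",
               sprintf("%g,%g,%g", shuffled$time, shuffled$force,
                       shuffled$displacement)), f2)
  expect_error(read_curve(f2), "strictly increasing")
  expect_error(read_curve("no/such/file.csv"), "not found")
})

test_that("attribute tables round-trip at six significant digits", {
  co <- tiny_cohort()
  curves <- simulate_cohort(
    cohort_spec(n_fish = c("IQF" = 2, "fresh-frozen" = 2),
                points_per_fillet = 2, seed = 5), curves = TRUE)$curves
  profiles <- lapply(curves, extract_tpa)
  f <- withr::local_tempfile(fileext = ".csv")
  d <- write_attributes(profiles, f)
  expect_equal(nrow(d), 8)
  back <- read_attributes(f)
  for (a in tpa_attribute_names())
    expect_equal(back[[a]], d[[a]], tolerance = 1e-6)
})

test_that("attribute writer flags empty input and missing attributes", {
  f <- withr::local_tempfile(fileext = ".csv")
  expect_warning(write_attributes(list(), f), "header only")
  expect_true(file.exists(f))
  cv <- simulate_curve(tpa_protocol(), fillet_params(12))
  p <- extract_tpa(cv)
  p$springiness <- NULL
  expect_error(write_attributes(list(p), f), "springiness")
})

test_that("cohort join keeps repeated measures and reports orphans", {
  co <- simulate_cohort(cohort_spec(seed = 2))
  joined <- read_cohort(co$tpa, co$sensory)
  expect_equal(length(unique(joined$tpa$fish_id)), 94)
  expect_equal(nrow(joined$tpa), 752)

  sens_missing <- co$sensory[-(1:3), ]
  expect_message(j2 <- read_cohort(co$tpa, sens_missing), "3 fish")
  expect_equal(length(unique(j2$tpa$fish_id)), 91)
  expect_equal(sort(j2$dropped), sort(co$sensory$fish_id[1:3]))

  empty <- co$sensory[0, ]
  expect_error(read_cohort(co$tpa, empty), "no overlapping fish")

  dup <- rbind(co$tpa, co$tpa[1, ])
  expect_error(read_cohort(dup, co$sensory), "duplicate")
})
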