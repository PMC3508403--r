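test_that("anammox nirS share: printed station-16 value and invariance", {
  f <- anammox_nirs_fraction(1728, 7245)
  expect_equal(round(100 * as.numeric(f)), 19)
  expect_equal(as.numeric(f), 1728 / (1728 + 7245), tolerance = 1e-12)
  expect_equal(anammox_nirs_fraction(0, 500), 0)
  # scale invariance under common rescaling
  for (k in c(0.1, 10, 1e3))
    expect_equal(as.numeric(anammox_nirs_fraction(k * 1728, k * 7245)),
                 as.numeric(f), tolerance = 1e-14)
})

test_that("below-detection handling excludes, never zeroes", {
  expect_error(anammox_nirs_fraction(NA, NA), "both targets")
  expect_warning(f <- anammox_nirs_fraction(NA, 500), "below detection")
  expect_true(is.na(f))
})

test_that("delta-method uncertainty matches a Monte-Carlo oracle", {
  a <- 1728; d <- 7245; sa <- 198; sd_ <- 813
  f <- anammox_nirs_fraction(a, d, sa, sd_)
  set.seed(42)
  am <- rnorm(2e4, a, sa); dm <- rnorm(2e4, d, sd_)
  sims <- am / (am + dm)
  expect_equal(attr(f, "sd"), sd(sims), tolerance = 0.05)
})

test_that("qPCR table parsing: n.d. becomes below_detection, not zero", {
  path <- system.file("extdata", "qpcr_nirs_synthetic.csv",
                      package = "benthicN")
  q <- read_qpcr_csv(path)
  nd <- q[q$station_id == 16 & q$layer_top_cm == 6 &
            q$target == "anammox_nirS", ]
  expect_true(nd$below_detection)
  expect_true(is.na(nd$copies_per_mg))
  expect_false(any(q$copies_per_mg == 0, na.rm = TRUE))
  s16 <- q[q$station_id == 16 & q$layer_top_cm == 0, ]
  expect_setequal(s16$copies_per_mg, c(1728, 7245))
})

test_that("cell-specific rate: arithmetic, inverse proportionality, round trip", {
  r <- cell_specific_rate(30, 1728, bulk_density = 1, copies_per_cell = 1)
  expect_equal(r, 30e6 / 1.728e6)  # ~17.4 fmol N cell^-1 d^-1
  expect_equal(cell_specific_rate(30, 2 * 1728), r / 2)
  # unit round trip: rate per cell times cells per cm^3 gives the input
  cells_cm3 <- 1728 * 1e3 * 1
  expect_equal(r * cells_cm3 / 1e6, 30, tolerance = 1e-12)
  expect_error(cell_specific_rate(30, 0), "positive")
})
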