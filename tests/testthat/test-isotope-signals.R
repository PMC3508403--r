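test_that("excess relative to air: baseline, arithmetic, channel independence", {
  n <- 5
  # ratios exactly at air equilibrium -> zero excess in both channels
  s <- make_slurry(rep(air$r29, n), rep(air$r30, n))
  ex <- excess_relative_to_air(s)
  expect_equal(ex$excess29, rep(0, n))
  expect_equal(ex$excess30, rep(0, n))

  # a ratio offset of 1e-4 at 500 umol l^-1 28N2 is 0.05 umol l^-1 excess
  s2 <- make_slurry(rep(air$r29 + 1e-4, n), rep(air$r30, n))
  ex2 <- excess_relative_to_air(s2)
  expect_equal(ex2$excess29, rep(1e-4 * 500, n), tolerance = 1e-12)
  # the 30N2 channel stays at zero no matter what r29 does
  expect_equal(ex2$excess30, rep(0, n))
})

test_that("excess is linear in the ratio deviation", {
  dev <- c(1e-5, 3e-5, 8e-5, 2e-4, 5e-4)
  for (k in c(0.5, 2, 7)) {
    s1 <- make_slurry(air$r29 + dev, air$r30 + dev / 10)
    sk <- make_slurry(air$r29 + k * dev, air$r30 + k * dev / 10)
    expect_equal(excess_relative_to_air(sk)$excess29,
                 k * excess_relative_to_air(s1)$excess29,
                 tolerance = 1e-12)
    expect_equal(excess_relative_to_air(sk)$excess30,
                 k * excess_relative_to_air(s1)$excess30,
                 tolerance = 1e-12)
  }
})

test_that("non-finite inputs are rejected with the offending index", {
  s <- make_slurry(air$r29 + c(1, 2, 3, 4, 5) * 1e-5,
                   rep(air$r30, 5))
  s$r29[3] <- NaN  # past the constructor on purpose
  expect_error(excess_relative_to_air(s), "index 3")
})

test_that("production slope: noiseless line, errors, degenerate design", {
  est <- production_slope(c(0, 2, 6, 10, 15),
                          c(0, 4, 12, 20, 30))
  expect_equal(est$slope, 2.0, tolerance = 1e-12)
  expect_lt(est$p_value, 1e-6)
  expect_true(est$accepted)
  expect_false(est$delay_detected)

  expect_error(production_slope(c(0, 1, 2), c(0, 1, 2)),
               "insufficient")
  expect_error(production_slope(rep(2, 5), 1:5), "degenerate")
})

test_that("a flat noise-free channel is not significant", {
  est <- production_slope(c(0, 5, 10, 15, 20, 26), rep(3, 6))
  expect_false(est$accepted)
  expect_equal(est$p_value, 1)
})

test_that("null data (no production) is rejected in >= 90% of replicates", {
  n_rej <- 0L
  n_rep <- 500L
  t_h <- seq(0, 26, length.out = 6)
  for (i in seq_len(n_rep)) {
    set.seed(i)
    y <- 10 + rnorm(6, 0, 0.5)
    if (!production_slope(t_h, y)$accepted) n_rej <- n_rej + 1L
  }
  expect_gte(n_rej / n_rep, 0.90)
})

test_that("an initial delay is detected and the series rejected", {
  t_h <- c(0, 5, 10, 15, 20, 26)
  y <- 2 * pmax(t_h - 10, 0)  # no production before 10 h, slope 2 after
  est <- production_slope(t_h, y)
  expect_true(est$delay_detected)
  expect_false(est$accepted)
})

test_that("slope recovery: true slope within 3 stderr in >= 99% of replicates", {
  t_h <- seq(0, 26, length.out = 40)  # enough df that 3 se covers >= 99%
  hits <- 0L
  n_rep <- 500L
  for (i in seq_len(n_rep)) {
    set.seed(1000 + i)
    b <- runif(1, 0.1, 3)
    y <- 1 + b * t_h + rnorm(40, 0, 0.3)
    est <- production_slope(t_h, y)
    if (abs(est$slope - b) <= 3 * est$stderr) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.99)
})

test_that("volumetric rate bridge: arithmetic, linearity, inverse", {
  # aqueous volume 0.25 l: 122 ml added water + 0.8 * 160 cm^3 pore water
  s <- make_slurry(rep(air$r29, 5), rep(air$r30, 5),
                   water_ml = 122, sed_cm3 = 160)
  expect_equal(aqueous_volume_l(s), 0.25)
  expect_equal(volumetric_rate(0.01, s),
               0.01 * 24 * 2 * (0.25 / 160) * 1e3)  # 0.75 nmol N cm^-3 d^-1
  expect_equal(volumetric_rate(0.01, s), 0.75)
  expect_equal(volumetric_rate(0, s), 0)

  # doubling the total aqueous volume doubles the rate
  s2 <- make_slurry(rep(air$r29, 5), rep(air$r30, 5),
                    water_ml = 372, sed_cm3 = 160)  # 0.372+0.128 = 0.5 l
  expect_equal(volumetric_rate(0.01, s2), 2 * volumetric_rate(0.01, s))

  # inverse conversion is the identity
  rate <- volumetric_rate(0.0137, s)
  slope_back <- rate / (24 * 2 * (aqueous_volume_l(s) / 160) * 1e3)
  expect_equal(slope_back, 0.0137, tolerance = 1e-12)

  core <- incubation_series("c", "core", "S", c(0, 2, 6, 10, 15),
                            rep(air$r29, 5), rep(air$r30, 5), 500)
  expect_error(volumetric_rate(0.01, core), "slurry")
  s_bad <- s; s_bad$volume_water_ml <- NA_real_
  expect_error(volumetric_rate(0.01, s_bad), "configuration")
})

test_that("core areal bridge follows the water-column height", {
  expect_equal(areal_rate_core(0.1, 0.125), 0.1 * 1000 * 0.125 * 24)
  expect_equal(areal_rate_core(0.1, 0.25), 2 * areal_rate_core(0.1, 0.125))
})
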