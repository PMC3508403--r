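test_that("pairing equations reproduce the forward oracle", {
  # forward: A = 10 with F_NH4 = 0.5 emits p29 = 5
  expect_equal(anammox_ex1(5, 0.5), 10)
  expect_equal(anammox_ex1(3, 1), 3)
  expect_equal(anammox_ex1(0, 0.7), 0)

  # forward: D = 100 with F = 0.5 emits p30 = 25
  expect_equal(denit_ex2(25, 0.5), 100)
  expect_equal(denit_ex2(7, 1), 7)
  expect_equal(denit_ex2(0, 0.3), 0)

  # forward: D = 100, A = 10, F = 0.5 -> p29 = 2F(1-F)D + AF = 55
  expect_equal(anammox_ex2(55, 25, 0.5), 10)
  f <- 0.4
  expect_equal(anammox_ex2(2 * ((1 - f) / f) * 30, 30, f), 0)
  expect_equal(anammox_ex2(3, 10, 1), 3)

  expect_error(anammox_ex1(5, 0), "\\(0, 1\\]")
  expect_error(denit_ex2(5, 1.3), "\\(0, 1\\]")
  expect_warning(res <- anammox_ex2(1, 25, 0.5), "floored")
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "floored"))
})

test_that("round trip: forward pairing then inversion recovers (D, A) exactly", {
  for (f in c(0.1, 0.25, 0.5, 0.8, 0.99, 1)) {
    for (D in c(0, 1, 10, 87.3, 200)) {
      for (A in c(0, 0.5, 12, 50)) {
        fw <- forward_pairing(D, A, f)
        expect_equal(denit_ex2(fw$p30, f), D, tolerance = 1e-12)
        a_hat <- suppressWarnings(anammox_ex2(fw$p29, fw$p30, f))
        expect_equal(as.numeric(a_hat), A, tolerance = 1e-12)
      }
    }
  }
})

test_that("labelling-fraction inversion: roots, degenerate case, infeasibility", {
  fs <- infer_fstar(55, 25, 10)
  expect_s3_class(fs, "labeling_fraction")
  expect_equal(fs$value, 0.5, tolerance = 1e-12)  # roots 0.5 and 10
  expect_identical(fs$source, "inferred")

  # A_target = 0 is the linear degenerate case
  expect_equal(infer_fstar(50, 25, 0)$value, 0.5, tolerance = 1e-12)

  # negative discriminant: 50^2 - 8*100*25 < 0
  expect_error(infer_fstar(0, 25, 100), "discriminant")

  # nominal-proximity root selection: construct two admissible roots
  # A F^2 - (p29 + 2 p30) F + 2 p30 = 0 with roots 0.4 and 0.9:
  # sum = 1.3 = (p29 + 2 p30)/A, product = 0.36 = 2 p30 / A
  A <- 100; p30 <- 0.36 * A / 2; p29 <- 1.3 * A - 2 * p30
  expect_equal(sort(c(infer_fstar(p29, p30, A, f_nominal = 0.45)$value,
                      infer_fstar(p29, p30, A, f_nominal = 0.95)$value)),
               c(0.4, 0.9), tolerance = 1e-9)
  # without a nominal fraction the larger root is taken
  expect_equal(infer_fstar(p29, p30, A)$value, 0.9, tolerance = 1e-9)
})

test_that("inversion is the identity on F over a forward grid", {
  for (f in c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)) {
    for (D in c(1, 10, 50, 200)) {
      for (A in c(0, 5, 20, 50)) {
        fw <- forward_pairing(D, A, f)
        if (fw$p29 + fw$p30 == 0) next
        fs <- infer_fstar(fw$p29, fw$p30, A, f_nominal = f)
        expect_equal(fs$value, f, tolerance = 1e-9)
      }
    }
  }
})

test_that("excess nitrate from the labelling-fraction gap", {
  expect_equal(excess_nitrate(200, 0.5, 0.5), 0)
  expect_equal(excess_nitrate(200, 0.5, 0.8), 200 * (2 - 1.25))  # 150
  expect_warning(x <- excess_nitrate(200, 0.9, 0.8), "floored")
  expect_equal(x, 0)
  # conversion to sediment units
  expect_equal(excess_nitrate(200, 0.5, 0.8, slurry_to_sediment = 2.05),
               150 * 2.05)
})

test_that("anammox fraction: printed station values and invariances", {
  expect_equal(round(100 * anammox_fraction(0.21, 2.73)), 7)
  expect_equal(round(100 * anammox_fraction(0.89, 1.46)), 38)
  expect_equal(anammox_fraction(0, 5), 0)
  expect_error(anammox_fraction(0, 0), "undefined")
  # scale invariance
  for (k in c(0.01, 3, 1e4))
    expect_equal(anammox_fraction(k * 0.89, k * 1.46),
                 anammox_fraction(0.89, 1.46), tolerance = 1e-14)
})

test_that("rIPT reduces to the classical isotope pairing total at ra = 0", {
  nl <- ript_nloss(50, 25, 0)
  # classical: D15 = p29 + 2 p30, D14 = (p29 / 2 p30) D15
  d15 <- 50 + 2 * 25
  d14 <- 50 / (2 * 25) * d15
  expect_equal(nl$nloss_total, d14 + d15)  # 200
  expect_equal(nl$denit, nl$nloss_total)
  expect_equal(nl$anammox, 0)

  for (p29 in c(1, 17, 80)) {
    for (p30 in c(2, 30, 75)) {
      d15 <- p29 + 2 * p30
      expect_equal(ript_nloss(p29, p30, 0)$nloss_total,
                   d15 * (1 + p29 / (2 * p30)), tolerance = 1e-12)
    }
  }
  expect_error(ript_nloss(10, 0, 0.2), "degenerate")
})

test_that("rIPT partition is internally consistent", {
  nl <- ript_nloss(40, 12, 0.3)
  expect_equal(nl$denit + nl$anammox, nl$nloss_total, tolerance = 1e-12)
  expect_equal(nl$anammox, 0.3 * nl$nloss_total, tolerance = 1e-12)
  expect_equal(nl$R29, 40 / 12)
  # an impossible (ra, R29) combination raises both inconsistency warnings
  expect_warning(expect_warning(ript_nloss(1, 25, 0.6), "exceeds 1"),
                 "inconsisten")
})

test_that("depth integration: printed surface rates and properties", {
  one <- function(rate) data.frame(top_cm = 0, bottom_cm = 2, rate = rate)
  expect_equal(depth_integrate(one(136), 2), 2.72)   # prints as 2.7
  expect_equal(depth_integrate(one(73), 2), 1.46)
  expect_equal(depth_integrate(one(0), 2), 0)

  # additivity over a layer partition
  split2 <- data.frame(top_cm = c(0, 1), bottom_cm = c(1, 2),
                       rate = c(136, 136))
  expect_equal(depth_integrate(split2, 2), depth_integrate(one(136), 2))
  # linearity in rates
  expect_equal(depth_integrate(one(272), 2), 2 * depth_integrate(one(136), 2))

  # partial overlap and NA (rejected channel) handling
  lay <- data.frame(top_cm = c(0, 2, 4), bottom_cm = c(2, 4, 6),
                    rate = c(100, 50, NA))
  expect_equal(depth_integrate(lay, 3), (100 * 2 + 50 * 1) * 1e-2)
  expect_equal(depth_integrate(lay, 6), (100 * 2 + 50 * 2 + 0) * 1e-2)
  expect_warning(depth_integrate(lay, 10), "truncated")
  bad <- data.frame(top_cm = c(0, 1), bottom_cm = c(2, 3), rate = c(1, 1))
  expect_error(depth_integrate(bad, 2), "overlap")
})
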