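test_that("simulators are deterministic under a fixed seed", {
  scn <- slurry_scenario(seed = 11)
  a <- simulate_slurry_ex2(scn); b <- simulate_slurry_ex2(scn)
  expect_identical(a$r29, b$r29)
  expect_identical(a$r30, b$r30)
  c_ <- simulate_slurry_ex2(slurry_scenario(seed = 12))
  expect_false(identical(a$r29, c_$r29))

  k1 <- simulate_core(core_scenario(seed = 5))
  k2 <- simulate_core(core_scenario(seed = 5))
  expect_identical(k1$r29, k2$r29)
})

test_that("noiseless Experiment 1 recovers the true anammox rate exactly", {
  scn <- slurry_scenario(true_A = 10, seed = 1, noise_sd_ratio = 0)
  s <- simulate_slurry_ex1(scn)
  tr <- attr(s, "truth")
  ex <- excess_relative_to_air(s)
  est <- production_slope(ex$time_h, ex$excess29)
  expect_true(est$accepted)
  p29 <- volumetric_rate(est$slope, s)        # N-atom units
  expect_equal(anammox_ex1(p29, tr$f_nh4), tr$true_A_natoms,
               tolerance = 1e-9)
  # and no 30N2 production at all
  est30 <- production_slope(ex$time_h, ex$excess30)
  expect_false(est30$accepted)
})

test_that("noiseless Experiment 2 recovers rates, F* and the injected store", {
  for (store in c(0, 12, 95, 222)) {
    scn <- slurry_scenario(intracellular_14no3 = store, seed = 3,
                           noise_sd_ratio = 0)
    s <- simulate_slurry_ex2(scn)
    tr <- attr(s, "truth")
    ex <- excess_relative_to_air(s)
    p29 <- volumetric_rate(production_slope(ex$time_h, ex$excess29)$slope, s)
    p30 <- volumetric_rate(production_slope(ex$time_h, ex$excess30)$slope, s)
    fs <- infer_fstar(p29, p30, tr$true_A_natoms, tr$f_nominal)
    expect_equal(fs$value, tr$f_true, tolerance = 1e-6)
    expect_equal(denit_ex2(p30, fs), tr$true_D_natoms, tolerance = 1e-6)
    got <- suppressWarnings(excess_nitrate(
      tr$conc15_no3, fs, tr$f_nominal, slurry_to_sediment_factor(s)))
    if (store == 0) {
      expect_lt(abs(got), 1e-6)
      expect_equal(fs$value, tr$f_nominal, tolerance = 1e-9)
    } else {
      expect_equal(got, store, tolerance = 1e-6 * store)
    }
  }
})

test_that("pairing normalization: channel sum equals total production", {
  # independent oracle: binomial atom pairing enumerated with dbinom
  for (f in c(0.2, 0.5, 0.76)) {
    for (D in c(0, 40)) {
      for (A in c(0, 9)) {
        pd <- dbinom(0:2, 2, f)            # denitrification pairs
        pa <- c(1 - f, f)                  # anammox: one labelled atom max
        p28 <- D * pd[1] + A * pa[1]
        p29 <- D * pd[2] + A * pa[2]
        p30 <- D * pd[3]
        expect_equal(p28 + p29 + p30, D + A, tolerance = 1e-12)
        fw <- forward_pairing(D, A, f)
        expect_equal(fw$p29, p29, tolerance = 1e-12)
        expect_equal(fw$p30, p30, tolerance = 1e-12)
        expect_equal(fw$p28, p28, tolerance = 1e-12)
      }
    }
  }
  # simulator slopes follow the same combinatorics
  scn <- slurry_scenario(true_D = 40, true_A = 9, seed = 2,
                         noise_sd_ratio = 0)
  s <- simulate_slurry_ex2(scn)
  tr <- attr(s, "truth")
  fw <- forward_pairing(40, 9, tr$f_true)
  to_slope <- scn$volume_sediment_cm3 / (24 * 1e3 * tr$aqueous_volume_l)
  expect_equal(tr$slope29, fw$p29 * to_slope, tolerance = 1e-12)
  expect_equal(tr$slope30, fw$p30 * to_slope, tolerance = 1e-12)
})

test_that("mass balance: 15N in produced N2 never exceeds 15N supplied", {
  scn <- slurry_scenario(true_D = 200, true_A = 50, seed = 9,
                         noise_sd_ratio = 0, duration_h = 28)
  s2 <- simulate_slurry_ex2(scn)
  ex <- excess_relative_to_air(s2)
  atoms15 <- ex$excess29 + 2 * ex$excess30   # umol 15N l^-1
  expect_true(all(atoms15 <= scn$added_15no3))
  s1 <- simulate_slurry_ex1(scn)
  ex1 <- excess_relative_to_air(s1)
  expect_true(all(ex1$excess29 + 2 * ex1$excess30 <= scn$added_15nh4))
})

test_that("noiseless core series at zero rates is flat at air ratios", {
  scn <- core_scenario(true_D14 = 0, true_D15 = 0, true_A = 0,
                       seed = 4, noise_sd_ratio = 0)
  s <- simulate_core(scn)
  expect_equal(s$r29, rep(air$r29, 5), tolerance = 1e-14)
  expect_equal(s$r30, rep(air$r30, 5), tolerance = 1e-14)
})

test_that("core simulator + rIPT recover total N-loss over a truth grid", {
  # the authoritative disambiguation of the revised-IPT algebra
  for (D14 in c(10, 56, 150, 300, 40)) {
    for (D15 in c(20, 125, 60, 250, 90)) {
      for (A in c(0, 5, 14, 60, 120)) {
        scn <- core_scenario(true_D14 = D14, true_D15 = D15, true_A = A,
                             seed = 1, noise_sd_ratio = 0)
        s <- simulate_core(scn)
        tr <- attr(s, "truth")
        nl <- ript_nloss(tr$p29_areal, tr$p30_areal, tr$ra)
        expect_equal(nl$nloss_total, tr$nloss_natoms,
                     tolerance = 1e-6)
        expect_equal(nl$anammox, 2 * A, tolerance = 1e-6)
      }
    }
  }
})

test_that("classical IPT identities hold when anammox is absent", {
  scn <- core_scenario(true_D14 = 80, true_D15 = 120, true_A = 0,
                       seed = 6, noise_sd_ratio = 0)
  tr <- attr(simulate_core(scn), "truth")
  p29 <- tr$p29_areal; p30 <- tr$p30_areal
  d15 <- p29 + 2 * p30
  d14 <- p29 / (2 * p30) * d15
  expect_equal(ript_nloss(p29, p30, 0)$nloss_total, d14 + d15,
               tolerance = 1e-9)
  expect_equal(d14 + d15, tr$nloss_natoms, tolerance = 1e-9)
})

test_that("scenario validation: explicit seed and domain checks", {
  expect_error(slurry_scenario(), "seed")
  expect_error(core_scenario(), "seed")
  expect_error(slurry_scenario(seed = 1, n_timepoints = 4))
  expect_error(slurry_scenario(seed = 1, true_D = -1))
})
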