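test_that("concentration profiles have the three-phase shapes with the peak where it was placed", {
  kin <- kinetic_params(transition_time = 7)
  C <- make_concentration_profiles(kin, 1:30)
  expect_equal(dim(C), c(30L, 3L))
  expect_true(all(C >= 0 & C <= 1))
  # liquid decreasing, gel increasing, transition peaked at the set time
  expect_true(all(diff(C[, "liquid"]) <= 0))
  expect_true(all(diff(C[, "gel"]) >= 0))
  expect_identical(which.max(C[, "transition"]), 7L)
  for (j in 1:3) expect_true(is_unimodal(C[, j]))

  # off-grid transition time snaps to the nearest grid point
  C2 <- make_concentration_profiles(kinetic_params(transition_time = 11.4), 1:30)
  expect_identical(which.max(C2[, "transition"]), 11L)

  # default kinetics close mass balance exactly
  expect_equal(rowSums(C), rep(1, 30), tolerance = 1e-12)

  expect_error(make_concentration_profiles(kin, c(1, 2, 2, 3, 4)), "increasing")
  expect_error(kinetic_params(steepness = -1), "steepness")
})

test_that("a later transition delays the gel-phase half-rise", {
  grid <- 1:30
  slow <- make_concentration_profiles(kinetic_params(transition_time = 14.5), grid)
  fast <- make_concentration_profiles(kinetic_params(transition_time = 6), grid)
  half_rise <- function(C) grid[which(C[, "gel"] >= 0.5 * max(C[, "gel"]))[1]]
  expect_gt(half_rise(slow), half_rise(fast))
})

test_that("spectral profiles are nonnegative, banded, independent and seed-deterministic", {
  grid <- default_wavenumber_grid()
  S <- make_spectral_profiles(grid, seed = 0)
  expect_equal(dim(S), c(3L, 1730L))
  expect_true(all(S >= 0))
  sv <- svd(S, nu = 0, nv = 0)$d
  expect_gt(sv[3] / sv[1], 1e-6)
  # every component has appreciable intensity at the three band centres
  for (wn in c(6900, 8600, 10800)) {
    j <- which.min(abs(grid - wn))
    expect_true(all(S[, j] > 0.05))
  }
  expect_identical(S, make_spectral_profiles(grid, seed = 0))
  expect_false(identical(S, make_spectral_profiles(grid, seed = 1)))
  expect_error(make_spectral_profiles(seq(2000, 3000, by = 10)), "range")
})

test_that("simulated batches realize the bilinear model with the stated noise", {
  gt <- small_truth(noise_sd = 0)
  b <- simulate_batch(gt, seed = 1)
  expect_equal(b$absorbance, gt$C_true %*% gt$S_true, tolerance = 0)
  sv <- svd(b$absorbance, nu = 0, nv = 0)$d
  expect_lt(sv[4] / sv[1], 1e-10)

  # injected noise is recovered empirically over the 30 x 1730 grid
  gtn <- ground_truth(kinetic_params(), noise_sd = 1e-3)
  bn <- simulate_batch(gtn, seed = 7)
  resid <- bn$absorbance - gtn$C_true %*% gtn$S_true
  expect_equal(sd(as.vector(resid)), 1e-3, tolerance = 0.1)

  # same seed identical, different seed different
  expect_identical(simulate_batch(gtn, seed = 3)$absorbance,
                   simulate_batch(gtn, seed = 3)$absorbance)
  expect_false(identical(simulate_batch(gtn, seed = 3)$absorbance,
                         simulate_batch(gtn, seed = 4)$absorbance))

  bad <- gt
  bad$S_true <- bad$S_true[1:2, ]
  expect_error(simulate_batch(bad), "dimension")
})

test_that("fault archetypes shift and reshape the kinetics as documented", {
  base <- kinetic_params(transition_time = 7)
  hr <- apply_fault(base, fault_spec("half_rennet", severity = 0.5))
  expect_gt(hr$transition_time, 9)
  expect_lt(hr$transition_amplitude, base$transition_amplitude)

  # severity -> 0 is the identity limit
  for (kind in c("half_rennet", "heating_off", "half_cacl2")) {
    same <- apply_fault(base, fault_spec(kind, severity = 0))
    expect_equal(unclass(same), unclass(base), tolerance = 1e-12)
  }

  # each archetype at severity 0.5 moves the transition peak >= 2 min
  C0 <- make_concentration_profiles(base, 1:30)
  t0 <- which.max(C0[, "transition"])
  for (kind in c("half_rennet", "heating_off", "half_cacl2")) {
    Cf <- make_concentration_profiles(
      apply_fault(base, fault_spec(kind, severity = 0.5)), 1:30)
    expect_gte(abs(which.max(Cf[, "transition"]) - t0), 2)
  }

  # distinct archetypes give distinct transition profiles
  C_ho <- make_concentration_profiles(
    apply_fault(base, fault_spec("heating_off", severity = 0.5)), 1:30)
  C_hr <- make_concentration_profiles(hr, 1:30)
  expect_gt(max(abs(C_ho[, "transition"] - C_hr[, "transition"])), 0.05)

  expect_error(fault_spec("no_such_fault"), "arg")
})

test_that("simulated rheology follows the logistic model", {
  p <- sigmoid_params(a = 100, b = 10, c = 2)
  cv <- simulate_rheology(p, times = c(10, 12, 40), noise_sd = 0)
  expect_equal(cv$g_prime[1], 50)
  expect_equal(cv$g_prime[2], 100 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(cv$g_prime[3], 100, tolerance = 1e-4)
  full <- simulate_rheology(p, times = 1:30, noise_sd = 0)
  expect_true(all(diff(full$g_prime) > 0))
  expect_error(sigmoid_params(a = 100, b = 10, c = 0), "nonzero")
})
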