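test_that("lack of fit matches its closed form", {
  D <- matrix(c(3, 4), 1)
  expect_equal(lof(D, D), 0)
  expect_equal(lof(D, matrix(0, 1, 2)), 100)
  expect_equal(lof(D, matrix(c(3, 0), 1)), 80)
  expect_error(lof(matrix(0, 2, 2), matrix(0, 2, 2)), "all zero")
  expect_error(lof(D, matrix(0, 2, 2)), "shape")
})

test_that("unimodal projection matches exhaustive quadratic-program search", {
  expect_equal(enforce_unimodality(c(1, 3, 2, 4, 1), peak = 4),
               c(1, 2.5, 2.5, 4, 1))
  # already unimodal input is unchanged
  u <- c(0.1, 0.5, 0.9, 0.6, 0.2)
  expect_equal(enforce_unimodality(u), u)
  # idempotence
  set.seed(21)
  for (i in 1:20) {
    x <- runif(5)
    y <- enforce_unimodality(x)
    expect_equal(enforce_unimodality(y), y, tolerance = 1e-12)
    expect_true(is_unimodal(y))
    # with the peak fixed at the argmax, the projection is the exhaustive
    # QP optimum for that peak
    expect_equal(y, brute_unimodal(x, peak = which.max(x)),
                 tolerance = 1e-10)
  }
  # symmetry: reversing the input reverses the output
  x <- c(0.2, 0.9, 0.1, 0.4, 0.3)
  expect_equal(enforce_unimodality(rev(x), peak = 6 - which.max(x)),
               rev(enforce_unimodality(x)))
})

test_that("the constrained concentration step matches brute-force NNLS on toys", {
  set.seed(31)
  for (i in 1:25) {
    S <- matrix(runif(4 * 3), 4, 3)        # 4 wavelengths x 3 components
    D <- matrix(rnorm(6 * 4), 6, 4)        # some rows force negativity
    C <- solve_concentrations(D, t(S), nonneg = TRUE, unimodal = FALSE)
    for (r in seq_len(nrow(D))) {
      expect_equal(C[r, ], brute_nnls(S, D[r, ]), tolerance = 1e-8)
    }
  }
  # clipping a negative coefficient cannot beat the unconstrained residual
  S <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  d <- c(-1, 2, 0.5)
  c_con <- solve_concentrations(matrix(d, 1), t(S), nonneg = TRUE,
                                unimodal = FALSE)
  c_unc <- solve_concentrations(matrix(d, 1), t(S), nonneg = FALSE,
                                unimodal = FALSE)
  expect_true(any(c_unc < 0))
  expect_true(all(c_con >= 0))
  expect_gte(sum((d - S %*% c_con[1, ])^2) + 1e-12,
             sum((d - S %*% c_unc[1, ])^2))
})

test_that("concentration and spectra steps recover a consistent noiseless system", {
  gt <- small_truth(noise_sd = 0, n_wn = 120)
  D <- gt$C_true %*% gt$S_true
  C <- solve_concentrations(D, gt$S_true)
  expect_equal(C, gt$C_true, ignore_attr = TRUE, tolerance = 1e-8)
  upd <- solve_spectra(D, gt$C_true, normalization = "none")
  expect_equal(upd$s_t, gt$S_true, ignore_attr = TRUE, tolerance = 1e-8)

  # unimodality flattens a bimodal unconstrained solution
  bim <- matrix(c(1, 3, 1, 3, 1), 5, 1)
  out <- solve_concentrations(bim %*% matrix(1, 1, 4), matrix(1, 1, 4))
  expect_true(is_unimodal(out[, 1]))

  # normalization moves scale between factors without touching the product
  u1 <- solve_spectra(D, gt$C_true, normalization = "unit_length")
  expect_equal(unname(sqrt(rowSums(u1$s_t^2))), rep(1, 3), tolerance = 1e-10)
  expect_equal(u1$c_mat %*% u1$s_t, upd$c_mat %*% upd$s_t, tolerance = 1e-10)

  expect_error(solve_concentrations(D, gt$S_true[c(1, 1), ]), "rank")
  expect_error(solve_spectra(D, gt$C_true[, c(1, 1, 2)]), "rank")
})

test_that("alternating least squares resolves noiseless renneting batches", {
  gt <- small_truth(noise_sd = 0)
  b <- simulate_batch(gt, seed = 1)
  sel <- select_pure_spectra(b, f = 3)
  m <- mcr_als(b, sel)
  expect_lt(tail(m$lof_history, 1), 0.1)
  expect_gt(m$explained_variance_pct, 99.99)
  # recovered profiles match the ground truth after best-correlation matching
  cc <- abs(cor(m$C, gt$C_true))
  expect_true(all(apply(cc, 2, max) > 0.999))
  # final LOF improves on the initial one and no divergence occurred
  expect_lt(tail(m$lof_history, 1), m$lof_history[1])
})

test_that("residuals of noisy fits estimate the injected noise", {
  for (s in 1:5) {
    gt <- small_truth(noise_sd = 0.003)
    b <- simulate_batch(gt, seed = s)
    m <- mcr_als(b, select_pure_spectra(b, f = 3))
    expect_true(m$converged)
    expect_gt(m$explained_variance_pct, 99.9)
    expect_gt(m$residual_sd, 0.003 / 1.5)
    expect_lt(m$residual_sd, 0.003 * 1.5)
  }
})

test_that("scale ambiguity is absorbed: normalization does not change the reconstruction", {
  gt <- small_truth(noise_sd = 0.003, n_wn = 150)
  b <- simulate_batch(gt, seed = 4)
  sel <- select_pure_spectra(b, f = 3)
  m1 <- mcr_als(b, sel, config = mcr_config(s_normalization = "unit_length"))
  m2 <- mcr_als(b, sel, config = mcr_config(s_normalization = "none"))
  expect_equal(m1$C %*% m1$S_T, m2$C %*% m2$S_T, tolerance = 1e-6)
  expect_equal(unname(sqrt(rowSums(m1$S_T^2))), rep(1, 3), tolerance = 1e-10)
})

test_that("an augmented fit shares spectra but separates fault concentration profiles", {
  base <- kinetic_params(transition_time = 7)
  grid <- seq(12500, 5824, length.out = 200)
  mk <- function(kin, id, s) {
    simulate_batch(ground_truth(kin, grid = grid, noise_sd = 0.003),
                   seed = s, batch_id = id)
  }
  batches <- list(
    mk(base, "noc_a", 1), mk(base, "noc_b", 2), mk(base, "noc_c", 3),
    mk(apply_fault(base, fault_spec("half_rennet", severity = 0.5)), "fb_1", 4),
    mk(apply_fault(base, fault_spec("heating_off", severity = 0.5)), "fb_2", 5),
    mk(apply_fault(base, fault_spec("half_cacl2", severity = 0.5)), "fb_3", 6)
  )
  set <- augment(batches)
  sel <- select_pure_spectra(set$absorbance[batch_rows(set, 1), ], f = 3)
  m <- mcr_als(set, sel)
  expect_equal(dim(m$S_T), c(3L, 200L))
  expect_equal(nrow(m$C), 180L)
  # per-batch unimodality within each segment
  for (i in 1:6) {
    seg <- m$C[batch_rows(set, i), ]
    for (j in 1:3) expect_true(is_unimodal(seg[, j], tol = 1e-9))
  }
  # the transition component of a fault batch departs from the in-control one
  tt <- transition_time(m)
  pulse_col <- tt$component[1]
  noc <- m$C[batch_rows(set, 1), pulse_col]
  fb <- m$C[batch_rows(set, 4), pulse_col]
  expect_gt(max(abs(noc - fb)) / max(noc), 0.05)
  # and its peak is delayed by at least 2 minutes
  expect_gte(tt$cp2_min[4] - tt$cp2_min[1], 2)
})

test_that("mcr_als rejects degenerate inputs and reports divergence distinctly", {
  gt <- small_truth(noise_sd = 0, n_wn = 60)
  b <- simulate_batch(gt, seed = 1)
  expect_error(mcr_als(b, b$absorbance[c(1, 1), ]), "independent")
  expect_error(mcr_als(matrix(0, 4, 4), diag(4)), "all zero")
})
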