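test_that("chart limits and statistics satisfy their structural contracts", {
  set.seed(8)
  mu <- c(4, 1, 6)
  L <- chol(matrix(c(2, 0.8, 0.3, 0.8, 1.5, 0.5, 0.3, 0.5, 1), 3))
  train <- sweep(matrix(rnorm(60 * 3), 60) %*% L, 2, mu, `+`)
  ch <- build_control_chart(train, k = 1, confidence = 0.99)
  expect_gt(ch$t2_limit, 0)
  expect_gt(ch$q_limit, 0)
  # K = 1 on correlated three-phase-like data retains the majority of variance
  expect_gt(ch$eigenvalues[1] / sum(ch$eigenvalues), 0.5)

  # the training mean scores T2 = 0, Q = 0
  centre <- monitor_batch(ch, matrix(colMeans(train), 1))
  expect_equal(centre$t2, 0, tolerance = 1e-20)
  expect_equal(centre$q, 0, tolerance = 1e-20)

  # monitoring the training data itself flags few T2 points at 99%
  self <- monitor_batch(ch, train)
  expect_lte(mean(self$t2_flag), 0.05)

  # K = F leaves no residual space: Q identically zero, flagged as such
  full <- build_control_chart(train, k = 3, confidence = 0.99)
  expect_true(full$zero_residual_variance)
  expect_equal(monitor_batch(full, train)$q, rep(0, 60), tolerance = 1e-18)

  # exact rank-K training data also gives all-zero training Q
  rank1 <- outer(rnorm(40), c(1, 2, 3))
  chr <- build_control_chart(rank1, k = 1)
  expect_true(chr$zero_residual_variance)
  expect_equal(max(monitor_batch(chr, rank1)$q), 0, tolerance = 1e-18)

  expect_error(build_control_chart(train[1:2, ], k = 2), "training")
  expect_error(monitor_batch(ch, train[, 1:2]), "column")
})

test_that("T2 is a Mahalanobis distance, invariant to re-basing the retained space", {
  set.seed(12)
  train <- matrix(rnorm(80 * 4), 80)
  ch <- build_control_chart(train, k = 2, confidence = 0.99)
  test <- matrix(rnorm(20 * 4), 20)
  t2_ref <- monitor_batch(ch, test)$t2
  xc <- sweep(test, 2, ch$train_mean)
  scores <- xc %*% ch$loadings
  lam <- diag(ch$eigenvalues[1:2], 2, 2)
  # oracle: quadratic form with the score covariance
  t2_direct <- rowSums((scores %*% solve(lam)) * scores)
  expect_equal(t2_direct, t2_ref, tolerance = 1e-10)
  # any invertible reparameterization of the score space, with the metric
  # transformed consistently, leaves T2 unchanged
  M <- matrix(c(1.3, -0.4, 0.9, 2.1), 2)
  s2 <- scores %*% t(M)
  cov2 <- M %*% lam %*% t(M)
  t2_reparam <- rowSums((s2 %*% solve(cov2)) * s2)
  expect_equal(t2_reparam, t2_ref, tolerance = 1e-9)
})

test_that("T2 false-alarm rate at 99% confidence is calibrated on in-control draws", {
  set.seed(2024)
  A <- matrix(rnorm(9), 3)
  Sig <- crossprod(A) + diag(3)
  L <- chol(Sig)
  mu <- c(5, 2, 8)
  train <- sweep(matrix(rnorm(500 * 3), 500) %*% L, 2, mu, `+`)
  test <- sweep(matrix(rnorm(10000 * 3), 10000) %*% L, 2, mu, `+`)
  ch <- build_control_chart(train, k = 2, confidence = 0.99)
  rate <- mean(monitor_batch(ch, test)$t2_flag)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("performance pools time points and handles degenerate denominators", {
  mk <- function(id, t2f, qf) {
    tibble::tibble(batch_id = id, time_min = seq_along(t2f),
                   t2 = as.numeric(t2f), q = as.numeric(qf),
                   t2_flag = t2f, q_flag = qf)
  }
  res <- list(mk("good", rep(FALSE, 4), c(FALSE, TRUE, FALSE, FALSE)),
              mk("bad", c(TRUE, TRUE, FALSE, TRUE), rep(TRUE, 4)))
  perf <- chart_performance(res, c(good = FALSE, bad = TRUE))
  q_row <- perf[perf$chart == "q", ]
  expect_equal(q_row$sensitivity, 1)
  expect_equal(q_row$specificity, 0.75)
  t2_row <- perf[perf$chart == "t2", ]
  expect_equal(t2_row$sensitivity, 0.75)
  expect_equal(t2_row$specificity, 1)
  either <- perf[perf$chart == "either", ]
  expect_equal(either$tp, 4L)

  # all-fault pool: specificity undefined, reported as NA
  allf <- chart_performance(list(mk("bad", rep(TRUE, 3), rep(TRUE, 3))),
                            c(bad = TRUE))
  expect_true(all(is.na(allf$specificity)))
  expect_equal(allf$sensitivity, rep(1, 3))

  # a fair-coin classifier scores ~0.5 on both rates
  set.seed(77)
  coin <- mk("mix", runif(2000) < 0.5, runif(2000) < 0.5)
  half_fault <- rbind(dplyr::mutate(coin, batch_id = "f")[1:1000, ],
                      dplyr::mutate(coin, batch_id = "g")[1001:2000, ])
  pc <- chart_performance(split(half_fault, half_fault$batch_id),
                          c(f = TRUE, g = FALSE))
  expect_lt(abs(pc$sensitivity[pc$chart == "t2"] - 0.5), 0.05)
  expect_lt(abs(pc$specificity[pc$chart == "t2"] - 0.5), 0.05)

  expect_error(chart_performance(res, c(TRUE, FALSE, TRUE)), "one entry")
})

test_that("every simulated fault batch is caught early by the full pipeline", {
  for (s in 1:5) {
    rep <- run_renneting_demo(seed = s, n_noc = 0)
    mon <- rep$monitoring
    for (fb in c("FB_1", "FB_2", "FB_3")) {
      sub <- mon[mon$batch_id == fb, ]
      flagged <- sub$t2_flag | sub$q_flag
      expect_true(any(flagged[sub$time_min <= 12]),
                  label = sprintf("seed %d %s first flag within 12 min", s, fb))
      expect_gte(mean(sub$q_flag), 0.5)
    }
    # the held-out in-control replicate stays essentially in control
    noc <- mon[mon$batch_id == "NOC_13c", ]
    expect_lte(mean(noc$t2_flag | noc$q_flag), 0.2)
  }
})
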