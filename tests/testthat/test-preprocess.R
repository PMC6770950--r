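test_that("batch files round-trip to full precision and reject malformed input", {
  gt <- small_truth(noise_sd = 0.003, n_wn = 40)
  b <- simulate_batch(gt, seed = 2, batch_id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_batch(b, path)
  b2 <- read_batch(path)
  expect_equal(b2$absorbance, b$absorbance, tolerance = 1e-12)
  expect_equal(b2$times, b$times)
  expect_equal(b2$wavenumbers, b$wavenumbers)
  expect_identical(b2$meta$batch_id, "rt")

  # a tiny hand-written file parses to its literal values
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,9000,8000,7000",
               "1,0.1,0.2,0.3",
               "2,0.4,0.5,0.6"), tiny)
  tb <- read_batch(tiny)
  expect_equal(tb$absorbance, rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)))
  expect_equal(tb$wavenumbers, c(9000, 8000, 7000))

  # errors name the offending location
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,9000,8000", "1,0.1,oops", "2,0.3,0.4"), bad)
  expect_error(read_batch(bad), "row 1, column 3")
  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,9000,8000", "1,0.1", "2,0.3,0.4"), ragged)
  expect_error(read_batch(ragged), "row 2")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,9000,9000", "1,0.1,0.2"), dup)
  expect_error(read_batch(dup), "Duplicate wavenumber")
})

test_that("range reduction keeps exactly the closed-interval columns in order", {
  b <- spectral_batch(1:5, c(4000, 5824, 6000, 12500),
                      matrix(1:20, 5, 4), list())
  r <- reduce_range(b, 5824, 12500)
  expect_equal(r$wavenumbers, c(5824, 6000, 12500))
  single <- reduce_range(b, 6900 - 1000, 6900 - 900)
  expect_equal(single$wavenumbers, 6000)
  expect_error(reduce_range(b, 1000, 2000), "No wavenumbers")

  # the default bounds drop the noisy low-wavenumber region of the
  # full instrument grid
  full <- small_truth(noise_sd = 0)
  fb <- simulate_batch(
    ground_truth(kinetic_params(), grid = default_wavenumber_grid(full = TRUE),
                 noise_sd = 0), seed = 1)
  red <- reduce_range(fb)
  expect_true(all(red$wavenumbers >= 5824))
  expect_equal(length(red$wavenumbers), 1730L)

  # nested reductions collapse to the tighter one
  b2 <- reduce_range(reduce_range(fb, 5000, 12500), 6000, 11000)
  expect_equal(b2$wavenumbers, reduce_range(fb, 6000, 11000)$wavenumbers)
})

test_that("SNV standardizes each spectrum and is row-local", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(11)
  X <- matrix(rnorm(20 * 50, mean = 2), 20)
  S <- snv(X)
  expect_equal(rowMeans(S), rep(0, 20), tolerance = 1e-10)
  expect_equal(apply(S, 1, sd), rep(1, 20), tolerance = 1e-10)
  # idempotent on standardized rows
  expect_equal(snv(S), S, tolerance = 1e-10)
  # commutes with row permutation
  perm <- sample(20)
  expect_equal(snv(X[perm, ]), S[perm, ])
  expect_error(snv(matrix(c(1, 1, 1, 2, 3, 4), 2, byrow = TRUE)), "Row 1")
})

test_that("mean centering is exact, idempotent and invertible", {
  X <- cbind(c(1, 3), c(10, 20))
  mc <- mean_center(X)
  expect_equal(mc$centered[, 1], c(-1, 1))
  expect_equal(mc$column_means, c(2, 15))
  expect_equal(mean_center(mc$centered)$centered, mc$centered)
  expect_equal(sweep(mc$centered, 2, mc$column_means, `+`), X,
               tolerance = 1e-12)
})

test_that("augmentation stacks batches recoverably and rejects grid mismatches", {
  gt <- small_truth(noise_sd = 0.003, n_wn = 25)
  batches <- lapply(1:6, function(s) simulate_batch(gt, seed = s,
                                                    batch_id = paste0("b", s)))
  set <- augment(batches)
  expect_equal(dim(set$absorbance), c(180L, 25L))
  expect_equal(set$layout$start_row, seq(1L, 151L, by = 30L))
  expect_equal(set$layout$end_row, seq(30L, 180L, by = 30L))
  for (i in 1:6) {
    expect_equal(set$absorbance[batch_rows(set, i), ],
                 batches[[i]]$absorbance)
  }
  # restacking the slices reproduces the matrix
  expect_equal(do.call(rbind, lapply(1:6, function(i)
    set$absorbance[batch_rows(set, i), ])), set$absorbance)

  one <- augment(batches[1])
  expect_equal(one$absorbance, batches[[1]]$absorbance)

  other <- simulate_batch(small_truth(noise_sd = 0.003, n_wn = 26), seed = 1)
  expect_error(augment(list(batches[[1]], other)), "grid differs")
})
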