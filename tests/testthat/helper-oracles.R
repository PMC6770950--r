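# Independent brute-force oracles used to pin down the constrained
# least-squares machinery, plus small fixture builders.

# Non-negative least squares min ||A x - b||, x >= 0, by enumerating every
# subset of variables clamped to zero and keeping the best feasible
# candidate. Exponential in ncol(A); fine for toy problems.
brute_nnls <- function(A, b) {
  p <- ncol(A)
  best <- NULL
  best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) == 0)
    x <- numeric(p)
    if (length(free)) {
      sol <- tryCatch(qr.solve(A[, free, drop = FALSE], b),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (any(x < -1e-12)) next
    rss <- sum((A %*% pmax(x, 0) - b)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- pmax(x, 0)
    }
  }
  best
}

# Least-squares unimodal fit of a short vector by exhaustive search over
# the quadratic program: every peak position x every active set of the
# adjacent-order constraints (active constraint = adjacent equality, i.e.
# pooled group solved by its mean). The optimum is the best feasible
# candidate over all enumerations.
brute_unimodal <- function(x, peak = NULL) {
  n <- length(x)
  peaks <- if (is.null(peak)) seq_len(n) else peak
  best <- x
  best_rss <- Inf
  for (m in peaks) {
    for (mask in 0:(2^(n - 1) - 1)) {
      active <- bitwAnd(mask, 2^(seq_len(n - 1) - 1)) != 0
      groups <- cumsum(c(1, !active))
      y <- stats::ave(x, groups)
      d <- diff(y)
      up_ok <- all(d[seq_len(m - 1)] >= -1e-12)
      down_ok <- m > n - 1 || all(d[m:(n - 1)] <= 1e-12)
      if (up_ok && down_ok) {
        rss <- sum((y - x)^2)
        if (rss < best_rss - 1e-12) {
          best_rss <- rss
          best <- y
        }
      }
    }
  }
  best
}

# Small ground truth on a coarse wavenumber grid to keep matrix sizes down.
small_truth <- function(transition_time = 7, noise_sd = 0, n_wn = 300,
                        steepness = 1, ...) {
  ground_truth(
    kinetic_params(transition_time = transition_time, steepness = steepness,
                   ...),
    times = 1:30,
    grid = seq(12500, 5824, length.out = n_wn),
    noise_sd = noise_sd
  )
}
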