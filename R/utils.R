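# Internal helpers shared across modules.

# Evaluate `code` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so simulation functions are pure in their seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

abort_bad_arg <- function(msg) {
  stop(msg, call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  ok_low <- if (closed_lower) x >= lower else x > lower
  ok_up <- if (closed_upper) x <= upper else x < upper
  if (!ok_low || !ok_up) {
    abort_bad_arg(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pool-adjacent-violators: least-squares non-decreasing fit (unit weights).
pava_increasing <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  vals <- x
  wts <- rep(1, n)
  len <- 0L
  v <- numeric(n)
  w <- numeric(n)
  for (i in seq_len(n)) {
    len <- len + 1L
    v[len] <- vals[i]
    w[len] <- 1
    while (len > 1L && v[len - 1L] > v[len]) {
      v[len - 1L] <- (w[len - 1L] * v[len - 1L] + w[len] * v[len]) /
        (w[len - 1L] + w[len])
      w[len - 1L] <- w[len - 1L] + w[len]
      len <- len - 1L
    }
  }
  out <- numeric(0)
  for (k in seq_len(len)) out <- c(out, rep(v[k], w[k]))
  out
}

# Count strict local maxima of a vector (plateaus collapse to one peak).
n_local_maxima <- function(x) {
  y <- rle(x)$values
  if (length(y) == 1L) return(1L)
  d <- sign(diff(y))
  peaks <- 0L
  if (d[1] < 0) peaks <- peaks + 1L        # boundary peak at the start
  if (length(d) > 1L) {
    peaks <- peaks + sum(d[-length(d)] > 0 & d[-1] < 0)
  }
  if (d[length(d)] > 0) peaks <- peaks + 1L # boundary peak at the end
  peaks
}

is_unimodal <- function(x, tol = 0) {
  if (tol > 0) x <- round(x / tol) * tol
  n_local_maxima(x) <= 1L
}
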