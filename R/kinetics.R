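#' Sol-gel transition time from resolved concentration profiles
#'
#' The spectroscopic transition time of a batch is the time at which the
#' transition-phase concentration profile — the component whose profile is
#' a unimodal pulse with an interior peak — reaches its maximum. Component
#' order in a curve-resolution model is arbitrary, so the pulse component
#' is identified operationally: the column whose peak stands highest above
#' its endpoint values (relative pulse score), earliest interior peak
#' breaking ties. The discrete peak is refined to sub-grid resolution by a
#' parabola through the peak and its two neighbours, which is how
#' fractional transition times arise from spectra acquired once per
#' minute.
#'
#' @param model An [mcr_als()] model.
#' @param batch Batch index or id within the model's layout, or `NULL` for
#'   all batches.
#' @return A tibble with one row per batch: `batch_id`, `component` (the
#'   pulse column), `cp2_min` (refined peak time), `on_boundary` (`TRUE`
#'   with a warning when no interior-peaked pulse exists and the boundary
#'   time is returned).
#' @export
transition_time <- function(model, batch = NULL) {
  stopifnot(inherits(model, "mcr_model"))
  if (ncol(model$C) < 2L) abort_bad_arg("Model needs at least 2 components.")
  idx <- if (is.null(batch)) seq_len(nrow(model$layout)) else batch
  if (is.character(idx)) idx <- match(idx, model$layout$batch_id)
  purrr::map_dfr(idx, function(i) {
    rows <- seq(model$layout$start_row[i], model$layout$end_row[i])
    Cb <- model$C[rows, , drop = FALSE]
    tb <- model$times[rows]
    scores <- apply(Cb, 2, function(col) {
      p <- which.max(col)
      if (p == 1L || p == length(col)) return(-Inf)
      rng <- max(col) - min(col)
      if (rng <= 0) return(-Inf)
      (col[p] - max(col[1], col[length(col)])) / rng
    })
    if (all(!is.finite(scores)) || max(scores) <= 0.05) {
      # no interior-peaked pulse: fall back to the best column's boundary
      j <- which.max(apply(Cb, 2, max))
      p <- which.max(Cb[, j])
      warning(sprintf(
        "Batch '%s': no interior-peaked transition profile; returning boundary time.",
        model$layout$batch_id[i]), call. = FALSE)
      return(tibble::tibble(batch_id = model$layout$batch_id[i],
                            component = colnames(Cb)[j], cp2_min = tb[p],
                            on_boundary = TRUE))
    }
    j <- which.max(scores)
    col <- Cb[, j]
    p <- which.max(col)
    cp2 <- parabolic_peak(tb[(p - 1):(p + 1)], col[(p - 1):(p + 1)])
    tibble::tibble(batch_id = model$layout$batch_id[i],
                   component = colnames(Cb)[j], cp2_min = cp2,
                   on_boundary = FALSE)
  })
}

# Vertex of the parabola through three (t, y) points.
parabolic_peak <- function(t, y) {
  fit <- stats::lm.fit(cbind(1, t, t^2), y)
  a2 <- fit$coefficients[3]
  if (!is.finite(a2) || a2 >= 0) return(t[2])
  unname(-fit$coefficients[2] / (2 * a2))
}

#' Fit the logistic time-curing model to an elastic-modulus curve
#'
#' Nonlinear least squares fit of `G'(t) = a / (1 + exp(-(t - b) / c))`
#' via Levenberg-Marquardt. Starting values are data-driven: `a` from the
#' maximum, `b` from the half-maximum crossing, and `c` from the
#' inter-quartile rise time divided by `log(9)` (the exact value for a
#' noiseless logistic).
#'
#' @param curve A [simulate_rheology()] tibble, or any data frame with
#'   time and G' columns.
#' @param time,g_prime Column names (tidy-select style strings) holding
#'   time (min) and elastic modulus (Pa).
#' @return An object of class `sigmoid_fit` with `a`, `b`, `c`, `rss`,
#'   `n`, `fitted`, `data`.
#' @export
fit_sigmoid <- function(curve, time = "time_min", g_prime = "g_prime") {
  t <- curve[[time]]
  y <- curve[[g_prime]]
  if (length(t) < 4L) abort_bad_arg("Need at least 4 points to fit the sigmoid.")
  rng <- max(y) - min(y)
  if (rng <= 1e-8 * max(abs(y), 1)) {
    abort_bad_arg("Curve is flat; the sigmoid model is not identifiable.")
  }
  a0 <- max(y)
  b0 <- t[which.min(abs(y - a0 / 2))]
  t25 <- t[which.min(abs(y - 0.25 * a0))]
  t75 <- t[which.min(abs(y - 0.75 * a0))]
  c0 <- max((t75 - t25) / log(9), 0.25 * mean(diff(t)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a / (1 + exp(-(t - b) / cc)),
      start = list(a = a0, b = b0, cc = c0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort_bad_arg(sprintf(
        "Sigmoid fit did not converge (%s); starting values were a = %g, b = %g, c = %g.",
        conditionMessage(e), a0, b0, c0))
    }
  )
  p <- stats::coef(fit)
  structure(
    list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["cc"]),
         rss = sum(stats::resid(fit)^2), n = length(t),
         fitted = stats::fitted(fit),
         data = tibble::tibble(time_min = t, g_prime = y)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> a = %.4g Pa, b = %.4g min, c = %.4g min",
              x$a, x$b, x$c))
  if (is.finite(x$rss)) cat(sprintf(", rss = %.4g", x$rss))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c),
                 unit = c("Pa", "min", "min"))
}

#' @exportS3Method generics::glance
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, rss = x$rss, n = x$n)
}

#' Kinetic critical times of a logistic curing curve
#'
#' For `y = a / (1 + exp(-(t - b) / c))` with `c > 0`, the first
#' derivative peaks at the midpoint `b` (maximum curing rate) and the
#' second derivative has its maximum at `b - c * log(2 + sqrt(3))`
#' (acceleration time, the onset of fast gelation, `AT_G'`) and its
#' minimum at `b + c * log(2 + sqrt(3))` (deceleration time); the three
#' are symmetric about `b`.
#'
#' @param fit A [fit_sigmoid()] or [sigmoid_params()] object with `c > 0`.
#' @return A one-row tibble: `acceleration_time`, `max_rate_time`,
#'   `deceleration_time` (minutes).
#' @export
critical_times <- function(fit) {
  if (!is.numeric(fit$c) || fit$c <= 0) {
    abort_bad_arg("Critical times require a growing curve (`c` > 0).")
  }
  off <- fit$c * log(2 + sqrt(3))
  tibble::tibble(
    acceleration_time = fit$b - off,
    max_rate_time = fit$b,
    deceleration_time = fit$b + off
  )
}

#' Pearson correlation with t-based significance
#'
#' Standard Pearson correlation between two equal-length vectors with the
#' two-sided p-value from the t transform on `n - 2` degrees of freedom,
#' used to compare spectroscopic transition times against rheological
#' acceleration times across batches.
#'
#' @param x,y Numeric vectors, equal length `n >= 3`, non-constant.
#' @return A one-row tibble: `r`, `p_value`, `n`, `t_statistic`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort_bad_arg("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort_bad_arg("Need at least 3 pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_bad_arg("Correlation is undefined for a constant vector.")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), t_statistic = unname(ct$statistic))
}

#' Correlate spectroscopic and rheological transition times
#'
#' Convenience wrapper: takes a data frame with one row per batch and
#' correlates the curve-resolution transition time against the
#' rheological acceleration time.
#'
#' @param data Data frame with the two columns.
#' @param cp2,at_gprime Column names.
#' @return A one-row tibble from [pearson_cor()].
#' @export
transition_correlation <- function(data, cp2 = "cp2_min",
                                   at_gprime = "at_gprime_min") {
  pearson_cor(data[[cp2]], data[[at_gprime]])
}

#' Reference transition times for fifteen renneting batches
#'
#' A published comparison of spectroscopic and rheological sol-gel
#' transition times for fifteen milk renneting batches spanning three
#' coagulation temperatures (30, 35, 40 degC), three pH levels (6.3, 6.5,
#' 6.7) and three fat contents (0.1, 2.55, 5 g/100 mL), including three
#' replicates of the centre-point condition. `cp2_min` is the time of the
#' maximum of the transition-phase concentration profile resolved from
#' in-line FT-NIR spectra; `at_gprime_min` is the acceleration time of the
#' elastic modulus extrapolated from sigmoid-fitted time-curing curves.
#' The two measures are strongly correlated, with the spectroscopic time
#' always leading the rheological one by a few minutes.
#'
#' @return A tibble with columns `batch`, `sample_id`, `temperature_c`,
#'   `fat_g_100ml`, `ph`, `cp2_min`, `at_gprime_min`.
#' @export
renneting_reference_times <- function() {
  path <- system.file("extdata", "renneting_reference_times.csv",
                      package = "rennetpat", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
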