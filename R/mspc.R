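#' Build a PCA-based multivariate control chart
#'
#' Trains a control chart on in-control concentration profiles: each
#' observation is the vector of `F` concentration values at one time
#' point, pooled over the training batches. PCA is fitted to the
#' mean-centered observations (sample covariance, `n - 1` denominator)
#' and two monitoring statistics are derived:
#'
#' * Hotelling's T-squared over the `K` retained components, with the
#'   small-sample F-distribution limit for future observations,
#'   `K (n - 1) (n + 1) / (n (n - K)) * qf(confidence, K, n - K)`
#'   (a large-sample chi-squared limit is available via `t2_method`);
#' * the Q statistic (squared residual distance from the model plane),
#'   with the Jackson-Mudholkar limit from the discarded eigenvalues,
#'   falling back to a moment-matched chi-squared (`g * chisq(h)`) when
#'   the Jackson-Mudholkar exponent is degenerate. When no residual
#'   variance exists (`K` equals the data rank) the Q limit is 0 and
#'   `zero_residual_variance` is flagged.
#'
#' @param train_c Matrix of training observations (rows = time points,
#'   columns = components), `nrow > K`; or an `mcr_model`, in which case
#'   `train_batches` selects which layout batches to train on.
#' @param k Retained components.
#' @param confidence Confidence level for both limits, in (0, 1).
#' @param t2_method `"f"` (small-sample, default) or `"chisq"`.
#' @param train_batches Batch ids/indices when `train_c` is an
#'   `mcr_model`.
#' @return An object of class `control_chart`: `train_mean`, `loadings`
#'   (`F x K`), `eigenvalues` (all), `t2_limit`, `q_limit`, `confidence`,
#'   `k`, `n_train`, `t2_method`, `q_method`, `zero_residual_variance`.
#' @export
build_control_chart <- function(train_c, k = 1, confidence = 0.99,
                                t2_method = c("f", "chisq"),
                                train_batches = NULL) {
  t2_method <- match.arg(t2_method)
  if (inherits(train_c, "mcr_model")) {
    rows <- unlist(lapply(train_batches, function(b) {
      i <- if (is.character(b)) match(b, train_c$layout$batch_id) else b
      seq(train_c$layout$start_row[i], train_c$layout$end_row[i])
    }))
    train_c <- train_c$C[rows, , drop = FALSE]
  }
  train_c <- as.matrix(train_c)
  n <- nrow(train_c)
  f <- ncol(train_c)
  check_number(confidence, "confidence", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  if (k < 1L || k > f) abort_bad_arg(sprintf("`k` must be between 1 and %d.", f))
  if (k >= n) abort_bad_arg("`k` must be smaller than the number of training observations.")
  mu <- colMeans(train_c)
  xc <- sweep(train_c, 2, mu)
  sv <- svd(xc, nu = 0)
  lambda <- sv$d^2 / (n - 1)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  t2_limit <- if (t2_method == "f") {
    k * (n - 1) * (n + 1) / (n * (n - k)) * stats::qf(confidence, k, n - k)
  } else {
    stats::qchisq(confidence, k)
  }
  disc <- lambda[-seq_len(k)]
  disc <- disc[disc > .Machine$double.eps * lambda[1]]
  zero_resid <- length(disc) == 0L
  if (zero_resid) {
    q_limit <- 0
    q_method <- "none"
  } else {
    th1 <- sum(disc); th2 <- sum(disc^2); th3 <- sum(disc^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (is.finite(h0) && h0 > 0) {
      z <- stats::qnorm(confidence)
      q_limit <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                          1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
      q_method <- "jackson_mudholkar"
    } else {
      g <- th2 / th1
      h <- th1^2 / th2
      q_limit <- g * stats::qchisq(confidence, h)
      q_method <- "moment_chisq"
    }
  }
  structure(
    list(train_mean = mu, loadings = loadings, eigenvalues = lambda,
         t2_limit = t2_limit, q_limit = q_limit, confidence = confidence,
         k = k, n_train = n, t2_method = t2_method, q_method = q_method,
         zero_residual_variance = zero_resid),
    class = "control_chart"
  )
}

#' @export
print.control_chart <- function(x, ...) {
  cat(sprintf(
    "<control_chart> K = %d of %d components, n_train = %d, %.0f%% limits\n",
    x$k, length(x$train_mean), x$n_train, 100 * x$confidence))
  cat(sprintf("  T2 limit: %.4g (%s)   Q limit: %.4g (%s)\n",
              x$t2_limit, x$t2_method, x$q_limit, x$q_method))
  cat(sprintf("  retained variance: %.1f%%\n",
              100 * sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues)))
  invisible(x)
}

#' Monitor a batch against a control chart
#'
#' Projects each observation (row of concentration values) onto the
#' chart's PCA model and computes, per time point, Hotelling's T-squared
#' over the retained scores (`sum(score_k^2 / lambda_k)`) and the Q
#' statistic (squared norm of the reconstruction residual). A point is
#' flagged off-control when its statistic exceeds the chart limit.
#'
#' Monitored profiles must come from the same curve-resolution model as
#' the training profiles (shared spectral profiles), so that components
#' align by construction; a column-count mismatch is refused.
#'
#' @param chart A [build_control_chart()].
#' @param test_c Matrix of observations with the training column count, or
#'   an `mcr_model` plus `batch`.
#' @param times Optional time axis for the output.
#' @param batch_id Identifier attached to the result.
#' @param batch Batch id/index when `test_c` is an `mcr_model`.
#' @return A tibble of class `monitoring_result`: `batch_id`, `time_min`,
#'   `t2`, `q`, `t2_flag`, `q_flag`.
#' @export
monitor_batch <- function(chart, test_c, times = NULL, batch_id = "batch",
                          batch = NULL) {
  stopifnot(inherits(chart, "control_chart"))
  if (inherits(test_c, "mcr_model")) {
    stopifnot(!is.null(batch))
    i <- if (is.character(batch)) match(batch, test_c$layout$batch_id) else batch
    rows <- seq(test_c$layout$start_row[i], test_c$layout$end_row[i])
    if (is.null(times)) times <- test_c$times[rows]
    if (identical(batch_id, "batch")) batch_id <- test_c$layout$batch_id[i]
    test_c <- test_c$C[rows, , drop = FALSE]
  }
  test_c <- as.matrix(test_c)
  f <- length(chart$train_mean)
  if (ncol(test_c) != f) {
    abort_bad_arg(sprintf(
      "Monitored profiles have %d columns but the chart was trained on %d components; cross-model monitoring requires an explicit column mapping.",
      ncol(test_c), f))
  }
  xc <- sweep(test_c, 2, chart$train_mean)
  scores <- xc %*% chart$loadings
  lam <- chart$eigenvalues[seq_len(chart$k)]
  t2 <- as.vector(scores^2 %*% (1 / lam))
  resid <- xc - scores %*% t(chart$loadings)
  q <- rowSums(resid^2)
  out <- tibble::tibble(
    batch_id = batch_id,
    time_min = if (is.null(times)) seq_len(nrow(test_c)) else as.numeric(times),
    t2 = t2, q = q,
    t2_flag = t2 > chart$t2_limit,
    q_flag = q > chart$q_limit
  )
  class(out) <- c("monitoring_result", class(out))
  attr(out, "chart") <- chart
  out
}

#' Plot a monitoring result
#'
#' T-squared and Q trajectories against their control limits.
#'
#' @param object A [monitor_batch()] result (or several row-bound ones).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.monitoring_result <- function(object, ...) {
  chart <- attr(object, "chart")
  dat <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("t2", "q"),
    names_to = "statistic", values_to = "value")
  dat$statistic <- toupper(dat$statistic)
  lims <- tibble::tibble(statistic = c("T2", "Q"),
                         limit = c(chart$t2_limit, chart$q_limit))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$time_min, y = .data$value, colour = .data$batch_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$limit),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Statistic", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pooled detection performance of control charts
#'
#' Pools the monitored time points of several batches and computes a
#' confusion matrix per chart rule — `t2`, `q`, and the combined
#' `either`-flag rule — treating every point of a fault batch as a true
#' positive target and every point of an in-control batch as a true
#' negative target. Sensitivity is `tp / (tp + fn)` and specificity
#' `tn / (tn + fp)`; a rate with an empty denominator is reported as `NA`.
#'
#' @param results List of [monitor_batch()] results (or one row-bound
#'   tibble with a `batch_id` column).
#' @param labels Named logical vector (or logical vector in batch order):
#'   `TRUE` for fault batches.
#' @return A tibble with columns `chart`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
chart_performance <- function(results, labels) {
  if (inherits(results, "data.frame")) {
    results <- split(tibble::as_tibble(results), results$batch_id)
    results <- results[unique(names(results))]
  }
  if (length(results) != length(labels)) {
    abort_bad_arg("`labels` must have one entry per monitored batch.")
  }
  if (!is.null(names(labels))) {
    ids <- vapply(results, function(r) r$batch_id[1], character(1))
    labels <- labels[ids]
    if (anyNA(labels)) abort_bad_arg("`labels` names do not match batch ids.")
  }
  pooled <- dplyr::bind_rows(purrr::map2(results, labels, function(r, lab) {
    dplyr::mutate(tibble::as_tibble(r), fault = lab)
  }))
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  purrr::map_dfr(
    list(t2 = "t2_flag", q = "q_flag", either = "either"),
    .id = "chart",
    function(colname) {
      flag <- if (colname == "either") {
        pooled$t2_flag | pooled$q_flag
      } else {
        pooled[[colname]]
      }
      tp <- sum(flag & pooled$fault)
      fp <- sum(flag & !pooled$fault)
      tn <- sum(!flag & !pooled$fault)
      fn <- sum(!flag & pooled$fault)
      tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                     sensitivity = rate(tp, tp + fn),
                     specificity = rate(tn, tn + fp))
    }
  )
}

#' Serialize a control chart to JSON
#'
#' @param chart A [build_control_chart()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_control_chart <- function(chart, path) {
  stopifnot(inherits(chart, "control_chart"))
  jsonlite::write_json(
    list(train_mean = chart$train_mean,
         loadings = as.data.frame(chart$loadings),
         eigenvalues = chart$eigenvalues,
         t2_limit = chart$t2_limit, q_limit = chart$q_limit,
         confidence = chart$confidence, k = chart$k,
         n_train = chart$n_train, t2_method = chart$t2_method,
         q_method = chart$q_method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
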