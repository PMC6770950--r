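#' Lack of fit between a matrix and its reconstruction
#'
#' `LOF (%) = 100 * sqrt(sum((D - D_hat)^2) / sum(D^2))`, the standard
#' figure of merit for bilinear curve resolution: the root residual sum of
#' squares as a percentage of the root total sum of squares of the data.
#'
#' @param d Data matrix.
#' @param d_hat Reconstruction, same shape.
#' @return Percentage, zero iff `d_hat` equals `d`.
#' @examples
#' lof(matrix(c(3, 4), 1), matrix(c(3, 0), 1)) # 80
#' @export
lof <- function(d, d_hat) {
  d <- as.matrix(d); d_hat <- as.matrix(d_hat)
  if (!all(dim(d) == dim(d_hat))) abort_bad_arg("`d` and `d_hat` must have the same shape.")
  ss <- sum(d^2)
  if (ss == 0) abort_bad_arg("`d` is all zero; LOF is undefined.")
  100 * sqrt(sum((d - d_hat)^2) / ss)
}

#' Project a vector onto the unimodal cone
#'
#' Least-squares projection onto sequences that are non-decreasing up to
#' the peak index and non-increasing after it, computed by
#' pool-adjacent-violators on the ascending and descending segments. The
#' peak index defaults to the argmax of the input (ties broken toward the
#' earlier time point), in which case the projection is exact and
#' idempotent; already-unimodal inputs pass through unchanged.
#'
#' @param x Numeric vector, finite entries.
#' @param peak Peak index; default `which.max(x)`.
#' @return Unimodal vector of the same length.
#' @export
enforce_unimodality <- function(x, peak = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_bad_arg("`x` must be finite numeric.")
  }
  n <- length(x)
  if (n <= 2L) return(x)
  p <- if (is.null(peak)) which.max(x) else as.integer(peak)
  if (p < 1L || p > n) abort_bad_arg("`peak` out of range.")
  up <- pava_increasing(x[seq_len(p)])
  down <- rev(pava_increasing(rev(x[p:n])))
  vp <- max(up[p], down[1])
  c(pmin(up[seq_len(max(p - 1L, 0L))], vp), vp,
    if (p < n) pmin(down[-1], vp))
}

#' Constraint and convergence settings for MCR-ALS
#'
#' @param nonneg_c Non-negativity on concentration profiles (on, as is
#'   physically required of phase fractions).
#' @param unimodal_c Unimodality on each concentration column (within each
#'   batch segment of an augmented set), resolving rotational ambiguity in
#'   transient-intermediate kinetics.
#' @param nonneg_s Non-negativity on spectral profiles. Off by default:
#'   the fitted data are usually SNV-transformed, whose values (and hence
#'   pure profiles) are legitimately negative.
#' @param s_normalization `"unit_length"` rescales each spectral profile to
#'   Euclidean norm 1 after its update, absorbing the inverse scale into
#'   the concentrations so the reconstruction is unchanged; `"none"` leaves
#'   the scale ambiguity alone.
#' @param lof_rel_tol Convergence tolerance on the lack of fit, percent.
#'   With `tol_mode = "relative"` (default) iteration stops when
#'   `|LOF_k - LOF_(k-1)| / LOF_(k-1) < lof_rel_tol / 100`, i.e. the
#'   default 0.1 stops at a 0.1% relative change; with `"absolute"` it
#'   stops when the LOF changes by fewer than `lof_rel_tol` percentage
#'   points.
#' @param tol_mode `"relative"` or `"absolute"`.
#' @param max_iterations Iteration cap (default 50).
#' @return A list of class `mcr_config`.
#' @export
mcr_config <- function(nonneg_c = TRUE, unimodal_c = TRUE, nonneg_s = FALSE,
                       s_normalization = c("unit_length", "none"),
                       lof_rel_tol = 0.1,
                       tol_mode = c("relative", "absolute"),
                       max_iterations = 50L) {
  check_number(lof_rel_tol, "lof_rel_tol", 0, Inf, closed_lower = FALSE)
  check_number(max_iterations, "max_iterations", 1, Inf)
  structure(
    list(nonneg_c = isTRUE(nonneg_c), unimodal_c = isTRUE(unimodal_c),
         nonneg_s = isTRUE(nonneg_s),
         s_normalization = match.arg(s_normalization),
         lof_rel_tol = lof_rel_tol, tol_mode = match.arg(tol_mode),
         max_iterations = as.integer(max_iterations)),
    class = "mcr_config"
  )
}

# Row-wise nonnegative least squares: min ||d_i - A x||, x >= 0, for each
# row d_i of B (rows = observations). Unconstrained rows that already
# satisfy the constraint skip the active-set solver.
nnls_rows <- function(A, B) {
  xtx <- crossprod(A)
  unc <- t(solve(xtx, crossprod(A, t(B))))
  bad <- which(apply(unc, 1, function(r) any(r < 0)))
  for (i in bad) {
    unc[i, ] <- pracma::lsqnonneg(A, B[i, ])$x
  }
  unc
}

#' Constrained least-squares update of the concentration profiles
#'
#' Given data `D` and spectral profiles `S^T`, computes each row of `C` as
#' the least-squares solution of `d = S c`, with non-negativity imposed by
#' an active-set solver, then (optionally) projects each column onto the
#' unimodal cone within each batch segment. Constraints are applied
#' sequentially, the common toolbox behaviour.
#'
#' @param d Data matrix, `M x N`.
#' @param s_t Spectral profiles, `F x N`, full row rank.
#' @param nonneg,unimodal Constraint switches.
#' @param layout Optional tibble with `start_row` / `end_row` delimiting
#'   batch segments of an augmented matrix; unimodality is enforced within
#'   each segment separately.
#' @return `M x F` concentration matrix.
#' @export
solve_concentrations <- function(d, s_t, nonneg = TRUE, unimodal = TRUE,
                                 layout = NULL) {
  d <- as.matrix(d); s_t <- as.matrix(s_t)
  f <- nrow(s_t)
  if (qr(s_t)$rank < f) abort_bad_arg("`s_t` is rank deficient.")
  s <- t(s_t)
  C <- if (nonneg) {
    nnls_rows(s, d)
  } else {
    t(solve(crossprod(s), crossprod(s, t(d))))
  }
  if (unimodal) {
    segs <- if (is.null(layout)) {
      list(seq_len(nrow(C)))
    } else {
      lapply(seq_len(nrow(layout)),
             function(i) seq(layout$start_row[i], layout$end_row[i]))
    }
    for (rows in segs) {
      for (j in seq_len(ncol(C))) {
        C[rows, j] <- enforce_unimodality(C[rows, j])
      }
    }
  }
  C
}

#' Constrained least-squares update of the spectral profiles
#'
#' Given data `D` and concentrations `C`, computes the least-squares
#' `S^T`, optionally non-negative (column-wise active set). With
#' `normalization = "unit_length"` each spectral profile is rescaled to
#' unit Euclidean norm and the inverse scale is absorbed into `C`, so the
#' product `C S^T` is unchanged; both adjusted matrices are returned.
#'
#' @param d Data matrix, `M x N`.
#' @param c_mat Concentrations, `M x F`, full column rank.
#' @param nonneg Non-negativity on the spectra.
#' @param normalization `"unit_length"` or `"none"`.
#' @return List with `s_t` (`F x N`) and `c_mat` (rescaled to match).
#' @export
solve_spectra <- function(d, c_mat, nonneg = FALSE,
                          normalization = c("unit_length", "none")) {
  normalization <- match.arg(normalization)
  d <- as.matrix(d); c_mat <- as.matrix(c_mat)
  f <- ncol(c_mat)
  if (qr(c_mat)$rank < f) abort_bad_arg("`c_mat` is rank deficient.")
  s_t <- if (nonneg) {
    t(nnls_rows(c_mat, t(d)))
  } else {
    solve(crossprod(c_mat), crossprod(c_mat, d))
  }
  if (normalization == "unit_length") {
    nrm <- sqrt(rowSums(s_t^2))
    nrm[nrm == 0] <- 1
    s_t <- s_t / nrm
    c_mat <- c_mat * rep(nrm, each = nrow(c_mat))
  }
  list(s_t = s_t, c_mat = c_mat)
}

#' Multivariate curve resolution by alternating least squares
#'
#' Decomposes a time-resolved spectral matrix `D` (`M x N`) into
#' `D = C S^T + E`: `F` concentration profiles `C` (`M x F`) describing how
#' each coagulation phase waxes and wanes over time, and `F` spectral
#' profiles `S^T` (`F x N`). Starting from non-random initial spectra
#' (typically [select_pure_spectra()]), the algorithm alternates the
#' constrained updates [solve_concentrations()] and [solve_spectra()],
#' monitoring the lack of fit ([lof()]) after every full cycle, and stops
#' when the LOF change between consecutive cycles falls below the
#' configured tolerance or the iteration cap is reached. Five consecutive
#' LOF increases abort the fit with a diagnostic error.
#'
#' For a `batch_set`, one model with a single shared `S^T` is fitted to
#' the row-wise augmented matrix, and unimodality is enforced within each
#' batch's segment separately.
#'
#' @param x Data: numeric matrix, [spectral_batch()] or [augment()]
#'   result.
#' @param initial_s_t Initial spectral estimates, `F x N` with `F`
#'   independent rows, or a `purity_result`.
#' @param config An [mcr_config()].
#' @param layout Optional segment layout (taken from the `batch_set` when
#'   `x` is one).
#' @return An object of class `mcr_model`: `C`, `S_T`, `lof_history`,
#'   `explained_variance_pct` (`100 * (1 - sum(E^2) / sum(D^2))`),
#'   `residual_sd` (element-wise sample SD of `E`), `iterations`,
#'   `converged`, `layout`, `times`, `wavenumbers`, `config`.
#' @export
mcr_als <- function(x, initial_s_t, config = mcr_config(), layout = NULL) {
  times <- NULL; wavenumbers <- NULL
  if (inherits(x, "spectral_batch")) {
    times <- x$times; wavenumbers <- x$wavenumbers
    x <- x$absorbance
  } else if (inherits(x, "batch_set")) {
    times <- x$times; wavenumbers <- x$wavenumbers
    if (is.null(layout)) layout <- x$layout
    x <- x$absorbance
  }
  x <- as.matrix(x)
  if (inherits(initial_s_t, "purity_result")) initial_s_t <- initial_s_t$initial_S
  s_t <- as.matrix(initial_s_t)
  f <- nrow(s_t)
  if (ncol(s_t) != ncol(x)) {
    abort_bad_arg("`initial_s_t` must have one column per wavenumber.")
  }
  if (qr(s_t)$rank < f) abort_bad_arg("`initial_s_t` rows are not independent.")
  ss_d <- sum(x^2)
  if (ss_d == 0) abort_bad_arg("Data matrix is all zero.")

  lof_history <- numeric(0)
  increases <- 0L
  converged <- FALSE
  iter <- 0L
  C <- NULL
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    C <- solve_concentrations(x, s_t, nonneg = config$nonneg_c,
                              unimodal = config$unimodal_c, layout = layout)
    if (qr(C)$rank < f) {
      abort_bad_arg(paste0(
        "Concentration profiles collapsed to rank ", qr(C)$rank,
        " at iteration ", iter, "; the component count is too high for these data."))
    }
    upd <- solve_spectra(x, C, nonneg = config$nonneg_s,
                         normalization = config$s_normalization)
    s_t <- upd$s_t
    C <- upd$c_mat
    cur <- lof(x, C %*% s_t)
    if (length(lof_history)) {
      prev <- lof_history[length(lof_history)]
      # an increase only counts beyond numerical noise on a non-trivial LOF
      increases <- if (cur > prev * (1 + 1e-9) && cur > 1e-8) increases + 1L else 0L
      if (increases >= 5L) {
        stop(structure(
          class = c("rennetpat_divergence", "error", "condition"),
          list(message = sprintf(
            "MCR-ALS diverging: LOF increased over 5 consecutive iterations (last %.4g%% at iteration %d).",
            cur, iter),
            call = NULL, lof_history = c(lof_history, cur), iterations = iter)
        ))
      }
      delta_ok <- if (config$tol_mode == "relative") {
        prev > 0 && abs(cur - prev) / prev < config$lof_rel_tol / 100
      } else {
        abs(cur - prev) < config$lof_rel_tol
      }
      lof_history <- c(lof_history, cur)
      if (delta_ok || cur < 1e-9) {
        converged <- TRUE
        break
      }
    } else {
      lof_history <- cur
      if (cur < 1e-9) { converged <- TRUE; break }
    }
  }
  E <- x - C %*% s_t
  if (is.null(layout)) {
    layout <- tibble::tibble(batch_id = "batch_1", start_row = 1L,
                             end_row = nrow(x))
  }
  colnames(C) <- paste0("component_", seq_len(f))
  rownames(s_t) <- colnames(C)
  structure(
    list(
      C = C, S_T = s_t,
      lof_history = lof_history,
      explained_variance_pct = 100 * (1 - sum(E^2) / ss_d),
      residual_sd = stats::sd(as.vector(E)),
      iterations = iter,
      converged = converged,
      layout = layout,
      times = if (is.null(times)) seq_len(nrow(x)) else times,
      wavenumbers = if (is.null(wavenumbers)) seq_len(ncol(x)) else wavenumbers,
      config = config
    ),
    class = "mcr_model"
  )
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf(
    "<mcr_model> %d components, %d iterations (%s)\n", ncol(x$C),
    x$iterations, if (x$converged) "converged" else "not converged"))
  cat(sprintf("  explained variance: %.4f%%   LOF: %.4f%%   residual SD: %.3g\n",
              x$explained_variance_pct, utils::tail(x$lof_history, 1),
              x$residual_sd))
  invisible(x)
}

#' Tidy an MCR model
#'
#' @param x An `mcr_model`.
#' @param matrix `"concentrations"` (long tibble: `batch_id`, `time_min`,
#'   `component`, `value`) or `"spectra"` (`component`, `wavenumber`,
#'   `value`).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mcr_model <- function(x, matrix = c("concentrations", "spectra"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "concentrations") {
    batch <- rep(x$layout$batch_id,
                 times = x$layout$end_row - x$layout$start_row + 1L)
    out <- tibble::as_tibble(as.data.frame(x$C))
    out <- dplyr::mutate(out, batch_id = batch, time_min = x$times,
                         .before = 1)
    tidyr::pivot_longer(out, dplyr::starts_with("component_"),
                        names_to = "component", values_to = "value")
  } else {
    out <- tibble::as_tibble(t(x$S_T), .name_repair = ~ rownames(x$S_T))
    out <- dplyr::mutate(out, wavenumber = x$wavenumbers, .before = 1)
    tidyr::pivot_longer(out, dplyr::starts_with("component_"),
                        names_to = "component", values_to = "value")
  }
}

#' @exportS3Method generics::glance
glance.mcr_model <- function(x, ...) {
  tibble::tibble(
    components = ncol(x$C),
    iterations = x$iterations,
    converged = x$converged,
    lof_pct = utils::tail(x$lof_history, 1),
    explained_variance_pct = x$explained_variance_pct,
    residual_sd = x$residual_sd
  )
}

#' Plot resolved profiles
#'
#' @param object An `mcr_model`.
#' @param matrix `"concentrations"` or `"spectra"`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mcr_model <- function(object,
                               matrix = c("concentrations", "spectra"),
                               ...) {
  matrix <- match.arg(matrix)
  dat <- tidy.mcr_model(object, matrix)
  if (matrix == "concentrations") {
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$time_min, y = .data$value,
      colour = .data$component, group = interaction(.data$batch_id, .data$component)
    )) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~batch_id) +
      ggplot2::labs(x = "Time (min)", y = "Concentration (a.u.)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$wavenumber, y = .data$value, colour = .data$component
    )) +
      ggplot2::geom_line() +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                    y = "Spectral intensity (a.u.)", colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Write an MCR model to a directory
#'
#' Writes `C` (with times and batch ids), `S_T` (with wavenumbers),
#' the LOF history and a diagnostics JSON, all as plain text.
#'
#' @param model An `mcr_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mcr_model <- function(model, dir) {
  stopifnot(inherits(model, "mcr_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cdf <- dplyr::bind_cols(
    tibble::tibble(
      batch_id = rep(model$layout$batch_id,
                     times = model$layout$end_row - model$layout$start_row + 1L),
      time_min = model$times
    ),
    tibble::as_tibble(as.data.frame(model$C))
  )
  utils::write.csv(cdf, file.path(dir, "concentrations.csv"),
                   row.names = FALSE, quote = FALSE)
  sdf <- data.frame(wavenumber = model$wavenumbers, t(model$S_T),
                    check.names = FALSE)
  utils::write.csv(sdf, file.path(dir, "spectra.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(iteration = seq_along(model$lof_history),
               lof_pct = model$lof_history),
    file.path(dir, "lof_history.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    as.list(glance.mcr_model(model)),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
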