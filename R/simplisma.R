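#' SIMPLISMA purity of each spectrum
#'
#' Purity of row `i` is `sd_i / (mean_i + alpha * max(mean))`: spectra with
#' high relative variation score as "pure", i.e. dominated by a single
#' underlying component. The offset `alpha` (a fraction of the largest row
#' mean) damps the purity of low-intensity, noise-dominated rows; as
#' `alpha` grows the ordering approaches ordering by standard deviation
#' alone.
#'
#' The formula targets non-negative intensity data. For rows that have
#' been standardized (e.g. SNV-treated spectra, whose means are all zero)
#' the denominator degenerates; it is then floored at a tiny positive
#' value, making the purity essentially flat so that selection in
#' [select_pure_spectra()] is driven by the independence weight alone.
#'
#' @param x Numeric matrix, rows = spectra.
#' @param alpha Non-negative noise offset fraction (default 0.01).
#' @return Numeric vector of purities, one per row, all finite.
#' @export
purity <- function(x, alpha = 0.01) {
  x <- as.matrix(x)
  check_number(alpha, "alpha", 0, Inf)
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  denom <- m + alpha * max(m)
  floor_val <- max(.Machine$double.eps, 1e-12 * max(abs(x)))
  denom[!is.finite(denom) | denom <= floor_val] <- floor_val
  s / denom
}

#' Select pure spectra as curve-resolution starting estimates
#'
#' Iterative SIMPLISMA selection over the rows (spectra) of a batch
#' matrix: the first selection maximizes [purity()]; each subsequent
#' selection maximizes purity weighted by an independence factor — the
#' determinant of the Gram matrix of the unit-normalized candidate and
#' already-selected rows — so duplicates of selected spectra (determinant
#' zero) can never be chosen again. On three-phase renneting data the
#' selections land at the start of the run (liquid milk), near the sol-gel
#' transition, and at the end (set gel), which is what makes them good
#' non-random starting spectra for [mcr_als()].
#'
#' Classical pure-variable detection works on columns; here it is run over
#' rows because the selections are used directly as initial spectral
#' profiles.
#'
#' @param x Numeric matrix (rows = spectra) or [spectral_batch()].
#' @param f Number of spectra to select, `<= nrow(x)`.
#' @param alpha Noise offset, see [purity()].
#' @return An object of class `purity_result`: `selected_indices`,
#'   `selected_times` (when available), `purity_values` (rounds x M
#'   matrix of weighted purities), `initial_S` (`f x N`, verbatim rows of
#'   `x`), `alpha`.
#' @export
select_pure_spectra <- function(x, f = 3, alpha = 0.01) {
  times <- NULL
  if (inherits(x, "spectral_batch")) {
    times <- x$times
    x <- x$absorbance
  }
  x <- as.matrix(x)
  m <- nrow(x)
  if (f < 1L || f > m) abort_bad_arg(sprintf("`f` must be between 1 and %d.", m))
  base_purity <- purity(x, alpha)
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1
  z <- x / norms
  gram <- tcrossprod(z)
  selected <- integer(0)
  purity_values <- matrix(NA_real_, nrow = f, ncol = m)
  for (round in seq_len(f)) {
    w <- vapply(seq_len(m), function(i) {
      if (i %in% selected) return(0)
      idx <- c(selected, i)
      det(gram[idx, idx, drop = FALSE])
    }, numeric(1))
    w <- pmax(w, 0)
    p <- w * base_purity
    purity_values[round, ] <- p
    pick <- which.max(p)
    if (p[pick] <= 0) {
      abort_bad_arg("No linearly independent spectrum left to select; reduce `f`.")
    }
    selected <- c(selected, pick)
  }
  structure(
    list(
      selected_indices = selected,
      selected_times = if (!is.null(times)) times[selected] else NULL,
      purity_values = purity_values,
      initial_S = x[selected, , drop = FALSE],
      alpha = alpha
    ),
    class = "purity_result"
  )
}

#' @export
print.purity_result <- function(x, ...) {
  cat(sprintf("<purity_result> %d spectra selected (alpha = %g)\n",
              length(x$selected_indices), x$alpha))
  cat("  indices:", paste(x$selected_indices, collapse = ", "), "\n")
  if (!is.null(x$selected_times)) {
    cat("  times (min):", paste(x$selected_times, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a purity result to JSON
#'
#' @param result A [select_pure_spectra()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purity_result <- function(result, path) {
  stopifnot(inherits(result, "purity_result"))
  jsonlite::write_json(
    list(
      selected_indices = result$selected_indices,
      selected_times = result$selected_times,
      alpha = result$alpha,
      purity_per_round = apply(result$purity_values, 1, max, na.rm = TRUE)
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
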