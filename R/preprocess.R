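#' Reduce a batch to a spectral range
#'
#' Keeps exactly the wavenumber columns with `low <= wavenumber <= high`
#' (closed interval on values, not indices), preserving column order. The
#' defaults drop the noisy, saturation-prone region below 5,824 cm^-1 that
#' is excluded before modelling.
#'
#' @param batch A [spectral_batch()].
#' @param low,high Interval bounds in cm^-1, `low < high` (equality allowed
#'   for a single-wavenumber selection).
#' @return A `spectral_batch` restricted to the interval.
#' @export
reduce_range <- function(batch, low = 5824, high = 12500) {
  stopifnot(inherits(batch, "spectral_batch"))
  if (low > high) abort_bad_arg("`low` must not exceed `high`.")
  keep <- batch$wavenumbers >= low & batch$wavenumbers <= high
  if (!any(keep)) {
    abort_bad_arg(sprintf("No wavenumbers in [%g, %g].", low, high))
  }
  spectral_batch(batch$times, batch$wavenumbers[keep],
                 batch$absorbance[, keep, drop = FALSE], batch$meta)
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum (row) to mean 0 and sample standard
#' deviation 1 (`n - 1` denominator), the usual correction for
#' multiplicative scatter effects in NIR spectra of turbid media such as
#' coagulating milk. The transform is row-local, so applying it per batch
#' or to a stacked multi-batch matrix gives identical rows.
#'
#' @param x A numeric matrix (rows = spectra) or a [spectral_batch()].
#' @param ... Passed between methods.
#' @return Same shape as the input, SNV-transformed.
#' @export
snv <- function(x, ...) UseMethod("snv")

#' @rdname snv
#' @export
snv.matrix <- function(x, ...) {
  if (ncol(x) < 2L) abort_bad_arg("SNV needs at least two wavenumbers per spectrum.")
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) {
    abort_bad_arg(sprintf(
      "Row %d is constant; SNV would divide by zero.", which(s == 0)[1]))
  }
  (x - m) / s
}

#' @rdname snv
#' @export
snv.spectral_batch <- function(x, ...) {
  spectral_batch(x$times, x$wavenumbers, snv.matrix(x$absorbance), x$meta)
}

#' Column mean-centering
#'
#' Removes the column (per-wavenumber) means, as done before exploratory
#' PCA. Returns both the centered matrix and the means so the operation is
#' exactly invertible.
#'
#' @param x Numeric matrix with at least two rows.
#' @return List with elements `centered` and `column_means`.
#' @export
mean_center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort_bad_arg("Centering needs at least two rows.")
  mu <- colMeans(x)
  list(centered = sweep(x, 2, mu), column_means = mu)
}

#' Stack batches into a row-wise augmented set
#'
#' Concatenates several batches that share one wavenumber grid into a
#' single augmented matrix (rows = all time points in batch order), the
#' arrangement used to fit one curve-resolution model with a shared set of
#' spectral profiles across trials. The layout records where each
#' sub-matrix starts so per-batch segments can be recovered exactly.
#'
#' @param batches List of [spectral_batch()] objects on identical
#'   wavenumber grids.
#' @return An object of class `batch_set`: `absorbance` (stacked matrix),
#'   `wavenumbers`, `times` (stacked), `layout` (tibble with `batch_id`,
#'   `start_row`, `end_row`), `batches` (the inputs).
#' @export
augment <- function(batches) {
  if (!length(batches)) abort_bad_arg("`batches` is empty.")
  stopifnot(all(vapply(batches, inherits, logical(1), "spectral_batch")))
  wn <- batches[[1]]$wavenumbers
  for (i in seq_along(batches)[-1]) {
    wi <- batches[[i]]$wavenumbers
    if (length(wi) != length(wn) || any(wi != wn)) {
      bad <- if (length(wi) != length(wn)) 1L else which(wi != wn)[1]
      abort_bad_arg(sprintf(
        "Batch %d wavenumber grid differs from batch 1 (first mismatch at position %d: %g vs %g).",
        i, bad,
        if (bad <= length(wi)) wi[bad] else NA_real_,
        if (bad <= length(wn)) wn[bad] else NA_real_))
    }
  }
  m <- vapply(batches, function(b) nrow(b$absorbance), integer(1))
  ids <- vapply(seq_along(batches), function(i) {
    id <- batches[[i]]$meta$batch_id
    if (is.null(id)) sprintf("batch_%d", i) else as.character(id)
  }, character(1))
  ends <- cumsum(m)
  layout <- tibble::tibble(
    batch_id = ids,
    start_row = c(1L, utils::head(ends, -1) + 1L),
    end_row = ends
  )
  structure(
    list(
      absorbance = do.call(rbind, lapply(batches, `[[`, "absorbance")),
      wavenumbers = wn,
      times = unlist(lapply(batches, `[[`, "times"), use.names = FALSE),
      layout = layout,
      batches = batches
    ),
    class = "batch_set"
  )
}

#' @export
print.batch_set <- function(x, ...) {
  cat(sprintf("<batch_set> %d batches, %d x %d stacked matrix\n",
              nrow(x$layout), nrow(x$absorbance), ncol(x$absorbance)))
  print(x$layout)
  invisible(x)
}

#' Extract one batch's rows from an augmented matrix
#'
#' @param set A [augment()] result (`batch_set`).
#' @param i Batch index or `batch_id`.
#' @return The rows of the stacked matrix belonging to that batch.
#' @export
batch_rows <- function(set, i) {
  stopifnot(inherits(set, "batch_set"))
  if (is.character(i)) i <- match(i, set$layout$batch_id)
  if (is.na(i) || i < 1 || i > nrow(set$layout)) {
    abort_bad_arg("Unknown batch index or id.")
  }
  seq(set$layout$start_row[i], set$layout$end_row[i])
}
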