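#' A time-resolved spectral batch
#'
#' Container for one renneting batch: `M` absorbance spectra acquired at
#' `times` (minutes) over `N` `wavenumbers` (cm^-1), plus free-form
#' metadata (batch id, operating conditions, fault specification, seed).
#'
#' @param times Numeric vector of acquisition times, minutes.
#' @param wavenumbers Strictly monotone numeric vector, cm^-1.
#' @param absorbance `M x N` numeric matrix, no missing values.
#' @param meta Named list of metadata.
#' @return An object of class `spectral_batch`.
#' @export
spectral_batch <- function(times, wavenumbers, absorbance, meta = list()) {
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(times)) {
    abort_bad_arg("`absorbance` must have one row per acquisition time.")
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    abort_bad_arg("`absorbance` must have one column per wavenumber.")
  }
  d <- diff(wavenumbers)
  if (length(wavenumbers) > 1 && !(all(d > 0) || all(d < 0))) {
    abort_bad_arg("`wavenumbers` must be strictly monotone.")
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    abort_bad_arg("`absorbance` contains missing or non-finite values.")
  }
  dimnames(absorbance) <- NULL
  structure(
    list(times = as.numeric(times), wavenumbers = as.numeric(wavenumbers),
         absorbance = absorbance, meta = meta),
    class = "spectral_batch"
  )
}

#' @export
print.spectral_batch <- function(x, ...) {
  cat(sprintf(
    "<spectral_batch> %d spectra x %d wavenumbers (%.0f-%.0f cm^-1), t = %.3g-%.3g min\n",
    nrow(x$absorbance), ncol(x$absorbance),
    max(x$wavenumbers), min(x$wavenumbers),
    min(x$times), max(x$times)
  ))
  if (!is.null(x$meta$batch_id)) cat(sprintf("  batch_id: %s\n", x$meta$batch_id))
  if (!is.null(x$meta$fault)) {
    cat(sprintf("  fault: %s (severity %.2g)\n",
                x$meta$fault$kind, x$meta$fault$severity))
  }
  invisible(x)
}

#' @describeIn spectral_batch Long-format view: one row per (time,
#'   wavenumber) cell, columns `time_min`, `wavenumber`, `absorbance`.
#' @param x A `spectral_batch`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spectral_batch <- function(x, ...) {
  tibble::tibble(
    time_min = rep(x$times, times = length(x$wavenumbers)),
    wavenumber = rep(x$wavenumbers, each = length(x$times)),
    absorbance = as.vector(x$absorbance)
  )
}

#' Plot a spectral batch
#'
#' Overlays all spectra of a batch coloured by acquisition time, the usual
#' first look at a renneting monitoring run.
#'
#' @param object A [spectral_batch()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spectral_batch <- function(object, ...) {
  dat <- tidy.spectral_batch(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$wavenumber, y = .data$absorbance,
    group = .data$time_min, colour = .data$time_min
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance",
                  colour = "Time (min)") +
    ggplot2::theme_minimal()
}

#' Write / read a spectral batch as delimited text
#'
#' The on-disk layout is a plain comma-separated matrix: the first row
#' holds the wavenumbers (first cell is the literal header `time_min`),
#' each following row starts with the acquisition time and continues with
#' the absorbance values. Values are written with 15 significant digits so
#' a write/read round trip reproduces the batch to full double precision.
#' Metadata is written to a JSON sidecar `<path>.json` when present.
#'
#' @param batch A [spectral_batch()] object.
#' @param path File path of the delimited matrix.
#' @param write_meta Write the metadata sidecar.
#' @return `write_batch()` returns `path` invisibly; `read_batch()` returns
#'   a [spectral_batch()].
#' @export
write_batch <- function(batch, path, write_meta = TRUE) {
  stopifnot(inherits(batch, "spectral_batch"))
  header <- paste(c("time_min", format(batch$wavenumbers, digits = 15,
                                       trim = TRUE, scientific = FALSE)),
                  collapse = ",")
  body <- vapply(seq_along(batch$times), function(i) {
    paste(format(c(batch$times[i], batch$absorbance[i, ]), digits = 15,
                 trim = TRUE),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  if (write_meta && length(batch$meta)) {
    jsonlite::write_json(serialize_meta(batch$meta),
                         paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

serialize_meta <- function(meta) {
  lapply(meta, function(v) {
    if (inherits(v, "kinetic_params") || inherits(v, "fault_spec")) {
      unclass(v)
    } else {
      v
    }
  })
}

#' @rdname write_batch
#' @export
read_batch <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("File '%s' does not exist.", path))
  nf <- utils::count.fields(path, sep = ",", quote = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    abort_bad_arg(sprintf(
      "Ragged file: row %d has %d fields but row 1 has %d.", bad, nf[bad], nf[1]))
  }
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  wn <- suppressWarnings(as.numeric(raw[1, -1]))
  if (anyNA(wn)) {
    abort_bad_arg(sprintf(
      "Non-numeric wavenumber in header column %d.", which(is.na(wn))[1] + 1L))
  }
  if (anyDuplicated(wn)) {
    abort_bad_arg(sprintf(
      "Duplicate wavenumber %g in header.", wn[duplicated(wn)][1]))
  }
  body <- as.matrix(raw[-1, , drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort_bad_arg(sprintf(
      "Non-numeric or missing cell at data row %d, column %d.",
      idx[1], idx[2]))
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  spectral_batch(times = num[, 1], wavenumbers = wn,
                 absorbance = num[, -1, drop = FALSE], meta = meta)
}

#' Write ground truth matrices as delimited text
#'
#' Writes `C_true` and `S_true` of a [ground_truth()] object as two
#' comma-separated matrices (with time / wavenumber axis columns) for
#' recovery testing outside R.
#'
#' @param truth A [ground_truth()] object.
#' @param c_path,s_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, c_path, s_path) {
  stopifnot(inherits(truth, "ground_truth"))
  cdf <- data.frame(time_min = truth$times, truth$C_true, check.names = FALSE)
  utils::write.csv(format(cdf, digits = 15, trim = TRUE), c_path,
                   row.names = FALSE, quote = FALSE)
  sdf <- data.frame(component = rownames(truth$S_true), truth$S_true,
                    check.names = FALSE)
  colnames(sdf) <- c("component", format(truth$wavenumbers, digits = 15,
                                         trim = TRUE, scientific = FALSE))
  utils::write.csv(sdf, s_path, row.names = FALSE, quote = FALSE)
  invisible(c(c_path, s_path))
}
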