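# Zero-phase FIR application with reflection padding: filtfilt alone leaves
# visible edge transients at these filter orders, so the input is extended
# by a mirrored margin of one filter length at each end before the
# forward-backward pass and trimmed afterwards.
fir_apply <- function(coefs, x) {
  n <- length(x)
  pad <- min(n - 1L, length(coefs))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(coefs, xp)
  y[(pad + 1L):(pad + n)]
}

#' Load a single-column ASCII signal segment
#'
#' Reads plain-text files with one sample value per line (the format of the
#' public epilepsy EEG releases) into an [ent_signal]. Blank lines are
#' ignored; a non-numeric line is an error reporting the line number.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (173.61 for the surface/intracranial
#'   study, 512 for the focal/non-focal study).
#' @param label Free-text label.
#' @param metadata Named list (study id, dataset, channel role, ...),
#'   attached verbatim.
#' @return An [ent_signal].
#' @export
load_ascii_segment <- function(path, fs, label = basename(path),
                               metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty file: ", path)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1]]
    stop(sprintf("non-numeric value at line %d of %s", bad, path))
  }
  ent_signal(vals, fs, label = label, metadata = metadata)
}

#' Band-pass FIR filtering of a signal
#'
#' Hamming-window FIR band-pass filter (default order 425, passband
#' 0.5-40 Hz, suppressing DC drift and 50-Hz mains noise), applied
#' zero-phase (forward-backward with mirrored edge padding) so the output
#' stays aligned with the input and has the same length.
#'
#' @param signal An [ent_signal].
#' @param f_lo,f_hi Passband edges in Hz; `0 < f_lo < f_hi < fs / 2`.
#' @param order FIR filter order; must be below the signal length.
#' @return The filtered [ent_signal].
#' @export
bandpass_fir <- function(signal, f_lo = 0.5, f_hi = 40, order = 425) {
  stopifnot(inherits(signal, "ent_signal"))
  nyq <- signal$fs / 2
  if (!(0 < f_lo && f_lo < f_hi && f_hi < nyq)) {
    stop("passband must satisfy 0 < f_lo < f_hi < fs/2")
  }
  if (order >= length(signal$samples)) {
    stop("filter order must be below the signal length")
  }
  coefs <- signal::fir1(order, c(f_lo, f_hi) / nyq, type = "pass")
  out <- signal
  out$samples <- fir_apply(coefs, signal$samples)
  out
}

#' Whole-segment entropy feature table
#'
#' Evaluates a list of estimator configurations on each segment, producing
#' the feature table behind the group tests and classification. Column
#' names are the configuration labels; the algorithm family of each column
#' is kept in the `"family"` attribute. Undefined entries are `NA`.
#'
#' @param segments List of [ent_signal] objects (consistently
#'   preprocessed).
#' @param configs List of [entropy_config] objects, e.g.
#'   [default_entropy_grids()].
#' @return `data.frame` (segments x configurations) with attribute
#'   `family` (named character vector, column -> algorithm family).
#' @export
batch_entropy <- function(segments, configs) {
  if (length(configs) == 0L) {
    out <- data.frame(row.names = seq_along(segments))
    attr(out, "family") <- character(0)
    return(out)
  }
  vals <- vapply(configs, function(cfg) {
    vapply(segments, function(s) {
      v <- try(compute_entropy(s, cfg), silent = TRUE)
      if (inherits(v, "try-error")) NA_real_ else v
    }, numeric(1))
  }, numeric(length(segments)))
  vals <- matrix(vals, nrow = length(segments))
  labels <- vapply(configs, `[[`, "", "label")
  out <- as.data.frame(vals)
  names(out) <- labels
  fam <- vapply(configs, `[[`, "", "family")
  names(fam) <- labels
  attr(out, "family") <- fam
  out
}
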