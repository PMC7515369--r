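#' Uniformly sampled time-series container
#'
#' Lightweight container for a single-channel, uniformly sampled signal,
#' optionally annotated with regime segments (e.g. the four 10-s regimes of
#' the benchmark signals).
#'
#' @param samples Numeric vector of sample values (arbitrary units).
#' @param fs Sampling rate in Hz; must be positive.
#' @param label Free-text description of the signal.
#' @param segments Optional `data.frame` with columns `start`, `end`
#'   (seconds) and `regime` (description). When present, segments must tile
#'   `[0, duration)` without gaps or overlap.
#' @param metadata Optional named list of extra fields (study id, dataset
#'   label, ...), kept verbatim.
#'
#' @return An object of class `ent_signal`: a list with elements `samples`,
#'   `fs`, `duration`, `label`, `segments`, `metadata`.
#' @export
#' @examples
#' s <- ent_signal(sin(2 * pi * 2 * seq(0, 1, by = 1 / 100)), fs = 100)
#' s$duration
ent_signal <- function(samples, fs, label = "", segments = NULL,
                       metadata = list()) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (anyNA(samples)) stop("`samples` must not contain NA values")
  duration <- length(samples) / fs
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    stopifnot(all(c("start", "end", "regime") %in% names(segments)))
    segments <- segments[order(segments$start), , drop = FALSE]
    if (any(segments$end <= segments$start)) {
      stop("segment intervals must have end > start")
    }
    tiles <- isTRUE(all.equal(segments$start[1], 0)) &&
      isTRUE(all.equal(segments$end[nrow(segments)], duration)) &&
      (nrow(segments) == 1L ||
         isTRUE(all.equal(segments$start[-1], segments$end[-nrow(segments)])))
    if (!tiles) stop("segments must tile [0, duration) without overlap")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, duration = duration,
         label = label, segments = segments, metadata = metadata),
    class = "ent_signal"
  )
}

#' @export
print.ent_signal <- function(x, ...) {
  cat(sprintf("<ent_signal> %s\n  %d samples @ %.6g Hz (%.6g s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$fs, x$duration))
  if (!is.null(x$segments)) {
    cat(sprintf("  %d regime segments: %s\n", nrow(x$segments),
                paste(x$segments$regime, collapse = "; ")))
  }
  invisible(x)
}

#' @export
length.ent_signal <- function(x) length(x$samples)

#' Extract the samples of one regime segment
#'
#' @param signal An [ent_signal] with segment annotations.
#' @param i Segment index (1-based, in time order).
#' @return Numeric vector of the samples whose time `t` (with sample `k` at
#'   `t = (k - 1) / fs`) satisfies `start <= t < end`.
#' @export
segment_samples <- function(signal, i) {
  stopifnot(inherits(signal, "ent_signal"), !is.null(signal$segments))
  seg <- signal$segments[i, ]
  k0 <- round(seg$start * signal$fs) + 1L
  k1 <- round(seg$end * signal$fs)
  signal$samples[k0:k1]
}

# Standard four 10-s regime annotation used by the benchmark generators.
four_segments <- function(duration, regimes) {
  n <- length(regimes)
  width <- duration / n
  data.frame(start = (seq_len(n) - 1) * width, end = seq_len(n) * width,
             regime = regimes, stringsAsFactors = FALSE)
}

# Time axis: sample k at t = (k - 1) / fs.
time_axis <- function(fs, duration) {
  seq(0, by = 1 / fs, length.out = round(fs * duration))
}
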