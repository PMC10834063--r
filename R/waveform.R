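#' Sampled waveform container
#'
#' A uniformly sampled time series with a declared unit.  Used for the
#' magnetic drive (T), magnetization (A/m), strain (dimensionless), shell
#' potential (V) and membrane current density (uA/cm^2).
#'
#' @param time Time axis, s (uniform, ascending).
#' @param values Sample values, finite.
#' @param unit Unit string.
#' @param label Free-text label.
#' @return Object of class `waveform`.
#' @export
waveform <- function(time, values, unit = "", label = "") {
  stopifnot(is.numeric(time), is.numeric(values),
            length(time) == length(values), length(time) >= 2,
            all(is.finite(time)), all(is.finite(values)))
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("waveform requires uniform sampling")
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 unit = unit, label = label),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s [%s], %d samples, fs = %.4g Hz, span %.4g s\n",
              x$label, x$unit, length(x$time), 1 / (x$time[2] - x$time[1]),
              x$time[length(x$time)] - x$time[1]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(time = x$time, value = x$values)
}

#' Sampling rate of a waveform
#' @param w A [waveform()].
#' @return Sampling rate, Hz.
#' @export
sample_rate <- function(w) {
  stopifnot(inherits(w, "waveform"))
  1 / (w$time[2] - w$time[1])
}

#' Read and write waveforms as CSV
#'
#' Two-column CSV (`time`, `value`); unit and label go into a comment-free
#' header row of column names `time_s` and `value_<unit>`.
#'
#' @param w A [waveform()].
#' @param path File path.
#' @return `write_waveform_csv` invisibly returns `path`;
#'   `read_waveform_csv` a [waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(w$time, w$values)
  names(df) <- c("time_s", paste0("value_", gsub("[^A-Za-z0-9]+", "_", w$unit)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- read.csv(path)
  unit <- sub("^value_", "", names(df)[2])
  waveform(df[[1]], df[[2]], unit = unit, label = basename(path))
}

#' Single-frequency amplitude of a waveform
#'
#' Complex demodulation: projects the signal on `exp(-2i pi f t)` and
#' returns twice the magnitude of the (normalized) projection, i.e. the
#' amplitude of a cosine component at `f`.  A Hann window (default)
#' suppresses leakage from strong components at other frequencies, which
#' matters when the component of interest is orders of magnitude below
#' the dominant tones; the window-weighted mean is removed first.
#'
#' @param w A [waveform()].
#' @param f Frequency, Hz.
#' @param window `"hann"` (default) or `"rect"`.
#' @return List with `amplitude` (same unit as the waveform) and `phase`
#'   (radians).
#' @export
tone_amplitude <- function(w, f, window = c("hann", "rect")) {
  stopifnot(inherits(w, "waveform"), is.numeric(f), f > 0)
  window <- match.arg(window)
  n <- length(w$values)
  win <- switch(window,
                hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)),
                rect = rep(1, n))
  x <- w$values - sum(win * w$values) / sum(win)
  z <- sum(win * x * exp(-2i * pi * f * w$time)) / sum(win)
  list(amplitude = 2 * Mod(z), phase = Arg(z))
}
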