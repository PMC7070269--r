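#' DC-removal filter specification
#'
#' The DC component of each IMU channel is removed by subtracting the output
#' of a first-order low-pass IIR filter from the signal, which acts as a
#' high-pass filter with the given cutoff (default 0.15 Hz). The filter
#' coefficient is alpha = dt / (RC + dt) with RC = 1 / (2 pi cutoff).
#'
#' @param cutoff_hz high-pass cutoff frequency in Hz (0 < cutoff < fs/2).
#' @param fs sampling rate in Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 0.15, fs = 25) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) stop("cutoff_hz must be in (0, fs/2)")
  structure(list(cutoff_hz = cutoff_hz, fs = fs), class = "filter_spec")
}

#' Remove the DC component of a trace
#'
#' Each channel is replaced by `x - lowpass(x)` where `lowpass` is a
#' first-order recursive filter. The filter state is initialised at the
#' first sample, which minimises the startup transient (a constant input
#' yields an exactly zero output from the first sample on). The whole
#' continuous trace is filtered once, before windowing.
#'
#' @param trace an [imu_trace()].
#' @param spec a [filter_spec()]; its `fs` must match the trace.
#' @return An [imu_trace()] of the same length, labels preserved.
#' @export
remove_dc <- function(trace, spec = filter_spec(fs = trace$fs)) {
  if (!inherits(trace, "imu_trace")) stop("trace must be an imu_trace")
  if (length(trace$t) == 0) stop("empty trace")
  if (abs(spec$fs - trace$fs) > 1e-9) stop("filter spec fs does not match trace fs")
  dt <- 1 / spec$fs
  rc <- 1 / (2 * pi * spec$cutoff_hz)
  alpha <- dt / (rc + dt)
  hp <- function(x) {
    low <- stats::filter(alpha * x, 1 - alpha, method = "recursive",
                         init = x[1])
    as.numeric(x - low)
  }
  imu_trace(trace$t, hp(trace$ax), hp(trace$ay), hp(trace$az),
            hp(trace$gx), hp(trace$gy), hp(trace$gz),
            fs = trace$fs, labels = trace$labels)
}

#' Windowing specification
#'
#' Traces are divided into fixed windows of 3 s (75 samples at 25 Hz)
#' without overlap; trailing partial windows are discarded.
#'
#' @param window_s window length in seconds.
#' @param fs sampling rate in Hz.
#' @param overlap fraction of overlap between consecutive windows (default 0).
#' @return An object of class `windowing_spec` with the derived
#'   `samples_per_window`.
#' @export
windowing_spec <- function(window_s = 3, fs = 25, overlap = 0) {
  spw <- round(window_s * fs)
  if (spw < 2) stop("window too short")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(window_s = window_s, fs = fs, overlap = overlap,
                 samples_per_window = spw), class = "windowing_spec")
}

#' Segment a labelled trace into fixed-size windows
#'
#' Each window carries a 75 x 6 sample matrix (channel order ax, ay, az, gx,
#' gy, gz) and one intensity class label: the majority intensity among the
#' window's per-sample labels, with ties broken toward the lower intensity
#' (the conservative choice for oxygen dosing on ambiguous windows).
#'
#' @param trace a labelled [imu_trace()] (typically after [remove_dc()]).
#' @param spec a [windowing_spec()].
#' @param subject_id subject identifier attached to each window.
#' @param labelled if `TRUE` (default) the trace must carry labels and each
#'   window gets an intensity label; if `FALSE` windows are unlabelled.
#' @return A list of `labeled_window` objects (fields `samples`, `label`,
#'   `subject_id`); `floor(N / samples_per_window)` of them when overlap is 0.
#' @export
segment_windows <- function(trace, spec = windowing_spec(fs = trace$fs),
                            subject_id = "S01", labelled = TRUE) {
  if (!inherits(trace, "imu_trace")) stop("trace must be an imu_trace")
  if (abs(spec$fs - trace$fs) > 1e-9) stop("windowing spec fs does not match trace fs")
  if (labelled && is.null(trace$labels)) stop("trace is unlabelled but labels were requested")
  spw <- spec$samples_per_window
  step <- max(1L, round(spw * (1 - spec$overlap)))
  n <- length(trace$t)
  starts <- seq(1L, by = step, length.out = max(0L, (n - spw) %/% step + 1L))
  if (n < spw) starts <- integer(0)
  chans <- cbind(ax = trace$ax, ay = trace$ay, az = trace$az,
                 gx = trace$gx, gy = trace$gy, gz = trace$gz)
  lapply(starts, function(s) {
    idx <- s:(s + spw - 1L)
    label <- NA_integer_
    if (labelled) {
      ints <- activity_intensity(trace$labels[idx])
      counts <- tabulate(ints + 1L, nbins = 3L)
      label <- which(counts == max(counts))[1] - 1L  # ties -> lower intensity
    }
    structure(list(samples = chans[idx, , drop = FALSE],
                   label = as.integer(label), subject_id = subject_id),
              class = "labeled_window")
  })
}
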