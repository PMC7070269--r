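CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")
CORR_PAIRS <- list(c("ax", "ay"), c("ax", "az"), c("ay", "az"),
                   c("gx", "gy"), c("gx", "gz"), c("gy", "gz"))

#' The 98-feature time-domain catalogue
#'
#' Stable, ordered catalogue of the 98 time-domain features extracted per
#' window from the six filtered channels. Family cardinalities: per-channel
#' RMS/SD/absolute-mean (18), mean of the derivative (6), within-sensor
#' pairwise Pearson correlations (6), simplified energy -- mean of squares
#' (6), skewness/kurtosis/median (18), min/max/range (18), interquartile
#' range (6), signal-magnitude-vector moments (10) and extremes (8), and
#' signal magnitude area (2); 98 in total. Frequency-domain and non-linear
#' features are deliberately excluded: the classifier must run on a
#' microcontroller.
#'
#' @return A data frame with columns `name`, `family`, `channels`; exactly
#'   98 rows in the fixed extraction order.
#' @export
feature_catalog <- function() {
  per_ch <- function(prefix) paste0(prefix, "_", CHANNELS)
  rows <- list(
    list(per_ch("rms"), "rms_sd_absmean"),
    list(per_ch("sd"), "rms_sd_absmean"),
    list(per_ch("absmean"), "rms_sd_absmean"),
    list(per_ch("dmean"), "deriv_mean"),
    list(vapply(CORR_PAIRS, function(p) paste0("corr_", p[1], "_", p[2]), ""),
         "pairwise_correlation"),
    list(per_ch("energy"), "energy"),
    list(per_ch("skew"), "moments"),
    list(per_ch("kurt"), "moments"),
    list(per_ch("median"), "moments"),
    list(per_ch("min"), "min_max_range"),
    list(per_ch("max"), "min_max_range"),
    list(per_ch("range"), "min_max_range"),
    list(per_ch("iqr"), "iqr"),
    list(paste0("smv_", rep(c("acc", "gyro"), each = 5), "_",
                rep(c("mean", "sd", "median", "skew", "kurt"), 2)), "smv_moments"),
    list(paste0("smv_", rep(c("acc", "gyro"), each = 4), "_",
                rep(c("iqr", "max", "min", "range"), 2)), "smv_range"),
    list(c("sma_acc", "sma_gyro"), "sma")
  )
  name <- unlist(lapply(rows, `[[`, 1), use.names = FALSE)
  family <- rep(vapply(rows, `[[`, "", 2),
                vapply(rows, function(r) length(r[[1]]), 0L))
  chan <- sub("^(rms|sd|absmean|dmean|energy|skew|kurt|median|min|max|range|iqr)_", "",
              name)
  chan[grepl("^corr_", name)] <- sub("^corr_", "", name[grepl("^corr_", name)])
  chan[grepl("^smv_acc|^sma_acc", name)] <- "ax,ay,az"
  chan[grepl("^smv_gyro|^sma_gyro", name)] <- "gx,gy,gz"
  data.frame(name = name, family = family, channels = chan,
             stringsAsFactors = FALSE)
}

catalog_hash <- function() string_hash(paste(feature_catalog()$name, collapse = ","))

# Moment helpers with the conventions used throughout: sample SD (n-1
# denominator), bias-uncorrected skewness g1 = m3/m2^1.5, Pearson
# (non-excess) kurtosis m4/m2^2; zero-variance inputs yield 0 for skewness,
# kurtosis and correlation so that noise-free sedentary windows stay finite.
moment_skew <- function(x) {
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}
moment_kurt <- function(x) {
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^4) / m2^2
}
safe_cor <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(0)
  sum(dx * dy) / den
}
iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Extract the 98 time-domain features from one window
#'
#' Pure function of the 75 x 6 sample matrix. Per channel: RMS, sample SD,
#' absolute mean, mean of successive differences scaled by fs (units per
#' second), simplified energy (mean of squares), skewness, kurtosis, median,
#' min, max, range and interquartile range (linear-interpolation quantiles).
#' Pearson correlations are computed within each sensor: (ax,ay), (ax,az),
#' (ay,az) and (gx,gy), (gx,gz), (gy,gz). The signal magnitude vector (SMV)
#' per sensor is the per-sample Euclidean norm of its three channels, from
#' which mean, SD, median, skewness, kurtosis, IQR, max, min and range are
#' taken; the signal magnitude area (SMA) per sensor is the mean of the sum
#' of the three absolute channel values.
#'
#' @param window a `labeled_window` from [segment_windows()] or a numeric
#'   matrix with 6 columns (ax, ay, az, gx, gy, gz).
#' @param fs sampling rate used to scale the derivative (Hz).
#' @return A named numeric vector of length 98 in [feature_catalog()] order.
#' @export
extract_features <- function(window, fs = 25) {
  m <- if (inherits(window, "labeled_window")) window$samples else window
  if (!is.matrix(m) || ncol(m) != 6 || nrow(m) < 2)
    stop("window must be an n x 6 matrix with n >= 2")
  if (!all(is.finite(m))) stop("window contains non-finite values")
  colnames(m) <- CHANNELS
  n <- nrow(m)

  mu <- colMeans(m)
  dev <- sweep(m, 2, mu)
  m2 <- colMeans(dev^2)
  energy <- colMeans(m^2)
  rms <- sqrt(energy)
  sds <- sqrt(colSums(dev^2) / (n - 1))
  absmean <- colMeans(abs(m))
  dmean <- colMeans(diff(m)) * fs  # mean successive difference, per second
  corr <- vapply(CORR_PAIRS, function(p) safe_cor(m[, p[1]], m[, p[2]]), 0)
  skew <- apply(m, 2, moment_skew)
  kurt <- apply(m, 2, moment_kurt)
  med <- apply(m, 2, stats::median)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  iqrs <- apply(m, 2, iqr7)

  smv <- function(cols) sqrt(rowSums(m[, cols, drop = FALSE]^2))
  smv_stats <- function(v) c(mean(v), stats::sd(v), stats::median(v),
                             moment_skew(v), moment_kurt(v))
  smv_ext <- function(v) c(iqr7(v), max(v), min(v), max(v) - min(v))
  va <- smv(1:3); vg <- smv(4:6)
  sma <- c(mean(rowSums(abs(m[, 1:3]))), mean(rowSums(abs(m[, 4:6]))))

  out <- c(rms, sds, absmean, dmean, corr, energy, skew, kurt, med,
           mins, maxs, maxs - mins, iqrs,
           smv_stats(va), smv_stats(vg), smv_ext(va), smv_ext(vg), sma)
  names(out) <- feature_catalog()$name
  out
}

#' Build the feature matrix of a set of windows
#'
#' @param windows a list of `labeled_window` objects.
#' @param fs sampling rate in Hz.
#' @return A list with `X` (n_windows x 98 matrix, columns named by the
#'   catalogue), `label` (integer intensity classes) and `subject`
#'   (character).
#' @export
feature_matrix <- function(windows, fs = 25) {
  X <- t(vapply(windows, extract_features, numeric(98), fs = fs))
  list(X = X,
       label = vapply(windows, function(w) w$label, 0L),
       subject = vapply(windows, function(w) w$subject_id, ""))
}

#' Run the full preprocessing + feature pipeline on a cohort
#'
#' DC-filters each subject's session, segments it into labelled windows and
#' extracts the 98 features.
#'
#' @param cohort an `imu_cohort` from [make_cohort()].
#' @param cutoff_hz DC-removal cutoff (Hz).
#' @param window_s window length (s).
#' @return As [feature_matrix()].
#' @export
cohort_features <- function(cohort, cutoff_hz = 0.15, window_s = 3) {
  wins <- list()
  for (entry in cohort) {
    tr <- remove_dc(entry$trace, filter_spec(cutoff_hz, entry$trace$fs))
    w <- segment_windows(tr, windowing_spec(window_s, tr$fs),
                         subject_id = entry$params$subject_id)
    wins <- c(wins, w)
  }
  feature_matrix(wins, fs = cohort[[1]]$trace$fs)
}
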