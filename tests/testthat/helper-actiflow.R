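# Shared fixtures and independent oracles used across the suite.

quiet_subject <- function(...) {
  subject_params(noise_sd_g = 0, noise_sd_dps = 0,
                 posture_tilts = c(sitting = 0, standing = 0, lying = 0,
                                   walking = 0, upstairs = 0, downstairs = 0),
                 ...)
}

random_window <- function(n = 75, scale = 1) {
  matrix(rnorm(n * 6, sd = scale), ncol = 6,
         dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
}

# Trace with hand-chosen per-sample labels (for windowing label tests).
labelled_trace <- function(labels, fs = 25) {
  n <- length(labels)
  imu_trace((seq_len(n) - 1) / fs, rnorm(n), rnorm(n), rnorm(n),
            rnorm(n), rnorm(n), rnorm(n), fs = fs, labels = labels)
}

# ---- naive feature oracle: direct loop/sum re-implementation ---------------

naive_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

naive_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, m2 = m2,
       skew = if (m2 == 0) 0 else m3 / m2^1.5,
       kurt = if (m2 == 0) 0 else m4 / m2^2)
}

naive_features <- function(m, fs = 25) {
  n <- nrow(m)
  ch <- list(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])
  per <- function(f) vapply(ch, f, 0)
  pearson <- function(x, y) {
    mx <- sum(x) / n; my <- sum(y) / n
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    if (den == 0) 0 else num / den
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  smv <- function(cols) {
    v <- numeric(n)
    for (i in seq_len(n)) v[i] <- sqrt(sum(m[i, cols]^2))
    v
  }
  stats9 <- function(v) {
    mo <- naive_moments(v)
    c(mo$mean, sqrt(sum((v - mo$mean)^2) / (n - 1)), naive_quantile(v, 0.5),
      mo$skew, mo$kurt)
  }
  ext4 <- function(v) c(naive_quantile(v, 0.75) - naive_quantile(v, 0.25),
                        max(v), min(v), max(v) - min(v))
  va <- smv(1:3); vg <- smv(4:6)
  c(per(function(x) sqrt(sum(x^2) / n)),
    per(function(x) sqrt(sum((x - sum(x) / n)^2) / (n - 1))),
    per(function(x) sum(abs(x)) / n),
    per(function(x) (sum(x[-1] - x[-n]) / (n - 1)) * fs),
    vapply(pairs, function(p) pearson(ch[[p[1]]], ch[[p[2]]]), 0),
    per(function(x) sum(x^2) / n),
    per(function(x) naive_moments(x)$skew),
    per(function(x) naive_moments(x)$kurt),
    per(function(x) naive_quantile(x, 0.5)),
    per(min), per(max), per(function(x) max(x) - min(x)),
    per(function(x) naive_quantile(x, 0.75) - naive_quantile(x, 0.25)),
    stats9(va), stats9(vg), ext4(va), ext4(vg),
    sum(abs(m[, 1]) + abs(m[, 2]) + abs(m[, 3])) / n,
    sum(abs(m[, 4]) + abs(m[, 5]) + abs(m[, 6])) / n)
}

# Exhaustive DFT peak search over the positive frequencies of a signal.
dominant_frequency <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  amp <- Mod(stats::fft(x))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) * fs / n
  freqs[which.max(amp)]
}

# Mann-Whitney AUC by exhaustive pair counting (ties count 1/2).
paircount_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y != 1]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small three-class Gaussian feature set with informative columns; used for
# classifier tests that do not need the full signal pipeline.
gaussian_intensity_data <- function(n_per_class = 60, m = 6, seed = 42) {
  set.seed(seed)
  y <- rep(0:2, each = n_per_class)
  X <- matrix(rnorm(3 * n_per_class * m), ncol = m)
  X[, 1] <- X[, 1] + 3 * (y > 0)    # separates sedentary vs active
  X[, 2] <- X[, 2] + 3 * (y == 2)   # separates light vs moderate
  colnames(X) <- sprintf("F%03d", seq_len(m))
  list(X = X, y = y)
}
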