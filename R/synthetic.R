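#' Six-channel inertial trace container
#'
#' Holds a uniformly sampled chest-worn IMU recording: three acceleration
#' channels in g and three angular-rate channels in deg/s, with optional
#' per-sample activity labels. Axis convention: with the sensor at the end of
#' the sternum, the Y axis points at the head and the Z axis along the
#' walking direction, so gravity appears on -Y when upright and on -X when
#' lying.
#'
#' @param t time stamps in seconds (strictly increasing, uniform step 1/fs).
#' @param ax,ay,az acceleration channels (g).
#' @param gx,gy,gz angular-rate channels (deg/s).
#' @param fs sampling rate in Hz (default 25).
#' @param labels optional character vector of per-sample activity names
#'   (see [activity_catalog()]).
#' @return An object of class `imu_trace`.
#' @export
imu_trace <- function(t, ax, ay, az, gx, gy, gz, fs = 25, labels = NULL) {
  n <- length(t)
  chans <- list(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  if (!all(lengths(chans) == n)) stop("all channels must have the same length as t")
  if (fs <= 0) stop("fs must be positive")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("non-monotone time")
    if (any(abs(dt - 1 / fs) > 1e-6)) stop("t must be a uniform grid with step 1/fs")
  }
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels must match trace length")
    activity_intensity(unique(labels))  # validates names
  }
  structure(c(list(t = t), chans, list(fs = fs, labels = labels)),
            class = "imu_trace")
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$t), x$fs, length(x$t) / x$fs,
              if (is.null(x$labels)) "" else
                paste0(", activities: ", paste(unique(x$labels), collapse = ", "))))
  invisible(x)
}

#' @export
as.data.frame.imu_trace <- function(x, ...) {
  d <- data.frame(t = x$t, ax = x$ax, ay = x$ay, az = x$az,
                  gx = x$gx, gy = x$gy, gz = x$gz)
  if (!is.null(x$labels)) d$activity <- x$labels
  d
}

#' @export
length.imu_trace <- function(x) length(x$t)

imu_concat <- function(traces) {
  fs <- traces[[1]]$fs
  stopifnot(all(vapply(traces, function(x) x$fs, 0) == fs))
  pull <- function(f) unlist(lapply(traces, `[[`, f), use.names = FALSE)
  n <- sum(vapply(traces, function(x) length(x$t), 0L))
  labs <- if (all(!vapply(traces, function(x) is.null(x$labels), TRUE))) pull("labels")
  imu_trace(t = (seq_len(n) - 1) / fs,
            ax = pull("ax"), ay = pull("ay"), az = pull("az"),
            gx = pull("gx"), gy = pull("gy"), gz = pull("gz"),
            fs = fs, labels = labs)
}

#' Per-subject gait and sensor parameters for the synthetic cohort
#'
#' Parameterises one synthetic subject: walking cadence (step frequency) and
#' vertical step amplitude, the multiplicative amplitude factor applied on
#' stairs, the angular-rate amplitude of gait, white-noise standard
#' deviations for each sensor, and small per-activity gravity-orientation
#' tilts. These parameters stand in for the variability of real recordings,
#' which are not publicly available.
#'
#' @param subject_id subject identifier.
#' @param cadence_hz walking step frequency in Hz, in (0.5, 3).
#' @param step_amp_g vertical acceleration amplitude of a step (g).
#' @param stair_amp_scale amplitude factor for stair activities (>= 1 typical).
#' @param gyro_amp_dps angular-rate oscillation amplitude (deg/s).
#' @param noise_sd_g,noise_sd_dps white-noise SDs for accelerometer (g) and
#'   gyroscope (deg/s) channels.
#' @param posture_tilts named numeric vector of per-activity tilt offsets in
#'   degrees (names from [activity_catalog()]); missing activities get 0.
#' @param seed integer seed making the subject's signals reproducible.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01", cadence_hz = 1.8,
                           step_amp_g = 0.22, stair_amp_scale = 1.5,
                           gyro_amp_dps = 40, noise_sd_g = 0.02,
                           noise_sd_dps = 1,
                           posture_tilts = c(sitting = 3, standing = 1, lying = 4,
                                             walking = 5, upstairs = 10, downstairs = -8),
                           seed = 1L) {
  if (cadence_hz <= 0.5 || cadence_hz >= 3) stop("cadence_hz must be in (0.5, 3)")
  amps <- c(step_amp_g, stair_amp_scale, gyro_amp_dps, noise_sd_g, noise_sd_dps)
  if (any(amps < 0)) stop("amplitudes and noise SDs must be non-negative")
  structure(list(subject_id = subject_id, cadence_hz = cadence_hz,
                 step_amp_g = step_amp_g, stair_amp_scale = stair_amp_scale,
                 gyro_amp_dps = gyro_amp_dps, noise_sd_g = noise_sd_g,
                 noise_sd_dps = noise_sd_dps, posture_tilts = posture_tilts,
                 seed = as.integer(seed)),
            class = "subject_params")
}

#' Hospital walking-circuit protocol
#'
#' The recording protocol: three minutes seated rest, a 12-minute walking
#' circuit with level-walking and stair sections (with optional seated stops
#' at chairs along the route), and three minutes seated rest. The default
#' segment plan is six laps of 102 s walking + 9 s upstairs + 9 s downstairs,
#' giving a light:moderate exposure ratio of about 5.7:1, matching the class
#' balance of the study cohort.
#'
#' @param rest_before_s,circuit_s,rest_after_s phase durations in seconds
#'   (defaults 180 / 720 / 180).
#' @param segment_plan data frame with columns `activity`, `duration_s`
#'   describing the circuit; durations must sum to `circuit_s`. Default:
#'   six walking/upstairs/downstairs laps.
#' @param stop_probability chance of inserting one seated stop (20--40 s of
#'   sitting) after each lap.
#' @param laps number of laps the default plan is divided into (stop
#'   insertion points).
#' @return An object of class `circuit_protocol`.
#' @export
circuit_protocol <- function(rest_before_s = 180, circuit_s = 720,
                             rest_after_s = 180, segment_plan = NULL,
                             stop_probability = 0.25, laps = 6) {
  if (is.null(segment_plan)) {
    lap <- data.frame(activity = c("walking", "upstairs", "downstairs"),
                      duration_s = c(102, 9, 9), stringsAsFactors = FALSE)
    segment_plan <- do.call(rbind, replicate(laps, lap, simplify = FALSE))
  } else {
    laps <- max(1L, laps)
  }
  if (nrow(segment_plan) == 0) stop("segment_plan must not be empty")
  if (abs(sum(segment_plan$duration_s) - circuit_s) > 1e-9)
    stop("segment durations must sum to circuit_s")
  if (stop_probability < 0 || stop_probability > 1)
    stop("stop_probability must be in [0, 1]")
  structure(list(rest_before_s = rest_before_s, circuit_s = circuit_s,
                 rest_after_s = rest_after_s, segment_plan = segment_plan,
                 stop_probability = stop_probability, laps = laps),
            class = "circuit_protocol")
}

#' Generate one labelled activity segment
#'
#' Signal model: a gravity vector (tilted by the subject's per-activity
#' offset) plus, for locomotion, a sum of two harmonics at the cadence and
#' twice the cadence, plus Gaussian white noise on every channel. Sedentary
#' postures are the gravity vector plus noise (standing gains a tiny postural
#' sway). Stair segments apply `stair_amp_scale` to the gait amplitudes and
#' use an asymmetric (fixed-phase second harmonic) vertical waveform -- the
#' sharper heel-strike profile of stair negotiation -- which makes the
#' vertical-axis skewness positive and approximately amplitude-invariant;
#' stairs also add a slow pitch sway on the pitch gyro channel.
#'
#' @param activity an activity name from [activity_catalog()].
#' @param duration_s segment duration in seconds (> 0).
#' @param subject a [subject_params()] object.
#' @param seed integer seed (defaults to the subject's seed).
#' @param fs sampling rate in Hz.
#' @return A labelled [imu_trace()].
#' @examples
#' s <- subject_params(noise_sd_g = 0, noise_sd_dps = 0,
#'                     posture_tilts = c(sitting = 0))
#' tr <- generate_activity_segment("sitting", 10, s)
#' range(tr$ay)  # gravity on -Y when seated upright
#' @export
generate_activity_segment <- function(activity, duration_s, subject,
                                      seed = subject$seed, fs = 25) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be positive")
  intensity <- activity_intensity(activity)  # errors on unknown activity
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  tilt <- unname(subject$posture_tilts[activity])
  if (is.na(tilt) || is.null(tilt)) tilt <- 0
  th <- tilt * pi / 180

  ax <- ay <- az <- gx <- gy <- gz <- numeric(n)
  if (activity == "lying") {
    ax <- ax - cos(th); ay <- ay - sin(th)
  } else {
    ay <- ay - cos(th); az <- az - sin(th)
  }

  A <- subject$step_amp_g
  G <- subject$gyro_amp_dps
  f <- subject$cadence_hz
  if (activity == "standing") {
    az <- az + 0.01 * sin(2 * pi * 0.4 * t)
  } else if (activity %in% c("walking", "upstairs", "downstairs")) {
    s <- 1; r2 <- 0.35; asym <- FALSE
    if (activity == "upstairs") {
      s <- subject$stair_amp_scale; asym <- TRUE
    } else if (activity == "downstairs") {
      s <- subject$stair_amp_scale; asym <- TRUE; r2 <- 0.45; f <- f * 1.06
    }
    w <- 2 * pi * f * t
    second <- if (asym) -r2 * A * cos(2 * w) else r2 * A * sin(2 * w)
    az <- az + s * (A * sin(w) + second)
    ay <- ay + s * 0.7 * A * cos(w)
    ax <- ax + s * 0.15 * A * sin(w + pi / 3)
    gx <- gx + s * G * sin(w)
    gy <- gy + s * 0.4 * G * cos(w)
    gz <- gz + s * 0.3 * G * sin(w + 2 * pi / 3)
    if (asym) gx <- gx + 8 * sin(2 * pi * 0.35 * t)  # slow stair pitch sway
  }

  local_seed(seed, {
    sg <- subject$noise_sd_g
    sd_ <- subject$noise_sd_dps
    ax <- ax + rnorm(n, 0, sg); ay <- ay + rnorm(n, 0, sg); az <- az + rnorm(n, 0, sg)
    gx <- gx + rnorm(n, 0, sd_); gy <- gy + rnorm(n, 0, sd_); gz <- gz + rnorm(n, 0, sd_)
  })
  imu_trace(t, ax, ay, az, gx, gy, gz, fs = fs,
            labels = rep(activity, n))
}

#' Generate one full circuit session for a subject
#'
#' Concatenates seated rest, the circuit segment plan (with optional seated
#' stops of 20--40 s inserted after laps), and seated rest, with continuous
#' per-sample labels. Deterministic given the seed; each segment uses a
#' derived sub-seed so sessions are reproducible segment by segment.
#'
#' @inheritParams generate_activity_segment
#' @param protocol a [circuit_protocol()].
#' @return A labelled [imu_trace()] of at least
#'   `rest_before_s + circuit_s + rest_after_s` seconds.
#' @export
generate_circuit_session <- function(subject, protocol = circuit_protocol(),
                                     seed = subject$seed, fs = 25) {
  plan <- protocol$segment_plan
  if (is.null(plan) || nrow(plan) == 0) stop("segment_plan must not be empty")
  per_lap <- max(1L, nrow(plan) %/% protocol$laps)

  stops <- local_seed(derive_seed(seed, 9999L), {
    lap_ends <- seq(per_lap, nrow(plan), by = per_lap)
    data.frame(after = lap_ends,
               insert = runif(length(lap_ends)) < protocol$stop_probability,
               duration = round(runif(length(lap_ends), 20, 40)))
  })

  segs <- list(list(activity = "sitting", duration = protocol$rest_before_s))
  for (i in seq_len(nrow(plan))) {
    segs[[length(segs) + 1L]] <- list(activity = plan$activity[i],
                                      duration = plan$duration_s[i])
    j <- match(i, stops$after)
    if (!is.na(j) && stops$insert[j]) {
      segs[[length(segs) + 1L]] <- list(activity = "sitting",
                                        duration = stops$duration[j])
    }
  }
  segs[[length(segs) + 1L]] <- list(activity = "sitting",
                                    duration = protocol$rest_after_s)

  traces <- lapply(seq_along(segs), function(i) {
    generate_activity_segment(segs[[i]]$activity, segs[[i]]$duration, subject,
                              seed = derive_seed(seed, i), fs = fs)
  })
  imu_concat(traces)
}

#' Default parameter ranges for a synthetic cohort
#'
#' Ranges reflect elderly COPD patients walking at their habitual pace:
#' cadence 1.5--2.1 Hz, modest vertical step amplitudes, stair amplitude
#' factor 1.3--1.7, and MEMS-grade sensor noise.
#'
#' @return A named list of `c(min, max)` ranges.
#' @export
cohort_ranges <- function() {
  list(cadence_hz = c(1.5, 2.1), step_amp_g = c(0.15, 0.30),
       stair_amp_scale = c(1.3, 1.7), gyro_amp_dps = c(25, 60),
       noise_sd_g = c(0.015, 0.03), noise_sd_dps = c(0.5, 1.5),
       tilt_deg = c(-8, 8))
}

#' Generate a labelled synthetic IMU cohort
#'
#' Draws per-subject gait parameters from the stated ranges (each subject
#' gets a seed derived from the cohort seed, so cohorts are reproducible
#' subject by subject) and generates one circuit session per subject.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out needs at
#'   least two). Default 18, the size of the study cohort.
#' @param base named list of parameter ranges as from [cohort_ranges()].
#' @param seed cohort seed.
#' @param protocol a [circuit_protocol()].
#' @return An object of class `imu_cohort`: a list of
#'   `list(params, trace)` pairs.
#' @export
make_cohort <- function(n_subjects = 18, base = cohort_ranges(), seed = 1L,
                        protocol = circuit_protocol()) {
  if (n_subjects < 2) stop("n_subjects must be >= 2 (LOSO needs at least 2)")
  ru <- function(rg) runif(1, rg[1], rg[2])
  cohort <- lapply(seq_len(n_subjects), function(i) {
    si <- derive_seed(seed, i)
    params <- local_seed(si, {
      acts <- activity_catalog()$name
      tilts <- stats::setNames(runif(length(acts), base$tilt_deg[1], base$tilt_deg[2]), acts)
      subject_params(
        subject_id = sprintf("S%02d", i),
        cadence_hz = ru(base$cadence_hz), step_amp_g = ru(base$step_amp_g),
        stair_amp_scale = ru(base$stair_amp_scale),
        gyro_amp_dps = ru(base$gyro_amp_dps),
        noise_sd_g = ru(base$noise_sd_g), noise_sd_dps = ru(base$noise_sd_dps),
        posture_tilts = tilts, seed = si)
    })
    list(params = params,
         trace = generate_circuit_session(params, protocol, seed = derive_seed(si, 7L)))
  })
  structure(cohort, class = "imu_cohort")
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort> %d subjects, %.1f min each (first subject)\n",
              length(x), length(x[[1]]$trace$t) / x[[1]]$trace$fs / 60))
  invisible(x)
}
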