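#' Therapy profiles: intensity to pulse-setting lookup
#'
#' The controller's lookup table. Seven physician-selectable profiles map
#' each intensity class to a pulse setting (0 = no pulse, 1..5 = the
#' concentrator's flow levels); settings are non-decreasing in intensity
#' within every profile.
#'
#' @return A 7 x 3 integer matrix, rows = profiles 1..7, columns
#'   sedentary/light/moderate.
#' @export
therapy_profiles <- function() {
  m <- rbind(c(1, 2, 4), c(1, 3, 5), c(1, 4, 5), c(2, 4, 5),
             c(3, 4, 5), c(0, 2, 5), c(0, 1, 4))
  dimnames(m) <- list(profile = 1:7, intensity = intensity_labels())
  m
}

#' @rdname therapy_profiles
#' @param profile_id profile number, 1..7.
#' @return `therapy_profile()` returns a list with `profile_id` and the
#'   three-element `settings` vector.
#' @export
therapy_profile <- function(profile_id) {
  if (!is.numeric(profile_id) || length(profile_id) != 1 ||
      !(profile_id %in% 1:7))
    stop("profile_id must be an integer in 1..7")
  structure(list(profile_id = as.integer(profile_id),
                 settings = therapy_profiles()[profile_id, ]),
            class = "therapy_profile")
}

#' @rdname therapy_profiles
#' @param intensity intensity class: 0/1/2 or sedentary/light/moderate.
#' @return `profile_lookup()` returns the pulse setting (integer 0..5).
#' @examples
#' profile_lookup(2, "light")  # 3
#' @export
profile_lookup <- function(profile_id, intensity) {
  p <- therapy_profile(profile_id)
  k <- canonical_intensity(intensity)
  unname(p$settings[k + 1L])
}

#' Pulse-dose bolus volume
#'
#' The concentrator delivers 12 mL per bolus per flow setting at 15 breaths
#' per minute, i.e. a per-setting minute volume of 180 mL/min at reference
#' conditions (20 degrees C, sea level). The bolus volume is therefore
#' `180 * setting / bpm` millilitres: slower breathing yields larger
#' boluses, faster breathing smaller ones.
#'
#' @param setting pulse setting, integer 0..5 (0 = no pulse).
#' @param bpm breathing rate in breaths per minute (> 0).
#' @return Bolus volume in millilitres.
#' @examples
#' bolus_volume(1, 15)  # 12
#' bolus_volume(3, 20)  # 27
#' @export
bolus_volume <- function(setting, bpm) {
  if (any(bpm <= 0)) stop("bpm must be positive")
  if (any(setting < 0 | setting > 5)) stop("setting must be in 0..5")
  180 * setting / bpm
}

#' Safety finite-state machine for flow changes
#'
#' A Mealy machine inserted after the classifier to prevent abrupt oxygen
#' flow changes (e.g. a jump from the sedentary to the moderate level or
#' vice versa): per classified window the machine moves its state at most
#' one intensity level toward the observed class, and its output is the
#' therapy profile's pulse setting for the new state. An optional debounce
#' requires `debounce` consecutive identical observations before the state
#' starts moving.
#'
#' @param current initial intensity state (0/1/2).
#' @param debounce consecutive identical observations required before a
#'   state change (default 1, i.e. react immediately).
#' @return `fsm_state()` returns an object of class `fsm_state`.
#' @export
fsm_state <- function(current = 0L, debounce = 1L) {
  current <- canonical_intensity(current)
  if (debounce < 1) stop("debounce must be >= 1")
  structure(list(current = current, last_obs = NA_integer_, streak = 0L,
                 debounce = as.integer(debounce)),
            class = "fsm_state")
}

#' @rdname fsm_state
#' @param state an `fsm_state`.
#' @param observed the intensity class emitted by the classifier for this
#'   window.
#' @param profile a [therapy_profile()] (or profile id 1..7).
#' @return `fsm_step()` returns `list(state, setting)`: the updated state
#'   and the emitted pulse setting.
#' @examples
#' st <- fsm_state(0)
#' p <- therapy_profile(2)
#' step1 <- fsm_step(st, 2, p)   # state moves 0 -> 1, setting 3
#' step2 <- fsm_step(step1$state, 2, p)  # state 2, setting 5
#' @export
fsm_step <- function(state, observed, profile) {
  if (!inherits(profile, "therapy_profile")) profile <- therapy_profile(profile)
  observed <- canonical_intensity(observed)
  if (identical(observed, state$last_obs)) {
    state$streak <- state$streak + 1L
  } else {
    state$streak <- 1L
    state$last_obs <- observed
  }
  if (observed != state$current && state$streak >= state$debounce) {
    state$current <- state$current + sign(observed - state$current)
  }
  list(state = state,
       setting = unname(profile$settings[state$current + 1L]))
}

#' Run the controller over a classified window stream
#'
#' Folds [fsm_step()] over a sequence of per-window intensity classes and
#' records the emitted state and pulse setting per window, the number of
#' setting adjustments, and the latency of every observed transition (the
#' number of windows from the first changed observation until the state
#' reaches the newly observed class).
#'
#' @param classified_stream integer vector of observed intensity classes
#'   (one per 3-s window).
#' @param profile a [therapy_profile()] or profile id.
#' @param initial initial [fsm_state()].
#' @return An object of class `flow_timeline`: `timeline` (data frame
#'   `window`, `observed`, `state`, `setting`), `adjustments`, `latency`
#'   (data frame per transition).
#' @export
run_closed_loop <- function(classified_stream, profile,
                            initial = fsm_state()) {
  if (length(classified_stream) == 0) stop("empty stream")
  if (!inherits(profile, "therapy_profile")) profile <- therapy_profile(profile)
  obs <- canonical_intensity(classified_stream)
  n <- length(obs)
  state_seq <- integer(n)
  setting_seq <- integer(n)
  st <- initial
  for (i in seq_len(n)) {
    out <- fsm_step(st, obs[i], profile)
    st <- out$state
    state_seq[i] <- st$current
    setting_seq[i] <- out$setting
  }
  adjustments <- sum(diff(c(unname(profile$settings[initial$current + 1L]),
                            setting_seq)) != 0)

  # latency per observed transition: windows from the first changed
  # observation until the state first equals the newly observed class
  # (NA if the observation changes again before the state gets there)
  run_starts <- which(c(TRUE, diff(obs) != 0))
  run_ends <- c(run_starts[-1] - 1L, n)
  lat <- list()
  for (k in seq_along(run_starts)) {
    i <- run_starts[k]
    target <- obs[i]
    from <- if (i == 1) initial$current else state_seq[i - 1L]
    if (target == from) next
    hit <- which(state_seq[i:run_ends[k]] == target)
    lat[[length(lat) + 1L]] <-
      data.frame(window = i, from = from, to = target,
                 latency = if (length(hit)) hit[1] else NA_integer_)
  }
  structure(list(timeline = data.frame(window = seq_len(n), t = (seq_len(n) - 1) * 3,
                                       observed = obs, state = state_seq,
                                       setting = setting_seq),
                 adjustments = adjustments,
                 latency = if (length(lat)) do.call(rbind, lat) else
                   data.frame(window = integer(0), from = integer(0),
                              to = integer(0), latency = integer(0)),
                 profile_id = profile$profile_id),
            class = "flow_timeline")
}

#' @export
print.flow_timeline <- function(x, ...) {
  cat(sprintf("<flow_timeline> %d windows, profile %d, %d adjustment(s)\n",
              nrow(x$timeline), x$profile_id, x$adjustments))
  invisible(x)
}

#' Adherence rate of manual flow adjustments
#'
#' Percentage of the needed flow adjustments actually performed by the
#' patient, reported to one decimal.
#'
#' @param performed adjustments carried out (0 <= performed <= needed).
#' @param needed adjustments required (> 0).
#' @return Percentage, rounded half-up to 1 decimal.
#' @examples
#' adherence_rate(17, 96)  # 17.7
#' @export
adherence_rate <- function(performed, needed) {
  if (needed <= 0) stop("needed must be positive")
  if (performed < 0 || performed > needed)
    stop("performed must be between 0 and needed")
  round_half_up(100 * performed / needed, 1)
}

#' Summary of an SpO2 time series
#'
#' Computes CT90 and CT85 (percentage of time spent with SpO2 below 90% and
#' 85%), the mean and minimum saturation, and the number of desaturation
#' events. An event is a maximal run of samples below `event_threshold`
#' lasting at least `min_event_s` seconds; runs separated by less than
#' `min_recovery_s` seconds of recovery are merged into one event.
#'
#' @param spo2 saturation values in percent (0..100), uniformly sampled.
#' @param t optional time stamps in seconds (default: 1 Hz grid).
#' @param thresholds CTxx thresholds (default 90 and 85).
#' @param event_threshold threshold defining a desaturation event (%).
#' @param min_event_s,min_recovery_s event duration and recovery gaps (s).
#' @return An object of class `spo2_report` with `ct` (named percentages),
#'   `mean`, `min`, `events`.
#' @export
spo2_summary <- function(spo2, t = NULL, thresholds = c(90, 85),
                         event_threshold = 90, min_event_s = 10,
                         min_recovery_s = 10) {
  if (length(spo2) == 0) stop("empty series")
  if (any(spo2 < 0 | spo2 > 100)) stop("SpO2 values must be in [0, 100]")
  if (is.null(t)) t <- seq_along(spo2) - 1
  if (length(t) != length(spo2)) stop("t must match spo2")
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1

  ct <- vapply(thresholds, function(thr) 100 * mean(spo2 < thr), 0)
  names(ct) <- paste0("ct", thresholds)

  below <- spo2 < event_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends, below = r$values)
  runs$dur <- (runs$end - runs$start + 1) * dt
  # merge below-runs separated by short recoveries
  ev <- runs[runs$below, , drop = FALSE]
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      gap <- (ev$start[i] - merged$end[nrow(merged)] - 1) * dt
      if (gap < min_recovery_s) {
        merged$end[nrow(merged)] <- ev$end[i]
        merged$dur[nrow(merged)] <- merged$dur[nrow(merged)] + gap + ev$dur[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  events <- sum(ev$dur >= min_event_s)

  structure(list(ct = ct, mean = mean(spo2), min = min(spo2),
                 events = events), class = "spo2_report")
}

#' @export
print.spo2_report <- function(x, ...) {
  cat(sprintf("SpO2: mean %.1f%%, min %.1f%%, %s, events %d\n",
              x$mean, x$min,
              paste(sprintf("%s %.1f%%", toupper(names(x$ct)), x$ct),
                    collapse = ", "),
              x$events))
  invisible(x)
}
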