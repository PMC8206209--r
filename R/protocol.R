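#' Perturbation protocol specification
#'
#' Describes one session of the ramp-and-hold (RaH) perturbation protocol:
#' a balanced, pseudo-random sequence of velocity-controlled wrist rotations
#' delivered while the participant holds a background torque, with every
#' perturbation onset aligned to the silent window that follows each fMRI
#' volume acquisition.
#'
#' @param velocities pool of signed perturbation velocities (deg/s). Positive
#'   values are extension rotations (stretching FCR), negative values flexion
#'   rotations (stretching ECU). Must contain 6 elements, 3 magnitudes in both
#'   signs.
#' @param reps_per_velocity repetitions of each velocity per session.
#' @param torque_target background torque the participant holds before each
#'   perturbation (mNm).
#' @param torque_tol torque tolerance that triggers the perturbation (mNm).
#' @param t_hold_range uniform bounds (s) for the hold time between reaching
#'   the torque target and the perturbation.
#' @param perturbation_duration duration of the ramp-and-hold motion (s); the
#'   perturbation is kept active for this fixed time at every velocity.
#' @param rest_range uniform bounds (s) of the rest period after each
#'   perturbation.
#' @param post_return_rest additional rest (s) after the robot returns the
#'   hand to neutral.
#' @param return_velocity velocity of the return movement (deg/s).
#' @param tr volume repetition time of the fMRI sequence (s).
#' @param silent_window duration of the gradient/RF-free window at the end of
#'   each TR period (s), during which EMG is usable.
#' @param n_contractions number of isometric normalization contractions
#'   (interleaved flexion/extension) before the perturbation sequence.
#' @param contraction_torque torque target of the contractions (mNm).
#' @param contraction_duration duration of each contraction (s).
#' @param seed integer seed controlling the trial order and timing draws.
#'
#' @return an object of class `llr_protocol_spec` (a named list).
#' @export
protocol_spec <- function(velocities = c(-200, -125, -50, 50, 125, 200),
                          reps_per_velocity = 10L,
                          torque_target = 200,
                          torque_tol = 25,
                          t_hold_range = c(0.4, 0.8),
                          perturbation_duration = 0.2,
                          rest_range = c(7, 10),
                          post_return_rest = 4,
                          return_velocity = 25,
                          tr = 1.225,
                          silent_window = 0.225,
                          n_contractions = 10L,
                          contraction_torque = 500,
                          contraction_duration = 5,
                          seed = 1L) {
  if (length(velocities) != 6L || length(unique(velocities)) != 6L ||
      !setequal(sign(velocities), c(-1, 1)) ||
      length(unique(abs(velocities))) != 3L) {
    abort("`velocities` must hold 6 distinct values: 3 magnitudes x 2 signs")
  }
  if (length(t_hold_range) != 2L || any(t_hold_range <= 0) ||
      diff(t_hold_range) < 0) {
    abort("`t_hold_range` must be increasing positive bounds")
  }
  if (length(rest_range) != 2L || diff(rest_range) <= 0) {
    abort("`rest_range` lower bound must be below the upper bound")
  }
  stopifnot_scalar(tr, "tr", positive = TRUE)
  stopifnot_scalar(silent_window, "silent_window", positive = TRUE)
  if (tr <= silent_window) abort("`tr` must exceed `silent_window`")
  if (silent_window < 0.225) {
    warn("silent window shorter than 225 ms: the 200 ms EMG segment plus the 25 ms settling gap may not fit")
  }
  stopifnot_scalar(perturbation_duration, "perturbation_duration", positive = TRUE)
  stopifnot_scalar(return_velocity, "return_velocity", positive = TRUE)
  if (reps_per_velocity < 1L) abort("`reps_per_velocity` must be >= 1")
  structure(
    list(velocities = as.numeric(velocities),
         reps_per_velocity = as.integer(reps_per_velocity),
         torque_target = torque_target, torque_tol = torque_tol,
         t_hold_range = t_hold_range,
         perturbation_duration = perturbation_duration,
         rest_range = rest_range, post_return_rest = post_return_rest,
         return_velocity = return_velocity, tr = tr,
         silent_window = silent_window,
         n_contractions = as.integer(n_contractions),
         contraction_torque = contraction_torque,
         contraction_duration = contraction_duration,
         seed = as.integer(seed)),
    class = "llr_protocol_spec")
}

#' Generate a session timeline from a protocol specification
#'
#' Draws a seeded random permutation of the balanced velocity design, then
#' schedules each perturbation: the hold time is drawn uniformly from
#' `t_hold_range`, and the perturbation onset snaps to the first silent-window
#' start (25 ms after a volume acquisition completes) at or after the trigger
#' time, so the entire 200 ms EMG segment is free of gradient activity.
#' Rest, robot return and post-return rest separate consecutive trials.
#'
#' Isometric normalization contractions (alternating flexion/extension) are
#' scheduled before the perturbation sequence, separated by 3 s gaps.
#'
#' @param spec a [protocol_spec()].
#' @return an object of class `llr_protocol`: list with `events` (tibble, one
#'   row per perturbation: `index`, `velocity`, `muscle_stretched`, `onset`,
#'   `t_hold`), `contractions` (tibble: `block`, `direction`, `onset`,
#'   `duration`), `volume_onsets` (numeric, acquisition start times, s),
#'   `session_duration` (s) and `spec`.
#' @export
gen_protocol <- function(spec) {
  if (!inherits(spec, "llr_protocol_spec")) abort("`spec` must come from protocol_spec()")
  withr::with_seed(substream_seed(spec$seed, "protocol"), {
    vels <- sample(rep(spec$velocities, each = spec$reps_per_velocity))
    n <- length(vels)
    t_hold <- runif(n, spec$t_hold_range[1], spec$t_hold_range[2])
    rest <- runif(n, spec$rest_range[1], spec$rest_range[2])

    # contraction phase: alternate flexion/extension, 3 s gaps, 2 s lead-in
    gap <- 3
    c_onset <- 2 + (seq_len(spec$n_contractions) - 1) * (spec$contraction_duration + gap)
    contractions <- tibble(
      block = seq_len(spec$n_contractions),
      direction = rep(c("flexion", "extension"), length.out = spec$n_contractions),
      onset = c_onset,
      duration = spec$contraction_duration)
    t <- max(c_onset) + spec$contraction_duration + 5  # settle before first trial

    t_acq <- spec$tr - spec$silent_window  # acquisition time within each TR
    onset <- numeric(n)
    for (i in seq_len(n)) {
      earliest <- t + t_hold[i]
      # first silent-window start (k*tr + t_acq) no earlier than earliest - 0.025
      k <- ceiling((earliest - t_acq - 0.025) / spec$tr)
      onset[i] <- k * spec$tr + t_acq + 0.025
      ret <- abs(vels[i]) * spec$perturbation_duration / spec$return_velocity
      t <- onset[i] + spec$perturbation_duration + rest[i] + ret + spec$post_return_rest
    }
    session_duration <- t + 2
    n_vol <- ceiling(session_duration / spec$tr)
    events <- tibble(
      index = seq_len(n),
      velocity = vels,
      muscle_stretched = stretched_muscle(vels),
      onset = onset,
      t_hold = t_hold)
  })
  structure(list(events = events, contractions = contractions,
                 volume_onsets = (seq_len(n_vol) - 1) * spec$tr,
                 session_duration = session_duration, spec = spec),
            class = "llr_protocol")
}

#' @export
print.llr_protocol <- function(x, ...) {
  cat(sprintf("<llr_protocol> %d perturbations, %d velocities, %d volumes (TR %.3f s), duration %.1f s\n",
              nrow(x$events), length(x$spec$velocities),
              length(x$volume_onsets), x$spec$tr, x$session_duration))
  invisible(x)
}

#' Write / read a protocol event table
#'
#' Events are stored as a tab-separated table with columns
#' `index`, `muscle`, `direction`, `velocity_deg_s`, `onset_s`, `t_hold_s`
#' (direction of the stretched muscle is always `"stretch"`; the companion
#' muscle's direction is derivable from the velocity sign).
#'
#' @param protocol an `llr_protocol`.
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   the events tibble.
#' @export
write_events <- function(protocol, path) {
  ev <- protocol$events
  out <- data.frame(index = ev$index, muscle = ev$muscle_stretched,
                    direction = "stretch", velocity_deg_s = ev$velocity,
                    onset_s = sprintf("%.6f", ev$onset),
                    t_hold_s = sprintf("%.6f", ev$t_hold))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  tibble(index = as.integer(df$index), velocity = as.numeric(df$velocity_deg_s),
         muscle_stretched = df$muscle, onset = as.numeric(df$onset_s),
         t_hold = as.numeric(df$t_hold_s))
}
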