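#' EMG simulation parameters
#'
#' Parameters of the synthetic surface-EMG generator. Clean EMG is modeled as
#' band-limited (20-250 Hz) Gaussian noise amplitude-modulated by a burst
#' envelope, so the band-pass stage of the processing pipeline passes it
#' essentially unchanged and ground-truth envelope areas have a closed form.
#' Amplitudes are expressed in units of the isometric-contraction level (1.0 =
#' the amplitude held during a normalization contraction), so normalized
#' envelopes are directly comparable across simulated participants.
#'
#' Motion artifacts are driven by a shared motion source derived from the
#' encoder trajectory; the measurement and reference channels see that source
#' through two *different* low-order polynomial nonlinearities with memory
#' (one-pole smoothing), so the two channels are strongly correlated but not
#' affinely related -- plain channel subtraction is imperfect and adaptive
#' noise cancellation has something to learn.
#'
#' @param fs sampling rate (Hz); must be at least 1000 Hz since the analysis
#'   band extends to 250 Hz.
#' @param background_level tonic background EMG amplitude (contraction units).
#' @param slr_gain short-latency burst area per unit speed
#'   (normalized-EMG*ms per deg/s); the burst occupies the 25-50 ms window.
#' @param llr_gain long-latency burst area per unit speed
#'   (normalized-EMG*ms per deg/s); the burst occupies the 50-100 ms window.
#' @param llr_cv trial-to-trial coefficient of variation of the LLR area.
#' @param shortening_scale attenuation of burst areas on trials that shorten
#'   the muscle.
#' @param artifact_gain ratio of the artifact peak to the typical LLR envelope
#'   peak (at the middle perturbation speed). Set to 0 for mock-scanner
#'   ("OUT") sessions with no electromagnetic interference.
#' @param artifact_coeffs_w,artifact_coeffs_r polynomial coefficients (powers
#'   1, 2, 3, ...) of the measurement-channel and reference-channel
#'   nonlinearities applied to the shared motion source. They must differ.
#' @param artifact_pole_w,artifact_pole_r corner frequency (Hz) of the
#'   one-pole smoothing ("memory") of each channel.
#' @param jitter_level broadband jitter added to the motion source, as a
#'   fraction of its peak, gated by the motion magnitude.
#' @param noise_sd sensor noise SD added to each recorded channel
#'   (contraction units).
#'
#' @return an object of class `llr_emg_sim_params`.
#' @export
emg_sim_params <- function(fs = 2000,
                           background_level = 0.02,
                           slr_gain = 0.2,
                           llr_gain = 0.5,
                           llr_cv = 0.2,
                           shortening_scale = 0.2,
                           artifact_gain = 5,
                           artifact_coeffs_w = c(1.0, 0, 0.3),
                           artifact_coeffs_r = c(0.8, 0.2),
                           artifact_pole_w = 50,
                           artifact_pole_r = 70,
                           jitter_level = 0.2,
                           noise_sd = 0.005) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs < 1000) abort("`fs` must be >= 1000 Hz: the EMG analysis band extends to 250 Hz")
  if (identical(as.numeric(artifact_coeffs_w), as.numeric(artifact_coeffs_r)) &&
      artifact_pole_w == artifact_pole_r && artifact_gain > 0) {
    inform("artifact channels are identically related: channel subtraction (SUB) will be exact")
  }
  structure(list(fs = fs, background_level = background_level,
                 slr_gain = slr_gain, llr_gain = llr_gain, llr_cv = llr_cv,
                 shortening_scale = shortening_scale,
                 artifact_gain = artifact_gain,
                 artifact_coeffs_w = as.numeric(artifact_coeffs_w),
                 artifact_coeffs_r = as.numeric(artifact_coeffs_r),
                 artifact_pole_w = artifact_pole_w,
                 artifact_pole_r = artifact_pole_r,
                 jitter_level = jitter_level, noise_sd = noise_sd),
            class = "llr_emg_sim_params")
}

# band-limited (lo-hi Hz) unit-RMS Gaussian carrier; padded to suppress
# filter edge transients
band_noise <- function(n, fs, lo = 20, hi = 250) {
  pad <- min(n, 400L)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  z <- signal::filtfilt(bf, rnorm(n + 2 * pad))
  z <- z[(pad + 1):(pad + n)]
  z / sqrt(mean(z^2))
}

# burst modulation envelope (amplitude, contraction units) for one trial
trial_envelope <- function(t, velocity, muscle, params, eps) {
  scale <- if (stimulus_direction(muscle, velocity) == "stretch") 1 else params$shortening_scale
  h_llr <- params$llr_gain * abs(velocity) * max(0, 1 + eps) * scale
  h_slr <- params$slr_gain * abs(velocity) * scale
  t_ms <- t * 1000
  a <- rep(params$background_level, length(t))
  # Hann bursts: area = peak * width/2  =>  peak = 2 * area / width (ms)
  a <- a + (2 * h_slr / 25) * hann01((t_ms - 25) / 25)
  a <- a + (2 * h_llr / 50) * hann01((t_ms - 50) / 50)
  list(a = a, true_H = h_llr,
       true_area = h_llr + params$background_level * 50)
}

#' Generate the clean EMG of a single trial
#'
#' Produces the 200 ms artifact-window clean signal: tonic background, a
#' short-latency burst in the 25-50 ms window and a long-latency burst in the
#' 50-100 ms window whose envelope area equals
#' `llr_gain * |v| * (1 + eps)`, with `eps ~ Normal(0, llr_cv^2)` drawn per
#' trial. Bursts on shortening trials are attenuated by `shortening_scale`.
#'
#' @param velocity signed perturbation velocity (deg/s).
#' @param muscle `"FCR"` or `"ECU"`; which channel is being simulated.
#' @param params an [emg_sim_params()].
#' @param seed integer seed.
#' @return list with `x` (clean signal), `envelope` (the modulation amplitude
#'   series), `t` (s, 0 at perturbation onset), `true_H` (ground-truth LLR
#'   burst area, normalized-EMG*ms) and `true_area` (burst plus tonic
#'   background over the 50-100 ms window -- what the Eq.-style envelope
#'   integral measures).
#' @export
gen_trial_emg <- function(velocity, muscle, params = emg_sim_params(), seed = 1L) {
  L <- round(0.2 * params$fs)
  t <- (seq_len(L) - 1) / params$fs
  withr::with_seed(substream_seed(seed, "trial_emg"), {
    eps <- rnorm(1, 0, params$llr_cv)
    env <- trial_envelope(t, velocity, muscle, params, eps)
    x <- env$a * band_noise(L, params$fs)
  })
  list(x = x, envelope = env$a, t = t, true_H = env$true_H,
       true_area = env$true_area)
}

one_pole <- function(x, fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
}

polyval1 <- function(coeffs, m) {
  out <- 0
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * m^k
  out
}

#' Generate motion artifacts from an encoder trajectory
#'
#' A shared motion source `m(t)` is built from the low-pass-filtered encoder
#' velocity plus motion-gated broadband jitter, scaled so a 125 deg/s
#' minimum-jerk perturbation has unit peak. The measurement-channel artifact
#' `w` and the reference-channel signal `r` are distinct polynomials of `m`,
#' each smoothed with its own one-pole filter, so `w = g(r)` for a nonlinear
#' `g` but `w != r`. The common output scale is set so the artifact peak is
#' about `artifact_gain` times the typical LLR envelope peak.
#'
#' @param theta encoder angle series (deg).
#' @param params an [emg_sim_params()].
#' @param seed integer seed (jitter).
#' @return list with `w` and `r`, same length as `theta`. A constant `theta`
#'   (no motion, hence no flux change) yields exact zeros.
#' @export
gen_artifact <- function(theta, params = emg_sim_params(), seed = 1L) {
  n <- length(theta)
  fs <- params$fs
  dth <- c(theta[2] - theta[1],
           (theta[3:n] - theta[1:(n - 2)]) / 2,
           theta[n] - theta[n - 1]) * fs
  if (all(dth == 0) || params$artifact_gain == 0) {
    return(list(w = numeric(n), r = numeric(n)))
  }
  bf <- signal::butter(2, 30 / (fs / 2), type = "low")
  m_raw <- signal::filtfilt(bf, dth)
  # reference scale: peak low-passed min-jerk velocity at 125 deg/s
  v_ref <- 1.875 * 125
  withr::with_seed(substream_seed(seed, "artifact"), {
    gate <- abs(m_raw) / max(abs(m_raw))
    jit <- params$jitter_level * max(abs(m_raw)) *
      band_noise(n, fs, 20, 150) * gate
    m <- (m_raw + jit) / v_ref
  })
  w0 <- one_pole(polyval1(params$artifact_coeffs_w, m), params$artifact_pole_w, fs)
  r0 <- one_pole(polyval1(params$artifact_coeffs_r, m), params$artifact_pole_r, fs)
  llr_peak <- 2 * params$llr_gain * 125 / 50
  s <- params$artifact_gain * llr_peak / max(polyval1(params$artifact_coeffs_w, 1), 1e-12)
  list(w = s * w0, r = s * r0)
}

# minimum-jerk position profile 0 -> delta over duration T, sampled at t
min_jerk <- function(t, delta, T) {
  u <- pmin(pmax(t / T, 0), 1)
  delta * (10 * u^3 - 15 * u^4 + 6 * u^5)
}

#' Generate a full synthetic session recording for one muscle
#'
#' Builds the continuous measurement channel `y`, reference channel `r` and
#' encoder angle `theta` for an entire session: isometric normalization
#' contractions (the muscle's own-direction blocks at unit amplitude), then
#' the perturbation sequence with clean bursts, motion artifacts during each
#' perturbation, and sensor noise. The measurement channel satisfies
#' `y = x + w` exactly, with `x` (clean EMG plus sensor noise) and `w` (motion
#' artifact) returned as ground truth.
#'
#' @param protocol an [gen_protocol()] result.
#' @param params an [emg_sim_params()]; set `artifact_gain = 0` to simulate a
#'   mock-scanner ("OUT") session.
#' @param muscle `"FCR"` or `"ECU"`.
#' @param seed integer seed.
#' @return an object of class `llr_recording`: list with `fs`, `y`, `r`,
#'   `theta`, `trial_markers` (1-based onset sample of each perturbation),
#'   `events`, `contraction_blocks` (tibble with `direction`, `onset`,
#'   `duration`, `active`), `muscle`, and `truth` (list: `x`, `w`, `trials`
#'   tibble with per-trial `true_H`/`true_area`, `background_area`).
#' @export
gen_session_recording <- function(protocol, params = emg_sim_params(),
                                  muscle = c("FCR", "ECU"), seed = 1L) {
  muscle <- match.arg(muscle)
  fs <- params$fs
  n <- round(protocol$session_duration * fs)
  ev <- protocol$events
  sd_ <- substream_seed(seed, paste0("session_", muscle))
  withr::with_seed(sd_, {
    amp <- rep(params$background_level, n)
    # contraction blocks: unit amplitude when this muscle is the active one
    active_dir <- if (muscle == "FCR") "flexion" else "extension"
    cb <- protocol$contractions
    cb$active <- cb$direction == active_dir
    for (i in seq_len(nrow(cb))) {
      if (!cb$active[i]) next
      i0 <- round(cb$onset[i] * fs) + 1L
      i1 <- min(n, i0 + round(cb$duration[i] * fs) - 1L)
      amp[i0:i1] <- 1
    }
    # trial bursts + encoder trajectory
    theta <- numeric(n)
    eps <- rnorm(nrow(ev), 0, params$llr_cv)
    Lw <- round(0.2 * fs)
    tw <- (seq_len(Lw) - 1) / fs
    trials <- vector("list", nrow(ev))
    pd <- protocol$spec$perturbation_duration
    for (i in seq_len(nrow(ev))) {
      i0 <- as.integer(round(ev$onset[i] * fs)) + 1L
      idx <- i0:(i0 + Lw - 1L)
      env <- trial_envelope(tw, ev$velocity[i], muscle, params, eps[i])
      amp[idx] <- amp[idx] + (env$a - params$background_level)
      # theta: min-jerk ramp, hold, linear return at return_velocity
      delta <- ev$velocity[i] * pd
      ramp_idx <- i0:(i0 + round(pd * fs) - 1L)
      theta[ramp_idx] <- min_jerk((seq_along(ramp_idx) - 1) / fs, delta, pd)
      hold_end <- min(n, round((ev$onset[i] + pd + 2) * fs))  # hold ~2 s then return
      if (hold_end > max(ramp_idx)) {
        theta[(max(ramp_idx) + 1L):hold_end] <- delta
      }
      ret_len <- round(abs(delta) / protocol$spec$return_velocity * fs)
      if (ret_len > 0 && hold_end < n) {
        ret_idx <- (hold_end + 1L):min(n, hold_end + ret_len)
        theta[ret_idx] <- delta * (1 - seq_along(ret_idx) / ret_len)
      }
      trials[[i]] <- tibble(
        index = ev$index[i], velocity = ev$velocity[i], muscle = muscle,
        direction = stimulus_direction(muscle, ev$velocity[i]),
        true_H = env$true_H, true_area = env$true_area)
    }
    x <- amp * band_noise(n, fs) + params$noise_sd * rnorm(n)
    # artifacts, trial-by-trial over a window covering the perturbation
    w <- numeric(n)
    r <- params$noise_sd * rnorm(n)
    if (params$artifact_gain > 0) {
      for (i in seq_len(nrow(ev))) {
        i0 <- round((ev$onset[i] - 0.05) * fs) + 1L
        i1 <- min(n, round((ev$onset[i] + pd + 0.1) * fs))
        art <- gen_artifact(theta[i0:i1], params, seed = sd_ + i)
        w[i0:i1] <- w[i0:i1] + art$w
        r[i0:i1] <- r[i0:i1] + art$r
      }
    }
    y <- x + w
  })
  structure(list(fs = fs, y = y, r = r, theta = theta,
                 trial_markers = as.integer(round(ev$onset * fs)) + 1L,
                 events = ev, contraction_blocks = cb, muscle = muscle,
                 truth = list(x = x, w = w,
                              trials = dplyr::bind_rows(trials),
                              background_area = params$background_level * 50)),
            class = "llr_recording")
}

#' @export
print.llr_recording <- function(x, ...) {
  cat(sprintf("<llr_recording> muscle %s, %.1f s at %g Hz, %d trials, %d contraction blocks\n",
              x$muscle, length(x$y) / x$fs, x$fs, length(x$trial_markers),
              nrow(x$contraction_blocks)))
  invisible(x)
}

#' Simulate ground-truth LLR amplitude tables for a multi-participant study
#'
#' Table-level companion to [gen_session_recording()]: draws per-trial LLR
#' amplitudes directly from the generative truth model (participant-specific
#' lognormal gains, velocity-proportional means, per-trial coefficient of
#' variation, attenuated shortening responses), without synthesizing raw EMG.
#' Useful for exercising the agreement statistics at realistic study sizes.
#'
#' @param n_participants number of participants.
#' @param sessions character vector of session labels; participants keep their
#'   gains across sessions (test-retest structure), trial noise is redrawn.
#' @param velocities pool of signed velocities (deg/s).
#' @param reps_per_velocity repetitions per velocity and session.
#' @param llr_gain,llr_cv,shortening_scale as in [emg_sim_params()].
#' @param between_sd SD of the participant/muscle lognormal gain factor.
#' @param seed integer seed.
#' @return tibble with columns `participant`, `session`, `muscle`, `velocity`,
#'   `repetition`, `direction`, `H`.
#' @export
sim_llr_study <- function(n_participants = 12, sessions = c("OUT1", "OUT2"),
                          velocities = c(-200, -125, -50, 50, 125, 200),
                          reps_per_velocity = 10, llr_gain = 0.5,
                          llr_cv = 0.2, shortening_scale = 0.2,
                          between_sd = 0.3, seed = 1L) {
  grid <- tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    session = sessions,
    muscle = c("FCR", "ECU"),
    velocity = velocities,
    repetition = seq_len(reps_per_velocity))
  withr::with_seed(substream_seed(seed, "llr_study"), {
    gains <- tidyr::expand_grid(
      participant = sprintf("P%02d", seq_len(n_participants)),
      muscle = c("FCR", "ECU"))
    gains$gain <- llr_gain * exp(rnorm(nrow(gains), 0, between_sd))
    out <- dplyr::left_join(grid, gains, by = c("participant", "muscle"))
    out$direction <- stimulus_direction(out$muscle, out$velocity)
    scale <- ifelse(out$direction == "stretch", 1, shortening_scale)
    eps <- pmax(-0.9, rnorm(nrow(out), 0, llr_cv))
    out$H <- out$gain * abs(out$velocity) * scale * (1 + eps)
  })
  dplyr::select(out, -"gain")
}
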