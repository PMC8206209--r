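#' Segment a session recording into per-trial artifact windows
#'
#' Extracts, for every trial marker, the 200 ms window (the silent-window
#' portion usable for EMG) whose first sample is the perturbation onset, for
#' the measurement channel, the reference channel and the encoder angle.
#' Markers too close to the end of the recording are skipped with a warning.
#'
#' @param recording an `llr_recording` (see [gen_session_recording()] or
#'   [read_recording()]).
#' @param window window length (s), 0.2 by default.
#' @return list of `llr_segment` objects: `y`, `r`, `theta` (raw windows),
#'   `fs`, `t` (s, 0 at onset) and `event` (the matching event row, if any).
#' @export
segment_trials <- function(recording, window = 0.2) {
  L <- round(window * recording$fs)
  n <- length(recording$y)
  out <- list()
  for (k in seq_along(recording$trial_markers)) {
    i0 <- recording$trial_markers[k]
    if (i0 < 1L || i0 + L - 1L > n) {
      warn(sprintf("trial %d marker too close to the recording end; segment skipped", k))
      next
    }
    idx <- i0:(i0 + L - 1L)
    ev <- if (!is.null(recording$events)) recording$events[k, ] else NULL
    out[[length(out) + 1L]] <- structure(
      list(y = recording$y[idx], r = recording$r[idx],
           theta = recording$theta[idx], fs = recording$fs,
           t = (idx - i0) / recording$fs, event = ev,
           muscle = recording$muscle),
      class = "llr_segment")
  }
  out
}

butter_filtfilt <- function(x, w, type) {
  bf <- signal::butter(4, w, type = type)
  signal::filtfilt(bf, x)
}

#' Band-pass filter a trial segment
#'
#' Applies the 4th-order Butterworth band-pass (20-250 Hz corners) to both the
#' measurement and reference channels, zero-phase (forward-backward), which
#' preserves burst latency at the cost of doubling the effective order.
#'
#' @param segment an `llr_segment`.
#' @param lo,hi corner frequencies (Hz).
#' @return the segment with `y_f` and `r_f` fields added.
#' @export
bandpass_segment <- function(segment, lo = 20, hi = 250) {
  if (segment$fs <= 2 * hi) {
    abort(sprintf("sampling rate %g Hz cannot support a %g Hz band-pass corner", segment$fs, hi))
  }
  w <- c(lo, hi) / (segment$fs / 2)
  segment$y_f <- butter_filtfilt(segment$y, w, "pass")
  segment$r_f <- butter_filtfilt(segment$r, w, "pass")
  segment
}

#' Estimate the clean EMG of a segment with a filtering method
#'
#' Three pipelines are supported. `STD` assumes scanner-related movement
#' artifacts are negligible and returns the measurement channel unchanged
#' (`x_hat = y_f`). `SUB` assumes the reference channel measures the true
#' interference and subtracts it (`x_hat = y_f - r_f`). `ANC` subtracts the
#' interference estimated by a trained adaptive-noise-cancellation model
#' (`x_hat = y_f - f_hat(r)`), see [anfis_train()].
#'
#' @param segment a band-passed `llr_segment` (see [bandpass_segment()]).
#' @param method `"STD"`, `"SUB"` or `"ANC"`.
#' @param model a trained `llr_anfis` model; required for `ANC`.
#' @return numeric vector `x_hat`, same length as the segment.
#' @export
apply_filter_method <- function(segment, method = c("STD", "SUB", "ANC"),
                                model = NULL) {
  method <- match.arg(method)
  if (is.null(segment$y_f)) abort("segment must be band-passed first (bandpass_segment())")
  switch(method,
    STD = segment$y_f,
    SUB = segment$y_f - segment$r_f,
    ANC = {
      if (is.null(model)) abort("ANC requires a trained model")
      anfis_denoise(segment$y_f, anfis_inputs(segment), model)
    })
}

#' Rectified low-pass EMG envelope
#'
#' Absolute value followed by a 4th-order Butterworth low-pass at `fc` Hz
#' (zero-phase); negative excursions introduced by the filter are clipped
#' at zero.
#'
#' @param x_hat estimated clean EMG series.
#' @param fs sampling rate (Hz).
#' @param fc envelope cut-off frequency (Hz).
#' @return non-negative envelope series, same length as `x_hat`.
#' @export
emg_envelope <- function(x_hat, fs, fc = 60) {
  env <- butter_filtfilt(abs(x_hat), fc / (fs / 2), "low")
  pmax(env, 0)
}

#' Normalization constant from isometric contractions
#'
#' Mean of the processed (STD pipeline) envelope over the central 3 s of each
#' contraction block in which the muscle is active (flexion blocks for FCR,
#' extension blocks for ECU), averaged across blocks. The same constant
#' normalizes stretch and shortening responses.
#'
#' @param recording an `llr_recording` with contraction blocks.
#' @param muscle `"FCR"` or `"ECU"`.
#' @param central central extent (s) of each block used, 3 s by default.
#' @return list with `muscle` and `value` (mean contraction envelope, > 0).
#' @export
normalization_constant <- function(recording, muscle = recording$muscle,
                                   central = 3) {
  cb <- recording$contraction_blocks
  if (is.null(cb) || nrow(cb) == 0L) abort("recording has no contraction blocks")
  active_dir <- if (muscle == "FCR") "flexion" else "extension"
  cb <- cb[cb$direction == active_dir, , drop = FALSE]
  if (nrow(cb) == 0L) abort(sprintf("no %s contraction blocks for muscle %s", active_dir, muscle))
  if (any(cb$duration < central)) abort("contraction blocks shorter than the central window")
  fs <- recording$fs
  vals <- vapply(seq_len(nrow(cb)), function(i) {
    pad <- (cb$duration[i] - central) / 2
    i0 <- round((cb$onset[i] + pad) * fs) + 1L
    i1 <- i0 + round(central * fs) - 1L
    w <- c(20, 250) / (fs / 2)
    xf <- butter_filtfilt(recording$y[i0:i1], w, "pass")
    mean(emg_envelope(xf, fs))
  }, numeric(1))
  value <- mean(vals)
  if (!is.finite(value) || value <= 0) abort("non-positive normalization constant")
  list(muscle = muscle, value = value)
}

#' LLR amplitude from a processed envelope
#'
#' The long-latency response amplitude is the trapezoidal integral of the
#' normalized envelope over the 50-100 ms window after perturbation onset,
#' with time expressed in milliseconds (units: normalized-EMG*ms). Both
#' window endpoints are included.
#'
#' @param envelope processed envelope covering at least 0-100 ms, with the
#'   first sample at the perturbation onset.
#' @param fs sampling rate (Hz).
#' @param norm normalization constant (see [normalization_constant()]); either
#'   the list or its numeric `value`.
#' @param window integration window (s), `c(0.05, 0.1)` by default.
#' @return non-negative scalar `H`.
#' @export
llr_amplitude <- function(envelope, fs, norm = 1, window = c(0.05, 0.1)) {
  if (is.list(norm)) norm <- norm$value
  t <- (seq_along(envelope) - 1) / fs
  if (window[2] > t[length(t)] + 1e-12) {
    abort("integration window extends past the end of the segment")
  }
  sel <- t >= window[1] - 1e-12 & t <= window[2] + 1e-12
  trapz_int(t[sel] * 1000, envelope[sel] / norm)
}

#' Process one recording into per-trial LLR amplitudes
#'
#' Runs segment -> band-pass -> filtering method -> envelope -> normalization
#' -> windowed integration for every trial of a recording, for one or more
#' filtering methods. For `ANC`, a model is trained per trial segment (the
#' artifact is position-dependent) using [anfis_train()].
#'
#' @param recording an `llr_recording`.
#' @param methods subset of `c("STD", "SUB", "ANC")`.
#' @param participant,session labels copied into the output.
#' @param anfis_config an [anfis_config()]; used only when `"ANC"` is
#'   requested.
#' @param norm optional precomputed [normalization_constant()].
#' @return tibble with columns `participant`, `session`, `filter`, `muscle`,
#'   `velocity`, `repetition`, `direction`, `H`.
#' @export
process_recording <- function(recording, methods = c("STD", "SUB", "ANC"),
                              participant = "P01", session = "S1",
                              anfis_config = NULL, norm = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(norm)) norm <- normalization_constant(recording)
  if (is.null(anfis_config)) anfis_config <- anfis_config()
  segs <- segment_trials(recording)
  rep_counter <- list()
  rows <- vector("list", length(segs) * length(methods))
  k <- 0L
  for (seg in segs) {
    seg <- bandpass_segment(seg)
    v <- seg$event$velocity
    key <- sprintf("%g", v)
    rep_counter[[key]] <- (rep_counter[[key]] %||% 0L) + 1L
    model <- NULL
    if ("ANC" %in% methods) {
      cfg <- anfis_config
      cfg$seed <- substream_seed(cfg$seed, sprintf("anc_%s_%s_%d", participant, session, seg$event$index))
      model <- anfis_train(anfis_inputs(seg), seg$y_f, cfg)
    }
    for (m in methods) {
      x_hat <- apply_filter_method(seg, m, model = model)
      env <- emg_envelope(x_hat, seg$fs)
      H <- llr_amplitude(env, seg$fs, norm)
      k <- k + 1L
      rows[[k]] <- tibble(
        participant = participant, session = session, filter = m,
        muscle = recording$muscle, velocity = v,
        repetition = rep_counter[[key]], index = seg$event$index,
        direction = stimulus_direction(recording$muscle, v), H = H)
    }
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble an LLR amplitude table across recordings
#'
#' Binds per-recording results (see [process_recording()]) into the full
#' factorial table keyed by (participant, session, filter, muscle, velocity,
#' repetition), and checks for duplicate keys. Missing trials stay absent.
#'
#' @param ... tibbles as returned by [process_recording()].
#' @return tibble of class `llr_table`.
#' @export
build_llr_table <- function(...) {
  tbl <- dplyr::bind_rows(...)
  key <- paste(tbl$participant, tbl$session, tbl$filter, tbl$muscle,
               tbl$velocity, tbl$repetition)
  if (anyDuplicated(key)) abort("duplicate (participant, session, filter, muscle, velocity, repetition) keys")
  if (any(tbl$H < 0)) abort("negative LLR amplitudes are not allowed")
  class(tbl) <- c("llr_table", class(tbl))
  tbl
}

#' Per-cell mean LLR amplitudes
#'
#' Averages amplitudes over repetitions within each
#' (participant, session, filter, muscle, velocity) cell.
#'
#' @param tbl an `llr_table` (or compatible tibble with an `H` column).
#' @return tibble with `H_bar` (cell mean) and `n_reps`.
#' @export
llr_means <- function(tbl) {
  dplyr::summarise(
    dplyr::group_by(tbl, dplyr::across(dplyr::any_of(
      c("participant", "session", "filter", "muscle", "velocity", "direction")))),
    H_bar = mean(.data$H), n_reps = dplyr::n(), .groups = "drop")
}

#' Write / read an LLR amplitude table
#'
#' Tidy tab-separated serialization of the per-trial amplitude table.
#'
#' @param tbl an `llr_table`.
#' @param path file path.
#' @export
write_llr_table <- function(tbl, path) {
  out <- as.data.frame(tbl)
  out$H <- sprintf("%.10g", out$H)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_llr_table
#' @export
read_llr_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$H <- as.numeric(df$H)
  build_llr_table(as_tibble(df))
}
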