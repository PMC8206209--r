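# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

tiny_spec <- function(seed = 7L) protocol_spec(reps_per_velocity = 2L, seed = seed)

tiny_protocol <- function() fixture("tiny_protocol", gen_protocol(tiny_spec()))

# small in-scanner session (FCR) with the default nonlinear artifact
tiny_in_recording <- function() {
  fixture("tiny_in", gen_session_recording(tiny_protocol(), emg_sim_params(),
                                           "FCR", seed = 3L))
}

# matching mock-scanner session: no artifact, no sensor noise
tiny_out_recording <- function() {
  fixture("tiny_out", gen_session_recording(
    tiny_protocol(), emg_sim_params(artifact_gain = 0, noise_sd = 0),
    "FCR", seed = 3L))
}

# band-passed segments of the in-scanner session
tiny_segments <- function() {
  fixture("tiny_segments",
          lapply(segment_trials(tiny_in_recording()), bandpass_segment))
}

# a deterministic three-input matrix for ANFIS unit tests
anfis_test_inputs <- function(n = 400L, fs = 2000, seed = 11L) {
  withr::with_seed(seed, {
    th <- 40 * (seq_len(n) - 1) / n
    r <- as.numeric(stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2))
    r[is.na(r)] <- 0
  })
  rd <- c(r[2] - r[1], (r[3:n] - r[1:(n - 2)]) / 2, r[n] - r[n - 1]) * fs
  cbind(r = r, r_dot = rd, theta = th)
}
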