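# internal helpers shared across modules

# Deterministic sub-seed derived from a root seed and a stage name.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483646L) + 1L
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive", name))
  invisible(x)
}

# trapezoidal integral of y over x (both numeric, same length)
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

# Hann (raised cosine) window of unit peak on [0, 1]
hann01 <- function(u) {
  out <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside]))
  out
}

#' Velocity sign to stretched muscle
#'
#' Convention used throughout the package: positive perturbation velocity is a
#' wrist extension rotation, which stretches the flexor carpi radialis (FCR)
#' and shortens the extensor carpi ulnaris (ECU); negative velocity does the
#' opposite.
#'
#' @param velocity signed perturbation velocity (deg/s).
#' @return character vector, `"FCR"` or `"ECU"`.
#' @export
stretched_muscle <- function(velocity) {
  ifelse(velocity > 0, "FCR", "ECU")
}

#' Stimulus direction of a muscle for a given perturbation
#'
#' @param muscle `"FCR"` or `"ECU"`.
#' @param velocity signed perturbation velocity (deg/s).
#' @return `"stretch"` or `"shortening"`.
#' @export
stimulus_direction <- function(muscle, velocity) {
  ifelse(stretched_muscle(velocity) == muscle, "stretch", "shortening")
}
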