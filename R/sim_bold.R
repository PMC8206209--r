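#' Synthetic BOLD phantom with known muscle-specific effects
#'
#' Generates an event-related 4D BOLD series on a small voxel grid: every
#' voxel's time course is
#' `beta_fcr * H*_FCR + beta_ecu * H*_ECU + beta0 + AR(1) noise`, where the
#' two regressors are built by [build_regressor()] from the protocol's trial
#' onsets and per-trial LLR amplitudes (each muscle's stretch trials), exactly
#' as the analysis model specifies. Ground-truth effect maps are two
#' spherical clusters (one per muscle); the default effect size is calibrated
#' so the expected peak t statistic under white noise is `effect_tstat`.
#'
#' @param protocol an [gen_protocol()] result (gives trial onsets and the
#'   volume grid).
#' @param amplitudes optional tibble with per-trial amplitudes (`index`, `H`);
#'   defaults to the truth model `llr_gain * |v|`.
#' @param hrf an [hrf_spec()].
#' @param dim integer length-3 voxel grid.
#' @param voxel_mm voxel size (mm).
#' @param cluster_radius radius (voxels) of each active sphere.
#' @param effect_tstat expected peak t under white noise at `noise_sd`;
#'   determines the beta amplitude inside the truth clusters.
#' @param baseline constant signal level `beta0`.
#' @param noise_sd marginal noise SD (signal units).
#' @param noise_ar1 lag-1 autocorrelation of the noise.
#' @param seed integer seed.
#' @return object of class `llr_bold_phantom`: `data` (4D array), `truth_beta_fcr`,
#'   `truth_beta_ecu` (3D), `reg_fcr`, `reg_ecu` (regressors), `volume_times`,
#'   `voxel_mm`, `beta_amp`, `noise_sd`, `noise_ar1`.
#' @export
gen_bold_phantom <- function(protocol, amplitudes = NULL, hrf = hrf_standard(),
                             dim = c(14, 14, 10), voxel_mm = 2,
                             cluster_radius = 2, effect_tstat = 8,
                             baseline = 100, noise_sd = 1, noise_ar1 = 0.3,
                             seed = 1L) {
  if (length(dim) != 3L || any(dim < 2 * cluster_radius + 1)) {
    abort("`dim` must be 3 positive extents able to hold the truth clusters")
  }
  ev <- protocol$events
  if (is.null(amplitudes)) {
    amplitudes <- tibble(index = ev$index, H = 0.5 * abs(ev$velocity))
  }
  ev <- dplyr::left_join(ev, amplitudes, by = "index")
  if (anyNA(ev$H)) abort("amplitudes missing for some protocol trials")
  vt <- protocol$volume_onsets
  reg <- lapply(c("FCR", "ECU"), function(mu) {
    sel <- ev$muscle_stretched == mu
    build_regressor(ev$onset[sel], ev$H[sel], hrf, vt)
  })
  names(reg) <- c("fcr", "ecu")
  # effect amplitude calibrated against the generating design (white noise)
  X <- cbind(fcr = reg$fcr, ecu = reg$ecu, intercept = 1)
  xtx_inv <- solve(crossprod(X))
  beta_amp <- if (effect_tstat == 0) {
    0
  } else if (noise_sd > 0) {
    effect_tstat * noise_sd * sqrt(xtx_inv[1, 1])
  } else 1
  sphere <- function(center) {
    g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
    d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
    array(as.numeric(d2 <= cluster_radius^2), dim)
  }
  c_fcr <- pmax(round(dim * 0.3), cluster_radius + 1)
  c_ecu <- pmin(round(dim * 0.7), dim - cluster_radius)
  truth_fcr <- sphere(c_fcr) * beta_amp
  truth_ecu <- sphere(c_ecu) * beta_amp
  nv <- length(vt)
  V <- prod(dim)
  withr::with_seed(substream_seed(seed, "bold_phantom"), {
    noise <- matrix(rnorm(nv * V), nv, V)
    if (noise_ar1 != 0) {
      noise <- apply(noise, 2, function(e) {
        as.numeric(stats::filter(e, noise_ar1, method = "recursive"))
      })
      noise <- noise * sqrt(1 - noise_ar1^2)
    }
    noise <- noise * noise_sd
  })
  signal <- outer(reg$fcr, as.numeric(truth_fcr)) +
    outer(reg$ecu, as.numeric(truth_ecu))
  data <- baseline + signal + noise  # volumes x voxels
  data4d <- array(t(data), c(dim, nv))
  structure(list(data = data4d, truth_beta_fcr = truth_fcr,
                 truth_beta_ecu = truth_ecu,
                 reg_fcr = reg$fcr, reg_ecu = reg$ecu,
                 volume_times = vt, voxel_mm = voxel_mm,
                 beta_amp = beta_amp, noise_sd = noise_sd,
                 noise_ar1 = noise_ar1),
            class = "llr_bold_phantom")
}

#' @export
print.llr_bold_phantom <- function(x, ...) {
  cat(sprintf("<llr_bold_phantom> %s voxels x %d volumes, beta = %.3g, noise sd %.3g (AR1 %.2f)\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$beta_amp, x$noise_sd, x$noise_ar1))
  invisible(x)
}
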