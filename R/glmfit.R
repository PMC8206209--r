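#' Hemodynamic response function specification
#'
#' Double-gamma HRF parameterization: the kernel is the difference of two
#' gamma densities (shape = delay / dispersion, scale = dispersion), with the
#' undershoot term scaled by `1 / peak_undershoot_ratio`, sampled on
#' `[0, kernel_length]` and normalized to unit peak. Two presets cover the
#' standard cortical response (peak delay 6 s, undershoot delay 16 s, ratio
#' 6) and the faster brainstem response (peak delay 4.5 s, undershoot delay
#' 10 s, ratio 15); both use 1 s dispersions and a 32 s kernel.
#'
#' @param peak_delay,undershoot_delay delays (s).
#' @param peak_dispersion,undershoot_dispersion dispersions (s), > 0.
#' @param peak_undershoot_ratio ratio of peak to undershoot amplitude.
#' @param onset shift of the response onset (s).
#' @param kernel_length kernel support (s); must exceed `undershoot_delay`.
#' @return object of class `llr_hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6, onset = 0,
                     kernel_length = 32) {
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0) abort("dispersions must be > 0")
  if (kernel_length <= undershoot_delay) abort("`kernel_length` must exceed `undershoot_delay`")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 onset = onset, kernel_length = kernel_length),
            class = "llr_hrf_spec")
}

#' @rdname hrf_spec
#' @export
hrf_standard <- function() hrf_spec()

#' @rdname hrf_spec
#' @export
hrf_brainstem <- function() {
  hrf_spec(peak_delay = 4.5, undershoot_delay = 10, peak_undershoot_ratio = 15)
}

#' Sample an HRF kernel
#'
#' @param spec an [hrf_spec()].
#' @param dt sampling step (s); must be smaller than the kernel length.
#' @return numeric kernel on `seq(0, kernel_length, by = dt)`, unit peak, with
#'   attribute `t` holding the time grid.
#' @export
hrf_kernel <- function(spec, dt = 0.005) {
  if (dt >= spec$kernel_length) abort("`dt` must be smaller than the kernel length")
  t <- seq(0, spec$kernel_length, by = dt)
  ts <- pmax(t - spec$onset, 0)
  h <- dgamma(ts, shape = spec$peak_delay / spec$peak_dispersion,
              scale = spec$peak_dispersion) -
    dgamma(ts, shape = spec$undershoot_delay / spec$undershoot_dispersion,
           scale = spec$undershoot_dispersion) / spec$peak_undershoot_ratio
  h <- h / max(h)
  attr(h, "t") <- t
  h
}

#' Build an amplitude-modulated event regressor
#'
#' Rectangular functions (default 50 ms duration, starting 50 ms after each
#' perturbation onset, height equal to the event's LLR amplitude) are placed
#' on a microtime grid, convolved with the HRF and sampled at the volume
#' acquisition start times.
#'
#' @param onsets event onset times (s).
#' @param amplitudes per-event amplitudes (conventionally the stretch-trial
#'   mean LLR amplitudes of the muscle).
#' @param hrf an [hrf_spec()].
#' @param volume_times volume acquisition start times (s).
#' @param boxcar_duration,onset_offset boxcar duration and post-onset lag (s).
#' @param microtime_dt microtime resolution (s); must be at most half the
#'   boxcar duration.
#' @return numeric design column, one value per volume.
#' @export
build_regressor <- function(onsets, amplitudes, hrf, volume_times,
                            boxcar_duration = 0.05, onset_offset = 0.05,
                            microtime_dt = 0.005) {
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, length(onsets))
  if (length(onsets) != length(amplitudes)) abort("`onsets` and `amplitudes` lengths differ")
  if (boxcar_duration <= 0) abort("`boxcar_duration` must be positive")
  if (microtime_dt > boxcar_duration / 2) abort("`microtime_dt` must be <= boxcar_duration / 2")
  t_end <- max(volume_times) + microtime_dt
  nt <- ceiling(t_end / microtime_dt) + 1L
  u <- numeric(nt)
  for (i in seq_along(onsets)) {
    i0 <- floor((onsets[i] + onset_offset) / microtime_dt) + 1L
    i1 <- i0 + round(boxcar_duration / microtime_dt) - 1L
    if (i0 > nt) next  # event beyond the series: contributes nothing
    idx <- i0:min(i1, nt)
    u[idx] <- u[idx] + amplitudes[i]
  }
  k <- hrf_kernel(hrf, microtime_dt)
  conv <- convolve(u, rev(k), type = "open")[seq_len(nt)] * microtime_dt
  conv[pmin(floor(volume_times / microtime_dt) + 1L, nt)]
}

# discrete-cosine high-pass confound basis (order floor(2 T / cutoff))
dct_basis <- function(n_scans, tr, cutoff) {
  T <- n_scans * tr
  K <- floor(2 * T / cutoff)
  if (K < 1L) return(NULL)
  n <- seq_len(n_scans) - 1
  B <- vapply(seq_len(K), function(k) cos(pi * k * (2 * n + 1) / (2 * n_scans)),
              numeric(n_scans))
  colnames(B) <- sprintf("dct%d", seq_len(K))
  B
}

#' Assemble a GLM design matrix
#'
#' Columns are, in order: the regressors of interest, the six head-motion
#' nuisance series (if given), per-session mean columns (replacing the single
#' intercept when more than one session is concatenated), and a
#' discrete-cosine high-pass basis of order `floor(2 T / cutoff)` per session.
#'
#' @param regressors named list of numeric design columns (one value per
#'   volume), e.g. the FCR and ECU LLR regressors.
#' @param volume_times volume acquisition start times (s).
#' @param nuisance optional matrix of nuisance series (columns).
#' @param sessions optional integer/factor of per-volume session labels.
#' @param highpass_cutoff high-pass cutoff period (s); `NULL` disables the
#'   basis.
#' @return object of class `llr_design`: list with `X` (matrix), `tr`,
#'   `volume_times`, `regressor_cols`.
#' @export
build_design <- function(regressors, volume_times, nuisance = NULL,
                         sessions = NULL, highpass_cutoff = 128) {
  n <- length(volume_times)
  reg <- do.call(cbind, regressors)
  if (is.null(colnames(reg))) colnames(reg) <- names(regressors)
  if (nrow(reg) != n) abort("regressor length must equal the volume count")
  X <- reg
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n) abort("nuisance rows must equal the volume count")
    colnames(nuisance) <- sprintf("nuis%d", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  tr <- if (n > 1) median(diff(volume_times)) else 1
  if (is.null(sessions)) {
    X <- cbind(X, intercept = 1)
    if (!is.null(highpass_cutoff)) {
      B <- dct_basis(n, tr, highpass_cutoff)
      if (!is.null(B)) X <- cbind(X, B)
    }
  } else {
    sessions <- as.factor(sessions)
    for (s in levels(sessions)) {
      col <- as.numeric(sessions == s)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- sprintf("session_%s", s)
    }
    if (!is.null(highpass_cutoff)) {
      for (s in levels(sessions)) {
        idx <- sessions == s
        B <- dct_basis(sum(idx), tr, highpass_cutoff)
        if (is.null(B)) next
        Bfull <- matrix(0, n, ncol(B))
        Bfull[idx, ] <- B
        colnames(Bfull) <- sprintf("%s_s%s", colnames(B), s)
        X <- cbind(X, Bfull)
      }
    }
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(sprintf("rank-deficient design; collinear columns: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(X = X, tr = tr, volume_times = volume_times,
                 regressor_cols = colnames(reg)),
            class = "llr_design")
}

#' Write a design matrix as a tab-separated table
#'
#' @param design an `llr_design`.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  df <- data.frame(volume_time = design$volume_times, design$X,
                   check.names = FALSE)
  write.table(format(df, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# 1D Gaussian convolution along one axis of a 3D array, edge replication
conv_axis <- function(arr, kernel, axis) {
  R <- (length(kernel) - 1L) / 2L
  d <- dim(arr)
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    off <- j - R - 1L
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

#' Gaussian spatial smoothing of a 4D series
#'
#' Separable 3D Gaussian smoothing per volume, with
#' `sigma = FWHM / (2 sqrt(2 ln 2))` converted to voxel units per axis. Any
#' masking is applied *after* smoothing.
#'
#' @param data4d 4D array (x, y, z, volume) or a 3D array (single volume).
#' @param fwhm_mm full width at half maximum (mm); 0 returns the input.
#' @param voxel_mm voxel size (mm), scalar or length-3.
#' @param mask optional logical/0-1 3D array applied after smoothing.
#' @return array of the same shape.
#' @export
smooth_volume <- function(data4d, fwhm_mm, voxel_mm = 2, mask = NULL) {
  if (fwhm_mm < 0) abort("`fwhm_mm` must be >= 0")
  voxel_mm <- rep(voxel_mm, length.out = 3)
  if (fwhm_mm > 0 && any(fwhm_mm < voxel_mm)) {
    warn("smoothing FWHM below the voxel size; applied anyway")
  }
  is3d <- length(dim(data4d)) == 3L
  if (is3d) dim(data4d) <- c(dim(data4d), 1L)
  d <- dim(data4d)
  if (fwhm_mm > 0) {
    sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
    kernels <- lapply(sig, function(s) {
      R <- max(1L, ceiling(3 * s))
      k <- exp(-((-R:R)^2) / (2 * s^2))
      k / sum(k)
    })
    for (v in seq_len(d[4])) {
      vol <- data4d[, , , v, drop = TRUE]
      dim(vol) <- d[1:3]
      for (ax in 1:3) vol <- conv_axis(vol, kernels[[ax]], ax)
      data4d[, , , v] <- vol
    }
  }
  if (!is.null(mask)) {
    for (v in seq_len(d[4])) data4d[, , , v] <- data4d[, , , v] * (mask > 0)
  }
  if (is3d) dim(data4d) <- d[1:3]
  data4d
}

#' Fit a voxelwise GLM by ordinary least squares
#'
#' @param Y numeric matrix, voxels x volumes, or a 4D array (flattened
#'   internally, with the spatial dimensions remembered).
#' @param design an `llr_design` (or a plain design matrix).
#' @return object of class `llr_glm_fit`: `beta` (voxels x columns), `mse`
#'   (residual mean square per voxel), `df`, `XtX_inv`, `design`, and `dim`
#'   (spatial dims when the input was a 4D array).
#' @export
fit_bold_glm <- function(Y, design) {
  X <- if (inherits(design, "llr_design")) design$X else as.matrix(design)
  dim3 <- NULL
  if (length(dim(Y)) == 4L) {
    dim3 <- dim(Y)[1:3]
    Y <- matrix(Y, prod(dim3), dim(Y)[4])
  }
  if (ncol(Y) != nrow(X)) abort("volume count of `Y` must match the design rows")
  if (anyDuplicated(t(X))) abort("design has duplicate columns")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) abort("rank-deficient design matrix")
  df <- nrow(X) - qrx$rank
  if (df <= 0) abort("no residual degrees of freedom")
  beta <- t(qr.coef(qrx, t(Y)))
  resid <- Y - beta %*% t(X)
  mse <- rowSums(resid^2) / df
  structure(list(beta = beta, mse = mse, df = df,
                 XtX_inv = solve(crossprod(X)),
                 columns = colnames(X), dim = dim3),
            class = "llr_glm_fit")
}

#' @export
glance.llr_glm_fit <- function(x, ...) {
  tibble(n_voxels = nrow(x$beta), n_columns = ncol(x$beta), df = x$df,
         mean_mse = mean(x$mse))
}

#' Contrast t-map from a GLM fit
#'
#' `t = c' beta / sqrt(mse * c' (X'X)^-1 c)` per voxel.
#'
#' @param fit an `llr_glm_fit`.
#' @param contrast numeric contrast vector (length = design columns) or the
#'   name of a single design column.
#' @param voxel_mm voxel size carried into the map.
#' @param mask optional 3D mask.
#' @return object of class `llr_stat_map`: `t` (3D array when spatial dims are
#'   known, else vector), `df`, `voxel_mm`, `mask`.
#' @export
contrast_tmap <- function(fit, contrast, voxel_mm = 2, mask = NULL) {
  if (is.character(contrast)) {
    contrast <- as.numeric(fit$columns == contrast)
    if (sum(contrast) != 1) abort("contrast column not found")
  }
  if (length(contrast) != ncol(fit$beta)) abort("contrast length must match the design columns")
  num <- drop(fit$beta %*% contrast)
  cvar <- drop(t(contrast) %*% fit$XtX_inv %*% contrast)
  tval <- if (cvar == 0) rep(0, length(num)) else num / sqrt(fit$mse * cvar)
  tval[!is.finite(tval) & num == 0] <- 0
  if (!is.null(fit$dim)) dim(tval) <- fit$dim
  structure(list(t = tval, df = fit$df, voxel_mm = voxel_mm, mask = mask),
            class = "llr_stat_map")
}

#' Second-level (group) one-sample t-map
#'
#' Voxelwise one-sample t across subject contrast maps, `df = n - 1`. Voxels
#' with zero between-subject variance and a nonzero mean are set to an
#' infinite-t sentinel and flagged.
#'
#' @param maps list of `llr_stat_map`s or numeric arrays (one per subject),
#'   identical grids.
#' @return an `llr_stat_map` with an extra `flagged` logical array marking
#'   zero-variance voxels.
#' @export
second_level_tmap <- function(maps) {
  vals <- lapply(maps, function(m) if (inherits(m, "llr_stat_map")) m$t else m)
  n <- length(vals)
  if (n < 2L) abort("need at least 2 subjects")
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1)))) {
    abort("subject maps have mismatched grids")
  }
  M <- vapply(vals, as.numeric, numeric(length(vals[[1]])))
  mu <- rowMeans(M)
  s <- apply(M, 1, sd)
  tval <- ifelse(s > 0, mu / (s / sqrt(n)),
                 ifelse(mu == 0, 0, sign(mu) * Inf))
  flagged <- s == 0 & mu != 0
  if (!is.null(d)) { dim(tval) <- d; dim(flagged) <- d }
  vm <- if (inherits(maps[[1]], "llr_stat_map")) maps[[1]]$voxel_mm else 2
  structure(list(t = tval, df = n - 1L, voxel_mm = vm, mask = NULL,
                 flagged = flagged),
            class = "llr_stat_map")
}

# 6-connected component labeling of a logical 3D array
label_clusters <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(bin)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, d)
      for (o in seq_len(6)) {
        nb <- ai + offs[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (bin[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

#' Threshold a statistical map
#'
#' A voxel is supra-threshold when `t > t_crit`, with `t_crit` the upper-tail
#' t quantile at `level` (uncorrected) or `level / m` (Bonferroni over the
#' `m` mask voxels). 6-connected clusters smaller than `k` voxels are then
#' removed.
#'
#' @param map an `llr_stat_map`.
#' @param level significance level in (0, 1).
#' @param method `"uncorrected"` or `"bonferroni"`.
#' @param k cluster-extent threshold (voxels).
#' @param mask optional 3D mask (defaults to the map's own, else all voxels).
#' @return object of class `llr_thresholded`: `binary` array, `clusters`
#'   tibble (`cluster`, `size`, `peak_t`, `peak_x`, `peak_y`, `peak_z`),
#'   `t_crit`, `n_tests`.
#' @export
threshold_map <- function(map, level = 0.001,
                          method = c("uncorrected", "bonferroni"), k = 0L,
                          mask = NULL) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  tarr <- map$t
  if (is.null(dim(tarr))) dim(tarr) <- c(length(tarr), 1L, 1L)
  mask <- mask %||% map$mask
  if (is.null(mask)) mask <- array(TRUE, dim(tarr))
  mask <- array(mask > 0, dim(tarr))
  m <- sum(mask)
  if (m == 0L) abort("empty mask")
  alpha <- if (method == "bonferroni") level / m else level
  t_crit <- qt(1 - alpha, map$df)
  bin <- (tarr > t_crit) & mask
  bin[is.na(bin)] <- FALSE
  lab <- label_clusters(bin)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  rows <- list()
  for (cl in seq_along(sizes)) {
    if (sizes[cl] < k) {
      bin[lab == cl] <- FALSE
      next
    }
    vox <- which(lab == cl)
    pk <- vox[which.max(tarr[vox])]
    ai <- arrayInd(pk, dim(tarr))
    rows[[length(rows) + 1L]] <- tibble(
      cluster = length(rows) + 1L, size = sizes[cl],
      peak_t = tarr[pk], peak_x = ai[1], peak_y = ai[2], peak_z = ai[3])
  }
  clusters <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(cluster = integer(), size = integer(), peak_t = numeric(),
           peak_x = integer(), peak_y = integer(), peak_z = integer())
  structure(list(binary = bin, clusters = clusters, t_crit = t_crit,
                 n_tests = m, level = level, method = method, k = k),
            class = "llr_thresholded")
}

#' @export
print.llr_stat_map <- function(x, ...) {
  cat(sprintf("<llr_stat_map> %s voxels, df = %s, t range [%.3g, %.3g]\n",
              paste(dim(x$t) %||% length(x$t), collapse = "x"), x$df,
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.llr_thresholded <- function(x, ...) {
  cat(sprintf("<llr_thresholded> %s at level %g (t_crit %.3f, %d tests): %d voxels in %d clusters\n",
              x$method, x$level, x$t_crit, x$n_tests, sum(x$binary),
              nrow(x$clusters)))
  invisible(x)
}
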