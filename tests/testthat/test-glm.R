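test_that("HRF kernels span 32 s, undershoot, and peak in the right order", {
  k_std <- hrf_kernel(hrf_standard(), 0.01)
  k_bs <- hrf_kernel(hrf_brainstem(), 0.01)
  expect_equal(max(attr(k_std, "t")), 32)
  expect_equal(max(k_std), 1)
  expect_lt(min(k_std), 0)  # undershoot exists
  expect_lt(min(k_bs), 0)
  expect_lt(attr(k_bs, "t")[which.max(k_bs)],
            attr(k_std, "t")[which.max(k_std)])
  expect_error(hrf_kernel(hrf_standard(), 40), "dt")
  expect_error(hrf_spec(kernel_length = 10), "kernel_length")
  expect_error(hrf_spec(peak_dispersion = 0), "dispersions")
})

test_that("event regressor matches a brute-force microtime convolution", {
  vt <- (0:199) * 1.225
  hrf <- hrf_standard()
  # single unit event: direct discrete convolution oracle
  reg <- build_regressor(10, 1, hrf, vt)
  dt <- 0.005
  nt <- ceiling((max(vt) + dt) / dt) + 1L
  u <- numeric(nt)
  i0 <- floor(10.05 / dt) + 1L
  u[i0:(i0 + round(0.05 / dt) - 1L)] <- 1
  k <- hrf_kernel(hrf, dt)
  oracle <- numeric(nt)
  for (m in which(u > 0)) {
    span <- m:min(nt, m + length(k) - 1L)
    oracle[span] <- oracle[span] + u[m] * k[seq_along(span)] * dt
  }
  expect_equal(reg, oracle[floor(vt / dt) + 1L], tolerance = 1e-9)
  # linearity and zero amplitude
  expect_equal(build_regressor(c(10, 50), c(2, 4), hrf, vt),
               2 * build_regressor(c(10, 50), c(1, 2), hrf, vt))
  expect_equal(build_regressor(c(10, 50), c(0, 0), hrf, vt), numeric(200))
  # event beyond the series contributes nothing, without error
  expect_equal(build_regressor(c(10, 1e5), c(1, 5), hrf, vt),
               build_regressor(10, 1, hrf, vt))
  expect_error(build_regressor(10, 1, hrf, vt, microtime_dt = 0.04), "microtime")
})

test_that("design assembly handles sessions, DCT order and collinearity", {
  vt <- (0:489) * 1.225  # ~600 s session
  reg <- list(fcr = sin(vt / 40), ecu = cos(vt / 55))
  d <- build_design(reg, vt)
  # order rule: floor(2 * 600 / 128) = 9 DCT columns plus intercept
  expect_equal(sum(grepl("^dct", colnames(d$X))), 9L)
  expect_true("intercept" %in% colnames(d$X))
  # no high-pass: regressors + intercept only
  d0 <- build_design(reg, vt, highpass_cutoff = NULL)
  expect_equal(colnames(d0$X), c("fcr", "ecu", "intercept"))
  # two equal-length sessions: session means replace the intercept
  ses <- rep(1:2, each = 245)
  d2 <- build_design(reg, vt, sessions = ses, highpass_cutoff = NULL)
  expect_equal(sum(grepl("^session_", colnames(d2$X))), 2L)
  expect_false("intercept" %in% colnames(d2$X))
  # collinear columns are named in the error
  expect_error(build_design(c(reg, list(dup = reg$fcr)), vt,
                            highpass_cutoff = NULL),
               "collinear.*dup|dup.*collinear")
  # nuisance block is appended with its own names
  nuis <- matrix(rnorm(490 * 6), 490)
  d6 <- build_design(reg, vt, nuisance = nuis, highpass_cutoff = NULL)
  expect_equal(sum(grepl("^nuis", colnames(d6$X))), 6L)
})

test_that("Gaussian smoothing preserves mass, constants and the delta profile", {
  vol <- array(0, c(15, 15, 11))
  vol[8, 8, 6] <- 1
  sm <- smooth_volume(vol, fwhm_mm = 4, voxel_mm = 2)
  expect_equal(sum(sm), 1, tolerance = 0.01)
  sig <- 4 / (2 * sqrt(2 * log(2))) / 2
  prof <- sm[, 8, 6] / sm[8, 8, 6]
  expect_equal(prof[9], exp(-1 / (2 * sig^2)), tolerance = 0.01)
  # identity and constant invariance
  expect_identical(smooth_volume(vol, 0), vol)
  const <- array(3, c(8, 8, 8))
  expect_equal(smooth_volume(const, 8, 2), const, tolerance = 1e-9)
  expect_warning(smooth_volume(vol, 1, voxel_mm = 2), "FWHM")
  # masking applied after smoothing
  mask <- array(FALSE, dim(vol)); mask[8, 8, 6] <- TRUE
  sm2 <- smooth_volume(vol, 4, 2, mask = mask)
  expect_equal(sm2[8, 8, 6], sm[8, 8, 6])
  expect_equal(sum(sm2 != 0), 1L)
})

test_that("OLS fit recovers noiseless betas and the orthonormal identity", {
  withr::with_seed(5, {
    X <- qr.Q(qr(matrix(rnorm(60 * 3), 60)))
    colnames(X) <- c("a", "b", "c")
    B <- matrix(rnorm(30), 10, 3)
  })
  Y <- B %*% t(X)
  fit <- fit_bold_glm(Y, X)
  expect_equal(fit$beta, B, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$df, 57)
  # orthonormal design: beta = X' y
  expect_equal(fit$beta, Y %*% X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_bold_glm(Y, cbind(X, X[, 1])), "duplicate|rank")
  expect_error(fit_bold_glm(Y[, -1], X), "volume count")
})

test_that("contrast t-maps follow the analytic t formula and invariances", {
  withr::with_seed(7, {
    n <- 120
    x <- rnorm(n)
    X <- cbind(x = x, intercept = 1)
    beta_true <- 0.8
    Y <- matrix(rnorm(1000 * n, sd = 2), 1000) +
      matrix(beta_true * x, 1000, n, byrow = TRUE)
  })
  fit <- fit_bold_glm(Y, X)
  tm <- contrast_tmap(fit, c(1, 0))
  se <- 2 * sqrt(solve(crossprod(X))[1, 1])
  expect_equal(mean(tm$t), beta_true / se, tolerance = 0.1)
  # c = 0 -> zero map; scaling c leaves t unchanged
  expect_equal(contrast_tmap(fit, c(0, 0))$t, rep(0, 1000))
  expect_equal(contrast_tmap(fit, c(2, 0))$t, tm$t, tolerance = 1e-12)
  expect_error(contrast_tmap(fit, c(1, 0, 0)), "length")
})

test_that("second-level map flags zero-variance voxels and uses df = n - 1", {
  m <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  maps <- replicate(18, m, simplify = FALSE)
  g <- second_level_tmap(maps)
  expect_equal(g$df, 17)
  expect_true(all(is.infinite(g$t[m != 0])))
  expect_true(all(g$flagged[m != 0]))
  # zero-mean voxels across subjects give t near 0
  withr::with_seed(1, {
    maps2 <- lapply(1:10, function(i) array(rnorm(100), c(5, 5, 4)))
  })
  g2 <- second_level_tmap(maps2)
  expect_lt(abs(mean(g2$t)), 0.2)
  expect_error(second_level_tmap(maps2[1]), "2 subjects")
})

test_that("thresholding uses t quantiles, Bonferroni and cluster extent", {
  tarr <- array(0, c(8, 8, 4))
  tarr[2:3, 2, 2] <- 5          # cluster of 2
  tarr[6, 6, 3] <- 6            # singleton
  map <- structure(list(t = tarr, df = 17, voxel_mm = 2, mask = NULL),
                   class = "llr_stat_map")
  thr <- threshold_map(map, 0.001)
  expect_equal(thr$t_crit, 3.646, tolerance = 1e-3)  # t quantile, df 17
  expect_equal(sum(thr$binary), 3L)
  expect_equal(nrow(thr$clusters), 2L)
  expect_equal(sort(thr$clusters$size), c(1L, 2L))
  # cluster extent removes small clusters; k beyond all sizes empties the map
  thr2 <- threshold_map(map, 0.001, k = 2L)
  expect_equal(sum(thr2$binary), 2L)
  expect_equal(sum(threshold_map(map, 0.001, k = 10L)$binary), 0L)
  # bonferroni with a single-voxel mask equals uncorrected
  mask1 <- array(FALSE, dim(tarr)); mask1[6, 6, 3] <- TRUE
  tb <- threshold_map(map, 0.01, "bonferroni", mask = mask1)
  tu <- threshold_map(map, 0.01, "uncorrected", mask = mask1)
  expect_equal(tb$t_crit, tu$t_crit)
  # t_crit nondecreasing in mask size
  masks <- c(4, 32, 256)
  crits <- vapply(masks, function(m) {
    mk <- array(FALSE, dim(tarr)); mk[seq_len(m)] <- TRUE
    threshold_map(map, 0.05, "bonferroni", mask = mk)$t_crit
  }, numeric(1))
  expect_true(all(diff(crits) > 0))
  expect_error(threshold_map(map, 0.001, mask = array(FALSE, dim(tarr))),
               "mask")
})
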