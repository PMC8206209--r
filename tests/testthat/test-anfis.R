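test_that("interference inputs carry the reference, its derivative and the angle", {
  seg <- tiny_segments()[[1]]
  X <- anfis_inputs(seg)
  expect_identical(colnames(X), c("r", "r_dot", "theta"))
  expect_identical(X[, "r"], seg$r_f)
  # constant r -> zero derivative; linear r -> constant derivative
  fake <- seg
  fake$r_f <- rep(2, length(seg$r_f))
  expect_equal(anfis_inputs(fake)[, "r_dot"], numeric(length(seg$r_f)))
  fake$r_f <- seq_along(seg$r_f) / seg$fs
  expect_equal(anfis_inputs(fake)[2:399, "r_dot"], rep(1, 398))
  fake$theta <- fake$theta[-1]
  expect_error(anfis_inputs(fake), "length")
})

test_that("grid-partition init places centers over the observed range", {
  X <- cbind(r = c(0, 0.25, 0.5, 0.75, 1), r_dot = c(-2, -1, 0, 1, 2),
             theta = 1:5)
  m <- anfis_init(anfis_config(mfs_per_input = 3L), X)
  expect_equal(m$premise[[1]][, "c"], c(0, 0.5, 1))
  expect_equal(m$premise[[1]][, "a"], rep(1 / 4, 3))
  expect_equal(m$premise[[1]][, "b"], rep(2, 3))
  expect_equal(nrow(m$rule_idx), 27L)  # 3 inputs x 3 MFs
  # zero-range input collapses to unit-width MFs, without NaN downstream
  X0 <- X; X0[, "theta"] <- 5
  expect_warning(m0 <- anfis_init(anfis_config(), X0), "zero range")
  expect_false(anyNA(anfis_forward(m0, X0)))
})

test_that("forward pass matches a hand-computed two-rule layer oracle", {
  # one input active (2 MFs), other two inputs single wide MF (always ~1)
  premise <- list(cbind(a = c(1, 1), b = c(2, 2), c = c(0, 2)),
                  cbind(a = 1e6, b = 2, c = 0),
                  cbind(a = 1e6, b = 2, c = 0))
  cons <- rbind(c(1, 0, 0, 0.5),   # rule 1: f = r + 0.5
                c(-2, 0, 0, 1))    # rule 2: f = -2 r + 1
  m <- anfis_model(premise, cons)
  x <- c(0.7, -0.1, 0.3)
  mu1 <- 1 / (1 + ((x[1] - 0) / 1)^4)
  mu2 <- 1 / (1 + ((x[1] - 2) / 1)^4)
  f1 <- x[1] + 0.5; f2 <- -2 * x[1] + 1
  manual <- (mu1 * f1 + mu2 * f2) / (mu1 + mu2)
  expect_equal(anfis_forward(m, matrix(x, 1)), manual, tolerance = 1e-9)
  # single rule: output is that rule's linear function
  m1 <- anfis_model(list(cbind(a = 1e6, b = 2, c = 0),
                         cbind(a = 1e6, b = 2, c = 0),
                         cbind(a = 1e6, b = 2, c = 0)),
                    matrix(c(2, -1, 0.5, 3), 1))
  X <- anfis_test_inputs(50)
  expect_equal(anfis_forward(m1, X),
               drop(cbind(X, 1) %*% c(2, -1, 0.5, 3)), tolerance = 1e-9)
  # zero consequents give a zero interference estimate
  m1$consequents[] <- 0
  expect_equal(anfis_forward(m1, X), numeric(50))
})

test_that("analytic premise gradient matches central differences", {
  X <- anfis_test_inputs(120)
  y <- 0.5 * X[, "r"] + 0.01 * X[, "theta"] + sin(X[, "r"])
  m <- anfis_init(anfis_config(), X)
  withr::with_seed(4, m$consequents <- matrix(rnorm(32, sd = 0.2), 8, 4))
  g <- llrpipe:::anfis_premise_grad(m, X, y)
  sse <- function(mod) sum((anfis_forward(mod, X) - y)^2)
  for (i in 1:3) for (mf in 1:2) for (p in 1:3) {
    h <- 1e-6 * max(abs(m$premise[[i]][mf, p]), 1)
    up <- m; up$premise[[i]][mf, p] <- up$premise[[i]][mf, p] + h
    dn <- m; dn$premise[[i]][mf, p] <- dn$premise[[i]][mf, p] - h
    expect_equal(g[[i]][mf, p], (sse(up) - sse(dn)) / (2 * h),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("hybrid training solves affine interference exactly (least-squares step)", {
  X <- anfis_test_inputs(400)
  y <- 2 * X[, "r"] + 0.5
  m <- anfis_train(X, y, anfis_config(seed = 3))
  expect_lt(sqrt(mean(anfis_denoise(y, X, m)^2)), 1e-6 * sqrt(mean(y^2)))
  # full affine case matches an ordinary least-squares oracle
  y2 <- 1.5 * X[, "r"] - 0.002 * X[, "r_dot"] + 0.3 * X[, "theta"] + 0.7
  m2 <- anfis_train(X, y2, anfis_config(seed = 5))
  lm_res <- sqrt(mean(resid(lm(y2 ~ X))^2))
  anfis_res <- sqrt(mean(anfis_denoise(y2, X, m2)^2))
  expect_lt(abs(anfis_res - lm_res), 1e-6 * sqrt(mean(y2^2)))
})

test_that("training trace and snapshot selection behave as specified", {
  X <- anfis_test_inputs(300, seed = 21)
  y <- X[, "r"]^2 + 0.1 * X[, "theta"]
  cfg <- anfis_config(epochs = 8L, seed = 9)
  m <- anfis_train(X, y, cfg)
  expect_equal(nrow(m$trace), 8L)
  expect_equal(m$selected_epoch, which.min(m$trace$val_rmse))
  # selection never does worse than epoch 1's validation error
  expect_lte(m$trace$val_rmse[m$selected_epoch], m$trace$val_rmse[1])
  # epochs = 1 selects epoch 1
  m1 <- anfis_train(X, y, anfis_config(epochs = 1L, seed = 9))
  expect_equal(m1$selected_epoch, 1L)
  # full-path determinism
  m2 <- anfis_train(X, y, cfg)
  expect_identical(m$consequents, m2$consequents)
  expect_identical(anfis_denoise(y, X, m), anfis_denoise(y, X, m2))
})

test_that("denoising is linear in the measurement for a fixed model", {
  X <- anfis_test_inputs(200)
  y1 <- X[, "r"] * 0.5; y2 <- cos(seq_len(200) / 20)
  m <- anfis_train(X, y1, anfis_config(seed = 2))
  expect_equal(anfis_denoise(y1 + y2, X, m),
               anfis_denoise(y1, X, m) + y2)
  mz <- m; mz$consequents[] <- 0
  expect_identical(anfis_denoise(y2, X, mz), y2)
  expect_error(anfis_denoise(y2[-1], X, m), "length")
})

test_that("ANC improves the clean-signal correlation over the uncorrected signal", {
  # parameter-recovery property: with the default nonlinear artifact and a
  # clean component present, the trained filter tracks the clean signal
  # better than leaving the artifact in. (Superiority over plain channel
  # subtraction shows up in the LLR-amplitude accuracy, covered by the
  # session-level ranking test: subtraction keeps waveform correlation high
  # while leaving a large envelope-amplitude residual.)
  wins_std <- 0L
  n_seeds <- 20L
  cors <- matrix(NA_real_, n_seeds, 2)
  pr <- tiny_protocol()
  for (s in seq_len(n_seeds)) {
    rec <- gen_session_recording(pr, emg_sim_params(), "FCR", seed = 100L + s)
    k <- 2L + (s %% 10L)  # rotate across trials
    seg <- bandpass_segment(segment_trials(rec)[[k]])
    i0 <- rec$trial_markers[k]
    idx <- i0:(i0 + length(seg$y) - 1L)
    x_f <- llrpipe:::butter_filtfilt(rec$truth$x[idx],
                                     c(20, 250) / (rec$fs / 2), "pass")
    m <- anfis_train(anfis_inputs(seg), seg$y_f, anfis_config(seed = s))
    x_hat <- anfis_denoise(seg$y_f, anfis_inputs(seg), m)
    cors[s, ] <- c(cor(seg$y_f, x_f), cor(x_hat, x_f))
    if (cors[s, 2] > cors[s, 1]) wins_std <- wins_std + 1L
  }
  expect_gte(wins_std, 17L)
  expect_gt(mean(cors[, 2]), mean(cors[, 1]) + 0.1)
})

test_that("models serialize to JSON and restore the same mapping", {
  X <- anfis_test_inputs(200)
  y <- X[, "r"]^2
  m <- anfis_train(X, y, anfis_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_anfis(m, path)
  back <- read_anfis(path)
  expect_equal(anfis_forward(back, X), anfis_forward(m, X), tolerance = 1e-12)
  expect_equal(back$selected_epoch, m$selected_epoch)
})

test_that("tidy and glance summarize a trained model", {
  X <- anfis_test_inputs(150)
  m <- anfis_train(X, X[, "r"], anfis_config(epochs = 3L, seed = 1))
  td <- tidy(m)
  expect_equal(nrow(td), 6L)  # 3 inputs x 2 MFs
  gl <- glance(m)
  expect_equal(gl$epochs, 3L)
  expect_equal(gl$n_rules, 8L)
})
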