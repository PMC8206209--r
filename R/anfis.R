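#' ANFIS training configuration
#'
#' Settings for the adaptive-noise-cancellation filter: a first-order
#' Takagi-Sugeno fuzzy inference system whose premise membership functions
#' are tuned by gradient descent and whose per-rule linear consequents are
#' solved by least squares (hybrid learning). Overfitting is controlled by
#' holding out one contiguous random interval of the time series per epoch
#' and keeping the parameters with the minimum validation error.
#'
#' @param mfs_per_input membership functions per input (grid partition); the
#'   rule count is `mfs_per_input ^ 3`. The default of 2 (8 rules, 32 linear
#'   consequents) keeps the consequent count an order of magnitude below the
#'   ~400 samples of a 200 ms trial segment; larger grids overfit short
#'   segments.
#' @param mf_type `"generalized_bell"` or `"gaussian"`.
#' @param epochs training epochs.
#' @param step_size initial premise step size (normalized-gradient step,
#'   scaled per parameter by the input range).
#' @param step_increase,step_decrease adaptive step-size factors: increase
#'   after 4 consecutive error drops, decrease after up-down oscillation.
#' @param val_fraction fraction of samples held out as one contiguous
#'   validation interval, redrawn each epoch. Must lie in (0, 0.5).
#' @param seed integer seed (validation-interval draws).
#' @return an object of class `llr_anfis_config`.
#' @export
anfis_config <- function(mfs_per_input = 2L,
                         mf_type = c("generalized_bell", "gaussian"),
                         epochs = 10L, step_size = 0.02,
                         step_increase = 1.1, step_decrease = 0.9,
                         val_fraction = 0.2, seed = 1L) {
  mf_type <- match.arg(mf_type)
  if (mfs_per_input < 2L) abort("`mfs_per_input` must be >= 2")
  if (val_fraction <= 0 || val_fraction >= 0.5) abort("`val_fraction` must be in (0, 0.5)")
  if (epochs < 1L) abort("`epochs` must be >= 1")
  structure(list(mfs_per_input = as.integer(mfs_per_input), mf_type = mf_type,
                 epochs = as.integer(epochs), step_size = step_size,
                 step_increase = step_increase, step_decrease = step_decrease,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "llr_anfis_config")
}

#' Interference-input matrix for adaptive noise cancellation
#'
#' Builds the three-component interference vector used by the ANC filter: the
#' band-passed reference signal `r`, its time derivative (central differences,
#' one-sided at the ends, scaled by the sampling rate) and the encoder angle.
#'
#' @param segment a band-passed `llr_segment`, or a numeric matrix with three
#'   columns (`r`, `r_dot`, `theta`) passed through unchanged.
#' @return numeric matrix with columns `r`, `r_dot`, `theta`.
#' @export
anfis_inputs <- function(segment) {
  if (is.matrix(segment)) {
    if (ncol(segment) != 3L) abort("input matrix must have 3 columns (r, r_dot, theta)")
    colnames(segment) <- c("r", "r_dot", "theta")
    return(segment)
  }
  if (is.null(segment$r_f)) abort("segment must be band-passed first (bandpass_segment())")
  r <- segment$r_f
  n <- length(r)
  if (length(segment$theta) != n) abort("reference and encoder series differ in length")
  r_dot <- c(r[2] - r[1], (r[3:n] - r[1:(n - 2)]) / 2, r[n] - r[n - 1]) * segment$fs
  cbind(r = r, r_dot = r_dot, theta = segment$theta)
}

# membership value and d(log mu)/d(a,b,c) for generalized bell / gaussian.
# x: vector; p: c(a, b, c). Returns list(mu, and optionally gradient parts).
mf_eval <- function(x, p, type) {
  a <- p[1]; b <- p[2]; c0 <- p[3]
  if (type == "generalized_bell") {
    u <- ((x - c0) / a)^2
    tb <- u^b
    1 / (1 + tb)
  } else {
    exp(-((x - c0)^2) / (2 * a^2))
  }
}

mf_dlog <- function(x, p, type) {
  a <- p[1]; b <- p[2]; c0 <- p[3]
  if (type == "generalized_bell") {
    u <- ((x - c0) / a)^2
    tb <- u^b
    D <- 1 + tb
    dla <- 2 * b * tb / (a * D)
    dlc <- 2 * b * u^(b - 1) * (x - c0) / (a^2 * D)
    dlc[u == 0] <- 0
    dlb <- ifelse(u > 0, -tb * log(u) / D, 0)
    cbind(a = dla, b = dlb, c = dlc)
  } else {
    cbind(a = (x - c0)^2 / a^3, b = 0, c = (x - c0) / a^2)
  }
}

#' Construct an ANFIS model from explicit parameters
#'
#' Low-level constructor; most callers use [anfis_init()] or [anfis_train()].
#'
#' @param premise list with one `K x 3` matrix per input (columns `a`, `b`,
#'   `c`: width, slope, center). Inputs may use different `K`.
#' @param consequents `R x 4` matrix of per-rule linear coefficients
#'   (`r`, `r_dot`, `theta`, bias), where `R` is the product of the per-input
#'   membership-function counts.
#' @param mf_type membership-function family.
#' @return object of class `llr_anfis`.
#' @export
anfis_model <- function(premise, consequents,
                        mf_type = c("generalized_bell", "gaussian")) {
  mf_type <- match.arg(mf_type)
  ks <- vapply(premise, nrow, integer(1))
  rule_idx <- as.matrix(expand.grid(lapply(ks, seq_len)))
  colnames(rule_idx) <- NULL
  if (nrow(consequents) != nrow(rule_idx) || ncol(consequents) != 4L) {
    abort("consequents must be (prod of MF counts) x 4")
  }
  structure(list(premise = premise, consequents = consequents,
                 rule_idx = rule_idx, mf_type = mf_type,
                 trace = NULL, selected_epoch = NA_integer_),
            class = "llr_anfis")
}

#' Initialize an ANFIS model by grid partition
#'
#' Membership-function centers are equally spaced over each input's observed
#' range, widths are `range / (2 * (K - 1))`, the bell slope is 2, and
#' consequents start at zero. A zero-range input would collapse its
#' membership functions; it is replaced by unit-width functions around the
#' constant value, with a warning.
#'
#' @param config an [anfis_config()].
#' @param inputs matrix from [anfis_inputs()].
#' @return an untrained `llr_anfis` model.
#' @export
anfis_init <- function(config, inputs) {
  K <- config$mfs_per_input
  premise <- vector("list", 3L)
  for (i in 1:3) {
    lo <- min(inputs[, i]); hi <- max(inputs[, i])
    if (hi - lo <= 0) {
      warn(sprintf("input %d has zero range; using unit-width membership functions", i))
      centers <- lo + seq(-0.5, 0.5, length.out = K)
      a <- 1
    } else {
      centers <- seq(lo, hi, length.out = K)
      a <- (hi - lo) / (2 * (K - 1))
    }
    premise[[i]] <- cbind(a = rep(a, K), b = rep(2, K), c = centers)
  }
  m <- anfis_model(premise, matrix(0, K^3, 4L), config$mf_type)
  m$ranges <- apply(inputs, 2, function(v) diff(range(v)))
  m$ranges[m$ranges <= 0] <- 1
  m
}

# layer 1-3: normalized firing strengths (N x R); flags all-zero rows
anfis_weights <- function(model, X) {
  n <- nrow(X)
  R <- nrow(model$rule_idx)
  W <- matrix(1, n, R)
  M <- vector("list", 3L)
  for (i in 1:3) {
    P <- model$premise[[i]]
    M[[i]] <- vapply(seq_len(nrow(P)),
                     function(m) mf_eval(X[, i], P[m, ], model$mf_type),
                     numeric(n))
    if (n == 1L) M[[i]] <- matrix(M[[i]], nrow = 1L)
    W <- W * M[[i]][, model$rule_idx[, i], drop = FALSE]
  }
  S <- rowSums(W)
  zero <- S <= 0
  if (any(zero)) {
    W[zero, ] <- 1 / R
    S[zero] <- 1
    inform(sprintf("%d samples fired no rule; uniform weights used", sum(zero)))
  }
  list(W = W, S = S, Wn = W / S, M = M)
}

#' Evaluate an ANFIS model
#'
#' First-order Sugeno forward pass: per-sample membership degrees, product
#' T-norm rule firing strengths, normalized weights, and the weighted sum of
#' per-rule linear outputs.
#'
#' @param model an `llr_anfis`.
#' @param inputs matrix from [anfis_inputs()].
#' @return numeric vector, one interference estimate per sample.
#' @export
anfis_forward <- function(model, inputs) {
  lw <- anfis_weights(model, inputs)
  X1 <- cbind(inputs, 1)
  Fmat <- X1 %*% t(model$consequents)
  rowSums(lw$Wn * Fmat)
}

# Least-squares consequents given premises. Rules that barely fire on the
# training samples make the system numerically singular (near-zero columns);
# those are detected by the R-diagonal of the pivoted QR and handled by a
# column-scaled ridge fallback that shrinks weakly determined consequents
# toward zero instead of letting them explode on held-out samples.
anfis_lse <- function(Wn, X1, y, verbose = FALSE) {
  R <- ncol(Wn)
  A <- Wn[, rep(seq_len(R), each = 4L), drop = FALSE] *
    X1[, rep(1:4, R), drop = FALSE]
  qra <- qr(A)
  rd <- abs(diag(qr.R(qra)))
  well <- qra$rank == ncol(A) && min(rd) > 1e-8 * max(rd)
  coef <- if (well) tryCatch(qr.coef(qra, y), error = function(e) NULL) else NULL
  if (is.null(coef) || anyNA(coef)) {
    if (verbose) warn("ill-conditioned least-squares system; ridge fallback")
    norms <- sqrt(colSums(A^2))
    keep <- norms > 1e-10 * max(norms)
    coef <- numeric(ncol(A))
    if (any(keep)) {
      As <- sweep(A[, keep, drop = FALSE], 2, norms[keep], "/")
      AtA <- crossprod(As)
      cs <- solve(AtA + diag(1e-6 * mean(diag(AtA)), ncol(As)),
                  crossprod(As, y))
      coef[keep] <- cs / norms[keep]
    }
  }
  matrix(coef, nrow = R, ncol = 4L, byrow = TRUE)
}

# analytic gradient of sum((yhat - y)^2) wrt premise parameters
anfis_premise_grad <- function(model, X, y) {
  lw <- anfis_weights(model, X)
  X1 <- cbind(X, 1)
  Fmat <- X1 %*% t(model$consequents)
  yhat <- rowSums(lw$Wn * Fmat)
  e <- yhat - y
  G <- (2 * e / lw$S) * (Fmat - yhat) * lw$W  # N x R
  grad <- vector("list", 3L)
  for (i in 1:3) {
    P <- model$premise[[i]]
    gi <- matrix(0, nrow(P), 3L, dimnames = list(NULL, c("a", "b", "c")))
    for (m in seq_len(nrow(P))) {
      use <- model$rule_idx[, i] == m
      gsum <- rowSums(G[, use, drop = FALSE])
      gi[m, ] <- colSums(gsum * mf_dlog(X[, i], P[m, ], model$mf_type))
    }
    grad[[i]] <- gi
  }
  grad
}

#' Train an ANFIS interference estimator (hybrid learning)
#'
#' Per epoch: (1) a contiguous validation interval of `val_fraction * N`
#' samples is drawn at a seeded random start; (2) rule consequents are solved
#' by linear least squares on the training samples given the current
#' premises; (3) train and validation RMSE are recorded; (4) one
#' normalized-gradient step (back-propagated squared error) updates the
#' premise parameters, with Jang-style adaptive step size. After all epochs
#' the parameter snapshot with minimum validation RMSE is restored.
#'
#' @param inputs matrix from [anfis_inputs()].
#' @param target the corrupted (band-passed) measurement series to explain.
#' @param config an [anfis_config()].
#' @return a trained `llr_anfis` with `trace` (tibble: epoch, train_rmse,
#'   val_rmse, step_size) and `selected_epoch` set.
#' @export
anfis_train <- function(inputs, target, config = anfis_config()) {
  n <- nrow(inputs)
  if (length(target) != n) abort("`target` length must match the input rows")
  model <- anfis_init(config, inputs)
  R <- nrow(model$rule_idx)
  if (n <= 10 * R) {
    inform(sprintf("only %d samples for %d rules; consequents may be weakly determined", n, R))
  }
  Lval <- max(1L, round(config$val_fraction * n))
  kappa <- config$step_size
  trace <- matrix(NA_real_, config$epochs, 3L)
  best <- list(val = Inf, epoch = NA_integer_, premise = NULL, consequents = NULL)
  err_hist <- numeric(0)
  withr::with_seed(substream_seed(config$seed, "anfis_val"), {
    starts <- sample.int(n - Lval + 1L, config$epochs, replace = TRUE)
  })
  X1 <- cbind(inputs, 1)
  for (ep in seq_len(config$epochs)) {
    val_idx <- starts[ep]:(starts[ep] + Lval - 1L)
    tr_idx <- setdiff(seq_len(n), val_idx)
    lw <- anfis_weights(model, inputs)
    model$consequents <- anfis_lse(lw$Wn[tr_idx, , drop = FALSE],
                                   X1[tr_idx, , drop = FALSE], target[tr_idx])
    Fmat <- X1 %*% t(model$consequents)
    yhat <- rowSums(lw$Wn * Fmat)
    rmse_tr <- sqrt(mean((yhat[tr_idx] - target[tr_idx])^2))
    rmse_val <- sqrt(mean((yhat[val_idx] - target[val_idx])^2))
    trace[ep, ] <- c(rmse_tr, rmse_val, kappa)
    if (rmse_val < best$val) {
      best <- list(val = rmse_val, epoch = ep, premise = model$premise,
                   consequents = model$consequents)
    }
    # adaptive step size on the training-error history
    err_hist <- c(err_hist, rmse_tr)
    h <- length(err_hist)
    if (h >= 5 && all(diff(tail(err_hist, 5)) < 0)) kappa <- kappa * config$step_increase
    if (h >= 5) {
      d <- sign(diff(tail(err_hist, 5)))
      if (all(d == c(1, -1, 1, -1)) || all(d == c(-1, 1, -1, 1))) {
        kappa <- kappa * config$step_decrease
      }
    }
    if (ep < config$epochs) {
      g <- anfis_premise_grad(model,
                              inputs[tr_idx, , drop = FALSE], target[tr_idx])
      gnorm <- sqrt(sum(unlist(g)^2))
      if (gnorm > 0) {
        for (i in 1:3) {
          scale <- c(model$ranges[i], 1, model$ranges[i])
          step <- -kappa * g[[i]] / gnorm *
            matrix(scale, nrow(g[[i]]), 3L, byrow = TRUE)
          model$premise[[i]] <- model$premise[[i]] + step
          model$premise[[i]][, "a"] <- pmax(model$premise[[i]][, "a"],
                                            1e-3 * model$ranges[i])
          model$premise[[i]][, "b"] <- pmin(pmax(model$premise[[i]][, "b"], 0.5), 10)
        }
      }
    }
  }
  model$premise <- best$premise
  model$consequents <- best$consequents
  model$selected_epoch <- best$epoch
  model$trace <- tibble(epoch = seq_len(config$epochs),
                        train_rmse = trace[, 1], val_rmse = trace[, 2],
                        step_size = trace[, 3])
  model$config <- config
  model
}

#' Remove the estimated interference from a measurement
#'
#' `x_hat = y_f - f_hat(r)`: subtracts the model's interference estimate from
#' the corrupted band-passed measurement.
#'
#' @param y_f band-passed measurement series.
#' @param inputs matrix from [anfis_inputs()].
#' @param model a trained `llr_anfis`.
#' @return estimated clean signal, same length as `y_f`.
#' @export
anfis_denoise <- function(y_f, inputs, model) {
  if (length(y_f) != nrow(inputs)) abort("`y_f` and `inputs` lengths differ")
  y_f - anfis_forward(model, inputs)
}

#' @export
print.llr_anfis <- function(x, ...) {
  cat(sprintf("<llr_anfis> %d rules (%s MFs)", nrow(x$rule_idx), x$mf_type))
  if (!is.null(x$trace)) {
    cat(sprintf(", %d epochs, selected epoch %d (val RMSE %.4g)",
                nrow(x$trace), x$selected_epoch,
                x$trace$val_rmse[x$selected_epoch]))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.llr_anfis <- function(x, ...) {
  rows <- list()
  for (i in 1:3) {
    P <- x$premise[[i]]
    rows[[i]] <- tibble(term = sprintf("mf_in%d_%d", i, seq_len(nrow(P))),
                        a = P[, "a"], b = P[, "b"], c = P[, "c"])
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.llr_anfis <- function(x, ...) {
  tibble(n_rules = nrow(x$rule_idx), mf_type = x$mf_type,
         epochs = if (is.null(x$trace)) NA_integer_ else nrow(x$trace),
         selected_epoch = x$selected_epoch,
         val_rmse = if (is.null(x$trace)) NA_real_ else x$trace$val_rmse[x$selected_epoch])
}

#' Training-trace plot for an ANFIS model
#'
#' @param object a trained `llr_anfis`.
#' @param ... unused.
#' @return a ggplot of train/validation RMSE per epoch, with the selected
#'   epoch marked.
#' @export
autoplot.llr_anfis <- function(object, ...) {
  if (is.null(object$trace)) abort("model has no training trace")
  df <- tidyr::pivot_longer(object$trace, c("train_rmse", "val_rmse"),
                            names_to = "set", values_to = "rmse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$rmse,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "RMSE", colour = NULL)
}

#' Serialize / restore an ANFIS model as JSON
#'
#' @param model a `llr_anfis`.
#' @param path file path.
#' @export
write_anfis <- function(model, path) {
  obj <- list(mf_type = model$mf_type,
              premise = lapply(model$premise, unname),
              consequents = model$consequents,
              selected_epoch = model$selected_epoch,
              trace = model$trace)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_anfis
#' @export
read_anfis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- obj$premise
  if (is.array(pr) && length(dim(pr)) == 3L) {
    # equal-sized per-input blocks are collapsed to an array on read
    pr <- lapply(seq_len(dim(pr)[1]), function(i) pr[i, , , drop = TRUE])
  }
  premise <- lapply(pr, function(p) {
    p <- matrix(as.numeric(as.matrix(p)), ncol = 3L)
    colnames(p) <- c("a", "b", "c")
    p
  })
  m <- anfis_model(premise, as.matrix(obj$consequents), obj$mf_type)
  m$selected_epoch <- obj$selected_epoch
  if (!is.null(obj$trace)) m$trace <- as_tibble(obj$trace)
  m
}
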