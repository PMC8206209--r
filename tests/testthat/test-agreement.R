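make_means <- function(h, sessions = "S") {
  grid <- tidyr::expand_grid(participant = sprintf("P%02d", 1:12),
                             muscle = c("FCR", "ECU"),
                             velocity = c(-200, -125, -50, 50, 125, 200))
  grid$H_bar <- h(seq_len(nrow(grid)))
  grid
}

test_that("pairing joins matched cells and yields the expected study size", {
  a <- make_means(function(i) i)
  b <- make_means(function(i) i + 1)
  p <- pair_sets(a, b, "stretch")
  # 12 participants x 2 muscles x 3 stretch velocities
  expect_equal(nrow(p), 72L)
  expect_equal(p$B - p$A, rep(1, 72))
  # identical tables give zero differences
  p0 <- pair_sets(a, a, "shortening")
  expect_equal(p0$B - p0$A, rep(0, 72))
  # disjoint keys error
  b2 <- b; b2$participant <- sub("^P", "Q", b2$participant)
  expect_error(suppressMessages(pair_sets(a, b2, "stretch")), "common")
})

test_that("Bland-Altman matches the direct-formula oracle", {
  p <- tibble::tibble(A = c(1, 2, 3, 4), B = c(2, 2, 4, 4))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0.5)
  expect_equal(ba$sd_diff, 0.5774, tolerance = 1e-4)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-0.6317, 1.6317), tolerance = 1e-4)
  # direct t-based CI oracle
  expect_equal(ba$ci_bias, 0.5 + c(-1, 1) * qt(0.975, 3) * sd(c(1, 0, 1, 0)) / 2)
  # degenerate cases
  eq <- bland_altman(tibble::tibble(A = 1:5, B = 1:5))
  expect_equal(c(eq$bias, eq$loa_low, eq$loa_high), c(0, 0, 0))
  shift <- bland_altman(tibble::tibble(A = 1:5, B = 1:5 + 2))
  expect_equal(shift$bias, 2)
  expect_equal(shift$loa_high - shift$loa_low, 0)
  expect_error(bland_altman(tibble::tibble(A = 1:2, B = 2:3)), "3")
})

test_that("swapping the paired sets negates bias and mirrors the limits", {
  withr::with_seed(3, {
    p <- tibble::tibble(A = rnorm(30, 10), B = rnorm(30, 11))
  })
  f <- bland_altman(p)
  r <- bland_altman(tibble::tibble(A = p$B, B = p$A))
  expect_equal(r$bias, -f$bias)
  expect_equal(r$loa_low, -f$loa_high)
  expect_equal(r$loa_high, -f$loa_low)
})

test_that("bias comparisons follow the normal-quantile oracle with Bonferroni", {
  p1 <- tibble::tibble(A = c(1, 2, 3, 4), B = c(2, 2, 4, 4))
  ba1 <- bland_altman(p1)
  expect_equal(compare_bias(ba1, ba1)$z, 0)
  expect_equal(compare_bias(ba1, ba1)$p, 1)
  # shift one bias by exactly 1.96 combined SEs -> unadjusted p = 0.05
  ba2 <- ba1
  ba2$bias <- ba1$bias + 1.96 * sqrt(2) * ba1$se_bias
  cmp <- compare_bias(ba2, ba1, n_comparisons = 3L)
  expect_equal(cmp$p, 0.05, tolerance = 1e-3)
  expect_equal(cmp$p_adjusted, 3 * cmp$p, tolerance = 1e-9)
  expect_equal(compare_bias(ba1, ba1, n_comparisons = 3L)$p_adjusted, 1)
})

test_that("interval Jaccard follows interval arithmetic and its invariances", {
  expect_equal(interval_jaccard(c(0, 2), c(0, 2)), 1)
  expect_equal(interval_jaccard(c(0, 2), c(1, 3)), 1 / 3)
  expect_equal(interval_jaccard(c(0, 1), c(2, 3)), 0)
  expect_equal(interval_jaccard(c(-1, 1), c(-2, 2)), 0.5)
  # symmetry, bounds, identity-iff-1 on random intervals
  withr::with_seed(8, {
    for (i in 1:25) {
      a <- sort(rnorm(2)); b <- sort(rnorm(2))
      j1 <- interval_jaccard(a, b)
      expect_identical(j1, interval_jaccard(b, a))
      expect_gte(j1, 0); expect_lte(j1, 1)
      if (j1 == 1) expect_equal(a, b)
    }
  })
  # degenerate zero-length intervals
  expect_equal(interval_jaccard(c(1, 1), c(1, 1)), 1)
  expect_equal(interval_jaccard(c(1, 1), c(2, 2)), 0)
})

test_that("Jaccard bootstrap is seeded, degenerate at 1 for identical exact LoA", {
  p <- tibble::tibble(A = c(1, 2, 3, 4), B = c(2, 2, 4, 4))
  ba <- bland_altman(p)
  ba0 <- ba; ba0$se_loa <- 0
  jb0 <- jaccard_bootstrap(ba0, ba0, n_boot = 200)
  expect_equal(jb0$mean, 1)
  expect_equal(jb0$sem, 0)
  # doubling the reference LoA with zero SEs halves the overlap: [-a,a] vs [-2a,2a]
  a0 <- ba0$loa_high - ba0$bias
  centered <- ba0; centered$loa_low <- -a0; centered$loa_high <- a0
  wide <- ba0; wide$loa_low <- -2 * a0; wide$loa_high <- 2 * a0
  expect_equal(jaccard_bootstrap(centered, wide, n_boot = 100)$mean, 0.5)
  # determinism and warning
  j1 <- jaccard_bootstrap(ba, ba, n_boot = 300, seed = 4)
  j2 <- jaccard_bootstrap(ba, ba, n_boot = 300, seed = 4)
  expect_identical(j1$draws, j2$draws)
  expect_warning(jaccard_bootstrap(ba, ba, n_boot = 50), "100")
})

test_that("z-scores standardize against matched reference cells", {
  ref <- tidyr::expand_grid(participant = "P01", muscle = "FCR",
                            velocity = 50, repetition = 1:10)
  ref$H <- c(8, 9, 10, 10, 10, 10, 11, 12, 10, 10)
  mu <- mean(ref$H); sg <- sd(ref$H)
  test <- ref[1:2, ]
  test$H <- c(mu, mu + 2 * sg)
  zs <- llr_zscores(test, ref)
  expect_equal(zs$z$z, c(0, 2))
  # self-standardization: exact mean 0 / SD 1 per cell (sample-SD identity)
  st <- sim_llr_study(n_participants = 3, sessions = "OUT1", seed = 5)
  zz <- llr_zscores(st, st)$z
  cells <- dplyr::summarise(dplyr::group_by(zz, .data$participant, .data$muscle,
                                            .data$velocity),
                            m = mean(.data$z), s = sd(.data$z),
                            .groups = "drop")
  expect_lt(max(abs(cells$m)), 1e-9)
  expect_lt(max(abs(cells$s - 1)), 1e-9)
  # zero reference SD flags trials
  ref0 <- ref; ref0$H <- 5
  zs0 <- llr_zscores(test, ref0)
  expect_true(all(zs0$z$flagged))
  expect_equal(nrow(zs0$sigma), 0L)
})

test_that("Bartlett wrapper matches the closed-form statistic and edge cases", {
  # identical sample variances -> statistic 0, p 1
  g <- list(c(1, 2, 3), c(4, 5, 6), c(-1, 0, 1))
  bt <- bartlett_groups(g)
  expect_equal(bt$statistic, 0)
  expect_equal(bt$p, 1)
  expect_equal(bt$df, 2)
  # closed-form oracle at variance ratio 9, n = 50 per group
  withr::with_seed(2, {
    x <- rnorm(50); y <- rnorm(50)
  })
  x <- (x - mean(x)) / sd(x); y <- 3 * (y - mean(y)) / sd(y)
  k <- 2; n <- 50; N <- 2 * n
  sp2 <- ((n - 1) * 1 + (n - 1) * 9) / (N - k)
  chi_oracle <- ((N - k) * log(sp2) - (n - 1) * (log(1) + log(9))) /
    (1 + (2 / (n - 1) - 1 / (N - k)) / (3 * (k - 1)))
  bt2 <- bartlett_groups(list(x, y))
  expect_equal(bt2$statistic, chi_oracle, tolerance = 1e-8)
  expect_lt(bt2$p, 0.001)
  # errors
  expect_error(bartlett_groups(list(1:3)), "2 groups")
  expect_error(bartlett_groups(list(1:3, 2)), "2 values")
  expect_error(bartlett_groups(list(1:3, c(2, 2, 2))), "variance")
})
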