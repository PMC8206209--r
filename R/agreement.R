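#' Pair per-cell mean LLR amplitudes from two tables
#'
#' Inner join of two mean-amplitude tables on (participant, muscle, velocity),
#' restricted to one stimulus direction ("stretch" or "shortening"). Unmatched
#' cells are dropped with a message.
#'
#' @param table_a,table_b tibbles of per-cell means (see [llr_means()]); `A`
#'   is conventionally the reference session, `B` the test session.
#' @param direction `"stretch"` or `"shortening"`.
#' @return tibble of class `llr_paired` with columns `participant`, `muscle`,
#'   `velocity`, `A`, `B`.
#' @export
pair_sets <- function(table_a, table_b, direction = c("stretch", "shortening")) {
  direction <- match.arg(direction)
  prep <- function(tbl) {
    tbl <- as_tibble(tbl)
    if (!"direction" %in% names(tbl)) {
      tbl$direction <- stimulus_direction(tbl$muscle, tbl$velocity)
    }
    tbl[tbl$direction == direction,
        c("participant", "muscle", "velocity", "H_bar")]
  }
  a <- prep(table_a); b <- prep(table_b)
  j <- dplyr::inner_join(a, b, by = c("participant", "muscle", "velocity"),
                         suffix = c("_a", "_b"))
  dropped <- nrow(a) + nrow(b) - 2 * nrow(j)
  if (nrow(j) == 0L) abort("no common (participant, muscle, velocity) cells")
  if (dropped > 0) inform(sprintf("%d unmatched cells dropped", dropped))
  out <- tibble(participant = j$participant, muscle = j$muscle,
                velocity = j$velocity, A = j$H_bar_a, B = j$H_bar_b)
  attr(out, "direction") <- direction
  class(out) <- c("llr_paired", class(out))
  out
}

#' Paired Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference `B - A`; the 95% limits of agreement
#' (LoA) are `bias +/- 1.96 * sd(diff)`, the interval within which, given one
#' measurement, the other is expected in 95% of cases. Confidence intervals
#' use the classical t-based forms: `bias +/- t * sd/sqrt(n)` for the bias and
#' `LoA +/- t * sd * sqrt(3/n)` for each limit.
#'
#' @param pairs an [pair_sets()] result, or any data frame with `A` and `B`
#'   columns.
#' @param conf confidence level for the intervals.
#' @return object of class `llr_bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `se_bias`, `se_loa`, `ci_bias`, `ci_loa_low`,
#'   `ci_loa_high`, `n`, `direction`.
#' @export
bland_altman <- function(pairs, conf = 0.95) {
  d <- pairs$B - pairs$A
  n <- length(d)
  if (n < 3L) abort("Bland-Altman analysis needs at least 3 pairs")
  bias <- mean(d)
  sdd <- sd(d)
  tq <- qt(1 - (1 - conf) / 2, n - 1)
  se_bias <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  loa <- bias + c(-1.96, 1.96) * sdd
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = loa[1], loa_high = loa[2],
                 se_bias = se_bias, se_loa = se_loa,
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_low = loa[1] + c(-1, 1) * tq * se_loa,
                 ci_loa_high = loa[2] + c(-1, 1) * tq * se_loa,
                 n = n, conf = conf,
                 direction = attr(pairs, "direction") %||% NA_character_),
            class = "llr_bland_altman")
}

#' @export
print.llr_bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> n = %d, bias = %.4g [%.4g, %.4g], LoA = [%.4g, %.4g]\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.llr_bland_altman <- function(x, ...) {
  tibble(term = c("bias", "loa_low", "loa_high"),
         estimate = c(x$bias, x$loa_low, x$loa_high),
         std.error = c(x$se_bias, x$se_loa, x$se_loa),
         conf.low = c(x$ci_bias[1], x$ci_loa_low[1], x$ci_loa_high[1]),
         conf.high = c(x$ci_bias[2], x$ci_loa_low[2], x$ci_loa_high[2]))
}

#' @export
glance.llr_bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         direction = x$direction)
}

#' Bland-Altman plot
#'
#' @param object an `llr_bland_altman`.
#' @param pairs the paired tibble the analysis was computed from.
#' @param ... unused.
#' @return a ggplot: per-pair mean vs difference, with bias and limits of
#'   agreement.
#' @export
autoplot.llr_bland_altman <- function(object, pairs, ...) {
  df <- tibble(m = (pairs$A + pairs$B) / 2, d = pairs$B - pairs$A)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "pair mean (normalized EMG * ms)",
                  y = "difference B - A")
}

#' Compare the biases of two Bland-Altman analyses
#'
#' Two-sided z-test on the difference of the two bias estimates using their
#' standard errors; the p-value is multiplied by `n_comparisons` (Bonferroni)
#' and capped at 1.
#'
#' @param ba1,ba2 `llr_bland_altman` objects.
#' @param n_comparisons size of the comparison family.
#' @return tibble with `z`, `p`, `p_adjusted`, `degenerate`.
#' @export
compare_bias <- function(ba1, ba2, n_comparisons = 1L) {
  se <- sqrt(ba1$se_bias^2 + ba2$se_bias^2)
  degenerate <- FALSE
  if (se == 0) {
    if (ba1$bias == ba2$bias) {
      z <- 0
    } else {
      z <- Inf
      degenerate <- TRUE
      warn("zero combined standard error with unequal biases; p = 0 is degenerate")
    }
  } else {
    z <- (ba1$bias - ba2$bias) / se
  }
  p <- 2 * pnorm(-abs(z))
  tibble(z = z, p = p, p_adjusted = min(1, p * n_comparisons),
         degenerate = degenerate)
}

#' Jaccard index of two intervals
#'
#' Length of the intersection over the length of the union. For overlapping
#' (or nested) intervals the union is their spanning interval; for disjoint
#' intervals the intersection is 0 and the union is the sum of lengths.
#' Degenerate zero-length intervals score 1 if identical, else 0.
#'
#' @param int1,int2 numeric length-2 vectors `c(low, high)`.
#' @return scalar in \[0, 1\].
#' @export
interval_jaccard <- function(int1, int2) {
  int1 <- sort(int1); int2 <- sort(int2)
  l1 <- diff(int1); l2 <- diff(int2)
  if (l1 == 0 && l2 == 0) return(as.numeric(all(int1 == int2)))
  inter <- max(0, min(int1[2], int2[2]) - max(int1[1], int2[1]))
  uni <- if (inter > 0 || min(int1[2], int2[2]) >= max(int1[1], int2[1])) {
    max(int1[2], int2[2]) - min(int1[1], int2[1])
  } else {
    l1 + l2
  }
  inter / uni
}

#' Bootstrap distribution of the limits-of-agreement Jaccard index
#'
#' The overlap between a test comparison's limits of agreement and a
#' reference comparison's limits of agreement is measured by the Jaccard
#' index of the two LoA intervals. Its sampling distribution is obtained by
#' drawing each LoA endpoint of both comparisons independently from
#' `Normal(estimate, SE)` and recomputing the index.
#'
#' @param ba_test,ba_ref `llr_bland_altman` objects.
#' @param n_boot bootstrap replicates (a warning is raised below 100).
#' @param seed integer seed.
#' @return object of class `llr_jaccard`: list with `j` (point estimate from
#'   the fitted LoA), `mean`, `sem`, `ci95`, `draws`, `n_boot`, `seed`.
#' @export
jaccard_bootstrap <- function(ba_test, ba_ref, n_boot = 2000L, seed = 1L) {
  if (n_boot < 100L) warn("fewer than 100 bootstrap replicates")
  withr::with_seed(substream_seed(seed, "jaccard_boot"), {
    lo_t <- rnorm(n_boot, ba_test$loa_low, ba_test$se_loa)
    hi_t <- rnorm(n_boot, ba_test$loa_high, ba_test$se_loa)
    lo_r <- rnorm(n_boot, ba_ref$loa_low, ba_ref$se_loa)
    hi_r <- rnorm(n_boot, ba_ref$loa_high, ba_ref$se_loa)
  })
  draws <- vapply(seq_len(n_boot), function(i) {
    interval_jaccard(c(lo_t[i], hi_t[i]), c(lo_r[i], hi_r[i]))
  }, numeric(1))
  structure(list(j = interval_jaccard(c(ba_test$loa_low, ba_test$loa_high),
                                      c(ba_ref$loa_low, ba_ref$loa_high)),
                 mean = mean(draws), sem = sd(draws) / sqrt(n_boot),
                 ci95 = unname(quantile(draws, c(0.025, 0.975))),
                 draws = draws, n_boot = n_boot, seed = seed),
            class = "llr_jaccard")
}

#' @export
print.llr_jaccard <- function(x, ...) {
  cat(sprintf("<Jaccard LoA overlap> J = %.3f (boot mean %.3f +/- %.3f sem, 95%% CI [%.3f, %.3f])\n",
              x$j, x$mean, x$sem, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Perturbation-level standardized z-scores
#'
#' Each test-session amplitude is standardized against the mean and sample SD
#' of its matched reference cell (same participant, muscle, velocity):
#' `z = (H - mu_ref) / sigma_ref`. Per-cell references with zero SD flag
#' their trials and exclude them from the dispersion summaries.
#'
#' @param test_tbl per-trial amplitudes to standardize (columns `participant`,
#'   `muscle`, `velocity`, `H`; a `filter` column is carried through).
#' @param ref_tbl per-trial reference amplitudes with the same key columns
#'   (at least 2 trials per cell).
#' @return list of class `llr_zscores`: `z` (per-trial tibble with `z` and
#'   `flagged`), `sigma` (per velocity-magnitude/direction SD of z).
#' @export
llr_zscores <- function(test_tbl, ref_tbl) {
  ref_stats <- dplyr::summarise(
    dplyr::group_by(as_tibble(ref_tbl), .data$participant, .data$muscle,
                    .data$velocity),
    mu = mean(.data$H), sigma = sd(.data$H), n_ref = dplyr::n(),
    .groups = "drop")
  if (any(ref_stats$n_ref < 2L)) abort("every reference cell needs at least 2 trials")
  z <- dplyr::inner_join(as_tibble(test_tbl), ref_stats,
                         by = c("participant", "muscle", "velocity"))
  if (nrow(z) == 0L) abort("no matching reference cells")
  z$flagged <- z$sigma <= 0
  z$z <- ifelse(z$flagged, NA_real_, (z$H - z$mu) / z$sigma)
  if (!"direction" %in% names(z)) {
    z$direction <- stimulus_direction(z$muscle, z$velocity)
  }
  z$speed <- abs(z$velocity)
  grp_cols <- intersect(c("filter", "speed", "direction"), names(z))
  sigma <- dplyr::summarise(
    dplyr::group_by(z[!z$flagged, ], dplyr::across(dplyr::all_of(grp_cols))),
    sigma_z = sd(.data$z), n = dplyr::n(), .groups = "drop")
  structure(list(z = z, sigma = sigma), class = "llr_zscores")
}

#' Bartlett test of homogeneity of variances
#'
#' Classical Bartlett statistic with a chi-squared reference distribution on
#' `k - 1` degrees of freedom; any multiple-comparison adjustment over a test
#' family is applied by the caller.
#'
#' @param groups list of two or more numeric vectors (each with at least 2
#'   values and nonzero variance).
#' @return tibble with `statistic`, `df`, `p`.
#' @export
bartlett_groups <- function(groups) {
  if (length(groups) < 2L) abort("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) abort("every group needs at least 2 values")
  if (any(vapply(groups, var, numeric(1)) <= 0)) abort("zero-variance group")
  ht <- bartlett.test(groups)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
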