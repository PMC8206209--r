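#' Sorensen-Dice overlap of two thresholded activation maps
#'
#' Both maps are thresholded (p < 0.001 uncorrected by default) and the
#' overlap score `S = 2 Vo / (V1 + V2)` is computed, where `Vo` is the number
#' of supra-threshold voxels common to both maps. When neither map has
#' supra-threshold voxels the score is defined as 0 and flagged.
#'
#' @param map1,map2 `llr_stat_map`s on identical grids.
#' @param level,method,k,mask thresholding arguments, see [threshold_map()].
#' @return tibble with `S`, `V1`, `V2`, `Vo`, `flagged`.
#' @export
dice_overlap <- function(map1, map2, level = 0.001,
                         method = "uncorrected", k = 0L, mask = NULL) {
  if (!identical(dim(map1$t), dim(map2$t))) abort("maps are on different grids")
  b1 <- threshold_map(map1, level, method, k, mask)$binary
  b2 <- threshold_map(map2, level, method, k, mask)$binary
  v1 <- sum(b1); v2 <- sum(b2); vo <- sum(b1 & b2)
  flagged <- (v1 + v2) == 0L
  tibble(S = if (flagged) 0 else 2 * vo / (v1 + v2),
         V1 = v1, V2 = v2, Vo = vo, flagged = flagged)
}

#' ICC(3,1) consistency for two repeated measurements
#'
#' Two-way mixed-effects intraclass correlation, single measure, consistency
#' form: with targets (voxels or subjects) random and session fixed, and only
#' two sessions, `ICC(3,1) = (BMS - EMS) / (BMS + EMS)` where BMS is the
#' between-target mean square and EMS the error mean square after removing
#' target and session effects. Additive session effects do not lower it.
#'
#' @param values numeric matrix, targets x 2 sessions (at least 3 complete
#'   targets; rows with missing values are dropped listwise).
#' @return object of class `llr_icc`: list with `icc`, `bms`, `ems`, `n`.
#' @export
icc31 <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 2L) abort("`values` must have 2 session columns")
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  if (n < 3L) abort("need at least 3 targets")
  k <- 2L
  grand <- mean(values)
  rowm <- rowMeans(values)
  colm <- colMeans(values)
  bms <- k * sum((rowm - grand)^2) / (n - 1)
  resid <- values - outer(rowm, rep(1, k)) -
    outer(rep(1, n), colm) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  if (bms + ems <= 0) abort("zero total variance; ICC undefined")
  structure(list(icc = (bms - ems) / (bms + ems), bms = bms, ems = ems, n = n),
            class = "llr_icc")
}

#' @export
print.llr_icc <- function(x, ...) {
  cat(sprintf("<ICC(3,1)> %.4f (BMS %.4g, EMS %.4g, n = %d)\n",
              x$icc, x$bms, x$ems, x$n))
  invisible(x)
}

#' @export
tidy.llr_icc <- function(x, ...) {
  tibble(term = "icc31", estimate = x$icc, bms = x$bms, ems = x$ems, n = x$n)
}

#' Region-of-interest mask
#'
#' @param labels 3D integer array, 0 = background.
#' @param table tibble mapping `id` to `name` and `hemisphere` (optional).
#' @return object of class `llr_roi`.
#' @export
roi_mask <- function(labels, table = NULL) {
  if (any(labels < 0)) abort("ROI labels must be non-negative")
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (is.null(table)) {
    table <- tibble(id = ids, name = sprintf("roi%d", ids),
                    hemisphere = NA_character_)
  }
  structure(list(labels = labels, table = as_tibble(table)),
            class = "llr_roi")
}

#' Participant-level per-ROI ICC of two session maps
#'
#' Within each ROI label, voxels are the random targets and the two sessions
#' the fixed repetitions; one ICC(3,1) per ROI. ROIs with fewer than 3 voxels
#' are skipped with a warning.
#'
#' @param roi an [roi_mask()].
#' @param map1,map2 `llr_stat_map`s (or numeric arrays) for the two sessions.
#' @return tibble with `roi`, `name`, `icc`, `n_voxels`.
#' @export
icc_participant <- function(roi, map1, map2) {
  v1 <- if (inherits(map1, "llr_stat_map")) map1$t else map1
  v2 <- if (inherits(map2, "llr_stat_map")) map2$t else map2
  if (!identical(dim(v1), dim(roi$labels)) || !identical(dim(v2), dim(roi$labels))) {
    abort("maps and ROI labels are on different grids")
  }
  rows <- list()
  for (i in seq_len(nrow(roi$table))) {
    id <- roi$table$id[i]
    sel <- roi$labels == id
    if (sum(sel) < 3L) {
      warn(sprintf("ROI %d has fewer than 3 voxels; skipped", id))
      next
    }
    res <- icc31(cbind(v1[sel], v2[sel]))
    nm <- roi$table$name[i]
    rows[[length(rows) + 1L]] <- tibble(roi = id, name = nm,
                                        icc = res$icc, n_voxels = res$n)
  }
  dplyr::bind_rows(rows)
}

#' Group-level voxelwise ICC map and per-ROI medians
#'
#' At each voxel, subjects are the random targets and the two sessions the
#' fixed repetitions; the per-ROI summary is the median of the voxel ICCs
#' inside each label.
#'
#' @param maps_s1,maps_s2 lists of per-subject maps (`llr_stat_map` or
#'   arrays), sessions 1 and 2, identical grids, at least 3 subjects.
#' @param roi optional [roi_mask()] for the medians.
#' @return list with `icc` (3D array; NA where total variance is zero) and
#'   `roi_medians` (tibble, or NULL).
#' @export
icc_group_map <- function(maps_s1, maps_s2, roi = NULL) {
  if (length(maps_s1) != length(maps_s2)) abort("session subject lists differ in length")
  n <- length(maps_s1)
  if (n < 3L) abort("need at least 3 subjects")
  get <- function(m) if (inherits(m, "llr_stat_map")) m$t else m
  d <- dim(get(maps_s1[[1]]))
  M1 <- vapply(maps_s1, function(m) as.numeric(get(m)), numeric(prod(d)))
  M2 <- vapply(maps_s2, function(m) as.numeric(get(m)), numeric(prod(d)))
  k <- 2
  rowm <- (M1 + M2) / 2                       # per voxel x subject
  grand <- rowMeans(rowm)                     # per voxel
  bms <- k * rowSums((rowm - grand)^2) / (n - 1)
  col1 <- rowMeans(M1); col2 <- rowMeans(M2)
  r1 <- M1 - rowm - col1 + grand
  r2 <- M2 - rowm - col2 + grand
  ems <- (rowSums(r1^2) + rowSums(r2^2)) / (n - 1)
  tot <- bms + ems
  icc <- ifelse(tot > 0, (bms - ems) / tot, NA_real_)
  dim(icc) <- d
  roi_medians <- NULL
  if (!is.null(roi)) {
    roi_medians <- dplyr::bind_rows(lapply(seq_len(nrow(roi$table)), function(i) {
      id <- roi$table$id[i]
      nm <- roi$table$name[i]
      sel <- roi$labels == id
      tibble(roi = id, name = nm,
             median_icc = median(icc[sel], na.rm = TRUE),
             n_voxels = sum(sel))
    }))
  }
  list(icc = icc, roi_medians = roi_medians)
}

#' Paired t-test with degenerate-case handling
#'
#' Classical paired t on the differences (`df = n - 1`, two-sided). Constant
#' nonzero differences (zero variance) return an infinite-t sentinel with
#' `flagged = TRUE` rather than an error from the underlying test.
#'
#' @param a,b paired numeric vectors.
#' @return tibble with `t`, `df`, `p`, `mean_diff`, `flagged`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired (equal length)")
  n <- length(a)
  if (n < 2L) abort("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(t = 0, df = n - 1L, p = 1, mean_diff = 0, flagged = TRUE))
    }
    return(tibble(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                  mean_diff = mean(d), flagged = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_diff = unname(ht$estimate), flagged = FALSE)
}
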