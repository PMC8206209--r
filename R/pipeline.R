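#' Run configuration
#'
#' One structured configuration object drives the staged pipeline
#' (simulate -> emg -> validate -> glm). All randomness flows from the single
#' `seed` through named substreams, so each stage is individually
#' reproducible. Any block can be overridden by the matching argument; the
#' rest keep package defaults.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed root seed.
#' @param protocol an [protocol_spec()].
#' @param emg_params an [emg_sim_params()] (in-scanner parameters; the OUT
#'   variant is derived by zeroing `artifact_gain`).
#' @param anfis an [anfis_config()].
#' @param hrf an [hrf_spec()].
#' @param threshold list with `level`, `method`, `k`.
#' @param methods filtering methods to run.
#' @return object of class `llr_run_config`.
#' @export
run_config <- function(out_dir = tempfile("llrpipe"), seed = 1L,
                       protocol = protocol_spec(seed = seed),
                       emg_params = emg_sim_params(),
                       anfis = anfis_config(seed = seed),
                       hrf = hrf_standard(),
                       threshold = list(level = 0.001, method = "uncorrected", k = 0L),
                       methods = c("STD", "SUB", "ANC")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 protocol = protocol, emg_params = emg_params,
                 anfis = anfis, hrf = hrf, threshold = threshold,
                 methods = methods),
            class = "llr_run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level blocks (`protocol`, `emg_params`,
#' `anfis`, `hrf`, `threshold`, plus scalar `seed`, `out_dir`, `methods`)
#' override the corresponding constructor defaults. Unknown fields raise an
#' error naming the block.
#'
#' @param path YAML file path.
#' @return an `llr_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  apply_block <- function(ctor, block, name) {
    args <- y[[block]] %||% list()
    ok <- names(formals(ctor))
    bad <- setdiff(names(args), ok)
    if (length(bad)) {
      abort(sprintf("unknown fields in config block '%s': %s", block,
                    paste(bad, collapse = ", ")))
    }
    if (!"seed" %in% names(args) && "seed" %in% ok) args$seed <- seed
    do.call(ctor, args)
  }
  run_config(
    out_dir = y$out_dir %||% tempfile("llrpipe"),
    seed = seed,
    protocol = apply_block(protocol_spec, "protocol"),
    emg_params = apply_block(emg_sim_params, "emg_params"),
    anfis = apply_block(anfis_config, "anfis"),
    hrf = apply_block(hrf_spec, "hrf"),
    threshold = utils::modifyList(list(level = 0.001, method = "uncorrected", k = 0L),
                                  y$threshold %||% list()),
    methods = y$methods %||% c("STD", "SUB", "ANC"))
}

config_manifest <- function(config, stage) {
  hashable <- config[setdiff(names(config), "out_dir")]
  txt <- jsonlite::toJSON(hashable, digits = NA, auto_unbox = TRUE, force = TRUE)
  list(stage = stage, seed = config$seed,
       config_hash = sprintf("%08x", sum(utf8ToInt(as.character(txt)) *
                                           (seq_along(utf8ToInt(as.character(txt))) %% 97 + 1)) %% 4294967291),
       package_version = as.character(utils::packageVersion("llrpipe")))
}

#' Simulation stage: protocol, recordings and phantom
#'
#' Generates the session timeline, one in-scanner recording per muscle, and a
#' BOLD phantom; writes the event table, recordings, phantom and truth maps
#' plus a manifest (seed, config hash) under `out_dir`.
#'
#' @param config an [run_config()].
#' @return invisibly, a list with the protocol, recordings, phantom and the
#'   written paths.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- gen_protocol(config$protocol)
  paths <- list(events = file.path(config$out_dir, "events.tsv"))
  write_events(protocol, paths$events)
  recordings <- list()
  for (mu in c("FCR", "ECU")) {
    recordings[[mu]] <- gen_session_recording(protocol, config$emg_params, mu,
                                              seed = config$seed)
    p <- file.path(config$out_dir, sprintf("recording_%s.tsv", mu))
    write_recording(recordings[[mu]], p)
    paths[[paste0("recording_", mu)]] <- p
  }
  phantom <- gen_bold_phantom(protocol, hrf = config$hrf, seed = config$seed)
  paths$phantom <- file.path(config$out_dir, "phantom.nii")
  write_volume(phantom$data, paths$phantom, phantom$voxel_mm)
  write_volume(phantom$truth_beta_fcr, file.path(config$out_dir, "truth_beta_fcr.nii"),
               phantom$voxel_mm)
  write_volume(phantom$truth_beta_ecu, file.path(config$out_dir, "truth_beta_ecu.nii"),
               phantom$voxel_mm)
  manifest <- config_manifest(config, "simulate")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest_simulate.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(protocol = protocol, recordings = recordings,
                 phantom = phantom, paths = paths))
}

#' EMG stage: per-method LLR amplitude tables
#'
#' Runs segmentation, band-pass filtering, the selected filtering pipelines,
#' envelope extraction, contraction normalization and windowed integration
#' for both muscles, writing one tidy table per filtering method.
#'
#' @param config an [run_config()].
#' @param recordings optional named list (`FCR`, `ECU`) of recordings;
#'   defaults to regenerating them from the config.
#' @param participant,session labels for the output table.
#' @return invisibly, the combined `llr_table`.
#' @export
run_emg <- function(config, recordings = NULL, participant = "P01",
                    session = "IN1") {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(recordings)) {
    protocol <- gen_protocol(config$protocol)
    recordings <- lapply(setNames(c("FCR", "ECU"), c("FCR", "ECU")),
                         function(mu) gen_session_recording(protocol, config$emg_params,
                                                            mu, seed = config$seed))
  }
  tabs <- lapply(recordings, process_recording, methods = config$methods,
                 participant = participant, session = session,
                 anfis_config = config$anfis)
  tbl <- do.call(build_llr_table, unname(tabs))
  for (m in unique(tbl$filter)) {
    write_llr_table(tbl[tbl$filter == m, ],
                    file.path(config$out_dir, sprintf("llr_table_%s.tsv", m)))
  }
  jsonlite::write_json(config_manifest(config, "emg"),
                       file.path(config$out_dir, "manifest_emg.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(tbl)
}

#' Validation stage: agreement statistics between test and reference tables
#'
#' Computes, per stimulus direction: paired Bland-Altman of each filtering
#' method's test table against the reference, pairwise bias z-tests
#' (Bonferroni over the method pairs), the Jaccard overlap of limits of
#' agreement against the reference comparison with bootstrap CIs, the
#' perturbation-level z-scores and their dispersion, and Bartlett tests of
#' the z-score variances against the reference comparison.
#'
#' @param test_tbl per-trial amplitudes for the in-scanner session (with a
#'   `filter` column).
#' @param ref_tbl1 per-trial reference amplitudes (first out-of-scanner
#'   session; the standardization reference).
#' @param ref_tbl2 per-trial amplitudes of the repeated reference session
#'   (defines the reference comparison).
#' @param n_boot,seed bootstrap settings.
#' @param out_dir optional directory for the JSON report.
#' @return list of class `llr_validation`: `bland_altman` (tibble),
#'   `bias_tests`, `jaccard`, `sigma_z`, `bartlett` tibbles.
#' @export
run_validate <- function(test_tbl, ref_tbl1, ref_tbl2, n_boot = 2000L,
                         seed = 1L, out_dir = NULL) {
  ref1m <- llr_means(ref_tbl1)
  ref2m <- llr_means(ref_tbl2)
  methods <- unique(test_tbl$filter)
  ba_rows <- list(); j_rows <- list(); bias_rows <- list()
  sig_rows <- list(); bart_rows <- list()
  for (d in c("stretch", "shortening")) {
    ba_ref <- bland_altman(pair_sets(ref1m, ref2m, d))
    ba_rows[[length(ba_rows) + 1L]] <-
      dplyr::mutate(glance(ba_ref), filter = "REF", direction = d)
    z_ref <- llr_zscores(dplyr::mutate(ref_tbl2, filter = "REF"), ref_tbl1)
    sig_rows[[length(sig_rows) + 1L]] <-
      z_ref$sigma[z_ref$sigma$direction == d, ]
    bas <- list()
    for (f in methods) {
      tm <- llr_means(test_tbl[test_tbl$filter == f, ])
      ba_f <- bland_altman(pair_sets(ref1m, tm, d))
      bas[[f]] <- ba_f
      ba_rows[[length(ba_rows) + 1L]] <-
        dplyr::mutate(glance(ba_f), filter = f, direction = d)
      jb <- jaccard_bootstrap(ba_f, ba_ref, n_boot = n_boot,
                              seed = substream_seed(seed, paste0("J", f, d)))
      j_rows[[length(j_rows) + 1L]] <- tibble(
        filter = f, direction = d, j = jb$j, j_boot_mean = jb$mean,
        sem = jb$sem, ci_low = jb$ci95[1], ci_high = jb$ci95[2])
      zf <- llr_zscores(test_tbl[test_tbl$filter == f, ], ref_tbl1)
      sig_rows[[length(sig_rows) + 1L]] <-
        zf$sigma[zf$sigma$direction == d, ]
      # Bartlett: method z-scores vs reference z-scores, per direction
      zt <- zf$z$z[!zf$z$flagged & zf$z$direction == d]
      zr <- z_ref$z$z[!z_ref$z$flagged & z_ref$z$direction == d]
      bt <- bartlett_groups(list(test = zt, ref = zr))
      bart_rows[[length(bart_rows) + 1L]] <-
        dplyr::mutate(bt, filter = f, direction = d,
                      p_adjusted = pmin(1, bt$p * length(methods)))
    }
    for (i in seq_along(methods)) {
      for (jx in seq_len(i - 1L)) {
        cmp <- compare_bias(bas[[methods[i]]], bas[[methods[jx]]],
                            n_comparisons = choose(length(methods), 2))
        bias_rows[[length(bias_rows) + 1L]] <-
          dplyr::mutate(cmp, pair = paste(methods[i], methods[jx], sep = "-"),
                        direction = d)
      }
    }
  }
  out <- structure(list(bland_altman = dplyr::bind_rows(ba_rows),
                        bias_tests = dplyr::bind_rows(bias_rows),
                        jaccard = dplyr::bind_rows(j_rows),
                        sigma_z = dplyr::bind_rows(sig_rows),
                        bartlett = dplyr::bind_rows(bart_rows)),
                   class = "llr_validation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(lapply(unclass(out), as.data.frame),
                         file.path(out_dir, "validation_report.json"),
                         digits = NA, dataframe = "columns")
  }
  out
}

#' GLM stage: fit, contrasts, thresholding and two-session reliability
#'
#' Smooths each session's phantom, builds the muscle-specific LLR design,
#' fits the voxelwise GLM, computes the `beta_FCR > 0` and `beta_ECU > 0`
#' t-maps, thresholds them, and summarizes two-session reliability (Dice on
#' the thresholded maps, whole-grid ICC(3,1) on the t values).
#'
#' @param phantoms list of one or two `llr_bold_phantom`s (sessions).
#' @param config an [run_config()].
#' @param amplitudes optional per-trial amplitude tibbles matching each
#'   phantom (defaults to the phantom's generating amplitudes).
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @return list of class `llr_glm_report`: per-session `tmaps` and
#'   `thresholded`, plus `dice` and `icc` tibbles when two sessions are given.
#' @export
run_glm <- function(phantoms, config = run_config(), amplitudes = NULL,
                    fwhm_mm = 8) {
  if (inherits(phantoms, "llr_bold_phantom")) phantoms <- list(phantoms)
  tmaps <- list(); thr <- list()
  for (s in seq_along(phantoms)) {
    ph <- phantoms[[s]]
    data <- smooth_volume(ph$data, fwhm_mm, ph$voxel_mm)
    X <- build_design(list(fcr = ph$reg_fcr, ecu = ph$reg_ecu),
                      ph$volume_times, highpass_cutoff = 128)
    fit <- fit_bold_glm(data, X)
    nc <- ncol(X$X)
    c_fcr <- c(1, rep(0, nc - 1)); c_ecu <- c(0, 1, rep(0, nc - 2))
    tmaps[[s]] <- list(
      fcr = contrast_tmap(fit, c_fcr, voxel_mm = ph$voxel_mm),
      ecu = contrast_tmap(fit, c_ecu, voxel_mm = ph$voxel_mm))
    thr[[s]] <- lapply(tmaps[[s]], threshold_map,
                       level = config$threshold$level,
                       method = config$threshold$method,
                       k = config$threshold$k)
  }
  dice <- icc <- NULL
  if (length(phantoms) >= 2L) {
    dice <- dplyr::bind_rows(lapply(c("fcr", "ecu"), function(mu) {
      dplyr::mutate(dice_overlap(tmaps[[1]][[mu]], tmaps[[2]][[mu]],
                                 level = config$threshold$level,
                                 method = config$threshold$method,
                                 k = config$threshold$k),
                    regressor = mu)
    }))
    icc <- dplyr::bind_rows(lapply(c("fcr", "ecu"), function(mu) {
      res <- icc31(cbind(as.numeric(tmaps[[1]][[mu]]$t),
                         as.numeric(tmaps[[2]][[mu]]$t)))
      tibble(regressor = mu, icc = res$icc, n_voxels = res$n)
    }))
  }
  structure(list(tmaps = tmaps, thresholded = thr, dice = dice, icc = icc),
            class = "llr_glm_report")
}
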