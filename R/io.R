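## Short content hash for provenance headers (djb2 over the serialized
## representation; provenance only, not cryptographic).
config_hash <- function(x) {
  chars <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (ch in chars) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed, hash) {
  c(sprintf("# seed=%d", as.integer(seed)),
    sprintf("# config_hash=%s", hash),
    sprintf("# package=sipcop %s",
            as.character(utils::packageVersion("sipcop"))))
}

write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one trial's sensor streams to CSV files
#'
#' Writes `<label>_loadcell.csv` (`t_s,f_bl_n,f_br_n,f_fl_n,f_fr_n`),
#' `<label>_mat.csv` (`t_s,p_0_0,...,p_15_15`, row-major, row 0 = back of
#' seat, col 0 = user's left), `<label>_imu.csv`
#' (`t_s,sensor,pitch_deg,roll_deg`), `<label>_tare.csv` and
#' `<label>_meta.json` (condition and generating-truth record). Every file
#' carries a seed and config-hash comment header.
#'
#' @param trial a `pr_trial`.
#' @param dir output directory (created if absent).
#' @param seed seed recorded in the headers.
#' @return named character vector of the file paths, invisibly.
#' @export
write_trial <- function(trial, dir, seed = trial$truth$seed) {
  stop_if_not(inherits(trial, "pr_trial"), "need a pr_trial")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  label <- condition_label(trial$condition)
  hash <- config_hash(trial$condition)
  hdr <- provenance_header(seed, hash)
  paths <- c(
    loadcell = file.path(dir, paste0(label, "_loadcell.csv")),
    mat = file.path(dir, paste0(label, "_mat.csv")),
    imu = file.path(dir, paste0(label, "_imu.csv")),
    tare = file.path(dir, paste0(label, "_tare.csv")),
    meta = file.path(dir, paste0(label, "_meta.json"))
  )
  write_csv_with_header(trial$loadcell, paths["loadcell"], hdr)
  write_csv_with_header(trial$mat, paths["mat"], hdr)
  write_csv_with_header(trial$imu, paths["imu"], hdr)
  write_csv_with_header(trial$tare, paths["tare"], hdr)
  meta <- list(condition = unclass(trial$condition), seed = seed,
               truth = trial$truth[setdiff(names(trial$truth), "upright_cop")],
               upright_cop = trial$truth$upright_cop)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one trial back from its CSV files
#'
#' @param dir directory containing the files written by [write_trial()].
#' @param label the trial label (`<participant>_<cushion>_<start>_
#'   <direction>_<repetition>`).
#' @return a `pr_trial`.
#' @export
read_trial <- function(dir, label) {
  rd <- function(suffix) {
    utils::read.csv(file.path(dir, paste0(label, "_", suffix, ".csv")),
                    comment.char = "#", stringsAsFactors = FALSE)
  }
  meta <- jsonlite::read_json(file.path(dir, paste0(label, "_meta.json")),
                              simplifyVector = TRUE)
  cond <- trial_condition(meta$condition$direction, meta$condition$cushion,
                          meta$condition$start_position,
                          meta$condition$repetition,
                          meta$condition$participant_id)
  truth <- as.list(meta$truth)
  truth$upright_cop <- meta$upright_cop
  structure(
    list(condition = cond, loadcell = rd("loadcell"), mat = rd("mat"),
         imu = rd("imu"), tare = rd("tare"), truth = truth),
    class = "pr_trial"
  )
}

#' Simulate a cohort and write it to disk
#'
#' Generates a [make_cohort()] cohort and writes every trial's CSVs, a
#' `ground_truth.csv`, a `manifest.csv` listing every file with its seed,
#' and `run_config.json` with the run parameters.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the whole run.
#' @param n_participants cohort size.
#' @param ... passed to [make_cohort()].
#' @return the manifest data frame, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, n_participants = 10, ...) {
  stop_if_not(is_number(n_participants) && n_participants >= 2,
              "n_participants must be >= 2")
  cohort <- make_cohort(n_participants = n_participants, seed = seed, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trial_dir <- file.path(out_dir, "trials")
  rows <- lapply(cohort$trials, function(tr) {
    paths <- write_trial(tr, trial_dir)
    cn <- tr$condition
    data.frame(label = condition_label(cn),
               participant = cn$participant_id, direction = cn$direction,
               cushion = cn$cushion, start_position = cn$start_position,
               repetition = cn$repetition, seed = tr$truth$seed,
               loadcell_file = basename(paths["loadcell"]),
               mat_file = basename(paths["mat"]),
               imu_file = basename(paths["imu"]),
               tare_file = basename(paths["tare"]),
               meta_file = basename(paths["meta"]))
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  hash <- config_hash(list(seed = seed, n = n_participants))
  hdr <- provenance_header(seed, hash)
  write_csv_with_header(manifest, file.path(out_dir, "manifest.csv"), hdr)
  write_csv_with_header(cohort$ground_truth,
                        file.path(out_dir, "ground_truth.csv"), hdr)
  geom <- cohort$configs[[1]]$geom
  jsonlite::write_json(
    list(seed = seed, n_participants = n_participants,
         geometry = unclass(geom), config_hash = hash),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Process a written cohort into per-condition regression results
#'
#' Reads the manifest and trial files of [run_simulate()], runs
#' [process_cohort()], and writes `regressions.csv`
#' (`participant,cushion,start_position,direction,slope,slope_se,intercept,r2,n`),
#' `sine_fits.csv`, `samples.csv` (per-sample rows for mixed modelling) and
#' `exclusions.txt`.
#'
#' @param out_dir directory of a simulated run.
#' @param keep_fraction see [truncate_to_95()].
#' @return the [process_cohort()] result, invisibly.
#' @export
run_process <- function(out_dir, keep_fraction = 0.95) {
  cfg <- jsonlite::read_json(file.path(out_dir, "run_config.json"),
                             simplifyVector = TRUE)
  geom <- seat_geometry(cfg$geometry$width_cm, cfg$geometry$depth_cm,
                        cfg$geometry$dump_angle_deg,
                        cfg$geometry$body_origin_offset_y)
  manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"),
                              comment.char = "#",
                              stringsAsFactors = FALSE)
  stop_if_not(nrow(manifest) >= 1, "empty manifest")
  trial_dir <- file.path(out_dir, "trials")
  trials <- list()
  for (label in manifest$label) {
    trials[[label]] <- tryCatch(read_trial(trial_dir, label),
                                error = function(e) {
                                  warning(sprintf("skipping %s: %s", label,
                                                  conditionMessage(e)),
                                          call. = FALSE)
                                  NULL
                                })
  }
  trials <- Filter(Negate(is.null), trials)
  res <- process_cohort(trials, geom = geom, keep_fraction = keep_fraction)
  hdr <- provenance_header(cfg$seed, cfg$config_hash)
  if (!is.null(res$regressions)) {
    write_csv_with_header(res$regressions,
                          file.path(out_dir, "regressions.csv"), hdr)
  }
  if (!is.null(res$sine_fits)) {
    write_csv_with_header(res$sine_fits,
                          file.path(out_dir, "sine_fits.csv"), hdr)
  }
  if (!is.null(res$samples)) {
    write_csv_with_header(res$samples, file.path(out_dir, "samples.csv"),
                          hdr)
  }
  writeLines(c(provenance_header(cfg$seed, cfg$config_hash),
               res$exclusions),
             file.path(out_dir, "exclusions.txt"))
  invisible(res)
}

#' Analyze a processed run: mixed models, thresholds, agreement
#'
#' Reads `samples.csv`, fits the candidate random-effects structures,
#' writes the model comparison (`model_comparison.csv`), the fixed-effect
#' table of each fit (`lmm_<n>.csv`), CoP thresholds for the configured
#' target reductions from the best model's direction-specific total slopes
#' (`thresholds.csv`: `direction,slope,target,cop_cm`), and - when ground
#' truth is available - the Bland-Altman comparison of fitted versus
#' theoretical forward-lean slopes (`bland_altman.csv`).
#'
#' @param out_dir directory of a processed run.
#' @param reductions target proportional reductions.
#' @param structures random-effects structure labels to fit.
#' @return list with `comparison`, `fits`, `thresholds`, `bland_altman`,
#'   invisibly.
#' @export
run_analyze <- function(out_dir, reductions = c(0.80, 0.90),
                        structures = LMM_STRUCTURES[1:3]) {
  cfg <- jsonlite::read_json(file.path(out_dir, "run_config.json"),
                             simplifyVector = TRUE)
  hdr <- provenance_header(cfg$seed, cfg$config_hash)
  samples_path <- file.path(out_dir, "samples.csv")
  stop_if_not(file.exists(samples_path), "samples.csv not found; run
run_process() first")
  samples <- utils::read.csv(samples_path, comment.char = "#",
                             stringsAsFactors = FALSE)
  stop_if_not(nrow(samples) > 0, "empty samples.csv")
  stop_if_not(length(unique(samples$participant)) >= 2,
              "need at least 2 participants")

  design <- build_lmm_design(samples)
  fits <- lapply(structures, function(st) fit_sip_lmm(design, st))
  names(fits) <- structures
  comparison <- compare_lmm_models(fits)
  write_csv_with_header(comparison,
                        file.path(out_dir, "model_comparison.csv"), hdr)
  for (i in seq_along(fits)) {
    write_csv_with_header(fits[[i]]$fixed,
                          file.path(out_dir, sprintf("lmm_%d.csv", i)), hdr)
  }

  ## thresholds from the best (lowest-AIC, converged if possible) model
  ok <- comparison$converged
  best_label <- if (any(ok)) comparison$label[ok][1] else comparison$label[1]
  best <- fits[[best_label]]
  dirs <- intersect(DIRECTIONS, unique(samples$direction))
  thr <- do.call(rbind, lapply(dirs, function(dd) {
    sl <- total_slope(best, dd)
    do.call(rbind, lapply(reductions, function(rr) {
      data.frame(direction = dd, slope = sl, target = rr,
                 cop_cm = cop_threshold(sl, rr))
    }))
  }))
  write_csv_with_header(thr, file.path(out_dir, "thresholds.csv"), hdr)

  ba <- NULL
  gt_path <- file.path(out_dir, "ground_truth.csv")
  reg_path <- file.path(out_dir, "regressions.csv")
  if (file.exists(gt_path) && file.exists(reg_path)) {
    gt <- utils::read.csv(gt_path, comment.char = "#",
                          stringsAsFactors = FALSE)
    reg <- utils::read.csv(reg_path, comment.char = "#",
                           stringsAsFactors = FALSE)
    fwd <- reg[reg$direction == "forward", , drop = FALSE]
    if (nrow(fwd) >= 2) {
      fitted <- tapply(fwd$slope, fwd$participant, mean)
      theo <- gt$forward_slope[match(names(fitted), gt$participant_id)]
      keep <- !is.na(theo)
      if (sum(keep) >= 2) {
        ba <- bland_altman(as.numeric(fitted[keep]), theo[keep])
        ba_df <- data.frame(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                            loa_lower = ba$loa_lower,
                            loa_upper = ba$loa_upper)
        write_csv_with_header(ba_df,
                              file.path(out_dir, "bland_altman.csv"), hdr)
      }
    }
  }
  invisible(list(comparison = comparison, fits = fits, thresholds = thr,
                 bland_altman = ba))
}

#' Run simulate, process and analyze in sequence
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_participants cohort size.
#' @param ... passed to [make_cohort()] via [run_simulate()].
#' @return the [run_analyze()] result, invisibly.
#' @export
run_all <- function(out_dir, seed = 1L, n_participants = 10, ...) {
  run_simulate(out_dir, seed = seed, n_participants = n_participants, ...)
  run_process(out_dir)
  run_analyze(out_dir)
}
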