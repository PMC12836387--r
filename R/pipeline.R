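# End-to-end orchestration: simulate or read a paired cohort, reduce each
# recording to NN intervals, compute every HRV index, and run the paired
# Pre/Post comparison.

# Index metadata: computation order and table units.
HRV_INDEX_UNITS <- c(
  hr = "bpm", sdnn = "ms", rmssd = "ms",
  tp = "ms2", ulf = "ms2", vlf = "ms2", lf = "ms2", hf = "ms2",
  n_hf = "", lf_hf = "",
  sd1 = "ms", sd2 = "ms", sd1_sd2 = "", sd2_sd1 = "",
  ac = "ms", dc = "ms")

#' Run configuration for the HRV pipeline
#'
#' @param mode `"simulate"` (generate a paired cohort with
#'   [generate_cohort()]) or `"analyze"` (read beat/RR files).
#' @param cohort For `"simulate"`: list with `n_subjects`, `shift`, `pre_cfg`
#'   (an [autonomic_config()]; defaults to the canine preset) and optional
#'   `artifact_cfg`.
#' @param inputs For `"analyze"`: data frame with columns `subject`,
#'   `condition` (`"pre"`/`"post"`) and `path`, plus optional
#'   `record_start_clock`.
#' @param window `NULL` to analyze the full record, or a list with
#'   `start_clock`, `end_clock`, `start_day`, `end_day` passed to
#'   [select_window()].
#' @param rules [filter_rules()] for NN filtering.
#' @param fs Tachogram resampling rate, Hz.
#' @param psd_method `"periodogram"` or `"welch"`.
#' @param band_edges Spectral band edges, Hz.
#' @param prsa [prsa_config()] parameters as a list with `L` and
#'   `rel_threshold`.
#' @param digits Decimal places in the formatted results table.
#' @param output_dir Directory for the result bundle, or `NULL` to skip
#'   writing.
#' @param seed Integer seed; required in `"simulate"` mode.
#' @return A list of class `hrv_run_config`.
#' @export
hrv_config <- function(mode = c("simulate", "analyze"),
                       cohort = NULL, inputs = NULL, window = NULL,
                       rules = filter_rules(), fs = 4,
                       psd_method = c("periodogram", "welch"),
                       band_edges = DEFAULT_BAND_EDGES,
                       prsa = list(L = 5L, rel_threshold = 1.05),
                       digits = 2, output_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  psd_method <- match.arg(psd_method)
  if (mode == "simulate") {
    if (is.null(cohort)) cohort <- list()
    if (is.null(cohort$pre_cfg)) cohort$pre_cfg <- autonomic_config()
    if (is.null(cohort$n_subjects)) cohort$n_subjects <- 6L
    if (is.null(cohort$shift)) cohort$shift <- 0
    if (is.null(seed)) stop("simulate mode requires a seed")
  } else if (is.null(inputs)) {
    stop("analyze mode requires an inputs table (subject, condition, path)")
  }
  structure(list(mode = mode, cohort = cohort, inputs = inputs,
                 window = window, rules = rules, fs = fs,
                 psd_method = psd_method, band_edges = band_edges,
                 prsa = prsa, digits = digits, output_dir = output_dir,
                 seed = seed),
            class = "hrv_run_config")
}

# All indices for one recording. Returns the named value vector plus the
# intermediate objects needed for the optional exports.
subject_hrv_indices <- function(beats, config) {
  if (!is.null(config$window)) {
    w <- config$window
    beats <- select_window(beats, w$start_clock, w$end_clock,
                           w$start_day, w$end_day)
  }
  nn <- filter_nn(beats, config$rules)
  td <- time_domain_indices(nn)
  tach <- resample_tachogram(nn, fs = config$fs)
  psd <- estimate_psd(tach, config$psd_method)
  sp <- if (config$psd_method == "welch") {
    spectral_indices(nn, fs = config$fs, method = "welch",
                     edges = config$band_edges)
  } else {
    band_powers(psd, config$band_edges)
  }
  po <- poincare_indices(nn)
  cfg_dc <- prsa_config(config$prsa$L, "deceleration", config$prsa$rel_threshold)
  cfg_ac <- prsa_config(config$prsa$L, "acceleration", config$prsa$rel_threshold)
  dc <- prsa_indices(nn, cfg_dc)
  ac <- prsa_indices(nn, cfg_ac)
  values <- c(hr = td$mean_hr, sdnn = td$sdnn, rmssd = td$rmssd,
              tp = sp$tp, ulf = sp$ulf, vlf = sp$vlf, lf = sp$lf, hf = sp$hf,
              n_hf = sp$n_hf, lf_hf = sp$lf_hf,
              sd1 = po$sd1, sd2 = po$sd2,
              sd1_sd2 = po$sd1_sd2, sd2_sd1 = po$sd2_sd1,
              ac = ac$capacity, dc = dc$capacity)
  list(values = values, nn = nn, psd = psd, prsa_dc = dc, prsa_ac = ac)
}

#' Run the HRV pipeline end to end
#'
#' For each subject and condition: window selection, NN filtering, time-domain
#' indices, spectral indices, Poincaré descriptors and PRSA capacities; then a
#' per-index paired Pre/Post comparison with the exact Wilcoxon signed-rank
#' test. A stage failure aborts only the affected subject (with a warning
#' naming subject and condition); the comparison requires at least 2 complete
#' subjects.
#'
#' With `output_dir` set, writes `results_table.csv`, `indices_long.csv`,
#' `manifest.json` and per-recording `psd/` and `prsa/` exports. The manifest
#' echoes the configuration, seed, package version and per-recording rejected
#' beat counts; no timestamps, so identical configuration and seed give a
#' byte-identical bundle.
#'
#' @param config An [hrv_config()].
#' @return A list of class `hrv_result`: `indices` (long data frame:
#'   `subject`, `condition`, `index`, `value`), `comparisons` (named list of
#'   [paired_comparison()]), `table` (from [results_table()]), `n_complete`,
#'   `manifest`.
#' @export
hrv_run <- function(config) {
  stopifnot(inherits(config, "hrv_run_config"))
  recordings <- gather_recordings(config)

  per_subject <- list()
  rejected <- list()
  for (subj in names(recordings)) {
    vals <- list()
    for (cond in c("pre", "post")) {
      res <- tryCatch(
        subject_hrv_indices(recordings[[subj]][[cond]], config),
        error = function(e) {
          warning(sprintf("subject %s (%s) failed: %s",
                          subj, cond, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(res)) break
      vals[[cond]] <- res
      rejected[[paste(subj, cond, sep = "_")]] <- res$nn$n_rejected
    }
    if (length(vals) == 2L) per_subject[[subj]] <- vals
  }
  if (length(per_subject) < 2L) {
    stop("fewer than 2 complete subjects; paired comparison aborted")
  }

  idx_names <- names(HRV_INDEX_UNITS)
  long <- do.call(rbind, lapply(names(per_subject), function(subj) {
    do.call(rbind, lapply(c("pre", "post"), function(cond) {
      data.frame(subject = subj, condition = cond, index = idx_names,
                 value = unname(per_subject[[subj]][[cond]]$values[idx_names]),
                 stringsAsFactors = FALSE)
    }))
  }))

  comparisons <- lapply(idx_names, function(ix) {
    pre <- vapply(per_subject, function(s) s$pre$values[[ix]], numeric(1))
    post <- vapply(per_subject, function(s) s$post$values[[ix]], numeric(1))
    tryCatch(paired_comparison(ix, pre, post, units = HRV_INDEX_UNITS[[ix]]),
             error = function(e) NULL)
  })
  names(comparisons) <- idx_names
  comparisons <- Filter(Negate(is.null), comparisons)
  table <- results_table(comparisons, digits = config$digits)

  manifest <- list(
    mode = config$mode, seed = config$seed,
    n_subjects = length(per_subject),
    subjects = names(per_subject),
    window = config$window,
    filter_rules = unclass(config$rules),
    fs = config$fs, psd_method = config$psd_method,
    band_edges = config$band_edges, prsa = config$prsa,
    n_rejected = rejected,
    package_version = as.character(utils::packageVersion("caninehrv")))

  result <- structure(list(indices = long, comparisons = comparisons,
                           table = table, n_complete = length(per_subject),
                           manifest = manifest, per_subject = per_subject),
                      class = "hrv_result")
  if (!is.null(config$output_dir)) write_bundle(result, config$output_dir)
  result
}

gather_recordings <- function(config) {
  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$cohort$pre_cfg, config$cohort$shift,
                              config$cohort$n_subjects, config$seed,
                              artifact_cfg = config$cohort$artifact_cfg)
    names(cohort) <- sprintf("S%02d", seq_along(cohort))
    lapply(cohort, function(s) list(pre = s$pre, post = s$post))
  } else {
    inputs <- config$inputs
    stopifnot(all(c("subject", "condition", "path") %in% names(inputs)))
    recs <- list()
    for (i in seq_len(nrow(inputs))) {
      clock <- if ("record_start_clock" %in% names(inputs))
        inputs$record_start_clock[i] else "00:00"
      subj <- as.character(inputs$subject[i])
      cond <- match.arg(tolower(inputs$condition[i]), c("pre", "post"))
      beats <- tryCatch(
        read_beats(inputs$path[i], record_start_clock = clock),
        error = function(e) {
          warning(sprintf("subject %s (%s) failed to read: %s",
                          subj, cond, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(beats)) recs[[subj]][[cond]] <- beats
    }
    incomplete <- vapply(recs, function(r) length(r) < 2L, logical(1))
    if (any(incomplete)) {
      warning(sprintf("dropping subject(s) without both conditions: %s",
                      paste(names(recs)[incomplete], collapse = ", ")),
              call. = FALSE)
      recs <- recs[!incomplete]
    }
    recs
  }
}

write_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "psd"), showWarnings = FALSE)
  dir.create(file.path(dir, "prsa"), showWarnings = FALSE)
  utils::write.csv(result$table, file.path(dir, "results_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$indices, file.path(dir, "indices_long.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (subj in names(result$per_subject)) {
    for (cond in c("pre", "post")) {
      rec <- result$per_subject[[subj]][[cond]]
      base <- paste(subj, cond, sep = "_")
      write_psd(rec$psd, file.path(dir, "psd", paste0(base, ".csv")))
      write_prsa(rec$prsa_dc, file.path(dir, "prsa", paste0(base, "_dc.csv")))
      write_prsa(rec$prsa_ac, file.path(dir, "prsa", paste0(base, "_ac.csv")))
    }
  }
  invisible(dir)
}

#' @export
print.hrv_result <- function(x, ...) {
  cat(sprintf("<hrv_result> %d complete subjects\n", x$n_complete))
  print(x$table, row.names = FALSE)
  invisible(x)
}
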