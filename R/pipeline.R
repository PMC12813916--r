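#' Write a cohort to disk
#'
#' Serializes a cohort as a participant-level CSV (one row per subject), a
#' long traces CSV (`id`, `time_ms`, `strain_pct`), and optionally the
#' generator configuration as JSON. All files are UTF-8 with a header row
#' and '.' as decimal separator; reading them back with [read_cohort()]
#' reproduces every field.
#'
#' @param cohort A [generate_cohort()] result.
#' @param participants_path,traces_path,config_path Output CSV/CSV/JSON
#'   paths (`config_path = NULL` skips the config).
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, participants_path, traces_path,
                         config_path = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  if (is.null(df)) df <- data.frame(id = character())
  utils::write.csv(df, participants_path, row.names = FALSE)
  traces <- do.call(rbind, lapply(unclass(cohort), function(r)
    data.frame(id = r$id, time_ms = r$strain$time,
               strain_pct = r$strain$strain)))
  if (is.null(traces)) traces <- data.frame(id = character(),
                                            time_ms = numeric(),
                                            strain_pct = numeric())
  utils::write.csv(traces, traces_path, row.names = FALSE)
  if (!is.null(config_path)) {
    cfg <- attr(cohort, "config")
    jsonlite::write_json(unclass(cfg), config_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(c(participants_path, traces_path, config_path))
}

cohort_required_columns <- c("id", "age", "sex", "sbp_sitting", "heart_rate",
                             "cycle_length", "mvc", "avo", "avc", "mvo",
                             "frame_rate", "cycle_length_mod1",
                             "cycle_length_mod2")

#' Read a cohort from disk
#'
#' Rebuilds [participant_record()] objects from the participant-level and
#' traces CSVs written by [write_cohort()]. Malformed input fails loudly:
#' missing required columns are reported by name, and a trace whose times
#' are not strictly increasing is rejected with its participant id.
#'
#' @param participants_path,traces_path CSV paths.
#' @return An object of class `cohort`.
#' @export
read_cohort <- function(participants_path, traces_path) {
  df <- utils::read.csv(participants_path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_columns, names(df))
  if (length(missing))
    stopf("cohort file '%s' is missing required column(s): %s",
          participants_path, paste(missing, collapse = ", "))
  traces <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
  tmissing <- setdiff(c("id", "time_ms", "strain_pct"), names(traces))
  if (length(tmissing))
    stopf("traces file '%s' is missing required column(s): %s",
          traces_path, paste(tmissing, collapse = ", "))
  has_idx <- all(c("gwi", "gcw", "gww", "gwe") %in% names(df))
  records <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tr <- traces[traces$id == row$id, , drop = FALSE]
    if (nrow(tr) == 0L) stopf("no trace found for participant '%s'", row$id)
    if (any(diff(tr$time_ms) <= 0))
      stopf("trace for participant '%s' has non-increasing times", row$id)
    participant_record(
      id = row$id, age = row$age, sex = row$sex,
      sbp_sitting = row$sbp_sitting, heart_rate = row$heart_rate,
      cycle_length = row$cycle_length,
      valve_events = valve_events(row$mvc, row$avo, row$avc, row$mvo),
      strain = strain_trace(tr$time_ms, tr$strain_pct, id = row$id,
                            cycle_length = row$cycle_length),
      frame_rate = row$frame_rate,
      gls = if ("gls" %in% names(df)) row$gls,
      modality_cycle_lengths = c(row$cycle_length_mod1,
                                 row$cycle_length_mod2),
      indices = if (has_idx) list(gwi = row$gwi, gcw = row$gcw,
                                  gww = row$gww, gwe = row$gwe))
  })
  structure(records, class = "cohort")
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic cohort (or
#' input files), QC thresholds, the pressure template, loop-shape comparison
#' options, and the per-variable reference-interval method map. The default
#' method map mirrors the reporting convention of the reference population:
#' normal intervals for the approximately Gaussian GWI/GCW/GLS, percentile
#' intervals for the skewed GWW/GWE/SBP/heart rate.
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param cohort A [cohort_config()] for simulation, or `NULL` when reading
#'   an existing cohort from `participants_path`/`traces_path`.
#' @param participants_path,traces_path Optional input CSVs (used when
#'   `cohort` is `NULL`).
#' @param thresholds A [qc_thresholds()] list.
#' @param template A [pressure_template()].
#' @param pressure_samples Samples of the pressure grid per cycle.
#' @param n_perm,perm_seed,loop_mode,standardize Loop-shape permutation
#'   options (see [permutation_test()]); `loop_groups = NULL` splits QC-passing
#'   participants at the median age.
#' @param loop_groups Optional function mapping the participant table to a
#'   two-level group label.
#' @param ri_methods Named character map from index name to
#'   reference-interval method.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            cohort = cohort_config(n = 200, seed = 1L),
                            participants_path = NULL, traces_path = NULL,
                            thresholds = qc_thresholds(),
                            template = pressure_template(),
                            pressure_samples = 1000L,
                            n_perm = 200L, perm_seed = 271828L,
                            loop_mode = "age_group", standardize = FALSE,
                            loop_groups = NULL,
                            ri_methods = c(gwi = "normal", gcw = "normal",
                                           gww = "percentile",
                                           gwe = "percentile")) {
  if (!is.character(output_dir) || length(output_dir) != 1L)
    stopf("'output_dir' must be a single path")
  for (f in c("sbp_max", "beat_timing_max", "hr_variation_max"))
    if (!is_number(thresholds[[f]]) || thresholds[[f]] < 0)
      stopf("QC threshold '%s' must be a non-negative number", f)
  structure(list(output_dir = output_dir, cohort = cohort,
                 participants_path = participants_path,
                 traces_path = traces_path, thresholds = thresholds,
                 template = template, pressure_samples = pressure_samples,
                 n_perm = n_perm, perm_seed = perm_seed,
                 loop_mode = loop_mode, standardize = standardize,
                 loop_groups = loop_groups, ri_methods = ri_methods),
            class = "pipeline_config")
}

stage_record <- function(stage, n_in, n_out, ...) {
  c(list(stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         n_in = n_in, n_out = n_out, n_excluded = n_in - n_out), list(...))
}

#' Run the full myocardial work pipeline
#'
#' Executes simulate (or load) -> quality control -> pressure estimation ->
#' work indices -> loop-shape comparison -> reference intervals, writing
#' every artifact under `config$output_dir`:
#' `cohort.csv` / `traces.csv` / `cohort_config.json` (inputs),
#' `indices.csv` (one row per QC-passing participant, signal-pipeline
#' indices), `loopshape.json` (permutation test between the two age groups),
#' `refranges.json` (reference intervals per index), and `runlog.jsonl`
#' (one JSON record per stage with in/out/excluded counts, which always
#' balance). A failure in any stage aborts with the stage name and the
#' offending participant id.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `log` (stage records), `files` (artifact
#'   paths), `indices` (the computed table) and `loopshape` (the
#'   [permutation_test()] result, or `NULL` if a group was too small).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log <- list()

  # stage 1: obtain cohort
  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, out("cohort.csv"), out("traces.csv"),
                 out("cohort_config.json"))
  } else {
    if (is.null(config$participants_path) || is.null(config$traces_path))
      stopf("stage simulate: no cohort config and no input paths given")
    cohort <- read_cohort(config$participants_path, config$traces_path)
  }
  n0 <- length(cohort)
  log$simulate <- stage_record("simulate", n0, n0,
                               seed = attr(cohort, "config")$seed %||% NA)

  # stage 2: quality control
  qc <- lapply(unclass(cohort), apply_qc, thresholds = config$thresholds)
  passed <- vapply(qc, function(q) q$passed, logical(1))
  reason_tab <- table(unlist(lapply(qc, function(q) q$reasons)))
  log$qc <- stage_record("qc", n0, sum(passed),
                         reasons = as.list(reason_tab))
  kept <- unclass(cohort)[passed]

  # stage 3: pressure + work indices
  rows <- lapply(kept, function(r) {
    tryCatch({
      p <- estimate_pressure(r$sbp_sitting, r$valve_events, r$cycle_length,
                             n_samples = config$pressure_samples,
                             template = config$template)
      wi <- work_indices(r$strain, p, r$valve_events)
      data.frame(id = r$id, age = r$age, sex = r$sex, gwi = wi$gwi,
                 gcw = wi$gcw, gww = wi$gww, gwe = wi$gwe,
                 qc_passed = TRUE, stringsAsFactors = FALSE)
    }, error = function(e)
      stopf("stage work_indices failed for participant '%s': %s",
            r$id, conditionMessage(e)))
  })
  indices <- if (length(rows)) do.call(rbind, rows)
  else data.frame(id = character(), age = numeric(), sex = character(),
                  gwi = numeric(), gcw = numeric(), gww = numeric(),
                  gwe = numeric(), qc_passed = logical())
  utils::write.csv(indices, out("indices.csv"), row.names = FALSE)
  log$work <- stage_record("work", sum(passed), nrow(indices))

  # stage 4: loop-shape comparison between two age groups
  loopshape <- NULL
  if (nrow(indices) >= 4L) {
    grp <- if (is.null(config$loop_groups)) {
      split_age <- stats::median(indices$age)
      factor(ifelse(indices$age <= split_age, "younger", "older"),
             levels = c("younger", "older"))
    } else config$loop_groups(indices)
    if (nlevels(droplevels(factor(grp))) == 2L && min(table(grp)) >= 2L) {
      loops <- lapply(kept, function(r) {
        p <- estimate_pressure(r$sbp_sitting, r$valve_events,
                               r$cycle_length,
                               n_samples = config$pressure_samples,
                               template = config$template)
        resample_loop(r$strain, p, r$valve_events,
                      cycle_length = r$cycle_length)
      })
      loopshape <- permutation_test(loops, grp, n_perm = config$n_perm,
                                    seed = config$perm_seed,
                                    mode = config$loop_mode,
                                    standardize = config$standardize)
      jsonlite::write_json(
        list(observed = loopshape$observed, p_dtw = loopshape$p_dtw,
             p_procrustes = loopshape$p_procrustes,
             p_combined = loopshape$p_combined, mode = loopshape$mode,
             n_perm = loopshape$n_perm, seed = loopshape$seed,
             groups = as.list(table(grp))),
        out("loopshape.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  log$loopshape <- stage_record("loopshape", nrow(indices),
                                if (is.null(loopshape)) 0L else nrow(indices))

  # stage 5: reference intervals on the computed indices
  refranges <- NULL
  if (nrow(indices) >= 2L) {
    refranges <- lapply(names(config$ri_methods), function(v) {
      ri <- reference_interval(indices[[v]], config$ri_methods[[v]])
      list(variable = v, lower = ri$lower, upper = ri$upper,
           method = ri$method, n = ri$n)
    })
    jsonlite::write_json(refranges, out("refranges.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log$refranges <- stage_record("refranges", nrow(indices),
                                if (is.null(refranges)) 0L else nrow(indices))

  writeLines(vapply(log, function(rec)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), character(1)),
    out("runlog.jsonl"))
  invisible(list(log = log, indices = indices, loopshape = loopshape,
                 files = vapply(c("cohort.csv", "traces.csv", "indices.csv",
                                  "runlog.jsonl"), out, character(1))))
}
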